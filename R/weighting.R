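#' Boltzmann population weights for a conformer ensemble
#'
#' Weights w_i proportional to exp(-(E_i - E_min) / RT); the shift by the
#' minimum energy is for numerical stability and does not change the
#' weights.
#'
#' @param energies Conformer energies, kcal/mol.
#' @param temperature Temperature in Kelvin (default 298.15).
#' @param gas_constant R in kcal/(mol K); default 1.987204e-3.
#' @return Object of class `boltzmann_weights`: fields `weights` (sum 1),
#'   `temperature`, `gas_constant`.
#' @export
#' @examples
#' boltzmann_weights(c(0, 0.5, 1.3))$weights
boltzmann_weights <- function(energies, temperature = 298.15,
                              gas_constant = 1.987204e-3) {
  energies <- as.numeric(energies)
  if (length(energies) == 0 || any(!is.finite(energies)))
    abort("`energies` must be a non-empty finite numeric vector.")
  if (!is.numeric(temperature) || temperature <= 0)
    abort("`temperature` must be positive.")
  x <- exp(-(energies - min(energies)) / (gas_constant * temperature))
  structure(
    list(weights = x / sum(x), temperature = temperature,
         gas_constant = gas_constant),
    class = "boltzmann_weights"
  )
}

#' @export
print.boltzmann_weights <- function(x, ...) {
  cat(sprintf("<boltzmann_weights> %d conformers at %.2f K; max weight %.3f\n",
              length(x$weights), x$temperature, max(x$weights)))
  invisible(x)
}

#' @export
as.numeric.boltzmann_weights <- function(x, ...) x$weights

#' Aggregate per-conformer features into conformer-weighted statistics
#'
#' For each feature, computes the five conformer-weighted statistics:
#' Boltzmann-weighted average, minimum, maximum, arithmetic mean, and the
#' value of the lowest-energy conformer.  Features missing (NA) in some
#' conformers are aggregated over the present subset with re-normalized
#' weights, with a warning.
#'
#' @param records Tibble of per-conformer feature values (one row per
#'   conformer; non-numeric columns and an `energy` column are ignored), as
#'   from [describe_ensemble()].
#' @param weights A [boltzmann_weights()] aligned with the rows of `records`.
#' @param energies Conformer energies aligned with the rows (used for the
#'   lowest-energy statistic).
#' @param ligand_id Identifier recorded on the result.
#' @return A tibble of class `aggregated_features`: columns `feature`,
#'   `boltzmann`, `min`, `max`, `mean`, `lowest`; attribute `ligand_id`.
#' @export
aggregate_features <- function(records, weights, energies,
                               ligand_id = "ligand") {
  tbl <- tibble::as_tibble(records)
  if (nrow(tbl) == 0) abort("`records` has zero rows.")
  if (inherits(weights, "boltzmann_weights")) weights <- weights$weights
  weights <- as.numeric(weights)
  if (length(weights) != nrow(tbl) || length(energies) != nrow(tbl))
    abort("`records`, `weights` and `energies` must be aligned by conformer.")
  tbl <- tbl[setdiff(names(tbl), c("conformer_id", "energy"))]
  tbl <- tbl[vapply(tbl, is.numeric, logical(1))]
  if (ncol(tbl) == 0) abort("`records` has no numeric feature columns.")
  lowest_idx <- order(as.numeric(energies), seq_len(nrow(tbl)))[1]
  incomplete <- character()
  rows <- purrr::map_dfr(names(tbl), function(f) {
    v <- tbl[[f]]
    ok <- !is.na(v)
    if (!all(ok)) incomplete <<- c(incomplete, f)
    if (!any(ok))
      return(tibble(feature = f, boltzmann = NA_real_, min = NA_real_,
                    max = NA_real_, mean = NA_real_, lowest = NA_real_))
    w <- weights[ok] / sum(weights[ok])
    tibble(
      feature = f,
      boltzmann = sum(w * v[ok]),
      min = min(v[ok]),
      max = max(v[ok]),
      mean = mean(v[ok]),
      lowest = if (is.na(v[lowest_idx])) NA_real_ else v[lowest_idx]
    )
  })
  if (length(incomplete) > 0)
    warn(paste0("Features aggregated over a conformer subset (missing values): ",
                paste(unique(incomplete), collapse = ", ")))
  structure(rows, ligand_id = as.character(ligand_id),
            class = c("aggregated_features", class(rows)))
}

#' Aggregate an ensemble end to end
#'
#' Convenience wrapper: Boltzmann weights from the ensemble energies, then
#' [aggregate_features()] on a feature table (computed with
#' [describe_ensemble()] if not supplied).
#'
#' @param ensemble A [conformer_ensemble()].
#' @param records Optional precomputed feature tibble (one row per
#'   conformer).
#' @param temperature Kelvin.
#' @param ... Passed to [describe_ensemble()] when `records` is `NULL`.
#' @return An `aggregated_features` tibble.
#' @export
aggregate_ensemble <- function(ensemble, records = NULL,
                               temperature = 298.15, ...) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (is.null(records)) records <- describe_ensemble(ensemble, ...)
  en <- ensemble_energies(ensemble)
  aggregate_features(records, boltzmann_weights(en, temperature), en,
                     ligand_id = ensemble$ligand_id)
}

#' Drop redundant conformer statistics for conformation-insensitive features
#'
#' Features whose value barely varies across any ligand's ensemble carry no
#' conformational information, so only their Boltzmann-weighted average is
#' retained; conformation-sensitive features keep all five statistics.  The
#' dispersion statistic per feature is the maximum over ligands of
#' (max - min) / max(|mean|, eps).
#'
#' @param tables A list of `aggregated_features` (one per ligand), or a
#'   single long tibble with a `ligand_id` column plus the
#'   `feature`/`boltzmann`/`min`/`max`/`mean`/`lowest` columns.
#' @param threshold Relative-dispersion threshold below which a feature is
#'   treated as conformation-insensitive (default 0.01).
#' @param eps Denominator floor.
#' @return List of class `variance_filter`: `table` (the long tibble),
#'   `report` (per feature: `dispersion`, `retained_stats`, `n_stats`),
#'   `threshold`, and the total column counts `n_before`/`n_after` of the
#'   implied wide expansion.
#' @export
variance_filter <- function(tables, threshold = 0.01, eps = 1e-8) {
  long <- combine_aggregated(tables)
  stats <- c("boltzmann", "min", "max", "mean", "lowest")
  report <- long |>
    dplyr::group_by(.data$feature, .data$ligand_id) |>
    dplyr::summarise(
      disp = (max(.data$max) - min(.data$min)) /
        pmax(abs(mean(.data$mean)), eps),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(dispersion = max(.data$disp), .groups = "drop") |>
    dplyr::mutate(
      retained_stats = purrr::map(.data$dispersion, function(d)
        if (is.na(d) || d < threshold) "boltzmann" else stats),
      n_stats = lengths(.data$retained_stats)
    )
  structure(
    list(table = long, report = report, threshold = threshold,
         n_before = 5L * nrow(report), n_after = sum(report$n_stats)),
    class = "variance_filter"
  )
}

# accepts a list of aggregated_features or an already-long tibble
combine_aggregated <- function(tables) {
  if (inherits(tables, "aggregated_features")) tables <- list(tables)
  if (is.list(tables) && !is.data.frame(tables)) {
    long <- purrr::map_dfr(tables, function(t) {
      dplyr::mutate(tibble::as_tibble(t),
                    ligand_id = attr(t, "ligand_id") %||% "ligand",
                    .before = 1)
    })
  } else {
    long <- tibble::as_tibble(tables)
  }
  need <- c("ligand_id", "feature", "boltzmann", "min", "max", "mean", "lowest")
  if (!all(need %in% names(long)))
    abort(paste0("Aggregated table needs columns: ",
                 paste(need, collapse = ", ")))
  if (nrow(long) == 0) abort("Need at least one ligand.")
  long
}

#' @export
print.variance_filter <- function(x, ...) {
  kept <- sum(x$report$n_stats == 1)
  cat(sprintf("<variance_filter> threshold %.3g: %d of %d features reduced to Boltzmann-only (%d -> %d columns)\n",
              x$threshold, kept, nrow(x$report), x$n_before, x$n_after))
  invisible(x)
}

#' Widen aggregated features into a ligand-by-feature-statistic table
#'
#' Builds the modelling design table: one row per ligand, one column per
#' retained feature statistic, named `<feature>_<stat>` with stat suffixes
#' `boltz`, `min`, `max`, `mean`, `lowest`.
#'
#' @param tables As in [variance_filter()].
#' @param filter Optional `variance_filter` result; only retained statistics
#'   are emitted.
#' @param stats Statistics to include when `filter` is `NULL`.
#' @return Wide tibble with a `ligand_id` column.
#' @export
pivot_aggregated <- function(tables, filter = NULL,
                             stats = c("boltzmann", "min", "max", "mean",
                                       "lowest")) {
  long <- combine_aggregated(tables)
  suffix <- c(boltzmann = "boltz", min = "min", max = "max", mean = "mean",
              lowest = "lowest")
  keep <- if (!is.null(filter)) {
    stopifnot(inherits(filter, "variance_filter"))
    setNames(filter$report$retained_stats, filter$report$feature)
  } else NULL
  narrow <- long |>
    tidyr::pivot_longer(dplyr::all_of(names(suffix)),
                        names_to = "stat", values_to = "value")
  if (!is.null(keep)) {
    narrow <- narrow |>
      dplyr::filter(purrr::map2_lgl(.data$feature, .data$stat,
                                    function(f, s) s %in% (keep[[f]] %||% character())))
  } else {
    narrow <- dplyr::filter(narrow, .data$stat %in% stats)
  }
  narrow |>
    dplyr::mutate(column = paste0(.data$feature, "_", suffix[.data$stat])) |>
    dplyr::select("ligand_id", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
}

#' Compare two feature tables (e.g. semiempirical vs DFT-refined structures)
#'
#' For each shared feature, reports the mean absolute percent difference over
#' ligands, 100 |a - b| / |b| with `b` the reference set (pairs with |b|
#' below `eps` are dropped and counted), plus the ordinary least-squares
#' regression of `a` on `b` (slope, intercept, R squared).
#'
#' @param a Wide tibble `ligand_id` x features (the set under test).
#' @param b Wide tibble with the same layout (the reference set).
#' @param eps Denominator floor below which a pair is dropped.
#' @return Tibble: `feature`, `mean_abs_pct_diff`, `n_used`, `n_dropped`,
#'   `slope`, `intercept`, `r_squared`.
#' @export
compare_sets <- function(a, b, eps = 1e-8) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  if (!all(c("ligand_id") %in% names(a)) || !"ligand_id" %in% names(b))
    abort("Both tables need a ligand_id column.")
  common_lig <- intersect(a$ligand_id, b$ligand_id)
  if (length(common_lig) == 0) abort("No common ligands between the two tables.")
  feats <- intersect(setdiff(names(a), "ligand_id"),
                     setdiff(names(b), "ligand_id"))
  feats <- feats[vapply(feats, function(f)
    is.numeric(a[[f]]) && is.numeric(b[[f]]), logical(1))]
  if (length(feats) == 0) abort("No shared numeric feature columns.")
  ai <- match(common_lig, a$ligand_id)
  bi <- match(common_lig, b$ligand_id)
  purrr::map_dfr(feats, function(f) {
    x <- b[[f]][bi]  # reference
    y <- a[[f]][ai]
    ok <- !is.na(x) & !is.na(y)
    usable <- ok & abs(x) >= eps
    pct <- if (any(usable)) mean(100 * abs(y[usable] - x[usable]) / abs(x[usable]))
           else NA_real_
    if (sum(ok) >= 2 && stats::var(x[ok]) > 0) {
      fit <- lm(y[ok] ~ x[ok])
      co <- coef(fit)
      sst <- sum((y[ok] - mean(y[ok]))^2)
      r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
    } else {
      co <- c(NA_real_, NA_real_); r2 <- NA_real_
    }
    tibble(feature = f, mean_abs_pct_diff = pct,
           n_used = sum(usable), n_dropped = sum(ok) - sum(usable),
           slope = unname(co[2]), intercept = unname(co[1]), r_squared = r2)
  })
}
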