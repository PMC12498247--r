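#' Equidistant conformer selection along a feature axis
#'
#' Selects up to `n` conformers so the chosen feature values cover the
#' ensemble range evenly: the minimum and maximum are always targets, with
#' evenly spaced target values in between; each target takes the closest
#' not-yet-selected conformer (ties broken by lower energy, then lower
#' index).  If the lowest-energy conformer is not among the selection it is
#' appended, so the result holds at most `n + 1` conformers.
#'
#' @param values Numeric feature value per conformer (the selection axis).
#' @param energies Numeric energy per conformer, kcal/mol.
#' @param n Number of equidistant targets (>= 2); default 10.
#' @param include_lowest Append the lowest-energy conformer when missed.
#' @param feature Name recorded for the selection axis.
#' @return An object of class `conformer_selection` with fields `selected`
#'   (1-based indices, in target order), `targets`, `selection_feature`,
#'   `lowest_energy_added`, `n_requested`, plus the input `values` and
#'   `energies`.
#' @export
#' @examples
#' sel <- select_equidistant(values = 0:19, energies = (0:19) / 10, n = 10)
#' sort(sel$selected)
select_equidistant <- function(values, energies, n = 10,
                               include_lowest = TRUE, feature = "feature") {
  values <- as.numeric(values)
  energies <- as.numeric(energies)
  m <- length(values)
  if (m == 0 || length(energies) != m)
    abort("`values` and `energies` must be non-empty and of equal length.")
  if (any(!is.finite(values)) || any(!is.finite(energies)))
    abort("`values` and `energies` must be finite.")
  if (!is.numeric(n) || n < 2) abort("`n` must be at least 2.")
  n <- as.integer(n)

  new_sel <- function(selected, targets, added) {
    structure(
      list(selected = selected, targets = targets, selection_feature = feature,
           lowest_energy_added = added, n_requested = n,
           values = values, energies = energies),
      class = "conformer_selection"
    )
  }

  if (m <= n)
    return(new_sel(seq_len(m),
                   seq(min(values), max(values), length.out = min(n, m)),
                   added = FALSE))

  rng <- range(values)
  if (diff(rng) == 0) {
    warn("All feature values identical; falling back to the n lowest-energy conformers.")
    sel <- order(energies, seq_len(m))[seq_len(n)]
    return(new_sel(sel, rep(values[1], n), added = FALSE))
  }

  targets <- seq(rng[1], rng[2], length.out = n)
  selected <- integer(0)
  for (t in targets) {
    cand <- setdiff(seq_len(m), selected)
    dv <- abs(values[cand] - t)
    # tie chain: closest value, then lower energy, then lower index
    pick <- cand[order(dv, energies[cand], cand)][1]
    selected <- c(selected, pick)
  }
  added <- FALSE
  if (include_lowest) {
    lowest <- order(energies, seq_len(m))[1]
    if (!(lowest %in% selected)) {
      selected <- c(selected, lowest)
      added <- TRUE
    }
  }
  new_sel(selected, targets, added)
}

#' Energy-based equidistant selection
#'
#' The baseline selection: equidistant targets along the conformer energy
#' axis itself (so the lowest-energy conformer is automatically an
#' endpoint).
#'
#' @param energies Numeric energies, kcal/mol.
#' @param n Number of targets (default 10).
#' @return A `conformer_selection` (see [select_equidistant()]).
#' @export
select_by_energy <- function(energies, n = 10) {
  select_equidistant(values = energies, energies = energies, n = n,
                     include_lowest = TRUE, feature = "energy")
}

#' Select conformers of an ensemble by a feature column
#'
#' Convenience wrapper: runs [select_equidistant()] on one column of a
#' feature table (as produced by [describe_ensemble()]) or on the ensemble
#' energies, and returns both the selection and the pruned ensemble.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param by `"energy"` or the name of a numeric column in `features`.
#' @param features Feature tibble aligned with the ensemble (row i =
#'   conformer i); required unless `by = "energy"`.
#' @param n Number of targets.
#' @return List with `selection` (a `conformer_selection`) and `ensemble`
#'   (the pruned [conformer_ensemble()]).
#' @export
select_conformers <- function(ensemble, by = "energy", features = NULL,
                              n = 10) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  en <- ensemble_energies(ensemble)
  if (identical(by, "energy")) {
    sel <- select_by_energy(en, n = n)
  } else {
    if (is.null(features) || !by %in% names(features))
      abort(paste0("Feature ", dQuote(by), " not found in `features`."))
    if (nrow(features) != n_conformers(ensemble))
      abort("`features` must have one row per conformer.")
    sel <- select_equidistant(features[[by]], en, n = n, feature = by)
  }
  list(selection = sel, ensemble = subset_ensemble(ensemble, sel$selected))
}

#' Coverage of the full ensemble by a selection
#'
#' For each feature, reports how much of the full-ensemble range the selected
#' conformers span: `range_fraction` = (selected max - selected min) /
#' (full max - full min), with 1 by convention when the full range is
#' degenerate.
#'
#' @param selection A `conformer_selection`.
#' @param feature_table Data frame of per-conformer feature values (row i =
#'   conformer i of the same ensemble); non-numeric columns and columns named
#'   `conformer_id`/`energy` are ignored.
#' @return Tibble with columns `feature`, `range_fraction`, `sel_min`,
#'   `sel_max`, `full_min`, `full_max`.
#' @export
coverage_metrics <- function(selection, feature_table) {
  stopifnot(inherits(selection, "conformer_selection"))
  tbl <- tibble::as_tibble(feature_table)
  tbl <- tbl[setdiff(names(tbl), c("conformer_id", "energy"))]
  tbl <- tbl[vapply(tbl, is.numeric, logical(1))]
  if (nrow(tbl) != length(selection$values))
    abort("`feature_table` must have one row per conformer of the selection.")
  idx <- selection$selected
  purrr::map_dfr(names(tbl), function(f) {
    v <- tbl[[f]]
    full <- range(v)
    sel <- range(v[idx])
    rf <- if (diff(full) == 0) 1 else (diff(sel) / diff(full))
    tibble(feature = f, range_fraction = rf,
           sel_min = sel[1], sel_max = sel[2],
           full_min = full[1], full_max = full[2])
  })
}

#' @export
print.conformer_selection <- function(x, ...) {
  cat(sprintf("<conformer_selection> %d of %d conformers by %s (n = %d%s)\n",
              length(x$selected), length(x$values), x$selection_feature,
              x$n_requested,
              if (x$lowest_energy_added) " + lowest-energy" else ""))
  cat("  selected:", paste(sort(x$selected), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.conformer_selection <- function(x, ...) {
  lowest <- order(x$energies, seq_along(x$energies))[1]
  tibble(
    index = seq_along(x$values),
    value = x$values,
    energy = x$energies,
    selected = seq_along(x$values) %in% x$selected,
    is_lowest_energy = seq_along(x$values) == lowest
  )
}

#' @export
glance.conformer_selection <- function(x, ...) {
  tibble(
    feature = x$selection_feature,
    n_requested = x$n_requested,
    n_selected = length(x$selected),
    n_total = length(x$values),
    lowest_energy_added = x$lowest_energy_added
  )
}
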