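#' Substituent pattern for toy complexes
#'
#' Dummy single-atom substituents attached to each phosphorus donor; no
#' valence chemistry, just spheres, which is all the sphere-based
#' descriptors need.
#'
#' @param p1,p2 Character vectors of element symbols attached to each P.
#' @param bond_length P-substituent distance, Angstrom.
#' @param splay Angle (degrees) between the Pd->P axis and each P->substituent
#'   bond (tetrahedral-like default).
#' @return List of class `substituent_pattern`.
#' @export
substituent_pattern <- function(p1 = c("C", "C", "C"), p2 = c("C", "C", "C"),
                                bond_length = 1.82, splay = 70.5) {
  structure(list(p1 = p1, p2 = p2, bond_length = bond_length, splay = splay),
            class = "substituent_pattern")
}

#' Build a toy PdCl2(P^P) complex with a prescribed bite angle
#'
#' Pd sits at the origin with the two phosphorus donors in the xy-plane at
#' the requested angle and Pd-P distance; the chlorides are placed trans to
#' the phosphines; dummy substituent atoms are attached to each P pointing
#' away from the metal.  [bite_angle()] on the result returns the requested
#' angle to machine precision.
#'
#' @param bite_angle Requested P-Pd-P angle, degrees, in (0, 180).
#' @param d_pdp Pd-P distance, Angstrom.
#' @param d_pdcl Pd-Cl distance, Angstrom.
#' @param pattern A [substituent_pattern()].
#' @param cl_angle Cl-Pd-Cl angle, degrees.
#' @param id,energy Passed to [conformer()].
#' @return A [conformer()] with atom order Pd, P, P, Cl, Cl, substituents.
#' @export
#' @examples
#' cf <- make_complex(95)
#' bite_angle(cf)
make_complex <- function(bite_angle, d_pdp = 2.3, d_pdcl = 2.35,
                         pattern = substituent_pattern(), cl_angle = 92,
                         id = "conf_0001", energy = 0) {
  if (!is.numeric(bite_angle) || bite_angle <= 0 || bite_angle >= 180)
    abort("`bite_angle` must be in (0, 180) degrees.")
  half <- bite_angle * pi / 360
  chalf <- cl_angle * pi / 360
  pd <- c(0, 0, 0)
  p <- list(d_pdp * c(cos(half), sin(half), 0),
            d_pdp * c(cos(half), -sin(half), 0))
  cl <- list(d_pdcl * c(-cos(chalf), sin(chalf), 0),
             d_pdcl * c(-cos(chalf), -sin(chalf), 0))
  splay <- pattern$splay * pi / 180
  subs <- list()
  sub_el <- character()
  for (k in 1:2) {
    els <- pattern[[paste0("p", k)]]
    if (length(els) == 0) next
    u <- p[[k]] / sqrt(sum(p[[k]]^2))
    v <- c(-u[2], u[1], 0)                      # in-plane perpendicular
    w <- c(0, 0, 1)
    # mirror the local frame for the second donor so equal patterns give an
    # exactly C2-symmetric complex
    s <- if (k == 1) 1 else -1
    for (j in seq_along(els)) {
      gamma <- 2 * pi * (j - 1) / length(els)
      dir <- cos(splay) * u +
        sin(splay) * (cos(gamma) * s * v + sin(gamma) * s * w)
      subs[[length(subs) + 1]] <- p[[k]] + pattern$bond_length * dir
      sub_el <- c(sub_el, els[j])
    }
  }
  xyz <- do.call(rbind, c(list(pd), p, cl, subs))
  el <- c("Pd", "P", "P", "Cl", "Cl", sub_el)
  d <- as.matrix(stats::dist(xyz))
  if (min(d[upper.tri(d)]) < 0.7)
    abort("Substituent pattern places atoms on top of one another.")
  conformer(tibble(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
            energy = energy, id = id, energy_method = "synthetic")
}

#' Specification for a synthetic conformer ensemble
#'
#' Describes a toy ensemble emulating a conformer-search output: bite angles
#' drawn from a normal distribution, substituent positions jittered, and
#' pseudo-energies either independent of the geometry or linear in the bite
#' angle, kept inside the energy window.
#'
#' @param n_conformers Ensemble size.
#' @param bite_mean,bite_sd Bite-angle distribution, degrees.
#' @param d_pdp,d_pdcl Core bond lengths, Angstrom.
#' @param pattern A [substituent_pattern()].
#' @param jitter_sd Gaussian jitter (Angstrom) applied to substituent atoms
#'   per conformer.
#' @param energy_model `"independent"` (uniform in the window, uncorrelated
#'   with geometry) or `"bite_linear"` (linear in bite angle plus noise).
#' @param energy_slope kcal/mol per degree, for `"bite_linear"`.
#' @param energy_noise_sd Energy noise, kcal/mol.
#' @param energy_window Window width, kcal/mol (default 5).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_conformers = 17, bite_mean = 95, bite_sd = 4,
                          d_pdp = 2.3, d_pdcl = 2.35,
                          pattern = substituent_pattern(), jitter_sd = 0.05,
                          energy_model = c("independent", "bite_linear"),
                          energy_slope = 0.5, energy_noise_sd = 0.5,
                          energy_window = 5, seed = 1L) {
  if (n_conformers < 1) abort("`n_conformers` must be at least 1.")
  if (bite_sd < 0 || jitter_sd < 0 || energy_noise_sd < 0)
    abort("Spread parameters must be non-negative.")
  if (energy_window <= 0) abort("`energy_window` must be positive.")
  structure(
    list(n_conformers = as.integer(n_conformers), bite_mean = bite_mean,
         bite_sd = bite_sd, d_pdp = d_pdp, d_pdcl = d_pdcl,
         pattern = pattern, jitter_sd = jitter_sd,
         energy_model = match.arg(energy_model),
         energy_slope = energy_slope, energy_noise_sd = energy_noise_sd,
         energy_window = energy_window, seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

#' Generate a synthetic conformer ensemble
#'
#' @param spec An [ensemble_spec()].
#' @param ligand_id Ligand identifier.
#' @return A [conformer_ensemble()] with energies relative to the minimum.
#' @export
make_ensemble <- function(spec, ligand_id = "toy_ligand") {
  stopifnot(inherits(spec, "ensemble_spec"))
  with_private_seed(spec$seed, {
    n <- spec$n_conformers
    bites <- pmin(179, pmax(1, rnorm(n, spec$bite_mean, spec$bite_sd)))
    e <- switch(spec$energy_model,
      independent = runif(n, 0, spec$energy_window),
      bite_linear = spec$energy_slope * (bites - min(bites)) +
        rnorm(n, 0, spec$energy_noise_sd)
    )
    e <- e - min(e)
    if (max(e) > spec$energy_window)
      e <- e * spec$energy_window / max(e)
    confs <- lapply(seq_len(n), function(i) {
      cf <- make_complex(bites[i], d_pdp = spec$d_pdp, d_pdcl = spec$d_pdcl,
                         pattern = spec$pattern,
                         id = sprintf("conf_%04d", i), energy = e[i])
      natom <- nrow(cf$atoms)
      if (spec$jitter_sd > 0 && natom > 5) {
        j <- 6:natom                      # substituents only; core stays exact
        cf$atoms$x[j] <- cf$atoms$x[j] + rnorm(length(j), 0, spec$jitter_sd)
        cf$atoms$y[j] <- cf$atoms$y[j] + rnorm(length(j), 0, spec$jitter_sd)
        cf$atoms$z[j] <- cf$atoms$z[j] + rnorm(length(j), 0, spec$jitter_sd)
      }
      cf
    })
    conformer_ensemble(confs, ligand_id = ligand_id,
                       energy_window = spec$energy_window)
  })
}

#' Ground-truth response rule for planted datasets
#'
#' Linear rule on named aggregated statistics:
#' y = sum_k coef_k * stat_k(feature_k) + noise.
#'
#' @param features Character vector of feature names (e.g. `"f1"`).
#' @param stats Statistic per term: `"boltzmann"`, `"min"`, `"max"`,
#'   `"mean"` or `"lowest"`.
#' @param coefs Numeric coefficients.
#' @param noise_sd Gaussian noise on y, kcal/mol.
#' @return List of class `response_rule` with a `terms` tibble.
#' @export
response_rule <- function(features, stats, coefs, noise_sd = 0.3) {
  stats <- match.arg(stats, c("boltzmann", "min", "max", "mean", "lowest"),
                     several.ok = TRUE)
  if (length(features) != length(stats) || length(features) != length(coefs))
    abort("`features`, `stats` and `coefs` must have equal length.")
  if (any(!is.finite(coefs))) abort("Coefficients must be finite.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(list(terms = tibble(feature = features, stat = stats,
                                coef = coefs),
                 noise_sd = noise_sd),
            class = "response_rule")
}

#' Specification for a planted-relationship modelling dataset
#'
#' Per ligand, a small synthetic ensemble is generated and `n_features`
#' pseudo-electronic conformer-level features are attached (ligand-level
#' mean drawn from N(0, 1), conformer-level spread drawn from the
#' `conformer_sd` range); the response follows the stated rule on the
#' aggregated statistics.
#'
#' @param n_ligands Number of ligands.
#' @param n_features Number of pseudo-electronic features (`f1`, `f2`, ...).
#' @param rule A [response_rule()].
#' @param n_conformers Range (min, max) of ensemble sizes.
#' @param conformer_sd Range of per-feature conformer-level standard
#'   deviations.
#' @param bite_mean,bite_sd Ranges for the per-ligand bite-angle
#'   distribution, degrees.
#' @param energy_window kcal/mol.
#' @param temperature Kelvin, for the Boltzmann statistics.
#' @param filter_threshold Optional [variance_filter()] threshold applied to
#'   the aggregated table; an error is raised if the rule references a
#'   statistic the filter drops.
#' @param seed RNG seed.
#' @return List of class `dataset_spec`.
#' @export
dataset_spec <- function(n_ligands = 42, n_features = 6,
                         rule = response_rule("f1", "max", 2),
                         n_conformers = c(8, 20), conformer_sd = c(0.2, 0.8),
                         bite_mean = c(85, 110), bite_sd = c(1, 4),
                         energy_window = 5, temperature = 298.15,
                         filter_threshold = NULL, seed = 1L) {
  stopifnot(inherits(rule, "response_rule"))
  if (n_ligands < 2) abort("`n_ligands` must be at least 2.")
  if (n_features < 1) abort("`n_features` must be at least 1.")
  structure(
    list(n_ligands = as.integer(n_ligands),
         n_features = as.integer(n_features), rule = rule,
         n_conformers = n_conformers, conformer_sd = conformer_sd,
         bite_mean = bite_mean, bite_sd = bite_sd,
         energy_window = energy_window, temperature = temperature,
         filter_threshold = filter_threshold, seed = as.integer(seed)),
    class = "dataset_spec"
  )
}

stat_suffix <- c(boltzmann = "boltz", min = "min", max = "max",
                 mean = "mean", lowest = "lowest")

#' Generate a planted-relationship dataset
#'
#' Generates one synthetic ensemble per ligand, attaches pseudo-electronic
#' conformer-level features, aggregates them through the Boltzmann-weighting
#' machinery, and computes the response from the ground-truth rule.  Because
#' the rule may act on ensemble statistics (e.g. a feature's conformer
#' maximum), a featurization restricted to lowest-energy-conformer values is
#' provably lossy on such datasets.
#'
#' @param spec A [dataset_spec()].
#' @return List: `table` (tibble: `ligand_id`, `y`, aggregated feature
#'   columns), `ensembles` (named list of [conformer_ensemble()]), `rule`
#'   (the ground truth), and `truth` (the noise-free response).
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  with_private_seed(spec$seed, {
    ensembles <- list()
    aggregated <- list()
    for (l in seq_len(spec$n_ligands)) {
      lig <- sprintf("L%02d", l)
      es <- ensemble_spec(
        n_conformers = sample(spec$n_conformers[1]:spec$n_conformers[2], 1),
        bite_mean = runif(1, spec$bite_mean[1], spec$bite_mean[2]),
        bite_sd = runif(1, spec$bite_sd[1], spec$bite_sd[2]),
        energy_model = "independent", energy_window = spec$energy_window,
        seed = sample.int(.Machine$integer.max %/% 2, 1)
      )
      ens <- make_ensemble(es, ligand_id = lig)
      n <- n_conformers(ens)
      for (j in seq_len(spec$n_features)) {
        m <- rnorm(1)
        s <- runif(1, spec$conformer_sd[1], spec$conformer_sd[2])
        vals <- m + s * rnorm(n)
        fname <- paste0("f", j)
        for (i in seq_len(n))
          ens$conformers[[i]]$properties[fname] <- vals[i]
      }
      ensembles[[lig]] <- ens
      records <- describe_ensemble(ens, features = c("geometry", "properties"))
      aggregated[[lig]] <- aggregate_ensemble(ens, records = records,
                                              temperature = spec$temperature)
    }
    filt <- NULL
    if (!is.null(spec$filter_threshold)) {
      filt <- variance_filter(aggregated, threshold = spec$filter_threshold)
      for (i in seq_len(nrow(spec$rule$terms))) {
        term <- spec$rule$terms[i, ]
        kept <- filt$report$retained_stats[[
          match(term$feature, filt$report$feature)]]
        if (is.null(kept) || !term$stat %in% kept)
          abort(sprintf(
            "Rule term %s(%s) references a statistic dropped by the variance filter.",
            term$stat, term$feature))
      }
    }
    wide <- pivot_aggregated(aggregated, filter = filt)
    truth <- rep(0, nrow(wide))
    for (i in seq_len(nrow(spec$rule$terms))) {
      term <- spec$rule$terms[i, ]
      col <- paste0(term$feature, "_", stat_suffix[[term$stat]])
      if (!col %in% names(wide))
        abort(paste0("Rule references missing column ", dQuote(col), "."))
      truth <- truth + term$coef * wide[[col]]
    }
    y <- truth + rnorm(nrow(wide), 0, spec$rule$noise_sd)
    table <- dplyr::bind_cols(tibble(ligand_id = wide$ligand_id, y = y),
                              wide[setdiff(names(wide), "ligand_id")])
    list(table = table, ensembles = ensembles, rule = spec$rule,
         truth = truth)
  })
}

#' Restrict a modelling table to lowest-energy-conformer features
#'
#' Keeps the id and response columns plus every `*_lowest` column: the
#' featurization a single-conformer (lowest-energy) workflow would produce.
#'
#' @param table Wide modelling table from [make_dataset()].
#' @param response,id_col Column names.
#' @return Tibble with only lowest-energy feature columns.
#' @export
lowest_energy_table <- function(table, response = "y",
                                id_col = "ligand_id") {
  keep <- c(id_col, intersect(response, names(table)),
            grep("_lowest$", names(table), value = TRUE))
  tibble::as_tibble(table)[keep]
}
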