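#' Locate the PdCl2(P^P) core atoms
#'
#' Finds the unique palladium atom and the two phosphorus and two chloride
#' atoms closest to it.  Extra P or Cl atoms (e.g. a remote counter-ion) are
#' tolerated; the nearest two of each are taken.
#'
#' @param conformer A [conformer()].
#' @return List with 1-based indices: `pd`, `p_pair` (length 2), `cl_pair`
#'   (length 2).
#' @export
detect_core_atoms <- function(conformer) {
  el <- elements(conformer)
  pd <- which(el == "Pd")
  if (length(pd) == 0) abort("Motif violated: no Pd atom found.")
  if (length(pd) > 1) abort("Motif violated: more than one Pd atom.")
  xyz <- coords(conformer)
  d <- sqrt(colSums((t(xyz) - xyz[pd, ])^2))
  pick2 <- function(sym, label) {
    idx <- which(el == sym)
    if (length(idx) < 2)
      abort(sprintf("Motif violated: fewer than two %s atoms.", label))
    idx[order(d[idx])][1:2]
  }
  list(pd = pd, p_pair = sort(pick2("P", "phosphorus")),
       cl_pair = sort(pick2("Cl", "chloride")))
}

#' Bite angle at the metal
#'
#' Angle (degrees) at Pd between the two Pd->P vectors of a chelating
#' bisphosphine.  Indices default to the detected core atoms.
#'
#' @param conformer A [conformer()].
#' @param pd,p1,p2 Atom indices (1-based); auto-detected when `NULL`.
#' @return Angle in degrees, within (0, 180].
#' @export
bite_angle <- function(conformer, pd = NULL, p1 = NULL, p2 = NULL) {
  if (is.null(pd) || is.null(p1) || is.null(p2)) {
    core <- detect_core_atoms(conformer)
    pd <- pd %||% core$pd
    p1 <- p1 %||% core$p_pair[1]
    p2 <- p2 %||% core$p_pair[2]
  }
  if (length(unique(c(pd, p1, p2))) != 3) abort("Indices must be distinct.")
  xyz <- coords(conformer)
  v1 <- xyz[p1, ] - xyz[pd, ]
  v2 <- xyz[p2, ] - xyz[pd, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) abort("Coincident atoms give a zero-length vector.")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Distance between two atoms
#'
#' @param conformer A [conformer()].
#' @param i,j Atom indices (1-based).
#' @return Euclidean distance in Angstrom.
#' @export
bond_length <- function(conformer, i, j) {
  xyz <- coords(conformer)
  n <- nrow(xyz)
  if (any(c(i, j) < 1 | c(i, j) > n)) abort("Atom index out of range.")
  sqrt(sum((xyz[i, ] - xyz[j, ])^2))
}

resolve_vbur_atoms <- function(conformer, center, exclude, include_h) {
  if (is.null(center) || is.null(exclude)) {
    core <- tryCatch(detect_core_atoms(conformer), error = function(e) NULL)
    if (is.null(center)) {
      if (is.null(core)) abort("No Pd found; supply `center` explicitly.")
      center <- core$pd
    }
    if (is.null(exclude))
      exclude <- if (is.null(core)) center else c(core$pd, core$cl_pair)
  }
  el <- elements(conformer)
  keep <- setdiff(seq_along(el), unique(c(center, exclude)))
  if (!include_h) keep <- keep[el[keep] != "H"]
  list(center = center, keep = keep)
}

#' Percent buried volume
#'
#' Percentage of a sphere of given radius centred on an atom (by default the
#' Pd) that is occupied by the scaled van der Waals spheres of the included
#' atoms.  By default the Pd itself and the two chlorides are excluded so the
#' value reflects the bisphosphine ligand; hydrogens are included.  Computed
#' on a cubic grid, with a Monte Carlo mode for cross-checking.
#'
#' @param conformer A [conformer()].
#' @param center Index of the sphere centre; default: the detected Pd.
#' @param radius Probe sphere radius in Angstrom (2-7 typically).
#' @param radii A [radius_table()]; the buried-volume convention scales Bondi
#'   radii by 1.17.
#' @param exclude Atom indices excluded from the occupancy (default: Pd and
#'   the two detected chlorides).
#' @param include_h Include hydrogens (default `TRUE`).
#' @param method `"grid"` (default) or `"mc"`.
#' @param spacing Grid spacing, Angstrom.
#' @param n_mc,mc_seed Monte Carlo sample size and seed.
#' @return Percent in \[0, 100\].
#' @export
buried_volume <- function(conformer, center = NULL, radius = 3.5,
                          radii = radius_table(scale = 1.17),
                          exclude = NULL, include_h = TRUE,
                          method = c("grid", "mc"), spacing = 0.05,
                          n_mc = 1e5, mc_seed = 2025) {
  method <- match.arg(method)
  if (!is.numeric(radius) || radius <= 0) abort("`radius` must be positive.")
  sel <- resolve_vbur_atoms(conformer, center, exclude, include_h)
  if (length(sel$keep) == 0) {
    warn("No atoms included in the buried-volume calculation; returning 0%.")
    return(0)
  }
  xyz <- coords(conformer)
  centers <- sweep(xyz[sel$keep, , drop = FALSE], 2, xyz[sel$center, ])
  rads <- atom_radii(radii, elements(conformer)[sel$keep])
  100 * probe_sphere_fraction(centers, rads, radius, method = method,
                              spacing = spacing, n_mc = n_mc, seed = mc_seed)
}

#' Equivalent cone angle from a solid-angle calculation
#'
#' Computes the solid angle Omega subtended at the apex (by default the Pd)
#' by the union of the included atoms' van der Waals spheres, using
#' quasi-uniform ray sampling, and reports the apex angle of the circular
#' cone with the same solid angle: Theta = 2 acos(1 - Omega / 2 pi), in
#' degrees.  By default the Pd and the chlorides are excluded so Theta
#' describes the bisphosphine ligand.
#'
#' @param conformer A [conformer()].
#' @param apex Apex atom index; default: the detected Pd.
#' @param included Indices of atoms contributing spheres; default: all atoms
#'   except Pd and the two detected chlorides.
#' @param radii A [radius_table()] (unscaled Bondi by default).
#' @param n_rays Number of quasi-uniform ray directions.
#' @param clamp If an atom sphere contains the apex, treat it as covering the
#'   whole sky (`TRUE`, default) or raise an error (`FALSE`).
#' @return Equivalent cone angle in degrees (0 for an empty included set).
#' @export
equivalent_cone_angle <- function(conformer, apex = NULL, included = NULL,
                                  radii = radius_table(), n_rays = 1e5,
                                  clamp = TRUE) {
  if (is.null(apex) || is.null(included)) {
    core <- tryCatch(detect_core_atoms(conformer), error = function(e) NULL)
    if (is.null(apex)) {
      if (is.null(core)) abort("No Pd found; supply `apex` explicitly.")
      apex <- core$pd
    }
    if (is.null(included)) {
      drop <- if (is.null(core)) apex else c(core$pd, core$cl_pair)
      included <- setdiff(seq_along(elements(conformer)), drop)
    }
  }
  included <- setdiff(included, apex)
  if (length(included) == 0) return(0)
  xyz <- coords(conformer)
  centers <- sweep(xyz[included, , drop = FALSE], 2, xyz[apex, ])
  rads <- atom_radii(radii, elements(conformer)[included])
  omega <- union_solid_angle(centers, rads, n_rays = n_rays, clamp = clamp)
  2 * acos(pmin(1, pmax(-1, 1 - omega / (2 * pi)))) * 180 / pi
}

#' Solvent accessible surface area per atom
#'
#' Shrake-Rupley style SASA: quasi-uniform test points on each atom's
#' solvent-extended sphere (vdW radius + probe) are kept if they fall outside
#' every other atom's extended sphere; the exposed fraction scales the full
#' extended-sphere area.
#'
#' @param conformer A [conformer()].
#' @param radii A [radius_table()] (unscaled by default).
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Test points per atom (>= 100).
#' @return Named numeric vector, one area (A^2) per atom, names =
#'   `"<element><index>"`.
#' @export
sasa <- function(conformer, radii = radius_table(), probe = 1.4,
                 n_points = 960) {
  if (n_points < 100) abort("`n_points` must be at least 100.")
  xyz <- coords(conformer)
  el <- elements(conformer)
  ext <- atom_radii(radii, el) + probe
  n <- nrow(xyz)
  sphere <- fibonacci_sphere(n_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sphere * ext[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij >= ext[i] + ext[j]) next
      exposed <- exposed &
        ((pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
           (pts[, 3] - xyz[j, 3])^2 > ext[j]^2)
    }
    out[i] <- mean(exposed) * 4 * pi * ext[i]^2
  }
  names(out) <- paste0(el, seq_len(n))
  out
}

#' Molecular volume as a union of van der Waals spheres
#'
#' @param conformer A [conformer()].
#' @param radii A [radius_table()] (unscaled by default).
#' @param method `"grid"` (default) or `"mc"`.
#' @param spacing Grid spacing, Angstrom.
#' @param n_mc,mc_seed Monte Carlo sample size and seed.
#' @return Volume in cubic Angstrom.
#' @export
molecular_volume <- function(conformer, radii = radius_table(),
                             method = c("grid", "mc"), spacing = 0.1,
                             n_mc = 2e5, mc_seed = 2025) {
  method <- match.arg(method)
  xyz <- coords(conformer)
  rads <- atom_radii(radii, elements(conformer))
  sphere_union_volume(xyz, rads, method = method, spacing = spacing,
                      n_mc = n_mc, seed = mc_seed)
}

# bond graph by covalent-radius cutoff (x 1.2); returns adjacency list
perceive_bonds <- function(conformer, factor = 1.2) {
  xyz <- coords(conformer)
  el <- elements(conformer)
  rc <- covalent_radii()
  unknown <- setdiff(unique(el), names(rc))
  if (length(unknown) > 0)
    abort(paste0("No covalent radius for element(s): ",
                 paste(unknown, collapse = ", ")))
  r <- unname(rc[el])
  n <- nrow(xyz)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  for (i in seq_len(n - 1)) {
    d <- sqrt(rowSums((xyz[(i + 1):n, , drop = FALSE] -
                         matrix(xyz[i, ], n - i, 3, byrow = TRUE))^2))
    cut <- factor * (r[i] + r[(i + 1):n])
    js <- which(d < cut) + i
    for (j in js) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

bfs_distances <- function(adj, start, blocked = integer()) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[blocked] <- NA
  d[start] <- 0
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!is.na(d[w]) && is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

#' Assign small/large donor roles to the two phosphorus atoms
#'
#' Ranks the two phosphorus donors by the percent buried volume (r = 3.0 A
#' about Pd) of each donor's substituent branch.  Atoms are attributed to the
#' phosphorus with the smaller graph distance in the ligand bond graph (Pd
#' and the chlorides removed); backbone atoms equidistant from both donors
#' count with weight 1/2 for each.
#'
#' @param conformer A [conformer()].
#' @param radius Probe sphere radius about Pd, Angstrom (convention: 3.0).
#' @param radii A [radius_table()]; buried-volume scaling (1.17) by default.
#' @param spacing Grid spacing for the occupancy integral.
#' @return List of class `donor_assignment`: `p_small`, `p_large` (atom
#'   indices), `vbur_small`, `vbur_large` (percent).
#' @export
assign_donor_roles <- function(conformer, radius = 3.0,
                               radii = radius_table(scale = 1.17),
                               spacing = 0.05) {
  core <- detect_core_atoms(conformer)
  adj <- perceive_bonds(conformer)
  blocked <- c(core$pd, core$cl_pair)
  d1 <- bfs_distances(adj, core$p_pair[1], blocked)
  d2 <- bfs_distances(adj, core$p_pair[2], blocked)
  xyz <- coords(conformer)
  el <- elements(conformer)
  branch_vbur <- function(which_p) {
    da <- if (which_p == 1) d1 else d2
    db <- if (which_p == 1) d2 else d1
    cand <- setdiff(seq_along(el), blocked)
    full <- cand[!is.na(da[cand]) & is.finite(da[cand]) &
                   (is.infinite(db[cand]) | da[cand] < db[cand])]
    half <- cand[!is.na(da[cand]) & is.finite(da[cand]) &
                   is.finite(db[cand]) & da[cand] == db[cand]]
    weighted_vbur(conformer, core$pd, radius, radii, full, half, spacing)
  }
  v1 <- branch_vbur(1)
  v2 <- branch_vbur(2)
  if (v1 <= v2) {
    res <- list(p_small = core$p_pair[1], p_large = core$p_pair[2],
                vbur_small = v1, vbur_large = v2)
  } else {
    res <- list(p_small = core$p_pair[2], p_large = core$p_pair[1],
                vbur_small = v2, vbur_large = v1)
  }
  structure(res, class = "donor_assignment")
}

# per-point occupancy: 1 inside any full-weight sphere, else 1/2 inside any
# half-weight sphere; averaged over the probe sphere
weighted_vbur <- function(conformer, center, radius, radii, full, half,
                          spacing) {
  xyz <- coords(conformer)
  el <- elements(conformer)
  origin <- xyz[center, ]
  frac_of <- function(idx) {
    if (length(idx) == 0) return(NULL)
    list(centers = sweep(xyz[idx, , drop = FALSE], 2, origin),
         radii = atom_radii(radii, el[idx]))
  }
  af <- frac_of(full); ah <- frac_of(half)
  g <- seq(-radius + spacing / 2, radius - spacing / 2, by = spacing)
  gx <- rep(g, times = length(g))
  gy <- rep(g, each = length(g))
  xy2 <- gx^2 + gy^2
  tot <- 0; acc <- 0
  covered_by <- function(set, x, y, z) {
    covered <- rep(FALSE, length(x))
    if (is.null(set)) return(covered)
    for (k in seq_len(nrow(set$centers))) {
      dz <- z - set$centers[k, 3]
      if (abs(dz) > set$radii[k]) next
      covered <- covered |
        ((x - set$centers[k, 1])^2 + (y - set$centers[k, 2])^2 + dz^2 <=
           set$radii[k]^2)
    }
    covered
  }
  for (z in g) {
    inside <- xy2 + z^2 <= radius^2
    if (!any(inside)) next
    x <- gx[inside]; y <- gy[inside]
    tot <- tot + length(x)
    cf <- covered_by(af, x, y, z)
    ch <- covered_by(ah, x, y, z)
    acc <- acc + sum(cf) + 0.5 * sum(ch & !cf)
  }
  if (tot == 0) return(0)
  100 * acc / tot
}

#' @export
print.donor_assignment <- function(x, ...) {
  cat(sprintf("<donor_assignment> p_small: atom %d (%.2f%%)  p_large: atom %d (%.2f%%)\n",
              x$p_small, x$vbur_small, x$p_large, x$vbur_large))
  invisible(x)
}

#' Per-conformer feature records for an ensemble
#'
#' Computes the steric and geometric descriptor vocabulary for every
#' conformer and copies through any ingested electronic properties.
#' Descriptors with two equivalent instances (the Pd-P and Pd-Cl bonds) are
#' emitted as `_avg`, `_min`, `_max` variants.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param radii A [radius_table()] used for cone angle, SASA and volume;
#'   buried volume always applies the 1.17 scaling on top of these radii.
#' @param features Character subset of
#'   `c("geometry", "vbur", "cone_angle", "sasa", "volume", "properties")`.
#' @param vbur_radii Probe radii (Angstrom) for the percent-buried-volume
#'   columns `vbur_r<r>`.
#' @param spacing Grid spacing for buried volume.
#' @param volume_spacing Grid spacing for molecular volume.
#' @param n_rays Ray count for the cone angle.
#' @param sasa_points Test points per atom for SASA.
#' @return Tibble with one row per conformer: `conformer_id`, `energy`, then
#'   descriptor columns.
#' @export
describe_ensemble <- function(ensemble, radii = radius_table(),
                              features = c("geometry", "vbur", "cone_angle",
                                           "sasa", "volume", "properties"),
                              vbur_radii = 2:7, spacing = 0.05,
                              volume_spacing = 0.1, n_rays = 1e5,
                              sasa_points = 960) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  features <- match.arg(features, several.ok = TRUE)
  vradii <- radius_table(set = radii$set, scale = 1.17 * radii$scale)
  rows <- purrr::map(ensemble$conformers, function(cf) {
    core <- detect_core_atoms(cf)
    rec <- list(conformer_id = cf$id, energy = cf$energy)
    if ("geometry" %in% features) {
      rec$bite_angle <- bite_angle(cf, core$pd, core$p_pair[1], core$p_pair[2])
      pp <- vapply(core$p_pair, function(i) bond_length(cf, core$pd, i), numeric(1))
      pc <- vapply(core$cl_pair, function(i) bond_length(cf, core$pd, i), numeric(1))
      rec$pd_p_avg <- mean(pp); rec$pd_p_min <- min(pp); rec$pd_p_max <- max(pp)
      rec$pd_cl_avg <- mean(pc); rec$pd_cl_min <- min(pc); rec$pd_cl_max <- max(pc)
    }
    if ("vbur" %in% features) {
      for (r in vbur_radii)
        rec[[paste0("vbur_r", r)]] <-
          buried_volume(cf, center = core$pd, radius = r, radii = vradii,
                        exclude = c(core$pd, core$cl_pair), spacing = spacing)
    }
    if ("cone_angle" %in% features)
      rec$cone_angle <- equivalent_cone_angle(cf, apex = core$pd,
                                              radii = radii, n_rays = n_rays)
    if ("sasa" %in% features)
      rec$sasa_pd <- sasa(cf, radii = radii, n_points = sasa_points)[core$pd]
    if ("volume" %in% features)
      rec$mol_volume <- molecular_volume(cf, radii = radii,
                                         spacing = volume_spacing)
    if ("properties" %in% features && length(cf$properties) > 0)
      rec <- c(rec, as.list(cf$properties))
    tibble::as_tibble(rec)
  })
  out <- dplyr::bind_rows(rows)
  if ("properties" %in% features) {
    prop_cols <- setdiff(names(out), c("conformer_id", "energy"))
    incomplete <- prop_cols[vapply(out[prop_cols],
                                   function(v) anyNA(v), logical(1))]
    if (length(incomplete) > 0)
      warn(paste0("Properties missing for some conformers (kept as NA): ",
                  paste(incomplete, collapse = ", ")))
  }
  out
}
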