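#' Van der Waals radii (Bondi set, with common extensions)
#'
#' Bondi's consistent van der Waals radii, extended with values for a few
#' elements Bondi did not tabulate (from the Mantina et al. extension) so
#' that typical organometallic complexes are fully covered.  All values in
#' Angstrom.
#'
#' @return Named numeric vector of radii keyed by element symbol.
#' @export
#' @examples
#' bondi_radii()[["P"]]
bondi_radii <- function() {
  c(
    H = 1.20, He = 1.40,
    Li = 1.82, Be = 1.53, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
    F = 1.47, Ne = 1.54,
    Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10, P = 1.80, S = 1.80,
    Cl = 1.75, Ar = 1.88,
    K = 2.75, Ca = 2.31, Fe = 2.04, Ni = 1.63, Cu = 1.40, Zn = 1.39,
    Ga = 1.87, Ge = 2.11, As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02,
    Ru = 2.05, Rh = 2.00, Pd = 1.63, Ag = 1.72, Cd = 1.58,
    In = 1.93, Sn = 2.17, Sb = 2.06, Te = 2.06, I = 1.98, Xe = 2.16,
    Ir = 2.00, Pt = 1.75, Au = 1.66, Hg = 1.55
  )
}

#' Covalent radii used for bond perception
#'
#' Single-bond covalent radii (Cordero et al. compilation), Angstrom.  Bonds
#' are perceived between atoms closer than 1.2 times the sum of their
#' covalent radii.
#'
#' @return Named numeric vector keyed by element symbol.
#' @export
covalent_radii <- function() {
  c(
    H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
    Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
    Fe = 1.32, Ni = 1.24, Cu = 1.32, Zn = 1.22, Br = 1.20,
    Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, I = 1.39,
    Ir = 1.41, Pt = 1.36, Au = 1.36
  )
}

#' Radius table for sphere-based descriptors
#'
#' Bundles a set of van der Waals radii with a multiplicative scale factor.
#' Percent buried volume conventionally uses Bondi radii scaled by 1.17
#' (the SambVca convention); SASA and molecular volume use unscaled radii.
#'
#' @param set Radius set name; currently `"bondi"`.
#' @param scale Multiplicative factor applied to every radius.
#' @param overrides Optional named numeric vector of per-element radii that
#'   replace or extend the base set (applied before scaling).
#' @return An object of class `radius_table`.
#' @export
#' @examples
#' rt <- radius_table(scale = 1.17)
#' atom_radii(rt, c("P", "C", "H"))
radius_table <- function(set = "bondi", scale = 1, overrides = NULL) {
  set <- match.arg(set)
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0)
    abort("`scale` must be a single positive number.")
  radii <- bondi_radii()
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      abort("`overrides` must be a named numeric vector.")
    radii[names(overrides)] <- overrides
  }
  if (any(!is.finite(radii)) || any(radii <= 0))
    abort("All radii must be positive and finite.")
  structure(list(set = set, radii = radii, scale = scale),
            class = "radius_table")
}

#' Look up scaled radii for a vector of elements
#'
#' @param table A [radius_table()].
#' @param elements Character vector of element symbols.
#' @return Numeric vector of scaled radii (Angstrom).
#' @export
atom_radii <- function(table, elements) {
  stopifnot(inherits(table, "radius_table"))
  unknown <- setdiff(unique(elements), names(table$radii))
  if (length(unknown) > 0)
    abort(paste0("No van der Waals radius for element(s): ",
                 paste(unknown, collapse = ", ")))
  unname(table$radii[elements]) * table$scale
}

#' @export
print.radius_table <- function(x, ...) {
  cat("<radius_table> set:", x$set, " scale:", x$scale,
      " (", length(x$radii), "elements )\n")
  invisible(x)
}
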