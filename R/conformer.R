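#' Create a conformer
#'
#' A conformer is one 3D structure: an ordered atom table, an energy and an
#' optional bag of externally computed properties (NPA charges, NMR shifts,
#' orbital energies, ...).
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`
#'   (coordinates in Angstrom).
#' @param energy Energy in kcal/mol (typically relative to the ensemble
#'   minimum).
#' @param id Conformer identifier.
#' @param energy_method Free-text tag for the level of theory (e.g.
#'   `"GFN2-xTB"`, `"DFT"`).
#' @param properties Named numeric vector of ingested descriptors.
#' @return An object of class `conformer`.
#' @export
#' @examples
#' atoms <- tibble::tibble(
#'   element = c("Pd", "P", "P", "Cl", "Cl"),
#'   x = c(0, 2.3, 0, -1.6, -1.6),
#'   y = c(0, 0, 2.3, -1.6, 1.6),
#'   z = 0
#' )
#' conformer(atoms, energy = -1.2, id = "conf_0001")
conformer <- function(atoms, energy = NA_real_, id = "conf_0001",
                      energy_method = NULL, properties = NULL) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("element", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    abort("`atoms` must have columns element, x, y, z.")
  atoms <- atoms[req]
  if (nrow(atoms) < 1) abort("A conformer needs at least one atom.")
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!is.numeric(xyz) || any(!is.finite(xyz)))
    abort("Atomic coordinates must be finite numbers.")
  if (!is.character(atoms$element)) atoms$element <- as.character(atoms$element)
  if (length(energy) != 1 || (!is.na(energy) && !is.finite(energy)))
    abort("`energy` must be a single finite number (or NA).")
  props <- as.numeric(properties %||% numeric())
  names(props) <- names(properties)
  structure(
    list(id = as.character(id), atoms = atoms, energy = as.numeric(energy),
         energy_method = energy_method, properties = props),
    class = "conformer"
  )
}

#' Atomic coordinates of a conformer as a matrix
#' @param conformer A [conformer()].
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(conformer) {
  stopifnot(inherits(conformer, "conformer"))
  m <- as.matrix(conformer$atoms[c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Element symbols of a conformer
#' @inheritParams coords
#' @return Character vector.
#' @export
elements <- function(conformer) {
  stopifnot(inherits(conformer, "conformer"))
  conformer$atoms$element
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer>", x$id, "-", nrow(x$atoms), "atoms, energy",
      format(x$energy, digits = 6), "kcal/mol\n")
  if (length(x$properties) > 0)
    cat("  properties:", paste(names(x$properties), collapse = ", "), "\n")
  invisible(x)
}

#' Create a conformer ensemble
#'
#' All low-energy conformers of one ligand complex, conventionally those
#' within a 5 kcal/mol window of the minimum.  All members must share the
#' same element sequence (identical atom ordering).
#'
#' @param conformers List of [conformer()] objects (non-empty).
#' @param ligand_id Identifier for the ligand/complex.
#' @param energy_window Energy window in kcal/mol (default 5).
#' @param check_window If `TRUE`, error when the energy spread exceeds
#'   `energy_window` (plus a 1e-6 tolerance).
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(conformers, ligand_id = "ligand",
                               energy_window = 5, check_window = FALSE) {
  if (!is.list(conformers) || length(conformers) == 0)
    abort("`conformers` must be a non-empty list of conformer objects.")
  ok <- vapply(conformers, inherits, logical(1), what = "conformer")
  if (!all(ok)) abort("All elements of `conformers` must be conformer objects.")
  elems <- lapply(conformers, elements)
  if (length(unique(vapply(elems, paste, character(1), collapse = " "))) != 1)
    abort("All conformers in an ensemble must share the same element sequence.")
  if (!is.numeric(energy_window) || energy_window <= 0)
    abort("`energy_window` must be positive.")
  en <- vapply(conformers, function(cf) cf$energy, numeric(1))
  if (check_window && all(is.finite(en)) &&
      diff(range(en)) > energy_window + 1e-6)
    abort(sprintf("Energy spread %.3f kcal/mol exceeds the %.3f kcal/mol window.",
                  diff(range(en)), energy_window))
  structure(
    list(ligand_id = as.character(ligand_id), conformers = conformers,
         energy_window = energy_window),
    class = "conformer_ensemble"
  )
}

#' Number of conformers in an ensemble
#' @param ensemble A [conformer_ensemble()].
#' @return Integer count.
#' @export
n_conformers <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  length(ensemble$conformers)
}

#' Conformer energies of an ensemble
#' @inheritParams n_conformers
#' @param relative If `TRUE`, shift so the minimum is zero.
#' @return Numeric vector, kcal/mol.
#' @export
ensemble_energies <- function(ensemble, relative = FALSE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  en <- vapply(ensemble$conformers, function(cf) cf$energy, numeric(1))
  if (relative) en <- en - min(en)
  en
}

#' Conformer ids of an ensemble
#' @inheritParams n_conformers
#' @return Character vector.
#' @export
conformer_ids <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  vapply(ensemble$conformers, function(cf) cf$id, character(1))
}

#' Subset an ensemble by conformer index
#' @inheritParams n_conformers
#' @param i Integer indices of conformers to keep.
#' @return A new, smaller `conformer_ensemble`.
#' @export
subset_ensemble <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  i <- as.integer(i)
  if (any(i < 1 | i > n_conformers(ensemble)))
    abort("Conformer index out of range.")
  conformer_ensemble(ensemble$conformers[i], ligand_id = ensemble$ligand_id,
                     energy_window = ensemble$energy_window)
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  en <- ensemble_energies(x)
  cat("<conformer_ensemble>", x$ligand_id, "-", length(x$conformers),
      "conformers,", nrow(x$conformers[[1]]$atoms), "atoms each\n")
  if (all(is.finite(en)))
    cat(sprintf("  energy span %.3f kcal/mol (window %.1f)\n",
                diff(range(en)), x$energy_window))
  invisible(x)
}

#' @export
as_tibble.conformer_ensemble <- function(x, ...) {
  purrr::map_dfr(x$conformers, function(cf) {
    dplyr::mutate(cf$atoms, conformer_id = cf$id, energy = cf$energy,
                  .before = 1)
  })
}
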