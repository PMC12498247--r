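#' XYZ comment-line dialect
#'
#' Concatenated-XYZ writers differ in how the per-frame energy is written in
#' the comment line.  The default dialect takes the first whitespace-separated
#' floating-point token as the energy; the `"key_value"` dialect looks for a
#' `key=value` token instead.
#'
#' @param energy How to locate the energy: `"first_float"` or `"key_value"`.
#' @param key Key name used by the `"key_value"` dialect.
#' @param units Energy units in the file: `"kcal/mol"` (stored as-is) or
#'   `"hartree"` (converted to kcal/mol, x 627.5094740631).
#' @param allow_missing If `TRUE`, frames without a parseable energy get
#'   `NA` instead of raising an error.
#' @return A list of class `xyz_dialect`.
#' @export
xyz_dialect <- function(energy = c("first_float", "key_value"),
                        key = "energy",
                        units = c("kcal/mol", "hartree"),
                        allow_missing = FALSE) {
  structure(list(energy = match.arg(energy), key = key,
                 units = match.arg(units),
                 allow_missing = isTRUE(allow_missing)),
            class = "xyz_dialect")
}

parse_frame_energy <- function(comment, dialect) {
  token <- NA_character_
  if (dialect$energy == "key_value") {
    m <- regmatches(comment,
                    regexpr(paste0(dialect$key, "\\s*=\\s*[-+0-9.eEdD]+"), comment))
    if (length(m) == 1) token <- sub(paste0("^", dialect$key, "\\s*=\\s*"), "", m)
  } else {
    toks <- strsplit(trimws(comment), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(toks))
    if (any(is.finite(num))) token <- toks[which(is.finite(num))[1]]
  }
  e <- suppressWarnings(as.numeric(token))
  if (is.na(e)) return(NA_real_)
  if (dialect$units == "hartree") e <- e * .HARTREE_KCAL
  e
}

#' Read a multi-frame XYZ file into a conformer ensemble
#'
#' Parses concatenated XYZ (atom-count line, comment line, atom lines per
#' frame).  One conformer is produced per frame, in file order; energies are
#' taken from the comment line according to the dialect; ids are assigned
#' `"conf_0001"`-style.
#'
#' @param path Path to the XYZ file.
#' @param ligand_id Ligand identifier; defaults to the file name without
#'   extension.
#' @param dialect An [xyz_dialect()].
#' @param energy_window Energy window recorded on the ensemble (kcal/mol).
#' @return A [conformer_ensemble()].
#' @export
read_xyz_ensemble <- function(path, ligand_id = NULL,
                              dialect = xyz_dialect(), energy_window = 5) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0) abort("Empty XYZ file.")
  conformers <- list()
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1)
      abort(sprintf("Frame %d: expected an atom count at line %d.", frame, pos))
    if (pos + 1L + nat > length(lines))
      abort(sprintf("Frame %d: declares %d atoms but the file ends early.",
                    frame, nat))
    comment <- lines[pos + 1L]
    atom_lines <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4)
    if (length(bad) > 0)
      abort(sprintf("Frame %d: malformed atom line %d (need element x y z).",
                    frame, bad[1]))
    el <- vapply(toks, `[[`, character(1), 1)
    xyz <- vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))
    if (any(!is.finite(xyz)))
      abort(sprintf("Frame %d: non-numeric coordinates.", frame))
    e <- parse_frame_energy(comment, dialect)
    if (is.na(e) && !dialect$allow_missing)
      abort(sprintf("Frame %d: could not parse an energy from the comment line %s.",
                    frame, dQuote(comment)))
    conformers[[frame]] <- conformer(
      tibble(element = el, x = xyz[1, ], y = xyz[2, ], z = xyz[3, ]),
      energy = e, id = sprintf("conf_%04d", frame)
    )
    pos <- pos + 2L + nat
  }
  conformer_ensemble(
    conformers,
    ligand_id = ligand_id %||% sub("\\.[^.]*$", "", basename(path)),
    energy_window = energy_window
  )
}

#' Write a conformer ensemble as concatenated XYZ
#'
#' The per-frame energy (kcal/mol) is written alone in the comment line in
#' fixed decimal format, so [read_xyz_ensemble()] with the default dialect
#' inverts the write.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param path Output path.
#' @param digits Decimal places for coordinates and energies.
#' @return `path`, invisibly.
#' @export
write_xyz_ensemble <- function(ensemble, path, digits = 6) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  fmt <- paste0("%.", digits, "f")
  out <- unlist(lapply(ensemble$conformers, function(cf) {
    n <- nrow(cf$atoms)
    c(as.character(n),
      sprintf(fmt, cf$energy),
      sprintf(paste0("%-3s ", fmt, " ", fmt, " ", fmt),
              cf$atoms$element, cf$atoms$x, cf$atoms$y, cf$atoms$z))
  }))
  tryCatch(writeLines(out, path),
           error = function(e) abort(paste0("Cannot write to ", path, ": ",
                                            conditionMessage(e))))
  invisible(path)
}

#' Read a per-conformer property table
#'
#' Reads a CSV whose first column (or `id_col`) holds conformer ids and whose
#' remaining columns are numeric descriptors computed externally (NPA
#' charges, 31P NMR shifts, orbital energies, bond occupancies, ...).
#'
#' @param path CSV path.
#' @param id_col Name or position of the conformer-id column (default: first).
#' @return A tibble with a `conformer_id` column plus numeric columns.
#' @export
read_property_table <- function(path, id_col = 1) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2) abort("Property table needs an id column plus at least one descriptor.")
  idname <- if (is.numeric(id_col)) names(tbl)[id_col] else id_col
  if (!idname %in% names(tbl)) abort(paste0("No id column ", dQuote(idname), "."))
  ids <- as.character(tbl[[idname]])
  if (anyDuplicated(ids))
    abort(paste0("Duplicate conformer id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  vals <- tbl[setdiff(names(tbl), idname)]
  for (cn in names(vals)) {
    v <- vals[[cn]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !is.na(v))) {
        row <- which(is.na(num) & !is.na(v))[1]
        abort(sprintf("Non-numeric value in column %s, row %d.", dQuote(cn), row))
      }
      vals[[cn]] <- num
    }
  }
  dplyr::bind_cols(tibble(conformer_id = ids), vals)
}

#' Attach a property table to an ensemble
#'
#' Joins descriptor columns onto matching conformers by id; ids present in
#' the table but absent from the ensemble are reported with a warning.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param properties Tibble from [read_property_table()] (or compatible, with
#'   a `conformer_id` column).
#' @return The ensemble with updated `properties` on each conformer.
#' @export
attach_properties <- function(ensemble, properties) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (!"conformer_id" %in% names(properties))
    abort("`properties` must have a conformer_id column.")
  ids <- conformer_ids(ensemble)
  extra <- setdiff(properties$conformer_id, ids)
  if (length(extra) > 0)
    warn(paste0("Property table ids not present in the ensemble: ",
                paste(extra, collapse = ", ")))
  feat <- setdiff(names(properties), "conformer_id")
  ensemble$conformers <- lapply(ensemble$conformers, function(cf) {
    row <- which(properties$conformer_id == cf$id)
    if (length(row) == 1) {
      vals <- as.numeric(properties[row, feat])
      names(vals) <- feat
      cf$properties[names(vals)] <- vals
    }
    cf
  })
  ensemble
}
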