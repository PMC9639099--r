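#' Point-charge structure tibbles
#'
#' A structure is a tibble with one row per atom and columns `serial`,
#' `name`, `residue_name`, `chain`, `residue_seq`, `x`, `y`, `z` (Angstrom),
#' `charge` (e) and `radius` (Angstrom), carrying the attributes `label`
#' (free text) and `et_entry_serial` (serial of the electron-transfer entry
#' atom, or `NA`). `as_structure()` validates a data frame and attaches the
#' class; all other functions in the package accept any data frame with
#' these columns.
#'
#' @param atoms Data frame with the atom columns above.
#' @param label Free-text label for the structure.
#' @param et_entry_serial Optional serial of the marked ET-entry atom.
#' @return A `structure_tbl` tibble.
#' @examples
#' as_structure(tibble::tibble(
#'   serial = 1:2, name = c("N", "C"), residue_name = "GLY", chain = "A",
#'   residue_seq = 1L, x = c(0, 1), y = 0, z = c(0, 1.5),
#'   charge = c(-0.3, 0.3), radius = 1.5))
#' @export
as_structure <- function(atoms, label = "structure", et_entry_serial = NULL) {
  cols <- c("serial", "name", "residue_name", "chain", "residue_seq",
            "x", "y", "z", "charge", "radius")
  missing_cols <- setdiff(cols, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("structure is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)[cols]
  if (nrow(atoms) == 0) abort("structure must contain at least one atom")
  num <- as.matrix(atoms[c("x", "y", "z", "charge", "radius")])
  if (!all(is.finite(num))) abort("structure coordinates/charges/radii must be finite")
  if (any(atoms$radius < 0)) abort("atom radii must be >= 0")
  if (anyDuplicated(atoms$serial)) abort("atom serials must be unique")
  if (!is.null(et_entry_serial) && !is.na(et_entry_serial) &&
      !et_entry_serial %in% atoms$serial) {
    abort("et_entry_serial does not refer to an atom in the structure")
  }
  attr(atoms, "label") <- label
  attr(atoms, "et_entry_serial") <-
    if (is.null(et_entry_serial)) NA_integer_ else as.integer(et_entry_serial)
  class(atoms) <- c("structure_tbl", class(atoms))
  atoms
}

is_structure <- function(x) inherits(x, "structure_tbl")

# rebuild a structure tibble after coordinate edits, preserving metadata
restamp <- function(atoms, template) {
  as_structure(atoms,
               label = attr(template, "label") %||% "structure",
               et_entry_serial = attr(template, "et_entry_serial"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.structure_tbl <- function(x, ...) {
  cat(sprintf("# point-charge structure '%s': %d atoms, net charge %+.3f e\n",
              attr(x, "label"), nrow(x), sum(x$charge)))
  et <- attr(x, "et_entry_serial")
  if (!is.na(et)) cat(sprintf("# ET entry atom: serial %d\n", et))
  NextMethod()
  invisible(x)
}

coords <- function(structure) {
  cbind(structure$x, structure$y, structure$z)
}
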