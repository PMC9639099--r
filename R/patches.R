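# 20 standard amino-acid residue names
.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# per-residue distance table for a placed structure: one row per residue,
# distance = min over its atoms of (z - radius), ranked closest first
residue_distances <- function(placed, standard_only = TRUE) {
  res <- dplyr::group_by(placed, .data$chain, .data$residue_name,
                         .data$residue_seq)
  res <- dplyr::summarise(res,
                          distance = min(.data$z - .data$radius),
                          charge = sum(.data$charge), .groups = "drop")
  if (standard_only) {
    res <- dplyr::filter(res, .data$residue_name %in% .standard_aa)
    if (nrow(res) == 0) {
      abort("structure has no standard amino-acid residues; use standard_only = FALSE")
    }
  }
  dplyr::arrange(res, .data$distance, .data$chain, .data$residue_seq)
}

#' Residue closest to the electrode
#'
#' For a placed structure, the residue whose closest atom surface
#' (`min(z - radius)` over its atoms) is nearest the electrode plane. Ties
#' break deterministically by (chain, residue_seq). By contact with the
#' placement criterion, the returned residue contains the atom that defines
#' the gap.
#'
#' @param placed A placed structure with residue labels.
#' @param standard_only Restrict to the 20 standard amino acids (cofactor
#'   hetero-groups excluded); default TRUE.
#' @return One-row tibble: `chain`, `residue_name`, `residue_seq`,
#'   `distance` (Angstrom), `charge` (e).
#' @export
nearest_residue <- function(placed, standard_only = TRUE) {
  if (all(is.na(placed$residue_name)) || all(placed$residue_name == "")) {
    abort("structure has no residue labels")
  }
  residue_distances(placed, standard_only)[1, ]
}

#' Net charge of the contact patch
#'
#' Sums the partial charges of all atoms in the `n` residues closest to the
#' electrode (all residues if fewer exist) and rounds to the nearest
#' integer — force-field residue charges are near-integers and the patch
#' charge is conventionally reported as one.
#'
#' @param placed A placed structure.
#' @param n Patch size in residues (default 10).
#' @param standard_only Restrict to standard amino acids; default TRUE.
#' @return Integer patch charge, e.
#' @export
patch_charge <- function(placed, n = 10, standard_only = TRUE) {
  if (n < 1) abort("patch size n must be >= 1")
  res <- residue_distances(placed, standard_only)
  as.integer(round(sum(head(res$charge, n))))
}
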