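#' Read an external per-orientation energy table
#'
#' CSV with header and columns `theta_deg`, `phi_deg` plus either
#' `e_total_kj_mol` or the three components `e_coulomb_kj_mol`,
#' `e_solvation_kj_mol`, `e_surface_kj_mol` (summed into a total). Such
#' tables typically come from a boundary-element Poisson-Boltzmann solver
#' run over the same orientation grid.
#'
#' @param path CSV path.
#' @return Tibble with `theta_deg`, `phi_deg`, `e_total_kj_mol`.
#' @export
read_energy_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("theta_deg", "phi_deg") %in% names(tab))) {
    abort("energy table must have theta_deg and phi_deg columns")
  }
  comp <- c("e_coulomb_kj_mol", "e_solvation_kj_mol", "e_surface_kj_mol")
  if (!"e_total_kj_mol" %in% names(tab)) {
    if (!all(comp %in% names(tab))) {
      abort(paste0("energy table needs e_total_kj_mol or all of ",
                   paste(comp, collapse = ", ")))
    }
    tab$e_total_kj_mol <- tab$e_coulomb_kj_mol + tab$e_solvation_kj_mol +
      tab$e_surface_kj_mol
  }
  tab[c("theta_deg", "phi_deg", "e_total_kj_mol")]
}

#' Interaction energy from total-energy bookkeeping
#'
#' Converts per-orientation total energies of the protein@electrode system
#' into interaction (adsorption) energies by subtracting the energies of the
#' isolated protein and the isolated electrode, computed with the same
#' method: `delta_e = e_total - e_protein - e_electrode`. Records supplying
#' component columns are first assembled into totals (Coulomb + solvation +
#' surface).
#'
#' @param record Data frame with `e_total_kj_mol` (or the three component
#'   columns accepted by [read_energy_table()]); other columns pass through.
#' @param e_protein Isolated-protein total energy, kJ/mol.
#' @param e_electrode Isolated-electrode total energy, kJ/mol.
#' @return `record` with a `delta_e_kj_mol` column appended.
#' @export
table_interaction_energy <- function(record, e_protein, e_electrode) {
  if (missing(e_protein) || missing(e_electrode) ||
      is.null(e_protein) || is.null(e_electrode)) {
    abort("isolated-state energies e_protein and e_electrode are required")
  }
  record <- as_tibble(record)
  comp <- c("e_coulomb_kj_mol", "e_solvation_kj_mol", "e_surface_kj_mol")
  if (!"e_total_kj_mol" %in% names(record)) {
    if (!all(comp %in% names(record))) {
      abort("record needs e_total_kj_mol or the three component columns")
    }
    record$e_total_kj_mol <- record$e_coulomb_kj_mol +
      record$e_solvation_kj_mol + record$e_surface_kj_mol
  }
  dplyr::mutate(record,
                delta_e_kj_mol = .data$e_total_kj_mol - e_protein - e_electrode)
}
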