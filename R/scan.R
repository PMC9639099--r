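#' Scan an orientation grid and build the adsorption ensemble
#'
#' The package's main pipeline. For every grid orientation, the structure is
#' rotated ([orient()]), placed at the fixed gap above the electrode plane
#' ([place()]), and its interaction energy, ET-entry distance, nearest
#' residue and contact-patch charge are evaluated. The per-orientation
#' energies are then converted to Boltzmann probabilities, Langmuir
#' constants `K_i` / `K_total`, ET rates and the reference current density
#' `J0`.
#'
#' Two energy backends are available: `"scic"`, the built-in
#' screened-Coulomb image-charge half-space model
#' ([scic_interaction_energy()]); and `"table"`, which looks per-orientation
#' total energies up in an external table (e.g. from a boundary-element
#' Poisson-Boltzmann solver) and applies the isolated-state subtraction
#' ([table_interaction_energy()]).
#'
#' @param structure A structure tibble with a marked ET-entry atom (distance
#'   and rate columns are NA otherwise).
#' @param env An [electrode_env()].
#' @param grid An orientation grid from [build_grid()].
#' @param backend `"scic"` or `"table"`.
#' @param table For the table backend: a data frame accepted by
#'   [table_interaction_energy()], covering every grid orientation.
#' @param e_protein,e_electrode Isolated-state energies for the table
#'   backend, kJ/mol (default 0: the table already holds interaction
#'   energies).
#' @param et An [et_params()].
#' @param patch_n Contact-patch size in residues.
#' @param patch_standard_only Restrict patch bookkeeping to standard amino
#'   acids.
#' @return An `orientation_scan` object; see [tidy.orientation_scan()] for
#'   the per-orientation table and [glance.orientation_scan()] for the
#'   one-row ensemble summary.
#' @examples
#' toy_protein(seed = 1) |>
#'   scan_orientations(electrode_env(ionic_strength = 0.15),
#'                     build_grid(dtheta = 30, equator_count = 12)) |>
#'   glance()
#' @export
scan_orientations <- function(structure, env = electrode_env(),
                              grid = build_grid(),
                              backend = c("scic", "table"), table = NULL,
                              e_protein = 0, e_electrode = 0,
                              et = et_params(), patch_n = 10,
                              patch_standard_only = TRUE) {
  backend <- match.arg(backend)
  structure <- as_structure(structure,
                            label = attr(structure, "label") %||% "structure",
                            et_entry_serial = attr(structure, "et_entry_serial"))
  has_entry <- !is.na(attr(structure, "et_entry_serial"))

  table_e <- NULL
  if (backend == "table") {
    if (is.null(table)) abort("table backend requires an energy table")
    tab <- table_interaction_energy(table, e_protein, e_electrode)
    key <- paste(round(tab$theta_deg, 6), round(tab$phi_deg, 6))
    gkey <- paste(round(grid$theta_deg, 6), round(grid$phi_deg, 6))
    hit <- match(gkey, key)
    if (anyNA(hit)) {
      miss <- grid[is.na(hit), c("theta_deg", "phi_deg")]
      abort(paste0("energy table is missing ", nrow(miss),
                   " grid orientation(s), e.g. ",
                   paste(sprintf("(%g, %g)", head(miss$theta_deg, 5),
                                 head(miss$phi_deg, 5)), collapse = ", ")))
    }
    table_e <- tab$delta_e_kj_mol[hit]
  }

  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    placed <- place(orient(structure, grid$theta_deg[i], grid$phi_deg[i]),
                    gap = env$gap)
    delta_e <- if (backend == "scic") {
      scic_interaction_energy(placed, env)$total
    } else {
      table_e[i]
    }
    res <- nearest_residue(placed, standard_only = patch_standard_only)
    tibble(
      theta_deg = grid$theta_deg[i], phi_deg = grid$phi_deg[i],
      weight_sr = grid$weight_sr[i],
      delta_e_kj_mol = delta_e,
      r_angstrom = if (has_entry) et_distance(placed) else NA_real_,
      nearest_residue = sprintf("%s %d", res$residue_name, res$residue_seq),
      q10_e = patch_charge(placed, n = patch_n,
                           standard_only = patch_standard_only))
  })
  records <- dplyr::bind_rows(rows)

  probs <- boltzmann_probabilities(records$delta_e_kj_mol, env$temperature)
  ks <- adsorption_constants(records$delta_e_kj_mol, env$temperature)
  records$probability <- probs
  records$K_i_au <- ks$K_i
  records$k_et_au <- if (has_entry) et_rate(records$r_angstrom, et) else NA_real_
  records$p_times_k_au <- records$probability * records$k_et_au

  J0 <- if (has_entry) {
    reference_current_density(probs, records$k_et_au, et)
  } else NA_real_

  out <- list(records = records, env = env, et = et,
              K_total = ks$K_total, J0 = J0, M = nrow(grid),
              backend = backend,
              label = attr(structure, "label"))
  class(out) <- "orientation_scan"
  out
}

#' @export
print.orientation_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<orientation_scan> '%s', %d orientations (%s backend)\n",
              x$label, x$M, x$backend))
  cat(sprintf("  minimum-energy orientation: theta %g, phi %g deg; dE_min %.3f kJ/mol (P = %.4f)\n",
              g$theta_min_deg, g$phi_min_deg, g$delta_e_min_kj_mol, g$p_min))
  cat(sprintf("  r_min %.2f A at %s, patch charge %+d e\n",
              g$r_min_angstrom, g$aa_min, g$q10_min_e))
  cat(sprintf("  K_total = %.4g AU, J0 = %.4g AU\n", g$K_total_au, g$J0_au))
  invisible(x)
}

#' Per-orientation records of a scan
#'
#' One row per sampled orientation: angles, solid-angle weight, interaction
#' energy, Boltzmann probability, orientation-resolved Langmuir constant,
#' ET-entry distance and rate, their product (each orientation's
#' contribution to J0), nearest residue and contact-patch charge.
#'
#' @param x An `orientation_scan`.
#' @param ... Unused.
#' @return A tibble with M rows.
#' @method tidy orientation_scan
#' @export
tidy.orientation_scan <- function(x, ...) x$records

#' One-row ensemble summary of a scan
#'
#' The minimum-energy orientation and its observables (`delta_e_min`,
#' `p_min`, `r_min`, nearest residue, patch charge) plus the ensemble-level
#' `K_total` and `J0`.
#'
#' @param x An `orientation_scan`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance orientation_scan
#' @export
glance.orientation_scan <- function(x, ...) {
  i <- which.min(x$records$delta_e_kj_mol)
  r <- x$records[i, ]
  tibble(M = x$M,
         theta_min_deg = r$theta_deg, phi_min_deg = r$phi_deg,
         delta_e_min_kj_mol = r$delta_e_kj_mol,
         p_min = r$probability,
         r_min_angstrom = r$r_angstrom,
         aa_min = r$nearest_residue,
         q10_min_e = r$q10_e,
         K_total_au = x$K_total,
         J0_au = x$J0)
}

#' Current/coverage isotherm report for a completed scan
#'
#' Evaluates the Langmuir coverage and total current of a scan over a grid
#' of osmotic pressures, optionally tracking the per-orientation coverage of
#' selected orientations (columns `chi_theta_phi`).
#'
#' @param scan An `orientation_scan`.
#' @param Pi_grid Osmotic pressures, AU.
#' @param track Optional integer indices of orientations (rows of
#'   `tidy(scan)`) whose individual coverages are appended.
#' @return Tibble with `pi_au`, `chi`, `j_au` and any tracked columns.
#' @export
isotherm_report <- function(scan, Pi_grid = 10^seq(-3, 3, length.out = 61),
                            track = NULL) {
  out <- adsorption_isotherm(Pi_grid, scan$K_total, scan$J0, scan$et)
  if (!is.null(track)) {
    for (i in track) {
      nm <- sprintf("chi_%g_%g", scan$records$theta_deg[i],
                    scan$records$phi_deg[i])
      out[[nm]] <- scan$records$probability[i] * out$chi
    }
  }
  out
}
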