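#' Synthetic quasi-spherical point-charge structure
#'
#' Generates a desk-scale stand-in for a prepared protein PQR: `n_atoms`
#' point charges with van der Waals radii placed uniformly inside a ball,
#' partial charges drawn from a normal distribution and affinely shifted so
#' the net charge hits `net_charge_target` exactly, residues assigned in
#' consecutive triples cycling through standard amino-acid names, and the
#' atom closest to the centroid named `FE` and marked as the
#' electron-transfer entry site (mimicking a buried metal cluster). Fully
#' reproducible from `seed`.
#'
#' When `dipole_target` (e*Angstrom) is given, a zero-sum charge
#' perturbation linear in the body-frame z coordinate is solved by Newton
#' iteration so the dipole modulus about the center of charge matches the
#' target; geometrically degenerate cases and unreachable targets error.
#'
#' @param n_atoms Number of atoms (>= 2).
#' @param body_radius Ball radius, Angstrom.
#' @param net_charge_target Net charge, e.
#' @param dipole_target Optional dipole modulus, e*Angstrom.
#' @param atom_radius_range Range of van der Waals radii, Angstrom.
#' @param charge_sd Spread of the raw partial charges, e.
#' @param seed Integer seed.
#' @return A structure tibble with marked ET entry atom.
#' @examples
#' toy_protein(n_atoms = 50, net_charge_target = 3, seed = 7) |> net_charge()
#' @export
toy_protein <- function(n_atoms = 150, body_radius = 15,
                        net_charge_target = -5, dipole_target = NULL,
                        atom_radius_range = c(1.2, 2.0), charge_sd = 0.3,
                        seed = 1) {
  if (n_atoms < 2) abort("n_atoms must be >= 2")
  if (body_radius <= 0) abort("body_radius must be > 0")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  # uniform in a ball: gaussian direction x cube-root radius
  dir <- matrix(rnorm(3 * n_atoms), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- body_radius * runif(n_atoms)^(1 / 3)
  xyz <- dir * r

  q <- rnorm(n_atoms, 0, charge_sd)
  q <- q - mean(q) + net_charge_target / n_atoms

  aa <- c("ALA", "GLY", "LYS", "ASP", "SER", "PHE", "GLU", "ARG", "LEU", "THR")
  res_idx <- (seq_len(n_atoms) - 1L) %/% 3L + 1L
  entry <- which.min(rowSums(xyz^2))

  atoms <- tibble(
    serial = seq_len(n_atoms),
    name = ifelse(seq_len(n_atoms) == entry, "FE",
                  paste0("C", (seq_len(n_atoms) - 1L) %% 3L + 1L)),
    residue_name = aa[(res_idx - 1L) %% length(aa) + 1L],
    chain = "A",
    residue_seq = res_idx,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = q,
    radius = runif(n_atoms, atom_radius_range[1], atom_radius_range[2]))

  s <- as_structure(atoms, label = sprintf("toy_protein(seed=%d)", seed),
                    et_entry_serial = entry)
  if (!is.null(dipole_target)) s <- .tune_dipole(s, dipole_target)
  s
}

# adjust dipole modulus via a zero-sum z-linear charge perturbation; the
# modulus is V-shaped in the perturbation strength, so bracket a sign change
# of (modulus - target) and polish with uniroot
.tune_dipole <- function(s, target) {
  zc <- s$z - mean(s$z)
  if (max(abs(zc)) < 1e-9) abort("dipole_target infeasible: degenerate geometry")
  g <- function(a) {
    s2 <- s
    s2$charge <- s$charge + a * zc
    dipole_moment(s2)$modulus_eA - target
  }
  grid <- sort(c(0, 2^seq(-6, 12), -(2^seq(-6, 12))))
  vals <- vapply(grid, g, numeric(1))
  flip <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (length(flip) == 0) {
    abort("dipole_target infeasible for this geometry (below the reachable minimum)")
  }
  i <- flip[1]
  a <- stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  if (abs(g(a)) > 1e-6) {
    abort("dipole_target infeasible: adjustment did not converge")
  }
  s$charge <- s$charge + a * zc
  restamp(s, s)
}

#' Two-point dipole fixture
#'
#' Charges of +1 and -1 e separated by `separation` Angstrom along z;
#' net charge zero, dipole modulus equal to `separation` e*Angstrom
#' (4.803 debye per e*Angstrom).
#'
#' @param separation Charge separation, Angstrom.
#' @return A two-atom structure.
#' @export
dipole_fixture <- function(separation = 1) {
  if (separation <= 0) abort("separation must be > 0")
  as_structure(tibble(
    serial = 1:2, name = c("P", "N"), residue_name = c("LYS", "ASP"),
    chain = "A", residue_seq = 1:2,
    x = 0, y = 0, z = c(separation / 2, -separation / 2),
    charge = c(1, -1), radius = 1.5),
    label = "dipole_fixture")
}

#' Synthetic per-orientation energy table with ground truth
#'
#' Evaluates a parametric energy landscape (plus optional gaussian noise) on
#' an orientation grid and returns the external-table CSV payload together
#' with brute-force ground truth for the ensemble observables: Boltzmann
#' probabilities, `K_total` and `J0` computed by direct summation,
#' independent of the package's ensemble path. Used to validate the table
#' backend and the ensemble pipeline end to end.
#'
#' @param grid An orientation grid from [build_grid()].
#' @param landscape Function of `(theta_deg, phi_deg)` (vectorised) giving
#'   the interaction energy, kJ/mol.
#' @param noise Gaussian noise s.d. added to the energies, kJ/mol.
#' @param seed Integer seed for the noise.
#' @param r_fn Function of `(theta_deg, phi_deg)` giving the ET distance,
#'   Angstrom (default: constant 1).
#' @param temperature Temperature, K.
#' @param params An [et_params()] used for the ground-truth J0.
#' @param path Optional CSV path; when given, the table is written there.
#' @return List with `table` (tibble `theta_deg`, `phi_deg`,
#'   `e_total_kj_mol`), `truth` (list `probabilities`, `K_total`, `J0`,
#'   `r`), and `path` (NULL unless written).
#' @export
synthetic_energy_table <- function(grid, landscape = function(theta, phi) 0,
                                   noise = 0, seed = 1,
                                   r_fn = function(theta, phi) 1,
                                   temperature = 298.15,
                                   params = et_params(), path = NULL) {
  e <- landscape(grid$theta_deg, grid$phi_deg)
  e <- rep_len(e, nrow(grid))
  if (!all(is.finite(e))) abort("landscape must be finite on the grid")
  if (noise > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    e <- e + rnorm(length(e), 0, noise)
  }
  r <- rep_len(r_fn(grid$theta_deg, grid$phi_deg), nrow(grid))

  # ground truth by direct, unstabilised summation
  M <- nrow(grid)
  kt <- kBT(temperature)
  boltz <- exp(-e / kt)
  probs <- boltz / sum(boltz)
  K_total <- sum(boltz / M)
  J0 <- sum(probs * params$C * exp(-params$beta * r)) / params$a0

  tab <- tibble(theta_deg = grid$theta_deg, phi_deg = grid$phi_deg,
                e_total_kj_mol = e)
  if (!is.null(path)) readr::write_csv(tab, path)
  list(table = tab,
       truth = list(probabilities = probs, K_total = K_total, J0 = J0, r = r),
       path = path)
}

# save/restore the RNG state so seeded generators do not disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
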