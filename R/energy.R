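#' Ionic strength of an electrolyte
#'
#' `I = 1/2 * sum(c_j z_j^2)` over the ion species. For a monovalent salt
#' such as NaCl this coincides with the salt concentration. Electroneutrality
#' is not enforced; a charge-imbalanced input is accepted with a warning.
#'
#' @param concentrations Ion concentrations, mol/L.
#' @param charges Integer ion charges, e.
#' @return Ionic strength, mol/L.
#' @examples
#' ionic_strength(c(0.15, 0.15), c(1, -1))  # 0.15 M NaCl
#' @export
ionic_strength <- function(concentrations, charges) {
  if (length(concentrations) != length(charges)) {
    abort("concentrations and charges must have equal length")
  }
  if (length(concentrations) == 0) return(0)
  if (any(concentrations < 0)) abort("concentrations must be >= 0")
  if (abs(sum(concentrations * charges)) > 1e-9 * max(sum(concentrations), 1)) {
    warn("ion charges do not balance; proceeding with the stated composition")
  }
  0.5 * sum(concentrations * charges^2)
}

#' Inverse Debye-Hueckel screening length
#'
#' `kappa = sqrt(2 e^2 N_A * 1000 * I / (eps0 eps_solvent k_B T))`, reported
#' in 1/Angstrom. At I = 0.15 mol/L, T = 298.15 K, eps = 80 this gives
#' kappa ~ 0.126 1/A (a screening length of ~8 A).
#'
#' @param I Ionic strength, mol/L.
#' @param temperature Temperature, K.
#' @param eps_solvent Solvent relative permittivity.
#' @return kappa in 1/Angstrom; 0 when `I = 0`.
#' @export
debye_kappa <- function(I, temperature = 298.15, eps_solvent = 80) {
  if (I < 0) abort("ionic strength must be >= 0")
  if (temperature <= 0) abort("temperature must be > 0")
  with(.const, sqrt(2 * e_C^2 * N_A * 1000 * I /
                      (eps0 * eps_solvent * k_B * temperature)) * 1e-10)
}

#' Solvent/electrolyte/electrode environment
#'
#' Bundles the solution and electrode parameters of a scan: ionic strength
#' (mol/L), temperature (K), protein-interior and solvent dielectric
#' constants, electrode potential `phi_e` (V, an absolute electric potential
#' that is zero at infinity, not a potential against a reference electrode),
#' the protein-electrode gap (Angstrom) and the Stern-layer thickness
#' (metadata only; the gap is the operative geometric parameter). The
#' screening constant `kappa` is derived via [debye_kappa()].
#'
#' @param ionic_strength Ionic strength, mol/L.
#' @param temperature Temperature, K.
#' @param eps_in Protein-interior relative permittivity (used by
#'   [coulomb_energy()]).
#' @param eps_solvent Solvent relative permittivity.
#' @param phi_e Electrode potential, V.
#' @param gap Plane-to-van-der-Waals gap, Angstrom.
#' @param stern Stern-layer thickness, Angstrom (metadata).
#' @return An `electrode_env` list with a derived `kappa` (1/Angstrom).
#' @examples
#' electrode_env(ionic_strength = 0.15, phi_e = 0.05)
#' @export
electrode_env <- function(ionic_strength = 0.15, temperature = 298.15,
                          eps_in = 4, eps_solvent = 80, phi_e = 0,
                          gap = 4.1, stern = 2.0) {
  env <- list(ionic_strength = ionic_strength, temperature = temperature,
              eps_in = eps_in, eps_solvent = eps_solvent, phi_e = phi_e,
              gap = gap, stern = stern,
              kappa = debye_kappa(ionic_strength, temperature, eps_solvent))
  class(env) <- "electrode_env"
  env
}

#' @export
print.electrode_env <- function(x, ...) {
  cat(sprintf(paste0("<electrode_env> I = %g M, T = %g K, phi_e = %+g V, ",
                     "eps_in = %g, eps_solvent = %g, gap = %g A, ",
                     "kappa = %.4f 1/A\n"),
              x$ionic_strength, x$temperature, x$phi_e, x$eps_in,
              x$eps_solvent, x$gap, x$kappa))
  invisible(x)
}

#' Intramolecular Coulomb energy
#'
#' `1/2 * sum_{i != j} k_e q_i q_j / (eps_in r_ij)` in kJ/mol. A large but
#' constant term: independent of the rigid body's orientation and distance
#' from the electrode, so it cancels out of interaction energies.
#'
#' @param structure A structure tibble.
#' @param eps_in Interior relative permittivity.
#' @return Energy, kJ/mol (0 for a single atom).
#' @export
coulomb_energy <- function(structure, eps_in = 4) {
  n <- nrow(structure)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(coords(structure)))
  if (any(d[upper.tri(d)] < 1e-9)) {
    abort("coincident atoms: Coulomb energy is singular")
  }
  qq <- outer(structure$charge, structure$charge)
  diag(d) <- Inf
  0.5 * .const$k_e / eps_in * sum(qq / d)
}

#' Screened-Coulomb image-charge interaction energy
#'
#' Protein-electrode electrostatic interaction energy from the closed-form
#' Green's function of the linearized Poisson-Boltzmann (Debye-Hueckel)
#' equation in a half-space bounded by a conductor held at `phi_e`: every
#' charge at height `z` feels the screened electrode field
#' `phi_e * exp(-kappa z)` and the attraction of its (and every other
#' charge's) mirror image through the plane. The protein charges sit
#' directly in the screened solvent (no low-dielectric cavity); the
#' construction satisfies the constant-potential boundary condition on the
#' plane exactly.
#'
#' The breakdown is `field_term = F * phi_e * sum_i q_i exp(-kappa z_i)` and
#' `image_term = -(k_e / (2 eps_solvent)) * sum_{i,j} q_i q_j
#' exp(-kappa d*_ij) / d*_ij`, `d*_ij` the distance from atom i to the
#' mirror of atom j (the self term `d*_ii = 2 z_i` included); the half on
#' the double sum reflects that the image charges are induced, not fixed.
#' The image term is always attractive (negative).
#'
#' @param placed A placed structure (all atoms at z > 0).
#' @param env An [electrode_env()].
#' @return One-row tibble: `field_term`, `image_term`, `total`, kJ/mol.
#' @examples
#' s <- place(toy_protein(seed = 1), gap = 4.1)
#' scic_interaction_energy(s, electrode_env(ionic_strength = 0.15))
#' @export
scic_interaction_energy <- function(placed, env = electrode_env()) {
  if (any(placed$z <= 0)) {
    abort("all charges must lie at z > 0 (above the electrode plane)")
  }
  q <- placed$charge
  kap <- env$kappa
  field <- .const$F_kJ * env$phi_e * sum(q * exp(-kap * placed$z))

  xyz <- coords(placed)
  mirror <- xyz
  mirror[, 3] <- -mirror[, 3]
  dm <- sqrt(pmax(outer(rowSums(xyz^2), rowSums(mirror^2), "+") -
                    2 * xyz %*% t(mirror), 0))
  dm[dm < 1e-12] <- 1e-12
  image <- -(.const$k_e / (2 * env$eps_solvent)) *
    sum(outer(q, q) * exp(-kap * dm) / dm)

  tibble(field_term = field, image_term = image, total = field + image)
}

#' Electrostatic potential of the screened image-charge model
#'
#' Evaluates the model potential (in volts) at arbitrary points: the
#' electrode term `phi_e * exp(-kappa z)` plus the screened Coulomb
#' potential of every charge and its negative mirror image. On the plane
#' z = 0 the charge and image contributions cancel pairwise, so the
#' potential equals `phi_e` there by construction.
#'
#' @param points Numeric matrix (n x 3) or data frame with x, y, z columns,
#'   Angstrom.
#' @param placed A placed structure.
#' @param env An [electrode_env()].
#' @return Potential at each point, V.
#' @export
scic_potential <- function(points, placed, env = electrode_env()) {
  pts <- as.matrix(as.data.frame(points)[, 1:3])
  kap <- env$kappa
  q <- placed$charge
  xyz <- coords(placed)
  mirror <- xyz
  mirror[, 3] <- -mirror[, 3]
  volt_per_eA <- .const$k_e / (.const$F_kJ * env$eps_solvent)
  pot <- env$phi_e * exp(-kap * pmax(pts[, 3], 0))
  for (j in seq_along(q)) {
    s  <- sqrt(colSums((t(pts) - xyz[j, ])^2))
    sp <- sqrt(colSums((t(pts) - mirror[j, ])^2))
    pot <- pot + volt_per_eA * q[j] *
      (exp(-kap * s) / pmax(s, 1e-12) - exp(-kap * sp) / pmax(sp, 1e-12))
  }
  pot
}

#' Charge induced on the electrode
#'
#' Integrates the induced surface charge density
#' `sigma = -eps0 eps_solvent dphi/dz |_{z=0}` of the analytic half-space
#' solution over a disc of radius `disc_radius` centered under the origin,
#' by midpoint ring quadrature. In the unscreened, grounded limit
#' (kappa = 0, phi_e = 0) the integral over a large disc approaches minus
#' the net protein charge (Gauss's law); a held potential adds a uniform
#' area-proportional contribution `eps kappa F phi_e / (4 pi k_e)` per
#' square Angstrom.
#'
#' @param placed A placed structure (may have zero atoms' worth of charge
#'   influence if `charge` is all zero).
#' @param env An [electrode_env()].
#' @param disc_radius Disc radius, Angstrom.
#' @param n_rings Number of radial quadrature rings.
#' @param n_azimuth Azimuthal points per ring.
#' @return Induced charge, e.
#' @export
induced_charge <- function(placed, env = electrode_env(), disc_radius = 200,
                           n_rings = 400, n_azimuth = 64) {
  lateral <- max(sqrt(placed$x^2 + placed$y^2), 0)
  if (disc_radius < lateral) {
    warn("disc_radius is smaller than the structure's lateral extent")
  }
  kap <- env$kappa
  q <- placed$charge
  xyz <- coords(placed)

  dr <- disc_radius / n_rings
  rho <- (seq_len(n_rings) - 0.5) * dr
  alpha <- (seq_len(n_azimuth) - 0.5) * (2 * pi / n_azimuth)
  px <- outer(rho, cos(alpha))          # n_rings x n_azimuth
  py <- outer(rho, sin(alpha))

  # sigma from the held potential: uniform, eps*kappa*F*phi_e/(4*pi*k_e) e/A^2
  sigma_plane <- env$eps_solvent * kap * .const$F_kJ * env$phi_e /
    (4 * pi * .const$k_e)
  total <- sigma_plane * pi * disc_radius^2

  # sigma from each charge: -q_j z_j (1 + kappa s) exp(-kappa s) / (2 pi s^3)
  area <- outer(rho * dr, rep(2 * pi / n_azimuth, n_azimuth))
  for (j in seq_along(q)) {
    s <- sqrt((px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + xyz[j, 3]^2)
    sigma_j <- -q[j] * xyz[j, 3] * (1 + kap * s) * exp(-kap * s) / (2 * pi * s^3)
    total <- total + sum(sigma_j * area)
  }
  total
}
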