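#' Electron-transfer model parameters
#'
#' Parameters of the exponential distance-decay rate model and the current
#' bookkeeping: decay constant `beta` (1/Angstrom; 0.45 by default, from
#' tunnelling-rate calculations for a related hydrogenase on graphene — the
#' steeper literature value 1.4 is available as the `"steep"` profile), rate
#' prefactor `C`, area per adsorbed protein `a0` and electrode area `A`.
#' `C`, `a0` and `A` absorb unknown prefactors (driving force,
#' reorganisation energy, reference states); they are carried in arbitrary
#' units and default to 1, but may serve as adjustable parameters when
#' fitting experimental currents.
#'
#' @param beta Decay constant, 1/Angstrom.
#' @param C Rate prefactor, AU.
#' @param a0 Area per adsorbed protein, AU.
#' @param A Electrode area, AU.
#' @param profile `"default"` (beta 0.45) or `"steep"` (beta 1.4);
#'   an explicit `beta` overrides the profile.
#' @return An `et_params` list.
#' @export
et_params <- function(beta = NULL, C = 1, a0 = 1, A = 1,
                      profile = c("default", "steep")) {
  profile <- match.arg(profile)
  if (is.null(beta)) beta <- if (profile == "steep") 1.4 else 0.45
  if (beta <= 0 || C <= 0 || a0 <= 0 || A <= 0) {
    abort("beta, C, a0 and A must all be > 0")
  }
  out <- list(beta = beta, C = C, a0 = a0, A = A)
  class(out) <- "et_params"
  out
}

#' Exponential distance-decay electron-transfer rate
#'
#' `k = C * exp(-beta * r)`: tunnelling/hopping between the electrode and
#' the enzyme's electron entry site decays exponentially with their
#' separation.
#'
#' @param r Distance(s), Angstrom; >= 0.
#' @param params An [et_params()].
#' @return Rate(s), AU.
#' @export
et_rate <- function(r, params = et_params()) {
  if (any(r < 0)) abort("distances must be >= 0")
  params$C * exp(-params$beta * r)
}

#' Reference current density
#'
#' Probability-weighted mean electron-transfer rate per unit protein
#' footprint, `J0 = (1/a0) * sum_i P_i k_i`. Independent of protein
#' concentration and electrode area; it sets the saturation current `A*J0`.
#'
#' @param probabilities Orientation probabilities summing to 1.
#' @param rates Per-orientation ET rates, AU.
#' @param params An [et_params()].
#' @return J0, AU.
#' @export
reference_current_density <- function(probabilities, rates,
                                      params = et_params()) {
  if (length(probabilities) != length(rates)) {
    abort("probabilities and rates must have equal length")
  }
  if (abs(sum(probabilities) - 1) > 1e-8) {
    abort("probabilities must sum to 1")
  }
  sum(probabilities * rates) / params$a0
}

#' Total electrode current
#'
#' `J = A * chi * J0`: proportional to electrode area and to its coverage.
#'
#' @param chi Coverage in [0, 1].
#' @param J0 Reference current density, AU.
#' @param params An [et_params()].
#' @return Current, AU.
#' @export
total_current <- function(chi, J0, params = et_params()) {
  if (any(chi < -1e-12 | chi > 1 + 1e-12)) abort("chi must lie in [0, 1]")
  params$A * chi * J0
}

#' Current-pressure isotherm
#'
#' Tabulates coverage and total current over a grid of osmotic pressures:
#' `chi = K Pi / (1 + K Pi)` and `J = A chi J0`. `J(Pi)` is nondecreasing
#' and saturates at the plateau `A * J0`.
#'
#' @param Pi_grid Osmotic pressures, AU; >= 0.
#' @param K_total Overall adsorption constant, AU.
#' @param J0 Reference current density, AU.
#' @param params An [et_params()].
#' @return Tibble with columns `pi_au`, `chi`, `j_au`.
#' @export
adsorption_isotherm <- function(Pi_grid, K_total, J0, params = et_params()) {
  chi <- coverage(Pi_grid, K_total)
  tibble(pi_au = Pi_grid, chi = chi,
         j_au = total_current(chi, J0, params))
}
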