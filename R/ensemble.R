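#' Boltzmann orientation probabilities
#'
#' `P_i = exp(-E_i / k_B T) / sum_j exp(-E_j / k_B T)`, computed with
#' max-subtraction so deeply negative adsorption energies (tens of k_B T in
#' salt-free solutions) cannot overflow. Adding a constant to every energy
#' leaves the probabilities unchanged, which is why interaction energies can
#' stand in for total energies.
#'
#' @param energies Per-orientation energies, kJ/mol.
#' @param temperature Temperature, K.
#' @return Probabilities summing to 1.
#' @examples
#' boltzmann_probabilities(c(0, -kBT_kJ(298.15) * log(2)))  # 1:2 ratio
#' @export
boltzmann_probabilities <- function(energies, temperature = 298.15) {
  if (length(energies) == 0) abort("at least one orientation energy is required")
  if (!all(is.finite(energies))) abort("energies must be finite")
  w <- -energies / kBT(temperature)
  w <- exp(w - max(w))
  w / sum(w)
}

#' Thermal energy in kJ/mol
#'
#' `k_B T` expressed on the molar scale (`R * T / 1000`); ~2.479 kJ/mol at
#' 298.15 K.
#'
#' @param temperature Temperature, K.
#' @return kJ/mol.
#' @export
kBT_kJ <- function(temperature = 298.15) kBT(temperature)

#' Orientation-resolved Langmuir adsorption constants
#'
#' `K_i = (unit_prefactor / M) * exp(-delta_e_i / k_B T)` and their sum
#' `K_total`. The `1/M` prefactor accounts for the rotational entropy a
#' protein loses when it adsorbs into one specific orientation out of the M
#' sampled ones. The bracket of vibrational/reference-state factors is not
#' computable here and is fixed to one arbitrary unit (AU), so K — and the
#' osmotic pressure it multiplies — carry arbitrary units, as is standard
#' for this model.
#'
#' @param energies Per-orientation interaction energies, kJ/mol.
#' @param temperature Temperature, K.
#' @param M Number of orientations; defaults to `length(energies)` and must
#'   match it.
#' @param unit_prefactor The constant bracket, AU.
#' @return List with `K_i` (length-M vector, AU) and `K_total` (AU).
#' @export
adsorption_constants <- function(energies, temperature = 298.15,
                                 M = length(energies), unit_prefactor = 1) {
  if (M != length(energies)) {
    abort("M must equal the number of orientation energies")
  }
  if (unit_prefactor <= 0) abort("unit_prefactor must be > 0")
  K_i <- (unit_prefactor / M) * exp(-energies / kBT(temperature))
  list(K_i = K_i, K_total = sum(K_i))
}

#' Langmuir coverage isotherm
#'
#' Fraction of the electrode covered by adsorbed protein at osmotic
#' pressure Pi: `chi = K Pi / (1 + K Pi)`. Linear in Pi for Pi << 1/K,
#' saturating at a full monolayer (chi = 1) for Pi >> 1/K. Assumes
#' non-interacting adsorbates (monolayer, ideal solution).
#'
#' @param Pi Osmotic pressure(s), AU; >= 0.
#' @param K_total Overall adsorption constant, AU.
#' @return Coverage in [0, 1], same length as `Pi`.
#' @export
coverage <- function(Pi, K_total) {
  if (any(Pi < 0)) abort("osmotic pressure must be >= 0")
  kp <- K_total * Pi
  ifelse(is.infinite(kp), 1, kp / (1 + kp))
}

#' Split coverage over orientations
#'
#' The coverage held by each orientation is proportional to its Boltzmann
#' probability, `chi_i = P_i * chi`, so the per-orientation coverages sum
#' back to the overall coverage.
#'
#' @param chi Overall coverage.
#' @param probabilities Orientation probabilities summing to 1.
#' @return Per-orientation coverages.
#' @export
orientation_coverage <- function(chi, probabilities) {
  if (abs(sum(probabilities) - 1) > 1e-8) {
    abort("probabilities must sum to 1")
  }
  probabilities * chi
}
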