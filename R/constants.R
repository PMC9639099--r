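# Physical constants (CODATA 2018) and the derived molar-scale factors used
# throughout. Internal units: length in Angstrom, charge in elementary
# charges e, energy in kJ/mol, potential in volt.

.const <- list(
  e_C        = 1.602176634e-19,   # elementary charge, C (exact)
  N_A        = 6.02214076e23,     # Avogadro, 1/mol (exact)
  k_B        = 1.380649e-23,      # Boltzmann, J/K (exact)
  eps0       = 8.8541878128e-12,  # vacuum permittivity, F/m
  R_kJ       = 8.314462618e-3,    # molar gas constant, kJ/(mol K)
  debye_Cm   = 3.33564e-30        # 1 debye in C m
)

# Coulomb constant e^2 N_A / (4 pi eps0), in kJ mol^-1 A e^-2 (~1389.3546)
.const$k_e <- .const$e_C^2 * .const$N_A /
  (4 * pi * .const$eps0) / 1000 * 1e10

# Faraday-style factor e N_A, in kJ mol^-1 e^-1 V^-1 (~96.485)
.const$F_kJ <- .const$e_C * .const$N_A / 1000

# 1 e*Angstrom in debye (~4.8032)
.const$eA_to_debye <- .const$e_C * 1e-10 / .const$debye_Cm

#' Physical constants used by the package
#'
#' Returns the CODATA-derived constants the energy and ensemble modules use:
#' the Coulomb constant `k_e` (kJ mol^-1 A e^-2), the molar charge-potential
#' factor `F_kJ` (kJ mol^-1 e^-1 V^-1), the gas constant `R_kJ`
#' (kJ mol^-1 K^-1) and the e*Angstrom to debye conversion `eA_to_debye`.
#'
#' @return A named list of constants.
#' @examples
#' physical_constants()$eA_to_debye  # ~4.803 D per e*Angstrom
#' @export
physical_constants <- function() {
  .const[c("k_e", "F_kJ", "R_kJ", "eA_to_debye",
           "e_C", "N_A", "k_B", "eps0")]
}

# thermal energy k_B T in kJ/mol
kBT <- function(temperature) .const$R_kJ * temperature
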