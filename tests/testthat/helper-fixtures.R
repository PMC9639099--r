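# shared fixtures and independent brute-force oracles

# minimal hand-built structure: explicit fields, no generator involved
atoms_tbl <- function(z, charge, radius = 1.5, x = 0, y = 0) {
  n <- length(z)
  tibble::tibble(
    serial = seq_len(n), name = paste0("C", seq_len(n)),
    residue_name = "GLY", chain = "A", residue_seq = seq_len(n),
    x = rep_len(x, n), y = rep_len(y, n), z = z,
    charge = rep_len(charge, n), radius = rep_len(radius, n))
}

single_charge <- function(z = 5, charge = 1, radius = 1) {
  as_structure(atoms_tbl(z, charge, radius), et_entry_serial = 1L)
}

# Boltzmann probabilities by direct, unstabilised summation (oracle)
brute_probabilities <- function(energies, temperature = 298.15) {
  kt <- 8.314462618e-3 * temperature
  w <- numeric(length(energies))
  for (i in seq_along(energies)) w[i] <- exp(-energies[i] / kt)
  w / sum(w)
}

# K_total by direct summation (oracle)
brute_K_total <- function(energies, temperature = 298.15) {
  kt <- 8.314462618e-3 * temperature
  tot <- 0
  for (e in energies) tot <- tot + exp(-e / kt) / length(energies)
  tot
}

# J0 by direct summation (oracle)
brute_J0 <- function(energies, r, beta = 0.45, C = 1, a0 = 1,
                     temperature = 298.15) {
  p <- brute_probabilities(energies, temperature)
  tot <- 0
  for (i in seq_along(p)) tot <- tot + p[i] * C * exp(-beta * r[i])
  tot / a0
}

# grid size by direct enumeration of the sampling rule (oracle)
enumerate_M <- function(dtheta = 10, equator_count = 36,
                        intify = round) {
  m <- 0
  for (th in seq(0, 180, by = dtheta)) {
    m <- m + max(1, intify(equator_count * sin(th * pi / 180) + 1e-12))
  }
  m
}
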