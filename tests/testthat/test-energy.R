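test_that("ionic strength follows I = 1/2 sum c z^2", {
  expect_equal(ionic_strength(c(0.15, 0.15), c(1, -1)), 0.15)
  expect_equal(ionic_strength(numeric(0), integer(0)), 0)
  expect_equal(ionic_strength(c(0.1, 0.1), c(2, -2)), 0.4)
  expect_warning(ionic_strength(c(0.1), c(2)), "balance")
  expect_error(ionic_strength(c(0.1), c(1, -1)), "equal length")
})

test_that("Debye kappa matches the physiological value and scales as sqrt(I)", {
  k <- debye_kappa(0.15, 298.15, 80)
  expect_lt(abs(k - 0.125) / 0.125, 0.02)
  expect_equal(debye_kappa(0), 0)
  expect_equal(debye_kappa(0.6), 2 * debye_kappa(0.15), tolerance = 1e-12)
})

test_that("electrode_env derives kappa and validates inputs", {
  env <- electrode_env(ionic_strength = 0.15)
  expect_equal(env$kappa, debye_kappa(0.15, env$temperature, env$eps_solvent))
  expect_equal(electrode_env(ionic_strength = 0)$kappa, 0)
  expect_error(electrode_env(ionic_strength = -1), ">= 0")
})

test_that("Coulomb energy reproduces the pair closed form and its symmetries", {
  two <- as_structure(atoms_tbl(z = c(0, 1), charge = 1))
  expect_equal(coulomb_energy(two, eps_in = 4), 347.34, tolerance = 1e-3)
  expect_equal(coulomb_energy(single_charge()), 0)
  neg <- two; neg$charge <- -neg$charge
  expect_equal(coulomb_energy(neg, 4), coulomb_energy(two, 4))
  # orientation/translation invariance
  s <- toy_protein(n_atoms = 25, seed = 12)
  expect_equal(coulomb_energy(orient(s, 77, 19), 4), coulomb_energy(s, 4),
               tolerance = 1e-9)
  co <- as_structure(atoms_tbl(z = c(1, 1), charge = 1))
  expect_error(coulomb_energy(co), "singular")
})

test_that("single-charge image energy matches the classical grounded-plane closed form", {
  one <- single_charge(z = 5, charge = 1)
  env <- electrode_env(ionic_strength = 0, phi_e = 0, eps_solvent = 80)
  e <- scic_interaction_energy(one, env)
  ke <- physical_constants()$k_e
  expect_equal(e$total, -ke / (2 * 80 * 2 * 5), tolerance = 1e-9)
  expect_equal(e$total, -0.868, tolerance = 1e-3)
  expect_equal(e$field_term, 0)

  # image term is even in the charge
  minus <- single_charge(z = 5, charge = -1)
  expect_equal(scic_interaction_energy(minus, env)$total, e$total)
})

test_that("field term is F * phi_e * q at kappa = 0 and screens with salt", {
  one <- single_charge(z = 5, charge = 1)
  env <- electrode_env(ionic_strength = 0, phi_e = 0.05)
  e <- scic_interaction_energy(one, env)
  expect_equal(e$field_term, 96.485 * 0.05, tolerance = 1e-3)
  salty <- electrode_env(ionic_strength = 0.15, phi_e = 0.05)
  expect_lt(scic_interaction_energy(one, salty)$field_term, e$field_term)
  expect_equal(scic_interaction_energy(one, salty)$field_term,
               e$field_term * exp(-salty$kappa * 5), tolerance = 1e-9)
})

test_that("energy breakdown is additive and the image term is always attractive", {
  s <- place(orient(toy_protein(seed = 13, n_atoms = 30), 40, 98), 4.1)
  for (I in c(0, 0.15)) for (phi in c(-0.05, 0, 0.05)) {
    e <- scic_interaction_energy(s, electrode_env(I, phi_e = phi))
    expect_equal(e$total, e$field_term + e$image_term, tolerance = 1e-12)
    expect_lt(e$image_term, 0)
  }
  below <- single_charge(z = -1)
  expect_error(scic_interaction_energy(below), "z > 0")
})

test_that("image attraction weakens monotonically with gap and with screening", {
  s0 <- orient(toy_protein(seed = 14, n_atoms = 30), 70, 120)
  gaps <- c(3, 4.1, 6, 10, 20)
  mags <- purrr::map_dbl(gaps, function(g) {
    abs(scic_interaction_energy(place(s0, g), electrode_env(0))$image_term)
  })
  expect_true(all(diff(mags) < 0))

  placed <- place(s0, 4.1)
  kappas <- c(0, 0.05, 0.125, 0.3, 1)
  magk <- purrr::map_dbl(kappas, function(k) {
    env <- electrode_env(0)
    env$kappa <- k
    abs(scic_interaction_energy(placed, env)$image_term)
  })
  expect_true(all(diff(magk) < 0))
})

test_that("the model potential equals phi_e on the electrode plane (Dirichlet condition)", {
  s <- place(orient(toy_protein(seed = 15, n_atoms = 40), 110, 270), 4.1)
  env <- electrode_env(ionic_strength = 0.15, phi_e = 0.05)
  set.seed(42)
  pts <- cbind(runif(100, -100, 100), runif(100, -100, 100), 0)
  pot <- scic_potential(pts, s, env)
  expect_lt(max(abs(pot - env$phi_e) / abs(env$phi_e)), 1e-10)
})

test_that("induced charge neutralizes the protein in the grounded unscreened limit", {
  s <- place(orient(toy_protein(seed = 16, n_atoms = 40,
                                net_charge_target = -5), 30, 40), 4.1)
  env <- electrode_env(ionic_strength = 0, phi_e = 0)
  Q <- net_charge(s)
  ic <- induced_charge(s, env, disc_radius = 50 * max(s$z),
                       n_rings = 600, n_azimuth = 64)
  expect_lt(abs(ic - (-Q)) / abs(Q), 0.02)
})

test_that("held potential induces area-proportional positive charge; quadrature converges", {
  nocharge <- single_charge(z = 5)
  nocharge$charge <- 0
  nocharge <- as_structure(nocharge, et_entry_serial = 1L)
  env <- electrode_env(ionic_strength = 0.15, phi_e = 0.05)
  q1 <- induced_charge(nocharge, env, disc_radius = 50, n_rings = 100)
  q2 <- induced_charge(nocharge, env, disc_radius = 100, n_rings = 100)
  expect_gt(q1, 0)
  expect_equal(q2 / q1, 4, tolerance = 1e-6)  # proportional to disc area

  # refinement: coarse -> fine changes more than fine -> finer
  s <- place(orient(toy_protein(seed = 17, n_atoms = 20), 10, 0), 4.1)
  env0 <- electrode_env(0)
  q_coarse <- induced_charge(s, env0, disc_radius = 300, n_rings = 50)
  q_fine <- induced_charge(s, env0, disc_radius = 300, n_rings = 100)
  q_finer <- induced_charge(s, env0, disc_radius = 300, n_rings = 200)
  expect_gt(abs(q_fine - q_coarse), abs(q_finer - q_fine))
  expect_warning(induced_charge(s, env0, disc_radius = 1, n_rings = 5),
                 "lateral")
})

test_that("table bookkeeping subtracts the isolated-state energies", {
  rec <- tibble::tibble(theta_deg = 0, phi_deg = 0, e_total_kj_mol = -100)
  out <- table_interaction_energy(rec, e_protein = -80, e_electrode = -12)
  expect_equal(out$delta_e_kj_mol, -8)

  comp <- tibble::tibble(theta_deg = 0, phi_deg = 0,
                         e_coulomb_kj_mol = -50, e_solvation_kj_mol = -40,
                         e_surface_kj_mol = -10)
  out2 <- table_interaction_energy(comp, e_protein = -80, e_electrode = -12)
  expect_equal(out2$delta_e_kj_mol, -8)

  # the isolated reference against itself is zero
  self <- tibble::tibble(e_total_kj_mol = -92)
  expect_equal(table_interaction_energy(self, -80, -12)$delta_e_kj_mol, 0)
  expect_error(table_interaction_energy(rec, e_protein = NULL,
                                        e_electrode = 0), "isolated")
})

test_that("energy tables read from CSV in both column dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(theta_deg = c(0, 10), phi_deg = c(0, 0),
                                  e_total_kj_mol = c(-1, -2)), f)
  expect_equal(read_energy_table(f)$e_total_kj_mol, c(-1, -2))
  readr::write_csv(tibble::tibble(theta_deg = 0, phi_deg = 0,
                                  e_coulomb_kj_mol = 1, e_solvation_kj_mol = 2,
                                  e_surface_kj_mol = 3), f)
  expect_equal(read_energy_table(f)$e_total_kj_mol, 6)
  readr::write_csv(tibble::tibble(a = 1), f)
  expect_error(read_energy_table(f), "theta_deg")
})
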