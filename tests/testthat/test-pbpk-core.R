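test_that("steady-state blood algebra: mixing bounds, identities, arithmetic", {
  # full-equilibrium fixed point: C_ven = Pb*C_chamber reproduces itself
  expect_equal(arterial_concentration(41.5 * 2, 2, 5.3033, 9.0156, 41.5),
               41.5 * 2, tolerance = 1e-12)
  expect_identical(arterial_concentration(0, 0, 5.3033, 9.0156, 41.5), 0)
  expect_equal(arterial_concentration(0, 1, 5.3033, 9.0156, 41.5),
               1.6331, tolerance = 1e-4)

  d <- derive_physiology(physiological_params())
  P <- chemical_params()$tissue_blood_partitions
  zero <- setNames(rep(0, 5), names(d$flows))
  expect_identical(venous_concentration(zero, d$flows, P, d$QC), 0)

  # equilibrium identity: C_t = P_t * c for all tissues gives C_ven = c
  ct <- P * 0.37
  expect_equal(venous_concentration(ct, d$flows, P, d$QC), 0.37,
               tolerance = 1e-12)

  # single nonzero tissue contributes its flow-weighted share
  one <- zero; one[["liver"]] <- 1.4
  expect_equal(venous_concentration(one, d$flows, P, d$QC),
               d$flows[["liver"]] * 1.4 / 0.7 / d$QC, tolerance = 1e-14)

  expect_error(venous_concentration(ct[1:4], d$flows, P, d$QC), "names")
})

test_that("right-hand side conserves mass analytically", {
  cfg <- default_cfg(500)
  zero <- setNames(rep(0, 10), names(bcmpbpk:::.initial_state(cfg)))
  expect_equal(unname(pbpk_rhs(0, zero, cfg)[[1]]), rep(0, 10),
               tolerance = 1e-15)

  # at an arbitrary interior state, chamber + n_rats*(tissue burden +
  # metabolized) + loss has zero time derivative
  for (kl in c(0, 0.025)) {
    cfg2 <- default_cfg(500, k_loss = kl)
    st <- setNames(c(10, 0.5, 1.2, 0.2, 0.8, 0.6, 0, 0, 0, 0),
                   names(zero))
    d <- pbpk_rhs(0, st, cfg2)[[1]]
    V <- cfg2$physiology$volumes
    total_dot <- d[1] + cfg2$n_rats * (sum(V * d[2:6]) + d[7] + d[8]) + d[10]
    expect_equal(as.numeric(total_dot), 0, tolerance = 1e-12)
  }
})

test_that("simulation matches the closed-form partition equilibrium without metabolism", {
  cfg <- chamber_config(c0_ppm = 1000, metabolic = no_metabolism(),
                        k_loss = 0)
  sim <- simulate_chamber(cfg, times = c(seq(0, 6, 1), seq(20, 200, 20)))
  d <- cfg$physiology
  P <- cfg$chemical$tissue_blood_partitions
  a0 <- ppm_to_mg_per_liter(1000, cfg$chemical$MW) * cfg$V_chamber
  c_eq <- a0 / (cfg$V_chamber +
                  cfg$n_rats * cfg$chemical$P_blood_air * sum(d$volumes * P))
  expect_equal(sim$chamber_mgl[nrow(sim)], c_eq, tolerance = 1e-6)
  expect_lt(mass_balance_error(sim), 1e-6)
})

test_that("zero initial concentration gives the identically zero trajectory", {
  cfg <- default_cfg(0)
  sim <- simulate_chamber(cfg, times = coarse_times)
  expect_true(all(as.matrix(sim[, -1]) == 0))
})

test_that("linear-only kinetics scale linearly with the initial bolus", {
  met <- metabolic_two_pathway(Vmax = 1e-12, Km = 1, kGST = 4.7)
  s1 <- simulate_chamber(chamber_config(c0_ppm = 400, metabolic = met),
                         times = coarse_times)
  s2 <- simulate_chamber(chamber_config(c0_ppm = 800, metabolic = met),
                         times = coarse_times)
  expect_equal(s2$chamber_ppm, 2 * s1$chamber_ppm, tolerance = 1e-7)
  expect_equal(s2$c_liver, 2 * s1$c_liver, tolerance = 1e-6)
})

test_that("chamber concentration declines monotonically and mass stays balanced", {
  for (c0 in c(200, 4000)) {
    for (met in list(metabolic_two_pathway(), metabolic_two_site())) {
      sim <- simulate_chamber(chamber_config(c0_ppm = c0, metabolic = met))
      expect_true(all(diff(sim$chamber_ppm) <= 0))
      expect_true(all(as.matrix(sim[, -1]) > -1e-9))
      expect_lt(mass_balance_error(sim), 1e-6)
    }
  }
})

test_that("two-site with CL2 = 0 matches two-pathway with kGST = 0 trajectory-wise", {
  m1 <- metabolic_two_pathway(Vmax = 3.7, Km = 0.3, kGST = 0)
  m2 <- metabolic_two_site(Vmax1 = 3.7, Km1 = 0.3, CL2 = 0)
  s1 <- simulate_chamber(chamber_config(c0_ppm = 1000, metabolic = m1))
  s2 <- simulate_chamber(chamber_config(c0_ppm = 1000, metabolic = m2))
  expect_equal(s2$chamber_ppm, s1$chamber_ppm, tolerance = 1e-7)
  expect_equal(s2$c_liver, s1$c_liver, tolerance = 1e-6)
})

test_that("stiff solution agrees with a fixed-step RK4 oracle", {
  cfg <- default_cfg(500)
  oracle <- rk4_simulate(cfg, t_end = 0.5, dt = 1e-4)
  sim <- simulate_chamber(cfg, times = oracle$t[-1])
  c_oracle <- unname(oracle$y[-1, 1]) / cfg$V_chamber
  expect_equal(sim$chamber_mgl, c_oracle, tolerance = 1e-5)
})

test_that("compiled and R backends integrate the same system", {
  cfg <- default_cfg(1000, metabolic = metabolic_two_site())
  sC <- simulate_chamber(cfg, times = coarse_times)
  sR <- simulate_chamber(cfg, times = coarse_times, backend = "R")
  expect_equal(sR$chamber_ppm, sC$chamber_ppm, tolerance = 1e-6)
  expect_equal(sR$c_liver, sC$c_liver, tolerance = 1e-5)
  expect_equal(sR$c_arterial, sC$c_arterial, tolerance = 1e-5)
})

test_that("Michaelis-Menten saturation reduces the fraction metabolized at higher boluses", {
  fracs <- vapply(c(200, 1000, 4000), function(c0) {
    met <- metabolic_two_pathway(Vmax = 3.8, Km = 0.35, kGST = 0)
    cfg <- chamber_config(c0_ppm = c0, metabolic = met, k_loss = 0)
    sim <- simulate_chamber(cfg, times = coarse_times)
    a0 <- ppm_to_mg_per_liter(c0, cfg$chemical$MW) * cfg$V_chamber
    n <- nrow(sim)
    cfg$n_rats * (sim$a_met_liver[n] + sim$a_met_kidney[n]) / a0
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
})

test_that("configuration and solver errors are surfaced distinctly", {
  expect_error(chamber_config(c0_ppm = -5), "c0_ppm")
  expect_error(chamber_config(c0_ppm = 500, n_rats = 2.5), "n_rats")
  expect_error(chamber_config(c0_ppm = 500, V_chamber = 0), "V_chamber")
  cfg <- default_cfg(500)
  expect_error(simulate_chamber(cfg, t_end = -1), "t_end")
  expect_error(simulate_chamber(cfg, times = c(2, 1)), "increasing")
})

test_that("simulation CSV writer produces the tidy column layout", {
  sim <- simulate_chamber(default_cfg(500), times = coarse_times)
  path <- tempfile(fileext = ".csv")
  write_simulation(sim, path)
  back <- read.csv(path)
  expect_identical(names(back)[1:3], c("time_hr", "chamber_ppm",
                                       "chamber_mgl"))
  expect_equal(back$chamber_ppm, sim$chamber_ppm, tolerance = 1e-10)
  unlink(path)
})
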