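sens_times <- seq(0, 6, by = 0.1)

test_that("normalized sensitivities start at zero and respect the null-influence construction", {
  cfg <- default_cfg(500)
  for (p in c("Vmax", "Km", "kGST", "k_loss", "P_adipose")) {
    s <- sensitivity_timecourse(cfg, p, "liver_concentration",
                                times = sens_times)
    expect_identical(s$S[1], 0)
    sc <- sensitivity_timecourse(cfg, p, "chamber_air", times = sens_times)
    expect_identical(sc$S[1], 0)
  }

  # cut kidney perfusion: the kidney partition can no longer matter
  cfg0 <- set_model_param(cfg, "Q_kidney", 0)
  s0 <- sensitivity_timecourse(cfg0, "P_kidney", "chamber_air",
                               times = sens_times)
  expect_true(all(s0$S == 0))

  expect_error(sensitivity_timecourse(cfg, "no_such_param", "chamber_air"),
               "unknown parameter")
})

test_that("central differences agree with the forward-sensitivity ODE oracle", {
  cfg <- default_cfg(500)
  for (p in c("Vmax", "Km")) {
    for (v in c("chamber_air", "liver_concentration")) {
      fd <- sensitivity_timecourse(cfg, p, v, times = sens_times)$S
      fo <- sensitivity_timecourse(cfg, p, v, method = "forward_ode",
                                   times = sens_times)$S
      i <- abs(fo) > 1e-6
      expect_lt(max(abs(fd[i] - fo[i]) / abs(fo[i])), 1e-4)
    }
  }
  # forward mode is only wired for the two-pathway metabolic constants
  expect_error(sensitivity_timecourse(cfg, "k_loss", "chamber_air",
                                      method = "forward_ode"),
               "forward_ode")
})

test_that("sensitivity is Richardson-consistent in the step size", {
  cfg <- default_cfg(500)
  s1 <- sensitivity_timecourse(cfg, "Vmax", "liver_concentration",
                               h = 1e-4, times = sens_times)$S
  s2 <- sensitivity_timecourse(cfg, "Vmax", "liver_concentration",
                               h = 5e-5, times = sens_times)$S
  i <- abs(s1) > 1e-3
  expect_lt(max(abs(s1[i] - s2[i]) / abs(s1[i])), 0.01)
})

test_that("more chamber loss always means less chamber chemical", {
  cfg <- default_cfg(500)
  s <- sensitivity_timecourse(cfg, "k_loss", "chamber_air",
                              times = sens_times)
  expect_true(all(s$S[s$t_hr > 0] <= 0))
})

test_that("surfaces stack recomputed time courses and reject degenerate grids", {
  cfg <- default_cfg(500, metabolic = metabolic_two_pathway(Vmax = 3.5))
  surf <- sensitivity_surface(cfg, "Vmax", range = c(2.5, 4.5), n_sub = 2,
                              variable = "liver_concentration",
                              times = sens_times)
  expect_identical(surf$param_values, c(2.5, 3.5, 4.5))
  # the row at the nominal value reproduces the standalone computation
  standalone <- sensitivity_timecourse(cfg, "Vmax", "liver_concentration",
                                       times = sens_times)
  expect_identical(surf$S[2, ], standalone$S)

  expect_error(sensitivity_surface(cfg, "Vmax", range = c(2.5, 4.5),
                                   n_sub = 1), "n_sub")
  expect_error(sensitivity_surface(cfg, "Vmax", range = c(4.5, 2.5)),
               "range")
  expect_error(sensitivity_surface(cfg, "Vmax", range = c(-1, 2)),
               "positivity")
})

test_that("identifiability diagnostics expose collinearity and rank", {
  cfg <- default_cfg(500)
  # duplicated parameter: exactly collinear columns, zero smallest sv
  dup <- identifiability_check(cfg, c("Vmax", "Vmax"), "chamber_air",
                               times = sens_times)
  expect_lt(dup$smallest_sv, 1e-10 * max(dup$singular_values))

  one <- identifiability_check(cfg, "Vmax", "chamber_air",
                               times = sens_times)
  expect_equal(one$condition_number, 1, tolerance = 1e-12)

  # the three two-pathway metabolic constants are jointly identifiable
  full <- identifiability_check(cfg, c("Vmax", "Km", "kGST"),
                                "liver_concentration", times = sens_times)
  expect_gt(full$smallest_sv, 0)
  expect_lt(full$condition_number, 1e6)

  # a null column is reported by name
  cfg0 <- set_model_param(cfg, "Q_kidney", 0)
  expect_warning(
    z <- identifiability_check(cfg0, c("Vmax", "P_kidney"), "chamber_air",
                               times = sens_times),
    "P_kidney")
  expect_identical(z$zero_columns, "P_kidney")
})

test_that("model parameters are gettable and settable by name", {
  cfg <- default_cfg(500)
  expect_identical(get_model_param(cfg, "Vmax"), 3.8)
  expect_identical(get_model_param(cfg, "P_blood_air"), 41.5)
  expect_equal(get_model_param(cfg, "Q_liver"),
               0.242 * cfg$physiology$QC, tolerance = 1e-12)
  cfg2 <- set_model_param(cfg, "Km", 0.5)
  expect_identical(cfg2$metabolic$Km, 0.5)
  expect_error(get_model_param(cfg, "Vmax9"), "unknown")
  expect_error(set_model_param(cfg, "Q_brain", 1), "unknown")
})
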