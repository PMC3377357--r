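test_that("cost is zero at the generating truth and rises in its neighborhood", {
  ds <- quick_dataset(metabolic_two_pathway())
  c0 <- as.numeric(cost_log_sse(unname(TRUTH_2P), ds, "two_pathway"))
  expect_lt(c0, 1e-10)
  for (i in 1:3) {
    up <- unname(TRUTH_2P); up[i] <- up[i] * 1.05
    dn <- unname(TRUTH_2P); dn[i] <- dn[i] * 0.95
    expect_gt(as.numeric(cost_log_sse(up, ds, "two_pathway")), c0)
    expect_gt(as.numeric(cost_log_sse(dn, ds, "two_pathway")), c0)
  }
})

test_that("vectorized cost equals a naive per-observation loop", {
  ds <- quick_dataset(metabolic_two_site(), c0 = c(500, 2000),
                      noise_cv = 0.05, seed = 11)
  params <- c(3.0, 0.5, 0.06)
  acc <- 0
  for (sid in unique(ds$series_id)) {
    d <- ds[ds$series_id == sid, ]
    cfg <- chamber_config(c0_ppm = d$c0_ppm_nominal[1],
                          metabolic = metabolic_two_site(params[1], params[2],
                                                         params[3]))
    sim <- simulate_chamber(cfg, times = d$t_hr)
    for (j in seq_len(nrow(d)))
      acc <- acc + (log(sim$chamber_ppm[j]) - log(d$c_ppm[j]))^2
  }
  expect_equal(as.numeric(cost_log_sse(params, ds, "two_site")), acc,
               tolerance = 1e-12)
})

test_that("non-positive observations are excluded with a count", {
  ds <- quick_dataset(metabolic_two_pathway(), c0 = 500)
  ds$c_ppm[3] <- 0
  cost <- cost_log_sse(unname(TRUTH_2P), ds, "two_pathway")
  expect_identical(attr(cost, "n_excluded"), 1L)
  expect_true(is.finite(as.numeric(cost)))
})

test_that("fitting from the truth does not move and reports zero cost", {
  ds <- quick_dataset(metabolic_two_pathway())
  fit <- fit_metabolic_params(ds, "two_pathway", start = unname(TRUTH_2P),
                              restarts = 0)
  expect_lt(fit$cost, 1e-10)
  expect_equal(unname(fit$estimates), unname(TRUTH_2P), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_true(all(fit$per_series_rmse$abs_err_ppm < 1e-3))
})

test_that("error report implements the printed two-norm-over-n formula", {
  # perfect fit: all errors zero
  ds <- quick_dataset(metabolic_two_pathway(), c0 = 500)
  fit0 <- list(hypothesis = "two_pathway", estimates = unname(TRUTH_2P))
  r0 <- rmse_report(fit0, ds)
  expect_true(all(r0$abs_err_ppm < 1e-9))

  # 4 unit residuals on a 100 ppm series: abs = sqrt(4)/4 = 0.5, rel = 0.005
  times4 <- c(0.5, 1, 1.5, 2)
  ds4 <- quick_dataset(metabolic_two_pathway(), c0 = 100, times = times4)
  ds4$c_ppm <- ds4$c_ppm + 1
  r4 <- rmse_report(fit0, ds4)
  expect_equal(r4$abs_err_ppm, 0.5, tolerance = 1e-6)
  expect_equal(r4$rel_err, 0.005, tolerance = 1e-6)

  # residuals (3, 4) on two observations: ||d||2 / n = 5 / 2
  ds2 <- quick_dataset(metabolic_two_pathway(), c0 = 100,
                       times = c(0.5, 1))
  ds2$c_ppm <- ds2$c_ppm + c(3, 4)
  r2 <- rmse_report(fit0, ds2)
  expect_equal(r2$abs_err_ppm, 2.5, tolerance = 1e-6)
})

test_that("log-space cost is invariant under common rescaling for linear kinetics", {
  met <- metabolic_two_pathway(Vmax = 1e-12, Km = 1, kGST = 4.7)
  ds <- quick_dataset(met, c0 = c(300, 900), noise_cv = 0.05, seed = 5)
  ds_scaled <- ds
  ds_scaled$c_ppm <- ds$c_ppm * 3.7
  ds_scaled$c0_ppm_nominal <- ds$c0_ppm_nominal * 3.7
  for (p in list(c(1e-12, 1, 4.7), c(1e-12, 1, 6))) {
    c_a <- as.numeric(cost_log_sse(p, ds, "two_pathway"))
    c_b <- as.numeric(cost_log_sse(p, ds_scaled, "two_pathway"))
    # adaptive stepping differs between the scaled solves; agreement is
    # limited by the solver tolerances, not exact arithmetic
    expect_equal(c_a, c_b, tolerance = 1e-6)
  }
})

test_that("each hypothesis describes the other's noise-free data closely", {
  ds_2p <- quick_dataset(metabolic_two_pathway())
  fit_2s <- fit_metabolic_params(ds_2p, "two_site", start = c(3.7, 0.3, 0.05),
                                 restarts = 0)
  ds_2s <- quick_dataset(metabolic_two_site())
  fit_2p <- fit_metabolic_params(ds_2s, "two_pathway",
                                 start = c(3.8, 0.35, 4.7), restarts = 0)
  # both cross-fits land within a few percent of the data everywhere
  expect_lt(max(fit_2s$per_series_rmse$rel_err), 0.05)
  expect_lt(max(fit_2p$per_series_rmse$rel_err), 0.05)
  # and of the same order as each other
  ratio <- max(fit_2s$per_series_rmse$rel_err) /
    max(fit_2p$per_series_rmse$rel_err)
  expect_true(ratio > 0.01 && ratio < 100)
})

test_that("invalid fitting inputs are rejected", {
  ds <- quick_dataset(metabolic_two_pathway(), c0 = 500)
  expect_error(fit_metabolic_params(ds, "two_pathway", start = c(-1, 1, 1)),
               "start")
  expect_error(fit_metabolic_params(ds, "two_pathway", start = c(1, 1)),
               "start")
  expect_error(cost_log_sse(c(1, -1, 0), ds, "two_pathway"), "positive")
  expect_error(rmse_report(list(estimates = NULL), ds))
})
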