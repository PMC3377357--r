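# shared fixtures: generating truths, coarse designs for fast tests, and a
# fixed-step RK4 integrator used as an independent oracle for the stiff solver

TRUTH_2P <- c(Vmax = 3.8, Km = 0.35, kGST = 4.7)
TRUTH_2S <- c(Vmax1 = 3.7, Km1 = 0.3, CL2 = 0.047)

coarse_times <- seq(0.5, 6, by = 0.5)

default_cfg <- function(c0 = 500, metabolic = metabolic_two_pathway(), ...)
  chamber_config(c0_ppm = c0, metabolic = metabolic, ...)

# effectively metabolism-free parameter set (constructors require Vmax > 0)
no_metabolism <- function()
  metabolic_two_pathway(Vmax = 1e-12, Km = 1, kGST = 0)

quick_dataset <- function(metabolic, c0 = c(200, 1000, 4000), noise_cv = 0,
                          seed = 1, times = coarse_times)
  generate_chamber_dataset(metabolic, c0_ppm = c0, times = times,
                           noise_cv = noise_cv, seed = seed)

# classic fixed-step RK4 on the R right-hand side; independent of lsoda
rk4_simulate <- function(cfg, t_end, dt) {
  y <- bcmpbpk:::.initial_state(cfg)
  n_steps <- round(t_end / dt)
  keep_every <- max(1L, round(n_steps / 50))
  out_t <- 0
  out_y <- matrix(y, nrow = 1)
  for (i in seq_len(n_steps)) {
    k1 <- pbpk_rhs(0, y, cfg)[[1]]
    k2 <- pbpk_rhs(0, y + dt / 2 * k1, cfg)[[1]]
    k3 <- pbpk_rhs(0, y + dt / 2 * k2, cfg)[[1]]
    k4 <- pbpk_rhs(0, y + dt * k3, cfg)[[1]]
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% keep_every == 0) {
      out_t <- c(out_t, i * dt)
      out_y <- rbind(out_y, y)
    }
  }
  list(t = out_t, y = out_y)
}
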