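.STATE_NAMES <- c("a_chamber", "c_adipose", "c_rapid", "c_slow", "c_liver",
                  "c_kidney", "a_met_liver", "a_met_kidney", "a_met_linear",
                  "a_lost")

#' Closed-chamber experiment configuration
#'
#' Binds the chamber (volume, rat count, first-order loss, initial bolus
#' concentration), the derived physiology, the chemical constants and one
#' metabolic hypothesis into the single object consumed by [simulate_chamber()].
#' All rats are identical; one rat's tissue ODEs are integrated and scaled
#' by `n_rats` in the chamber exchange. Chamber defaults are the BCM
#' gas-uptake design: 9 L chamber, 3 rats, loss 0.025/hr.
#'
#' @param c0_ppm initial chamber concentration after the bolus, ppm v/v.
#' @param metabolic a [metabolic_two_pathway()] or [metabolic_two_site()]
#'   object; selects the metabolism hypothesis.
#' @param physiology a `derived_physiology` object (or `physiological_params`,
#'   which is derived automatically).
#' @param chemical a [chemical_params()] object.
#' @param V_chamber chamber gas volume, L.
#' @param n_rats number of rats in the chamber (positive integer).
#' @param k_loss first-order chamber loss rate, 1/hr.
#' @return object of class `chamber_config`.
#' @export
#' @examples
#' cfg <- chamber_config(c0_ppm = 500, metabolic = metabolic_two_pathway())
#' sim <- simulate_chamber(cfg, t_end = 6)
#' head(sim)
chamber_config <- function(c0_ppm,
                           metabolic = metabolic_two_pathway(),
                           physiology = physiological_params(),
                           chemical = chemical_params(),
                           V_chamber = 9, n_rats = 3, k_loss = 0.025) {
  if (inherits(physiology, "physiological_params"))
    physiology <- derive_physiology(physiology)
  stopifnot(inherits(physiology, "derived_physiology"),
            inherits(chemical, "chemical_params"),
            inherits(metabolic, "metabolic_params"))
  if (V_chamber <= 0) stop("V_chamber must be > 0", call. = FALSE)
  if (n_rats < 1 || n_rats != round(n_rats))
    stop("n_rats must be a positive integer", call. = FALSE)
  if (k_loss < 0) stop("k_loss must be >= 0", call. = FALSE)
  if (c0_ppm < 0) stop("c0_ppm must be >= 0", call. = FALSE)

  hypothesis <- if (inherits(metabolic, "metabolic_two_pathway"))
    "two_pathway" else "two_site"
  structure(list(V_chamber = V_chamber, n_rats = as.integer(n_rats),
                 k_loss = k_loss, c0_ppm = c0_ppm,
                 physiology = physiology, chemical = chemical,
                 hypothesis = hypothesis, metabolic = metabolic),
            class = "chamber_config")
}

# flatten a chamber_config into the parameter vector the C model expects
.parms_vector <- function(cfg) {
  ph <- cfg$physiology
  ch <- cfg$chemical
  m <- cfg$metabolic
  ord <- c("adipose", "rapidly_perfused", "slowly_perfused", "liver", "kidney")
  triple <- if (cfg$hypothesis == "two_pathway")
    c(m$Vmax, m$Km, m$kGST) else c(m$Vmax1, m$Km1, m$CL2)
  c(QC = ph$QC, QP = ph$QP, Pb = ch$P_blood_air,
    ph$flows[ord], ph$volumes[ord], ch$tissue_blood_partitions[ord],
    Vch = cfg$V_chamber, n_rats = cfg$n_rats, k_loss = cfg$k_loss,
    hyp = if (cfg$hypothesis == "two_pathway") 1 else 2,
    m1 = triple[1], m2 = triple[2], m3 = triple[3],
    share_l = m$liver_share, share_k = m$kidney_share)
}

.initial_state <- function(cfg) {
  a0 <- ppm_to_mg_per_liter(cfg$c0_ppm, cfg$chemical$MW) * cfg$V_chamber
  setNames(c(a0, rep(0, 9)), .STATE_NAMES)
}

#' Steady-state arterial concentration at the lung/blood interface
#'
#' The lung and blood compartments are algebraic: arterial blood leaving the
#' lung satisfies QC*C_art + QP*C_art/Pb = QC*C_ven + QP*C_chamber, i.e.
#' C_art = (QC*C_ven + QP*C_chamber) / (QC + QP/Pb). Exhaled air is the
#' alveolar equilibrium C_art/Pb.
#'
#' @param C_ven mixed venous blood concentration, mg/L.
#' @param C_chamber chamber gas concentration, mg/L.
#' @param QC cardiac output, L/hr.
#' @param QP alveolar ventilation, L/hr.
#' @param P_b blood:air partition coefficient.
#' @return arterial concentration, mg/L.
#' @export
arterial_concentration <- function(C_ven, C_chamber, QC, QP, P_b) {
  if (any(c(C_ven, C_chamber, QC, QP, P_b) < 0))
    stop("all inputs must be >= 0", call. = FALSE)
  (QC * C_ven + QP * C_chamber) / (QC + QP / P_b)
}

#' Flow-weighted mixed venous concentration
#'
#' C_ven = sum_t Q_t * (C_t / P_t) / QC over the five tissue compartments,
#' each tissue's venous effluent being at equilibrium with the tissue via
#' its tissue:blood partition coefficient (flow-limited assumption).
#'
#' @param C_tissue named numeric of tissue concentrations, mg/L.
#' @param flows named numeric of tissue blood flows, L/hr; must sum to `QC`.
#' @param partitions named numeric of tissue:blood partition coefficients.
#' @param QC cardiac output, L/hr.
#' @return mixed venous concentration, mg/L.
#' @export
venous_concentration <- function(C_tissue, flows, partitions, QC) {
  keys <- names(C_tissue)
  if (is.null(keys) || !setequal(keys, names(flows)) ||
      !setequal(keys, names(partitions)))
    stop("C_tissue, flows and partitions must share compartment names",
         call. = FALSE)
  if (abs(sum(flows) - QC) > 1e-9 * QC)
    stop("flows must sum to QC", call. = FALSE)
  sum(flows[keys] * (C_tissue[keys] / partitions[keys])) / QC
}

#' Right-hand side of the closed-chamber PBPK system (R implementation)
#'
#' Mass-conservation ODEs for the chamber amount, the five flow-limited
#' tissue concentrations of one rat, and cumulative bookkeeping states
#' (amount metabolized in liver/kidney, amount through the linear pathway,
#' amount lost from the chamber). This R version mirrors the compiled C
#' model used by [simulate_chamber()] and serves as the reference for
#' fixed-step oracle integration; metabolism terms clamp concentrations at
#' zero because stiff solvers probe slightly negative values.
#'
#' @param t time, hr (unused; the system is autonomous).
#' @param state named numeric state vector (see [simulate_chamber()] columns).
#' @param cfg a [chamber_config()] object.
#' @return list of derivatives, deSolve convention.
#' @export
pbpk_rhs <- function(t, state, cfg) {
  ph <- cfg$physiology
  ch <- cfg$chemical
  m <- cfg$metabolic
  ord <- .TISSUES
  Q <- ph$flows[ord]; V <- ph$volumes[ord]
  P <- ch$tissue_blood_partitions[ord]

  C <- state[2:6]
  c_ch <- state[[1]] / cfg$V_chamber
  c_ven <- sum(Q * (C / P)) / ph$QC
  c_art <- (ph$QC * c_ven + ph$QP * c_ch) / (ph$QC + ph$QP / ch$P_blood_air)

  cl <- max(C[[4]], 0)
  ck <- max(C[[5]], 0)
  if (cfg$hypothesis == "two_pathway") {
    met_l <- m$liver_share * (m$Vmax * cl / (m$Km + cl) + m$kGST * cl * V[[4]])
    met_k <- m$kidney_share * (m$Vmax * ck / (m$Km + ck) + m$kGST * ck * V[[5]])
    lin <- m$liver_share * m$kGST * cl * V[[4]] +
      m$kidney_share * m$kGST * ck * V[[5]]
  } else if (cfg$hypothesis == "two_site") {
    met_l <- m$liver_share * (m$Vmax1 * cl + m$CL2 * cl^2) / (m$Km1 + cl)
    met_k <- m$kidney_share * (m$Vmax1 * ck + m$CL2 * ck^2) / (m$Km1 + ck)
    lin <- m$liver_share * m$CL2 * cl^2 / (m$Km1 + cl) +
      m$kidney_share * m$CL2 * ck^2 / (m$Km1 + ck)
  } else stop("unknown hypothesis: ", cfg$hypothesis, call. = FALSE)

  dC <- Q * (c_art - C / P) / V
  dC[[4]] <- dC[[4]] - met_l / V[[4]]
  dC[[5]] <- dC[[5]] - met_k / V[[5]]

  d_ach <- cfg$n_rats * ph$QP * (c_art / ch$P_blood_air - c_ch) -
    cfg$k_loss * state[[1]]

  list(c(d_ach, dC, met_l, met_k, lin, cfg$k_loss * state[[1]]))
}

#' Simulate a closed-chamber gas-uptake experiment
#'
#' Integrates the stiff PBPK system from a chamber bolus (`c0_ppm` in the
#' chamber, naive rats) using deSolve's `lsoda` on the compiled model.
#' Default output grid is 0 to `t_end` hours at 0.02 hr, matching the
#' roughly 6-hour span of the vapor-uptake experiments.
#'
#' @param cfg a [chamber_config()] object.
#' @param t_end end of simulation, hr (> 0). Ignored when `times` is given.
#' @param times optional explicit output grid (strictly increasing, >= 0);
#'   a leading 0 is added internally if absent.
#' @param rtol,atol solver tolerances (relative; absolute in mg or mg/L).
#' @param backend `"compiled"` (default, C right-hand side) or `"R"`
#'   ([pbpk_rhs()]); the two agree to solver tolerance.
#' @return a `pbpk_sim` data.frame: `time_hr`, `chamber_mgl`, `chamber_ppm`,
#'   tissue concentrations `c_adipose`, `c_rapid`, `c_slow`, `c_liver`,
#'   `c_kidney` (mg/L), cumulative `a_met_liver`, `a_met_kidney`,
#'   `a_met_linear`, `a_lost` (mg), and algebraic `c_arterial`, `c_venous`
#'   (mg/L). The configuration is attached as attribute `cfg`.
#' @export
simulate_chamber <- function(cfg, t_end = 6, times = NULL,
                             rtol = 1e-8, atol = 1e-10,
                             backend = c("compiled", "R")) {
  stopifnot(inherits(cfg, "chamber_config"))
  backend <- match.arg(backend)
  if (is.null(times)) {
    if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
    times <- seq(0, t_end, by = 0.02)
  }
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  drop_t0 <- times[1] > 0
  solve_times <- if (drop_t0) c(0, times) else times

  y0 <- .initial_state(cfg)
  out <- if (backend == "compiled") {
    deSolve::lsoda(y = y0, times = solve_times, func = "pbpk_derivs",
                   parms = .parms_vector(cfg), dllname = "bcmpbpk",
                   initfunc = "pbpk_initmod", nout = 2,
                   outnames = c("c_arterial", "c_venous"),
                   rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    deSolve::lsoda(y = y0, times = solve_times, func = pbpk_rhs, parms = cfg,
                   rtol = rtol, atol = atol, maxsteps = 50000)
  }

  istate <- attr(out, "istate")
  if (nrow(out) < length(solve_times) || (!is.null(istate) && istate[1] < 0))
    stop(structure(class = c("bcmpbpk_solver_error", "error", "condition"),
                   list(message = paste0(
                     "stiff solver failed (istate = ", istate[1], ") at t ~ ",
                     signif(out[nrow(out), 1], 4), " hr; ",
                     nrow(out), "/", length(solve_times), " points returned"),
                     call = NULL)))

  df <- as.data.frame(out)
  names(df)[1:11] <- c("time_hr", .STATE_NAMES)
  df$chamber_mgl <- df$a_chamber / cfg$V_chamber
  df$chamber_ppm <- mg_per_liter_to_ppm(df$chamber_mgl, cfg$chemical$MW)
  if (backend == "R") {
    # recompute the algebraic bloods for the R backend
    ph <- cfg$physiology; ch <- cfg$chemical
    Q <- ph$flows[.TISSUES]; P <- ch$tissue_blood_partitions[.TISSUES]
    cmat <- as.matrix(df[, c("c_adipose", "c_rapid", "c_slow",
                             "c_liver", "c_kidney")])
    df$c_venous <- as.numeric(cmat %*% (Q / P)) / ph$QC
    df$c_arterial <- (ph$QC * df$c_venous + ph$QP * df$chamber_mgl) /
      (ph$QC + ph$QP / ch$P_blood_air)
  }
  df <- df[, c("time_hr", "chamber_ppm", "chamber_mgl",
               "c_adipose", "c_rapid", "c_slow", "c_liver", "c_kidney",
               "a_met_liver", "a_met_kidney", "a_met_linear", "a_lost",
               "c_arterial", "c_venous")]
  if (drop_t0) df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "cfg") <- cfg
  class(df) <- c("pbpk_sim", "data.frame")
  df
}

#' Mass-balance residual of a simulation
#'
#' At every output time the chamber amount, the rats' tissue burdens,
#' cumulative metabolism and cumulative chamber loss must sum to the initial
#' bolus. Returns the maximum absolute residual relative to the initial
#' amount (0 for a perfectly closed balance).
#'
#' @param sim a `pbpk_sim` from [simulate_chamber()].
#' @return maximum relative mass-balance error (dimensionless).
#' @export
mass_balance_error <- function(sim) {
  cfg <- attr(sim, "cfg")
  stopifnot(inherits(sim, "pbpk_sim"), inherits(cfg, "chamber_config"))
  V <- cfg$physiology$volumes[.TISSUES]
  a0 <- ppm_to_mg_per_liter(cfg$c0_ppm, cfg$chemical$MW) * cfg$V_chamber
  if (a0 == 0) return(0)
  body <- as.matrix(sim[, c("c_adipose", "c_rapid", "c_slow",
                            "c_liver", "c_kidney")]) %*% V
  total <- sim$chamber_mgl * cfg$V_chamber +
    cfg$n_rats * (as.numeric(body) + sim$a_met_liver + sim$a_met_kidney) +
    sim$a_lost
  max(abs(total - a0)) / a0
}

#' Write a simulation result to tidy CSV
#'
#' @param sim a `pbpk_sim`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "pbpk_sim"))
  write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}
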