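.TISSUE_PREFIX <- c(P = "tissue_blood_partitions", Q = "flows", V = "volumes")

#' Get or set a scalar model parameter by name
#'
#' Addressable parameters: the metabolic constants of the active hypothesis
#' (`Vmax`, `Km`, `kGST` or `Vmax1`, `Km1`, `CL2`), chamber scalars
#' (`k_loss`, `V_chamber`), lung/blood scalars (`QC`, `QP`, `P_blood_air`)
#' and per-tissue scalars `P_<tissue>`, `Q_<tissue>`, `V_<tissue>` with
#' tissue one of adipose, rapidly_perfused, slowly_perfused, liver, kidney.
#' Setting a flow or volume perturbs that scalar alone (a local
#' perturbation; the other derived quantities are left at their nominal
#' values).
#'
#' @param cfg a [chamber_config()].
#' @param name parameter name.
#' @param value new value (for `set_model_param`).
#' @return the parameter value, or the modified config.
#' @export
get_model_param <- function(cfg, name) {
  stopifnot(inherits(cfg, "chamber_config"))
  if (name %in% names(cfg$metabolic)[1:3]) return(cfg$metabolic[[name]])
  if (name %in% c("k_loss", "V_chamber")) return(cfg[[name]])
  if (name %in% c("QC", "QP")) return(cfg$physiology[[name]])
  if (name == "P_blood_air") return(cfg$chemical$P_blood_air)
  parts <- regmatches(name, regexec("^([PQV])_(.+)$", name))[[1]]
  if (length(parts) == 3 && parts[3] %in% .TISSUES) {
    slot <- .TISSUE_PREFIX[[parts[2]]]
    owner <- if (parts[2] == "P") cfg$chemical else cfg$physiology
    return(owner[[slot]][[parts[3]]])
  }
  stop("unknown parameter name: '", name, "'", call. = FALSE)
}

#' @rdname get_model_param
#' @export
set_model_param <- function(cfg, name, value) {
  stopifnot(inherits(cfg, "chamber_config"))
  if (name %in% names(cfg$metabolic)[1:3]) {
    cfg$metabolic[[name]] <- value
    return(cfg)
  }
  if (name %in% c("k_loss", "V_chamber")) {
    cfg[[name]] <- value
    return(cfg)
  }
  if (name %in% c("QC", "QP")) {
    cfg$physiology[[name]] <- value
    return(cfg)
  }
  if (name == "P_blood_air") {
    cfg$chemical$P_blood_air <- value
    return(cfg)
  }
  parts <- regmatches(name, regexec("^([PQV])_(.+)$", name))[[1]]
  if (length(parts) == 3 && parts[3] %in% .TISSUES) {
    if (parts[2] == "P")
      cfg$chemical$tissue_blood_partitions[[parts[3]]] <- value
    else if (parts[2] == "Q") cfg$physiology$flows[[parts[3]]] <- value
    else cfg$physiology$volumes[[parts[3]]] <- value
    return(cfg)
  }
  stop("unknown parameter name: '", name, "'", call. = FALSE)
}

.extract_variable <- function(sim, variable) {
  switch(variable,
         chamber_air = sim$chamber_mgl,
         liver_concentration = sim$c_liver,
         stop("unknown variable: ", variable, call. = FALSE))
}

#' Normalized local sensitivity time course
#'
#' Computes `S(t) = (p / y(t)) * dy(t)/dp`, the dimensionless fractional
#' change of the output per fractional change of the parameter, for chamber
#' air concentration or liver concentration. Default method is a central
#' finite difference with relative step `h` on the full simulation; an
#' augmented forward-sensitivity ODE integration is available as an
#' independent verification route for the two-pathway metabolic constants.
#' Where `|y(t)| < guard` (e.g. at t = 0, when the liver is still clean)
#' the normalization is singular and S is defined as 0; the initial state
#' carries no parameter, so S(0) = 0 for every parameter.
#'
#' @param cfg a [chamber_config()] (its `c0_ppm` defines the experiment;
#'   500 ppm is the canonical sensitivity exposure).
#' @param parameter scalar parameter name, see [get_model_param()].
#' @param variable `"chamber_air"` or `"liver_concentration"`.
#' @param method `"central_fd"` or `"forward_ode"`.
#' @param h relative finite-difference step.
#' @param times output grid, hr.
#' @param guard |y| threshold below which S is set to 0.
#' @param rtol,atol solver tolerances; tighter than the simulation defaults
#'   because the finite difference divides solver noise by `2 h`.
#' @return a `sensitivity_result` data.frame (`t_hr`, `S`) with attributes
#'   `parameter`, `variable`, `method`, `c0_ppm`.
#' @export
#' @examples
#' cfg <- chamber_config(c0_ppm = 500, metabolic = metabolic_two_pathway())
#' s <- sensitivity_timecourse(cfg, "Vmax", "liver_concentration")
#' s$t_hr[which.max(abs(s$S))]  # peak within the first two hours
sensitivity_timecourse <- function(cfg, parameter,
                                   variable = c("chamber_air",
                                                "liver_concentration"),
                                   method = c("central_fd", "forward_ode"),
                                   h = 1e-4, times = seq(0, 6, by = 0.02),
                                   guard = 1e-12, rtol = 1e-12, atol = 1e-14) {
  variable <- match.arg(variable)
  method <- match.arg(method)
  p0 <- get_model_param(cfg, parameter)

  if (method == "central_fd") {
    y0 <- .extract_variable(
      simulate_chamber(cfg, times = times, rtol = rtol, atol = atol),
      variable)
    yp <- .extract_variable(
      simulate_chamber(set_model_param(cfg, parameter, p0 * (1 + h)),
                       times = times, rtol = rtol, atol = atol), variable)
    ym <- .extract_variable(
      simulate_chamber(set_model_param(cfg, parameter, p0 * (1 - h)),
                       times = times, rtol = rtol, atol = atol), variable)
    S <- ifelse(abs(y0) < guard, 0, (yp - ym) / (2 * h * y0))
  } else {
    S <- .forward_sensitivity(cfg, parameter, variable, times, guard)
  }

  structure(data.frame(t_hr = times, S = S),
            parameter = parameter, variable = variable, method = method,
            c0_ppm = cfg$c0_ppm,
            class = c("sensitivity_result", "data.frame"))
}

# Forward-sensitivity oracle: integrate the six core states together with
# their derivatives w.r.t. one two-pathway metabolic constant, using the
# analytic state Jacobian of the flow-limited system.
.forward_sensitivity <- function(cfg, parameter, variable, times, guard) {
  if (cfg$hypothesis != "two_pathway" ||
      !parameter %in% c("Vmax", "Km", "kGST"))
    stop("forward_ode sensitivities are implemented for the two-pathway ",
         "metabolic constants (Vmax, Km, kGST); use method = 'central_fd'",
         call. = FALSE)
  ph <- cfg$physiology; ch <- cfg$chemical; m <- cfg$metabolic
  Q <- ph$flows[.TISSUES]; V <- ph$volumes[.TISSUES]
  P <- ch$tissue_blood_partitions[.TISSUES]
  QC <- ph$QC; QP <- ph$QP; Pb <- ch$P_blood_air
  Vch <- cfg$V_chamber; n <- cfg$n_rats; kl <- cfg$k_loss
  D <- QC + QP / Pb
  E_A <- (QP / Vch) / D          # dC_art/dA_ch
  E_C <- (Q / P) / D             # dC_art/dC_t

  aug_rhs <- function(t, y, parms) {
    A <- y[1]; C <- y[2:6]; S <- y[7:12]
    c_ch <- A / Vch
    c_ven <- sum(Q * (C / P)) / QC
    c_art <- (QC * c_ven + QP * c_ch) / D
    cl <- max(C[4], 0); ck <- max(C[5], 0)

    met_l <- m$liver_share * (m$Vmax * cl / (m$Km + cl) +
                                m$kGST * cl * V[4])
    met_k <- m$kidney_share * (m$Vmax * ck / (m$Km + ck) +
                                 m$kGST * ck * V[5])
    dA <- n * QP * (c_art / Pb - c_ch) - kl * A
    dC <- Q * (c_art - C / P) / V
    dC[4] <- dC[4] - met_l / V[4]
    dC[5] <- dC[5] - met_k / V[5]

    # state Jacobian of (A, C1..C5)
    J <- matrix(0, 6, 6)
    J[1, 1] <- n * QP * (E_A / Pb - 1 / Vch) - kl
    J[1, 2:6] <- n * QP * E_C / Pb
    J[2:6, 1] <- (Q / V) * E_A
    J[2:6, 2:6] <- (Q / V) %o% E_C
    diag(J[2:6, 2:6]) <- diag(J[2:6, 2:6]) - Q / (V * P)
    dmetl_dcl <- m$liver_share *
      (m$Vmax * m$Km / (m$Km + cl)^2 + m$kGST * V[4])
    dmetk_dck <- m$kidney_share *
      (m$Vmax * m$Km / (m$Km + ck)^2 + m$kGST * V[5])
    J[5, 5] <- J[5, 5] - dmetl_dcl / V[4]
    J[6, 6] <- J[6, 6] - dmetk_dck / V[5]

    dfdp <- numeric(6)
    if (parameter == "Vmax") {
      dfdp[5] <- -m$liver_share * (cl / (m$Km + cl)) / V[4]
      dfdp[6] <- -m$kidney_share * (ck / (m$Km + ck)) / V[5]
    } else if (parameter == "Km") {
      dfdp[5] <- m$liver_share * m$Vmax * cl / (m$Km + cl)^2 / V[4]
      dfdp[6] <- m$kidney_share * m$Vmax * ck / (m$Km + ck)^2 / V[5]
    } else {
      dfdp[5] <- -m$liver_share * cl
      dfdp[6] <- -m$kidney_share * ck
    }

    list(c(dA, dC, as.numeric(J %*% S) + dfdp))
  }

  a0 <- ppm_to_mg_per_liter(cfg$c0_ppm, ch$MW) * Vch
  y0 <- c(a0, numeric(5), numeric(6))
  drop_t0 <- times[1] > 0
  solve_times <- if (drop_t0) c(0, times) else times
  out <- deSolve::lsoda(y0, solve_times, aug_rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
  if (drop_t0) out <- out[-1, , drop = FALSE]

  p0 <- get_model_param(cfg, parameter)
  if (variable == "chamber_air") {
    y <- out[, 2] / Vch
    dy <- out[, 8] / Vch
  } else {
    y <- out[, 6]
    dy <- out[, 12]
  }
  ifelse(abs(y) < guard, 0, p0 * dy / y)
}

#' Sensitivity surface over a parameter-variability range
#'
#' Recomputes the normalized sensitivity time course at each of `n_sub + 1`
#' equally spaced values of the parameter across `range`, stacking the
#' rows into a time-by-parameter-value surface. This shows how stable the
#' sensitivity structure is when the optimized estimate is varied across
#' its plausible range (e.g. Vmax over 2.5-4.5 mg/hr around the optimized
#' 3.8 mg/hr).
#'
#' @inheritParams sensitivity_timecourse
#' @param range length-2 numeric `(lo, hi)`, `lo < hi`.
#' @param n_sub number of subintervals of the range (>= 2).
#' @return a `sensitivity_surface`: list with `param_values`, `t_hr`, and
#'   matrix `S` (rows = parameter values, columns = times).
#' @export
sensitivity_surface <- function(cfg, parameter, range, n_sub = 8,
                                variable = c("chamber_air",
                                             "liver_concentration"),
                                method = "central_fd", h = 1e-4,
                                times = seq(0, 6, by = 0.02)) {
  variable <- match.arg(variable)
  if (length(range) != 2 || range[1] >= range[2])
    stop("range must be (lo, hi) with lo < hi", call. = FALSE)
  if (n_sub < 2) stop("n_sub must be >= 2", call. = FALSE)
  if (range[1] <= 0)
    stop("range excludes the positivity domain of '", parameter, "'",
         call. = FALSE)
  pv <- seq(range[1], range[2], length.out = n_sub + 1)
  S <- t(vapply(pv, function(p) {
    sensitivity_timecourse(set_model_param(cfg, parameter, p), parameter,
                           variable, method = method, h = h, times = times)$S
  }, numeric(length(times))))
  structure(list(parameter = parameter, variable = variable,
                 param_values = pv, t_hr = times, S = S),
            class = "sensitivity_surface")
}

#' Identifiability diagnostic from sensitivity time courses
#'
#' Assembles the matrix whose columns are the normalized sensitivity time
#' courses of the requested parameters and reports its smallest singular
#' value, condition number, and a per-column same-sign flag. Parameters are
#' locally identifiable when the columns cannot combine to zero: a strictly
#' positive smallest singular value rules out exact collinearity, and an
#' all-positive (or all-negative) column can never be cancelled by itself.
#' Diagnostic only; no hard threshold is applied.
#'
#' @inheritParams sensitivity_timecourse
#' @param parameters character vector of >= 2 parameter names (a single
#'   name is allowed and yields condition number 1).
#' @return list: `parameters`, `singular_values`, `smallest_sv`,
#'   `condition_number`, `same_sign` (named logical), `zero_columns`
#'   (names of identically-zero columns), and the matrix `M`.
#' @export
identifiability_check <- function(cfg, parameters,
                                  variable = c("chamber_air",
                                               "liver_concentration"),
                                  method = "central_fd", h = 1e-4,
                                  times = seq(0, 6, by = 0.02)) {
  variable <- match.arg(variable)
  if (length(parameters) < 1) stop("need >= 1 parameter", call. = FALSE)
  M <- vapply(parameters, function(p)
    sensitivity_timecourse(cfg, p, variable, method = method, h = h,
                           times = times)$S,
    numeric(length(times)))
  M <- as.matrix(M)
  colnames(M) <- parameters
  zero_cols <- parameters[apply(M, 2, function(x) all(x == 0))]
  if (length(zero_cols) > 0)
    warning("identically-zero sensitivity column(s): ",
            paste(zero_cols, collapse = ", "), call. = FALSE)
  sv <- svd(M, nu = 0, nv = 0)$d
  same_sign <- apply(M, 2, function(x) {
    xt <- x[abs(x) > 0]
    length(xt) > 0 && (all(xt > 0) || all(xt < 0))
  })
  list(parameters = parameters, singular_values = sv,
       smallest_sv = min(sv),
       condition_number = if (min(sv) > 0) max(sv) / min(sv) else Inf,
       same_sign = same_sign, zero_columns = zero_cols, M = M)
}
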