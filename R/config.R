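#' Default run configuration
#'
#' A single nested list carrying every model constant (rat physiology,
#' BCM chemical constants, chamber design), the metabolic parameter sets of
#' both hypotheses, the experiment design and the noise/seed settings.
#' Every value can be overridden from a JSON or YAML file via
#' [read_run_config()].
#'
#' @return named list, see [read_run_config()] for the keys.
#' @export
default_run_config <- function() {
  list(
    bw_kg = 0.25, qcc = 15, qv_ratio = 1.7,
    flow_fractions = list(adipose = 0.082, slowly_perfused = 0.257,
                          kidney = 0.138, liver = 0.242),
    volume_fractions = list(slowly_perfused = 0.674, liver = 0.044,
                            kidney = 0.0075, adipose = 0.112),
    mw = 129.38, p_blood_air = 41.5,
    partitions = list(liver = 0.7, rapidly_perfused = 0.7, kidney = 0.7,
                      slowly_perfused = 0.267, adipose = 7.8),
    chamber = list(volume_l = 9, n_rats = 3, loss_per_hr = 0.025),
    hypothesis = "two_pathway",
    metabolic = list(
      two_pathway = list(Vmax = 3.8, Km = 0.35, kGST = 4.7),
      two_site = list(Vmax1 = 3.7, Km1 = 0.3, CL2 = 0.047)),
    design = list(c0_ppm = c(200, 500, 1000, 2000, 4000),
                  t_start = 0.1, t_end = 6, dt = 0.1),
    noise_cv = 0.05, seed = 1L)
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read and validate a run configuration file
#'
#' Reads JSON (`.json`) or YAML (`.yml`/`.yaml`) and merges it over
#' [default_run_config()], so a file need only state the keys it changes.
#' Validation errors name the offending key.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return validated run-config list.
#' @export
read_run_config <- function(path = NULL) {
  rc <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    user <- if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required for YAML configs", call. = FALSE)
      yaml::read_yaml(path)
    } else stop("config must be .json, .yml or .yaml: ", path, call. = FALSE)
    known <- names(rc)
    unknown <- setdiff(names(user), known)
    if (length(unknown) > 0)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    rc <- .merge_config(rc, user)
  }
  validate_run_config(rc)
}

#' @rdname read_run_config
#' @param rc run-config list to validate.
#' @export
validate_run_config <- function(rc) {
  chk <- function(ok, key, what)
    if (!isTRUE(ok)) stop("config key '", key, "' invalid: ", what,
                          call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(rc$bw_kg) && rc$bw_kg > 0, "bw_kg", "positive number required")
  chk(num1(rc$qcc) && rc$qcc > 0, "qcc", "positive number required")
  chk(num1(rc$qv_ratio) && rc$qv_ratio > 0, "qv_ratio",
      "positive number required")
  chk(num1(rc$mw) && rc$mw > 0, "mw", "positive number required")
  chk(num1(rc$p_blood_air) && rc$p_blood_air > 0, "p_blood_air",
      "positive number required")
  chk(num1(rc$chamber$volume_l) && rc$chamber$volume_l > 0,
      "chamber.volume_l", "positive number required")
  chk(num1(rc$chamber$n_rats) && rc$chamber$n_rats >= 1,
      "chamber.n_rats", "positive integer required")
  chk(num1(rc$chamber$loss_per_hr) && rc$chamber$loss_per_hr >= 0,
      "chamber.loss_per_hr", "non-negative number required")
  chk(rc$hypothesis %in% c("two_pathway", "two_site"), "hypothesis",
      "must be 'two_pathway' or 'two_site'")
  chk(num1(rc$noise_cv) && rc$noise_cv >= 0, "noise_cv",
      "non-negative number required")
  for (k in c("adipose", "slowly_perfused", "kidney", "liver"))
    chk(num1(rc$flow_fractions[[k]]), paste0("flow_fractions.", k),
        "missing or non-numeric")
  for (k in c("slowly_perfused", "liver", "kidney", "adipose"))
    chk(num1(rc$volume_fractions[[k]]), paste0("volume_fractions.", k),
        "missing or non-numeric")
  for (k in .TISSUES)
    chk(num1(rc$partitions[[k]]) && rc$partitions[[k]] > 0,
        paste0("partitions.", k), "positive number required")
  chk(is.numeric(rc$design$c0_ppm) && length(rc$design$c0_ppm) >= 1 &&
        all(rc$design$c0_ppm > 0), "design.c0_ppm",
      "non-empty positive vector required")
  chk(num1(rc$design$t_start) && rc$design$t_start > 0, "design.t_start",
      "positive number required")
  chk(num1(rc$design$t_end) && rc$design$t_end > rc$design$t_start,
      "design.t_end", "must exceed design.t_start")
  chk(num1(rc$design$dt) && rc$design$dt > 0, "design.dt",
      "positive number required")
  # constructors re-check the closure invariants and raise named errors
  .rc_physiology(rc)
  .rc_chemical(rc)
  .rc_metabolic(rc, rc$hypothesis)
  rc
}

.rc_physiology <- function(rc)
  physiological_params(BW = rc$bw_kg, QCC = rc$qcc, QV = rc$qv_ratio,
                       flow_fractions = unlist(rc$flow_fractions),
                       volume_fractions = unlist(rc$volume_fractions))

.rc_chemical <- function(rc)
  chemical_params(MW = rc$mw, P_blood_air = rc$p_blood_air,
                  tissue_blood_partitions = unlist(rc$partitions))

.rc_metabolic <- function(rc, hypothesis) {
  m <- rc$metabolic[[hypothesis]]
  if (is.null(m)) stop("config key 'metabolic.", hypothesis, "' missing",
                       call. = FALSE)
  if (hypothesis == "two_pathway")
    metabolic_two_pathway(Vmax = m$Vmax, Km = m$Km, kGST = m$kGST)
  else
    metabolic_two_site(Vmax1 = m$Vmax1, Km1 = m$Km1, CL2 = m$CL2)
}

#' Build a chamber configuration from a run config
#'
#' @param rc validated run-config list.
#' @param c0_ppm initial chamber concentration, ppm.
#' @param hypothesis override of `rc$hypothesis`.
#' @return a [chamber_config()].
#' @export
run_config_chamber <- function(rc, c0_ppm, hypothesis = rc$hypothesis) {
  chamber_config(c0_ppm = c0_ppm,
                 metabolic = .rc_metabolic(rc, hypothesis),
                 physiology = .rc_physiology(rc),
                 chemical = .rc_chemical(rc),
                 V_chamber = rc$chamber$volume_l,
                 n_rats = rc$chamber$n_rats,
                 k_loss = rc$chamber$loss_per_hr)
}

.design_times <- function(rc)
  seq(rc$design$t_start, rc$design$t_end, by = rc$design$dt)
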