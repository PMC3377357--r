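#' Generate a synthetic multi-concentration closed-chamber dataset
#'
#' Emulates the structure of digitized vapor-uptake experiments: several
#' chamber-depletion series differing only in the initial bolus
#' concentration, all generated by [simulate_chamber()] under a known
#' ("truth") metabolic parameter set. Observation noise, when requested, is
#' multiplicative lognormal (`c_obs = c_model * exp(eps)`,
#' `eps ~ N(0, cv^2)`), the natural error model when fitting operates on
#' the natural log of the data. The default design is five series spanning
#' 200-4000 ppm sampled every 0.1 hr from 0.1 to 6 hr; the first sample is
#' taken after chamber mixing, not at the bolus instant.
#'
#' @param metabolic truth metabolic parameters ([metabolic_two_pathway()] or
#'   [metabolic_two_site()]).
#' @param c0_ppm initial concentrations, one series each, ppm.
#' @param times observation grid, hours (strictly increasing, > 0).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise; 0 gives exact model output.
#' @param seed integer seed making noisy generation reproducible.
#' @param physiology,chemical,V_chamber,n_rats,k_loss passed to
#'   [chamber_config()].
#' @return a `chamber_dataset`: data.frame with columns `series_id`,
#'   `c0_ppm_nominal`, `t_hr`, `c_ppm`, carrying the generator settings in
#'   attribute `provenance`.
#' @export
#' @examples
#' ds <- generate_chamber_dataset(metabolic_two_pathway(), noise_cv = 0)
#' table(ds$series_id)
generate_chamber_dataset <- function(metabolic = metabolic_two_pathway(),
                                     c0_ppm = c(200, 500, 1000, 2000, 4000),
                                     times = seq(0.1, 6, by = 0.1),
                                     noise_cv = 0.05,
                                     seed = 1L,
                                     physiology = physiological_params(),
                                     chemical = chemical_params(),
                                     V_chamber = 9, n_rats = 3,
                                     k_loss = 0.025) {
  if (length(c0_ppm) == 0) stop("c0_ppm must be non-empty", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("times must be positive and strictly increasing", call. = FALSE)
  if (length(times) < 2) stop("need >= 2 observations per series",
                              call. = FALSE)

  if (noise_cv > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }

  rows <- lapply(seq_along(c0_ppm), function(i) {
    cfg <- chamber_config(c0_ppm = c0_ppm[i], metabolic = metabolic,
                          physiology = physiology, chemical = chemical,
                          V_chamber = V_chamber, n_rats = n_rats,
                          k_loss = k_loss)
    sim <- simulate_chamber(cfg, times = times)
    obs <- sim$chamber_ppm
    if (noise_cv > 0)
      obs <- obs * exp(rnorm(length(obs), 0, noise_cv))
    data.frame(series_id = sprintf("s%02d_%gppm", i, c0_ppm[i]),
               c0_ppm_nominal = c0_ppm[i], t_hr = times, c_ppm = obs)
  })
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  attr(ds, "provenance") <- list(
    source = "synthetic",
    hypothesis = if (inherits(metabolic, "metabolic_two_pathway"))
      "two_pathway" else "two_site",
    truth = unclass(metabolic)[1:3],
    c0_ppm = c0_ppm, noise_cv = noise_cv,
    seed = if (noise_cv > 0) as.integer(seed) else NA_integer_,
    V_chamber = V_chamber, n_rats = n_rats, k_loss = k_loss)
  class(ds) <- c("chamber_dataset", "data.frame")
  ds
}

.validate_dataset <- function(ds) {
  need <- c("series_id", "c0_ppm_nominal", "t_hr", "c_ppm")
  if (!all(need %in% names(ds)))
    stop("dataset must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(ds) == 0) stop("dataset has no observations", call. = FALSE)
  if (any(!is.finite(ds$t_hr)) || any(!is.finite(ds$c_ppm)))
    stop("non-numeric or missing values in t_hr/c_ppm", call. = FALSE)
  if (any(ds$c_ppm < 0)) stop("negative concentrations present",
                              call. = FALSE)
  for (sid in unique(ds$series_id)) {
    tt <- ds$t_hr[ds$series_id == sid]
    if (length(tt) < 2)
      stop("series '", sid, "' has fewer than 2 observations", call. = FALSE)
    if (any(diff(tt) <= 0))
      stop("times not strictly increasing in series '", sid, "'",
           call. = FALSE)
  }
  invisible(ds)
}

#' Read / write a chamber dataset as CSV
#'
#' Lossless round trip of the tabular format (`series_id`,
#' `c0_ppm_nominal`, `t_hr`, `c_ppm`). `write_chamber_dataset()` also echoes
#' generator provenance, when present, into a sidecar `<path>.json`.
#' Malformed files are rejected with the offending line or series named.
#'
#' @param path CSV file path.
#' @return `read_chamber_dataset()`: a validated `chamber_dataset`.
#' @export
read_chamber_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ds <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("cannot parse '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  if (nrow(ds) == 0 || ncol(ds) < 4)
    stop("'", path, "': empty or truncated dataset file", call. = FALSE)
  num <- c("c0_ppm_nominal", "t_hr", "c_ppm")
  for (col in num) {
    v <- suppressWarnings(as.numeric(ds[[col]]))
    if (anyNA(v))
      stop("'", path, "': non-numeric ", col, " at line(s) ",
           paste(which(is.na(v)) + 1L, collapse = ", "), call. = FALSE)
    ds[[col]] <- v
  }
  .validate_dataset(ds)
  side <- paste0(path, ".json")
  attr(ds, "provenance") <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE)
  else list(source = "external")
  class(ds) <- c("chamber_dataset", "data.frame")
  ds
}

#' @rdname read_chamber_dataset
#' @param ds a `chamber_dataset`.
#' @export
write_chamber_dataset <- function(ds, path) {
  .validate_dataset(ds)
  write.csv(as.data.frame(ds)[, c("series_id", "c0_ppm_nominal",
                                  "t_hr", "c_ppm")],
            path, row.names = FALSE)
  prov <- attr(ds, "provenance")
  if (!is.null(prov) && !identical(prov$source, "external"))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}
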