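#' @useDynLib bcmpbpk
#' @importFrom stats optim rnorm runif setNames sd median quantile
#' @importFrom utils read.csv write.csv modifyList
NULL

# molar volume of an ideal gas at 25 degC, 1 atm, in mL/mmol (ppm convention)
.MOLAR_VOLUME_ML <- 24450

.TISSUES <- c("adipose", "rapidly_perfused", "slowly_perfused", "liver", "kidney")

#' Physiological parameters for an adult F344 rat
#'
#' Bundles body weight, the allometric cardiac-output coefficient, the
#' ventilation:perfusion ratio, and the fractional blood flows and tissue
#' volumes of the named compartments. Defaults are literature values for
#' adult Fischer 344 rats in closed-chamber gas-uptake experiments. The
#' rapidly perfused compartment is not parameterized directly: its flow
#' fraction is the remainder to 1 and its volume fraction the remainder to
#' 0.91 (blood is the residual 9\% of body weight and carries no state).
#'
#' @param BW body weight, kg.
#' @param QCC cardiac output allometric coefficient, L/hr/kg^0.75.
#' @param QV alveolar ventilation to perfusion ratio, dimensionless.
#' @param flow_fractions named numeric: fraction of cardiac output perfusing
#'   adipose, slowly_perfused, kidney and liver.
#' @param volume_fractions named numeric: fraction of body weight occupied by
#'   slowly_perfused, liver, kidney and adipose tissue.
#' @param blood_fraction fraction of body weight that is blood.
#' @return object of class `physiological_params`.
#' @export
#' @examples
#' p <- physiological_params()
#' derive_physiology(p)$QC  # 15 * 0.25^0.75
physiological_params <- function(BW = 0.25,
                                 QCC = 15,
                                 QV = 1.7,
                                 flow_fractions = c(adipose = 0.082,
                                                    slowly_perfused = 0.257,
                                                    kidney = 0.138,
                                                    liver = 0.242),
                                 volume_fractions = c(slowly_perfused = 0.674,
                                                      liver = 0.044,
                                                      kidney = 0.0075,
                                                      adipose = 0.112),
                                 blood_fraction = 0.09) {
  if (!is.numeric(BW) || length(BW) != 1L || !is.finite(BW) || BW <= 0)
    stop("BW must be a single positive number", call. = FALSE)
  if (!is.numeric(QCC) || length(QCC) != 1L || QCC <= 0)
    stop("QCC must be a single positive number", call. = FALSE)
  if (!is.numeric(QV) || length(QV) != 1L || QV <= 0)
    stop("QV must be a single positive number", call. = FALSE)

  need_flow <- c("adipose", "slowly_perfused", "kidney", "liver")
  need_vol <- c("slowly_perfused", "liver", "kidney", "adipose")
  if (!all(need_flow %in% names(flow_fractions)))
    stop("flow_fractions must name: ", paste(need_flow, collapse = ", "),
         call. = FALSE)
  if (!all(need_vol %in% names(volume_fractions)))
    stop("volume_fractions must name: ", paste(need_vol, collapse = ", "),
         call. = FALSE)
  flow_fractions <- flow_fractions[need_flow]
  volume_fractions <- volume_fractions[need_vol]

  if (any(flow_fractions <= 0 | flow_fractions >= 1))
    stop("every flow fraction must lie in (0, 1)", call. = FALSE)
  if (any(volume_fractions <= 0 | volume_fractions >= 1))
    stop("every volume fraction must lie in (0, 1)", call. = FALSE)
  if (blood_fraction <= 0 || blood_fraction >= 1)
    stop("blood_fraction must lie in (0, 1)", call. = FALSE)
  if (sum(flow_fractions) >= 1)
    stop("flow fractions sum to ", sum(flow_fractions),
         "; must be < 1 (remainder perfuses the rapidly perfused tissue)",
         call. = FALSE)
  if (sum(volume_fractions) >= 1 - blood_fraction)
    stop("volume fractions sum to ", sum(volume_fractions), "; must be < ",
         1 - blood_fraction,
         " (remainder is the rapidly perfused tissue)", call. = FALSE)

  structure(list(BW = BW, QCC = QCC, QV = QV,
                 flow_fractions = flow_fractions,
                 volume_fractions = volume_fractions,
                 blood_fraction = blood_fraction),
            class = "physiological_params")
}

#' Chemical parameters: molecular weight and partition coefficients
#'
#' Defaults describe bromochloromethane (BCM, CH2BrCl): blood:air partition
#' 41.5 and tissue:blood partitions derived from tissue:air measurements.
#' MW is computed from standard atomic masses (12.011 + 2*1.008 + 79.904 +
#' 35.453 = 129.38 g/mol).
#'
#' @param MW molecular weight, g/mol.
#' @param P_blood_air blood:air partition coefficient.
#' @param tissue_blood_partitions named numeric, tissue:blood partition
#'   coefficient for each of the five tissue compartments.
#' @return object of class `chemical_params`.
#' @export
chemical_params <- function(MW = 129.38,
                            P_blood_air = 41.5,
                            tissue_blood_partitions = c(
                              liver = 0.7,
                              rapidly_perfused = 0.7,
                              kidney = 0.7,
                              slowly_perfused = 0.267,
                              adipose = 7.8)) {
  if (!is.numeric(MW) || length(MW) != 1L || MW <= 0)
    stop("MW must be a single positive number", call. = FALSE)
  if (P_blood_air <= 0)
    stop("P_blood_air must be > 0", call. = FALSE)
  if (!all(.TISSUES %in% names(tissue_blood_partitions)))
    stop("tissue_blood_partitions must name: ",
         paste(.TISSUES, collapse = ", "), call. = FALSE)
  tissue_blood_partitions <- tissue_blood_partitions[.TISSUES]
  if (any(tissue_blood_partitions <= 0))
    stop("all partition coefficients must be > 0", call. = FALSE)

  structure(list(MW = MW, P_blood_air = P_blood_air,
                 tissue_blood_partitions = tissue_blood_partitions),
            class = "chemical_params")
}

#' Derive absolute flows and volumes from fractional physiology
#'
#' Computes cardiac output by allometry (QC = QCC * BW^0.75), alveolar
#' ventilation (QP = QV * QC), per-tissue blood flows (fraction * QC) and
#' volumes (fraction * BW). The rapidly perfused compartment closes both
#' balances: its flow is QC minus the four named flows, and its volume is
#' (0.91 - sum of named volume fractions) * BW, so the five tissues total
#' 0.91 * BW with blood the remaining 0.09 * BW.
#'
#' @param p a [physiological_params()] object.
#' @return object of class `derived_physiology` with elements `QC`, `QP`
#'   (L/hr), `flows` and `volumes` (named over the five tissues, L/hr and L).
#' @export
derive_physiology <- function(p) {
  stopifnot(inherits(p, "physiological_params"))
  QC <- p$QCC * p$BW^0.75
  QP <- p$QV * QC

  flows <- setNames(numeric(5), .TISSUES)
  flows[names(p$flow_fractions)] <- p$flow_fractions * QC
  flows["rapidly_perfused"] <- QC - sum(p$flow_fractions * QC)

  tissue_total <- 1 - p$blood_fraction
  volumes <- setNames(numeric(5), .TISSUES)
  volumes[names(p$volume_fractions)] <- p$volume_fractions * p$BW
  volumes["rapidly_perfused"] <-
    (tissue_total - sum(p$volume_fractions)) * p$BW

  structure(list(QC = QC, QP = QP,
                 flows = flows[.TISSUES], volumes = volumes[.TISSUES],
                 BW = p$BW, blood_fraction = p$blood_fraction),
            class = "derived_physiology")
}

#' Convert chamber gas concentration between ppm (v/v) and mg/L
#'
#' Uses the 25 degC, 1 atm molar-volume convention (24.45 L/mol):
#' c\[mg/L\] = c\[ppm\] * MW / 24450.
#'
#' @param c_ppm concentration in parts per million by volume (>= 0).
#' @param MW molecular weight, g/mol.
#' @return concentration in mg/L.
#' @export
ppm_to_mg_per_liter <- function(c_ppm, MW) {
  if (!is.numeric(MW) || any(MW <= 0))
    stop("MW must be positive", call. = FALSE)
  if (any(c_ppm < 0)) stop("c_ppm must be >= 0", call. = FALSE)
  c_ppm * MW / .MOLAR_VOLUME_ML
}

#' @rdname ppm_to_mg_per_liter
#' @param c_mgl concentration in mg/L (>= 0).
#' @export
mg_per_liter_to_ppm <- function(c_mgl, MW) {
  if (!is.numeric(MW) || any(MW <= 0))
    stop("MW must be positive", call. = FALSE)
  if (any(c_mgl < 0)) stop("c_mgl must be >= 0", call. = FALSE)
  c_mgl * .MOLAR_VOLUME_ML / MW
}
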