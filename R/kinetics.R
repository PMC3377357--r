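#' Metabolic parameters for the two-pathway hypothesis
#'
#' Saturable CYP2E1 oxidation (Michaelis-Menten, `Vmax`, `Km`) plus a
#' first-order glutathione-S-transferase (GST) conjugation term
#' (`kGST * C * V_tissue`). Whole-body metabolism is split 94.8\% liver /
#' 5.2\% kidney; the split applies to the whole bracketed rate. Defaults
#' are the optimized closed-chamber values for BCM.
#'
#' @param Vmax maximum oxidation velocity, mg/hr.
#' @param Km affinity constant, mg/L.
#' @param kGST first-order GST proportionality constant, 1/hr.
#' @param liver_share,kidney_share fractions of total-body metabolism;
#'   must sum to 1.
#' @return object of class `metabolic_two_pathway`.
#' @export
metabolic_two_pathway <- function(Vmax = 3.8, Km = 0.35, kGST = 4.7,
                                  liver_share = 0.948,
                                  kidney_share = 0.052) {
  if (Vmax <= 0 || Km <= 0) stop("Vmax and Km must be > 0", call. = FALSE)
  if (kGST < 0) stop("kGST must be >= 0", call. = FALSE)
  if (abs(liver_share + kidney_share - 1) > 1e-12)
    stop("liver_share + kidney_share must equal 1", call. = FALSE)
  structure(list(Vmax = Vmax, Km = Km, kGST = kGST,
                 liver_share = liver_share, kidney_share = kidney_share),
            class = c("metabolic_two_pathway", "metabolic_params"))
}

#' Metabolic parameters for the two-binding-site hypothesis
#'
#' A single enzyme (CYP2E1) with an active and an effector site:
#' rate = (Vmax1*C + CL2*C^2) / (Km1 + C), asymptotically linear with
#' slope CL2 at high substrate. `CL2` is the clearance of the second site,
#' Vmax2/Km2. Defaults are the optimized closed-chamber values for BCM.
#'
#' @param Vmax1 maximum rate of the first binding site, mg/hr.
#' @param Km1 affinity constant of the first site, mg/L.
#' @param CL2 second-site clearance, L/hr.
#' @inheritParams metabolic_two_pathway
#' @return object of class `metabolic_two_site`.
#' @export
metabolic_two_site <- function(Vmax1 = 3.7, Km1 = 0.3, CL2 = 0.047,
                               liver_share = 0.948, kidney_share = 0.052) {
  if (Vmax1 <= 0 || Km1 <= 0) stop("Vmax1 and Km1 must be > 0", call. = FALSE)
  if (CL2 < 0) stop("CL2 must be >= 0", call. = FALSE)
  if (abs(liver_share + kidney_share - 1) > 1e-12)
    stop("liver_share + kidney_share must equal 1", call. = FALSE)
  structure(list(Vmax1 = Vmax1, Km1 = Km1, CL2 = CL2,
                 liver_share = liver_share, kidney_share = kidney_share),
            class = c("metabolic_two_site", "metabolic_params"))
}

#' Organ metabolism rates under the two-pathway hypothesis
#'
#' Met_l = liver_share * (Vmax*C_liv/(Km + C_liv) + kGST*C_liv*V_liv) and
#' the analogous kidney term scaled by kidney_share.
#'
#' @param C_liv,C_kid liver and kidney tissue concentrations, mg/L (>= 0).
#' @param p a [metabolic_two_pathway()] object.
#' @param V_liv,V_kid liver and kidney volumes, L.
#' @return named numeric `c(Met_l, Met_k)`, mg/hr.
#' @export
met_rates_two_pathway <- function(C_liv, C_kid, p, V_liv, V_kid) {
  stopifnot(inherits(p, "metabolic_two_pathway"))
  if (any(C_liv < 0) || any(C_kid < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  Met_l <- p$liver_share *
    (p$Vmax * C_liv / (p$Km + C_liv) + p$kGST * C_liv * V_liv)
  Met_k <- p$kidney_share *
    (p$Vmax * C_kid / (p$Km + C_kid) + p$kGST * C_kid * V_kid)
  c(Met_l = Met_l, Met_k = Met_k)
}

#' Organ metabolism rates under the two-binding-site hypothesis
#'
#' Met_l = liver_share * (Vmax1*C_liv + CL2*C_liv^2) / (Km1 + C_liv) and
#' the analogous kidney term scaled by kidney_share. With CL2 = 0 this
#' reduces exactly to single-site Michaelis-Menten kinetics.
#'
#' @inheritParams met_rates_two_pathway
#' @param p a [metabolic_two_site()] object.
#' @return named numeric `c(Met_l, Met_k)`, mg/hr.
#' @export
met_rates_two_site <- function(C_liv, C_kid, p, V_liv, V_kid) {
  stopifnot(inherits(p, "metabolic_two_site"))
  if (any(C_liv < 0) || any(C_kid < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  Met_l <- p$liver_share *
    (p$Vmax1 * C_liv + p$CL2 * C_liv^2) / (p$Km1 + C_liv)
  Met_k <- p$kidney_share *
    (p$Vmax1 * C_kid + p$CL2 * C_kid^2) / (p$Km1 + C_kid)
  c(Met_l = Met_l, Met_k = Met_k)
}
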