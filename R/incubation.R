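#' Oxygen-based volumetric electron transport rate
#'
#' Converts light-dark bottle oxygen rates to a volumetric electron
#' transport rate: JV_O = (NP_O - R_d) x 3.47e-2, where NP_O is the net
#' oxygen evolution rate and R_d the dark respiration rate, both in
#' mg O2 m^-3 h^-1. The factor converts hours to seconds, mg O2 to
#' umol O2, and counts 4 electrons per O2 evolved (see [jv_o_factor()]).
#' Negative values are allowed (net-heterotrophic water).
#'
#' @param NP_O net oxygen evolution rate, mg O2 m^-3 h^-1.
#' @param R_d dark respiration rate, mg O2 m^-3 h^-1.
#' @param factor the unit-chain conversion factor.
#' @return JV_O in umol e^- m^-3 s^-1 (vectorised).
#' @examples
#' jv_o(100, 0)  # 3.47
#' @export
jv_o <- function(NP_O, R_d, factor = jv_o_factor()) {
  (NP_O - R_d) * factor
}

#' Oxygen rates from bottle readings
#'
#' Start/end oxygen concentrations of paired light and dark bottles to
#' hourly rates: NP_O from the light bottle, R_d from the dark bottle
#' (positive = consumption).
#'
#' @param bottles tibble with `O2_start_light`, `O2_end_light`,
#'   `O2_start_dark`, `O2_end_dark` (mg O2 m^-3) and `duration` (h).
#' @return the tibble with `NP_O`, `R_d` and `JV_O` columns added.
#' @export
oxygen_rates <- function(bottles) {
  bottles <- as_tibble(bottles)
  if (any(bottles$duration <= 0)) abort("`duration` must be positive.")
  bottles %>%
    mutate(
      NP_O = (.data$O2_end_light - .data$O2_start_light) / .data$duration,
      R_d = (.data$O2_start_dark - .data$O2_end_dark) / .data$duration,
      JV_O = jv_o(.data$NP_O, .data$R_d)
    )
}

#' Gross carbon fixation from a 13C tracer incubation
#'
#' Standard isotope-mixing tracer computation: the fraction of particulate
#' carbon newly fixed equals the rise of the particulate 13C atom fraction
#' over its natural abundance, relative to the enrichment of the dissolved
#' inorganic carbon pool,
#' \deqn{GP_C = POC \frac{a_{inc} - a_{nat}}{a_{DIC} - a_{nat}} / t.}
#' Only atom-percent differences enter, so the result is invariant to a
#' common additive shift of all three atom fractions.
#'
#' @param bottles tibble with `atom13C_incubated`, `atom13C_natural`,
#'   `atom13C_DIC_enriched` (atom % 13C), `POC` (mg C m^-3), `duration` (h).
#' @return the tibble with a `GP_C` column (mg C m^-3 h^-1) added.
#' @examples
#' b <- tibble::tibble(atom13C_incubated = 2.0, atom13C_natural = 1.1,
#'                     atom13C_DIC_enriched = 11.1, POC = 100, duration = 3)
#' gp_13c(b)$GP_C  # 3
#' @export
gp_13c <- function(bottles) {
  bottles <- as_tibble(bottles)
  need <- c("atom13C_incubated", "atom13C_natural", "atom13C_DIC_enriched",
            "POC", "duration")
  if (!all(need %in% names(bottles))) {
    abort(paste("`bottles` must contain", paste(need, collapse = ", ")))
  }
  grad <- bottles$atom13C_DIC_enriched - bottles$atom13C_natural
  if (any(grad <= 0)) {
    abort("Isotopic gradient (DIC enrichment over natural abundance) must be positive.")
  }
  if (any(bottles$duration <= 0)) abort("`duration` must be positive.")
  bottles %>%
    mutate(GP_C = .data$POC *
             (.data$atom13C_incubated - .data$atom13C_natural) /
             (.data$atom13C_DIC_enriched - .data$atom13C_natural) /
             .data$duration)
}

#' RCII-specific carbon fixation rate
#'
#' PB_C = GP_C / RCII, in mg C nmol RCII^-1 h^-1.
#'
#' @param GP_C volumetric gross carbon fixation, mg C m^-3 h^-1.
#' @param RCII RCII concentration, nmol m^-3, strictly positive.
#' @return PB_C (vectorised).
#' @export
pb_c <- function(GP_C, RCII) {
  if (any(RCII <= 0, na.rm = TRUE)) abort("`RCII` must be strictly positive.")
  GP_C / RCII
}
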