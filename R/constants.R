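#' Unit-chain constants of the rate conversions
#'
#' The two fixed conversion factors of the pipeline, re-derivable from first
#' principles, plus the cross-section unit bridge.
#'
#' @details
#' `jv_o_factor()` converts a net oxygen evolution rate in
#' mg O2 m^-3 h^-1 into a volumetric electron transport rate in
#' umol e^- m^-3 s^-1: one hour is 3600 s, 1 mg O2 is 1000/32 umol O2, and
#' each O2 evolved requires 4 electrons, so the factor is
#' (1/3600) x (1000/32) x 4 = 3.472e-2, conventionally printed 3.47e-2.
#'
#' `phi_conversion_factor()` links the RCII-specific electron transport rate
#' (umol e^- nmol RCII^-1 s^-1) and the RCII-specific carbon fixation rate
#' (mg C nmol RCII^-1 h^-1): 3600 s h^-1 x 12 mg C mmol C^-1 x 10^-3 = 43.2.
#'
#' `sigma_unit_scale()` bridges PAR in umol photons m^-2 s^-1 and an
#' absorption cross section quoted in nm^2, yielding electron rates in
#' umol e^- nmol RCII^-1 s^-1: 6.022e23 photons umol^-1 x 1e-6 x 1e-18
#' m^2 nm^-2 x 1e3 (mol/mol to umol/nmol) = 6.022e-4.
#'
#' @param sig_figs number of significant figures to round to (the field
#'   convention prints three).
#' @return a single numeric value.
#' @examples
#' jv_o_factor()            # 0.0347
#' phi_conversion_factor()  # 43.2
#' @export
jv_o_factor <- function(sig_figs = 3) {
  signif((1 / 3600) * (1000 / 32) * 4, sig_figs)
}

#' @rdname jv_o_factor
#' @export
phi_conversion_factor <- function() {
  3600 * 12 * 1e-3
}

#' @rdname jv_o_factor
#' @export
sigma_unit_scale <- function() {
  6.022e23 * 1e-6 * 1e-18 * 1e3
}
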