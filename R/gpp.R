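#' FRRf-based RCII-specific carbon fixation rate
#'
#' Converts the electron transport rate into a carbon fixation rate through
#' a modelled electron requirement: PB_f = J_f / Phi_e,C x 43.2
#' (mg C nmol RCII^-1 h^-1). Non-positive predictions of the requirement
#' make the record unusable and yield NA.
#'
#' @param J_f RCII-specific electron transport rate
#'   (umol e^- nmol RCII^-1 s^-1).
#' @param phi_pred predicted electron requirement (mol e^- mol C^-1), > 0.
#' @param factor the conversion factor, [phi_conversion_factor()].
#' @return PB_f (vectorised); NA where `phi_pred` <= 0.
#' @examples
#' pb_f_from_phi(1, 4)  # 10.8
#' @export
pb_f_from_phi <- function(J_f, phi_pred, factor = phi_conversion_factor()) {
  ifelse(phi_pred > 0, J_f / phi_pred * factor, NA_real_)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Daily depth-integrated gross primary productivity
#'
#' \deqn{GPP = \int_0^Z RCII(z) \sum_{t=1}^{L} PB(z, t)\, dz}
#' The hourly RCII-specific rates PB(z, t) are summed over the L daylight
#' hours at each depth, multiplied by the RCII concentration profile, and
#' integrated over depth with the trapezoid rule on the supplied grid
#' (1.25 m in the deep basin, 0.5 m in the shallow basin by convention).
#' With PB in mg C nmol RCII^-1 h^-1 and RCII in nmol m^-3 the result is in
#' mg C m^-2 d^-1.
#'
#' @param depth_grid ascending depths from 0 to the integration bottom (m).
#' @param RCII_z RCII concentration at each grid depth (nmol m^-3).
#' @param PB_zt matrix of PB values, one row per grid depth, one column per
#'   daylight hour.
#' @return GPP in mg C m^-2 d^-1.
#' @examples
#' z <- seq(0, 10, by = 0.5)
#' daily_gpp(z, rep(2, length(z)), matrix(3, length(z), 12))  # 2*3*12*10
#' @export
daily_gpp <- function(depth_grid, RCII_z, PB_zt) {
  PB_zt <- as.matrix(PB_zt)
  if (length(depth_grid) != length(RCII_z) ||
      nrow(PB_zt) != length(depth_grid)) {
    abort("`depth_grid`, `RCII_z` and rows of `PB_zt` must align.")
  }
  if (is.unsorted(depth_grid, strictly = TRUE)) {
    abort("`depth_grid` must be strictly ascending.")
  }
  daily_pb <- rowSums(PB_zt)        # sum over the L daylight hours
  trapz(depth_grid, RCII_z * daily_pb)
}

#' Ratio of FRRf-based to 13C-based daily productivity
#'
#' @param gpp_f FRRf-derived daily GPP.
#' @param gpp_13c 13C-derived daily GPP; must be > 0 for the ratio to be
#'   defined (otherwise NA).
#' @return gpp_f / gpp_13c (vectorised).
#' @export
relative_gpp <- function(gpp_f, gpp_13c) {
  ifelse(gpp_13c > 0, gpp_f / gpp_13c, NA_real_)
}

#' Hourly surface PAR over a daylight period
#'
#' Half-sine model of the diel irradiance course: E_0(t) =
#' E_noon sin(pi t / L) evaluated at hour midpoints t = 0.5, ..., L - 0.5.
#'
#' @param E_noon peak (noon) surface PAR.
#' @param day_length day length L in hours.
#' @return numeric vector of length `day_length`.
#' @export
hourly_surface_par <- function(E_noon, day_length = 12) {
  if (day_length < 1) abort("`day_length` must be at least 1 hour.")
  t_mid <- seq(0.5, day_length - 0.5, by = 1)
  E_noon * sin(pi * t_mid / day_length)
}
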