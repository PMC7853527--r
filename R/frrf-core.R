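#' Instrument configuration
#'
#' Instrument constants of the fluorometer needed to scale fluorescence
#' yields to reaction-centre concentrations and to spectrally correct the
#' ambient cross section.
#'
#' @param kr_over_efrrf the ratio K_R / E_FRRf of the instrument constant
#'   (photons m^-3 s^-1) to the excitation flashlet intensity; treated as a
#'   single configured scalar, constant across samples.
#' @param leds LED centre wavelengths in use, subset of `c(444, 512, 633)`.
#' @param e_frrf_spectrum excitation spectrum; defaults to the LED model
#'   from [led_excitation_spectrum()].
#' @param sigma_scale unit bridge between PAR x nm^2 and electron rates;
#'   see [sigma_unit_scale()].
#' @param grid wavelength grid for the excitation spectrum.
#' @return a list of class `instrument_config`.
#' @export
instrument_config <- function(kr_over_efrrf = 1e12,
                              leds = c(444, 512, 633),
                              e_frrf_spectrum = NULL,
                              sigma_scale = sigma_unit_scale(),
                              grid = default_grid()) {
  if (kr_over_efrrf <= 0) abort("`kr_over_efrrf` must be positive.")
  if (sigma_scale <= 0) abort("`sigma_scale` must be positive.")
  if (is.null(e_frrf_spectrum)) {
    e_frrf_spectrum <- led_excitation_spectrum(leds, grid)
  }
  assert_spectrum(e_frrf_spectrum, "e_frrf_spectrum")
  if (par_integral(e_frrf_spectrum) <= 0) {
    abort("Excitation spectrum must integrate to a positive value.")
  }
  structure(
    list(kr_over_efrrf = kr_over_efrrf, leds = sort(leds),
         e_frrf_spectrum = e_frrf_spectrum, sigma_scale = sigma_scale),
    class = "instrument_config"
  )
}

#' Quality-control filter on the RCII closure probability
#'
#' Screens FRRf records on the probability of an RCII closing during the
#' first flashlet of the saturation phase, measured dark (`Rsigma_PSII`) and
#' under ambient light (`Rsigma_PSII_prime`). Rows are kept when both
#' probabilities lie in the closed interval \[`lower`, `upper`\]; the
#' instrument targets 0.05 and values outside 0.03-0.08 indicate under- or
#' over-saturating flash energy. Missing probabilities reject the row.
#'
#' @param records tibble of FRRf records with `Rsigma_PSII` and
#'   `Rsigma_PSII_prime` columns; an `excitation` column (character label of
#'   the LED combination) is used for the per-combination summary if present.
#' @param lower,upper inclusive acceptance bounds.
#' @return a list with `kept` and `rejected` tibbles (the `rejected` table
#'   gains a `qc_reason` column) and a `summary` tibble with N, median and
#'   range of both probabilities per excitation combination.
#' @export
qc_filter <- function(records, lower = 0.03, upper = 0.08) {
  records <- as_tibble(records)
  need <- c("Rsigma_PSII", "Rsigma_PSII_prime")
  if (!all(need %in% names(records))) {
    abort("`records` must contain Rsigma_PSII and Rsigma_PSII_prime.")
  }
  rs <- records$Rsigma_PSII
  rsp <- records$Rsigma_PSII_prime
  missing <- is.na(rs) | is.na(rsp)
  in_band <- !missing & rs >= lower & rs <= upper & rsp >= lower & rsp <= upper
  rejected <- records[!in_band, , drop = FALSE]
  rejected$qc_reason <- ifelse(missing[!in_band], "missing Rsigma",
                               "Rsigma outside acceptance band")
  kept <- records[in_band, , drop = FALSE]
  grp <- if ("excitation" %in% names(kept)) "excitation" else character(0)
  summary <- kept %>%
    group_by(across(dplyr::all_of(grp))) %>%
    summarise(
      n = n(),
      Rsigma_median = median(.data$Rsigma_PSII),
      Rsigma_min = min(.data$Rsigma_PSII),
      Rsigma_max = max(.data$Rsigma_PSII),
      Rsigma_prime_median = median(.data$Rsigma_PSII_prime),
      Rsigma_prime_min = min(.data$Rsigma_PSII_prime),
      Rsigma_prime_max = max(.data$Rsigma_PSII_prime),
      .groups = "drop"
    )
  list(kept = kept, rejected = rejected, summary = summary)
}

#' Derive photophysiological parameters from fluorescence yields
#'
#' Adds, per record: the maximum photochemical efficiency
#' `Fv_over_Fm = (Fm - Fo)/Fm`; the fraction of open reaction centres
#' `qP = (F' - Fo')/(Fm' - Fo')` (identified with 1 - C); and the
#' normalised Stern-Volmer non-photochemical quenching
#' `NPQ_NSV = Fo'/(Fm' - Fo')`. Records with `Fm_prime == Fo_prime` have
#' undefined qP/NPQ and are flagged in `photophys_ok` for exclusion
#' downstream.
#'
#' @param records tibble with yield columns `Fo`, `Fm`, `Fo_prime`,
#'   `F_prime`, `Fm_prime`.
#' @return the input tibble with `Fv_over_Fm`, `qP`, `NPQ_NSV` and
#'   `photophys_ok` columns added.
#' @export
derive_photophys <- function(records) {
  records <- as_tibble(records)
  need <- c("Fo", "Fm", "Fo_prime", "F_prime", "Fm_prime")
  if (!all(need %in% names(records))) {
    abort(paste("`records` must contain", paste(need, collapse = ", ")))
  }
  records %>%
    mutate(
      Fv_over_Fm = (.data$Fm - .data$Fo) / .data$Fm,
      .fvp = .data$Fm_prime - .data$Fo_prime,
      photophys_ok = .data$.fvp > 0,
      qP = ifelse(.data$photophys_ok,
                  (.data$F_prime - .data$Fo_prime) / .data$.fvp, NA_real_),
      NPQ_NSV = ifelse(.data$photophys_ok,
                       .data$Fo_prime / .data$.fvp, NA_real_)
    ) %>%
    select(-".fvp")
}

#' RCII concentration from the dark minimum fluorescence yield
#'
#' RCII = (K_R / E_FRRf) x (Fo / sigma_PSII) x 1e-9, in nmol m^-3.
#'
#' @param Fo minimum (dark) fluorescence yield, instrument units.
#' @param sigma_PSII dark functional absorption cross section (nm^2), > 0.
#' @param instrument an [instrument_config()].
#' @return RCII concentration, nmol m^-3 (vectorised).
#' @examples
#' inst <- instrument_config(kr_over_efrrf = 1e12)
#' rcii_concentration(0.5, 5, inst)  # 100
#' @export
rcii_concentration <- function(Fo, sigma_PSII, instrument) {
  if (any(sigma_PSII <= 0)) abort("`sigma_PSII` must be positive.")
  if (any(Fo < 0)) abort("`Fo` must be non-negative.")
  instrument$kr_over_efrrf * (Fo / sigma_PSII) * 1e-9
}

#' RCII-specific and volumetric electron transport rate
#'
#' The Sigma algorithm: J_f = E x sigma_PSII'(SCF-adjusted) x qP, with the
#' cross section in nm^2 bridged to electron units by the instrument's
#' `sigma_scale` so that J_f comes out in umol e^- nmol RCII^-1 s^-1.
#' The volumetric rate is JV_f = J_f x RCII.
#'
#' @param E ambient PAR (umol photons m^-2 s^-1), >= 0.
#' @param sigma_PSII_prime_scf SCF-adjusted ambient cross section (nm^2).
#' @param qP fraction of open reaction centres, in \[0, 1\].
#' @param instrument an [instrument_config()] (supplies the unit bridge).
#' @param RCII optional RCII concentration (nmol m^-3); when given, a tibble
#'   with both `J_f` and `JV_f` is returned, otherwise just `J_f`.
#' @return numeric `J_f`, or a tibble with `J_f` and `JV_f`.
#' @export
electron_transport <- function(E, sigma_PSII_prime_scf, qP,
                               instrument = instrument_config(),
                               RCII = NULL) {
  if (any(E < 0) || any(sigma_PSII_prime_scf < 0) || any(qP < 0)) {
    abort("`E`, `sigma_PSII_prime_scf` and `qP` must be non-negative.")
  }
  J_f <- E * sigma_PSII_prime_scf * qP * instrument$sigma_scale
  if (is.null(RCII)) return(J_f)
  tibble(J_f = J_f, JV_f = J_f * RCII)
}
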