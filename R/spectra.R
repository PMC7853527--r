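#' Spectra on the 400-700 nm grid
#'
#' All spectral quantities in the package (irradiance, absorption, and the
#' chlorophyll-specific phytoplankton absorption a*phy) live on a shared
#' uniform wavelength grid spanning 400 to 700 nm inclusive. A spectrum is a
#' two-column tibble with columns `wavelength` (nm) and `value`
#' (units depend on context: umol photons m^-2 s^-1 nm^-1 for irradiance,
#' m^-1 for absorption, m^2 mg Chl-a^-1 for a*phy).
#'
#' @param wavelength numeric vector of wavelengths (nm); must be uniform,
#'   strictly increasing, and span 400-700 inclusive.
#' @param value non-negative finite values, same length as `wavelength`.
#' @return a tibble with columns `wavelength` and `value`.
#' @examples
#' s <- spectrum_on_grid(400:700, rep(1, 301))
#' par_integral(s)
#' @export
spectrum_on_grid <- function(wavelength, value) {
  if (length(wavelength) != length(value)) {
    abort("`wavelength` and `value` must have the same length.")
  }
  step <- diff(wavelength)
  if (length(wavelength) < 2 || any(step <= 0) ||
      max(abs(step - step[1])) > 1e-9) {
    abort("`wavelength` must be strictly increasing with a uniform step.")
  }
  if (wavelength[1] != 400 || wavelength[length(wavelength)] != 700) {
    abort("The wavelength grid must span 400 to 700 nm inclusive.")
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    abort("Spectrum values must be finite and non-negative.")
  }
  tibble(wavelength = as.numeric(wavelength), value = as.numeric(value))
}

#' Default wavelength grid (1 nm step)
#' @param step grid step in nm; must divide 300.
#' @return numeric vector 400, 400+step, ..., 700.
#' @export
default_grid <- function(step = 1) {
  if (300 %% step != 0) abort("`step` must divide 300 nm.")
  seq(400, 700, by = step)
}

assert_spectrum <- function(x, arg = "spectrum") {
  if (!is.data.frame(x) || !all(c("wavelength", "value") %in% names(x))) {
    abort(paste0("`", arg, "` must be a tibble with columns wavelength, value."))
  }
  invisible(x)
}

assert_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || max(abs(a$wavelength - b$wavelength)) > 1e-9) {
    abort("Spectra must share an identical wavelength grid.")
  }
  invisible(NULL)
}

#' Integrate a spectrum over PAR (400-700 nm)
#'
#' Trapezoid integral of the spectral values over wavelength, giving (for an
#' irradiance spectrum in umol photons m^-2 s^-1 nm^-1) the broadband PAR in
#' umol photons m^-2 s^-1.
#'
#' @param spectrum a spectrum tibble from [spectrum_on_grid()].
#' @return a single numeric value.
#' @export
par_integral <- function(spectrum) {
  assert_spectrum(spectrum)
  w <- spectrum$wavelength
  v <- spectrum$value
  sum(diff(w) * (head(v, -1) + tail(v, -1)) / 2)
}

#' Read / write two-column spectrum files
#'
#' Spectra are exchanged as comma-separated text with a header row and
#' columns `wavelength` (or `wavelength_nm`) and `value`.
#'
#' @param path file path.
#' @param spectrum a spectrum tibble.
#' @return `read_spectrum()` returns a spectrum tibble; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  d <- utils::read.csv(path)
  names(d)[names(d) == "wavelength_nm"] <- "wavelength"
  spectrum_on_grid(d$wavelength, d$value)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  assert_spectrum(spectrum)
  utils::write.csv(spectrum, path, row.names = FALSE)
  invisible(path)
}

gaussian_peak <- function(grid, center, width, height) {
  height * exp(-0.5 * ((grid - center) / width)^2)
}

#' Synthetic component absorption and emission spectra
#'
#' Smooth synthetic stand-ins for the literature spectral models used in
#' bio-optics: pure-water absorption (monotonically rising towards the red),
#' chlorophyll-specific phytoplankton absorption a*phy with pigment peaks in
#' the blue and red (the cyanobacteria variant adds a phycocyanin shoulder
#' near 630 nm), instrument LED excitation spectra, and a broadband growth
#' chamber lamp. These are package-generated synthetic spectra, shaped like
#' their real counterparts but not copies of any published coefficient set.
#'
#' @param grid wavelength grid, default 1 nm.
#' @param type for `phytoplankton_absorption_spectrum()`: `"eukaryote"`
#'   (chlorophyll/carotenoid peaks only) or `"cyanobacteria"` (adds the
#'   phycobilin peaks at 550-630 nm).
#' @param leds for `led_excitation_spectrum()`: subset of `c(444, 512, 633)`
#'   nm centre wavelengths.
#' @return a spectrum tibble; absorption in m^-1 (water) or
#'   m^2 mg Chl-a^-1 (a*phy); LED/lamp spectra in relative units.
#' @export
water_absorption_spectrum <- function(grid = default_grid()) {
  v <- 0.005 + 0.6 * ((grid - 400) / 300)^4 + 0.02 * exp((grid - 700) / 40)
  spectrum_on_grid(grid, v)
}

#' @rdname water_absorption_spectrum
#' @export
phytoplankton_absorption_spectrum <- function(type = c("eukaryote", "cyanobacteria"),
                                              grid = default_grid()) {
  type <- match.arg(type)
  v <- gaussian_peak(grid, 440, 25, 0.030) +  # Chl-a Soret band
    gaussian_peak(grid, 490, 25, 0.012) +     # carotenoids
    gaussian_peak(grid, 675, 12, 0.018)       # Chl-a red band
  if (type == "cyanobacteria") {
    v <- v + gaussian_peak(grid, 565, 25, 0.010) + # phycoerythrin
      gaussian_peak(grid, 630, 18, 0.014)          # phycocyanin
  }
  spectrum_on_grid(grid, v + 0.001)
}

#' @rdname water_absorption_spectrum
#' @export
led_excitation_spectrum <- function(leds = c(444, 512, 633),
                                    grid = default_grid()) {
  if (!all(leds %in% c(444, 512, 633))) {
    abort("`leds` must be a subset of c(444, 512, 633).")
  }
  v <- Reduce(`+`, lapply(leds, function(l) gaussian_peak(grid, l, 12, 1)))
  spectrum_on_grid(grid, v)
}

#' @rdname water_absorption_spectrum
#' @export
chamber_lamp_spectrum <- function(grid = default_grid()) {
  # white LED: blue pump plus broad phosphor hump
  v <- gaussian_peak(grid, 450, 15, 1) + gaussian_peak(grid, 560, 70, 0.8)
  spectrum_on_grid(grid, v)
}

#' Synthetic incident sunlight spectrum
#'
#' Deterministic smooth daylight-like spectrum, normalised so that its PAR
#' integral equals `E0`. The `overcast` variant is blue-shifted relative to
#' the `clear` one, so the two differ in shape but never in integrated PAR.
#' The spectrum is a pure function of `(date_index, kind)`: repeated calls
#' reproduce it exactly.
#'
#' @param date_index integer used to vary the shape slightly across dates
#'   (solar elevation proxy).
#' @param kind `"clear"` or `"overcast"` sky.
#' @param E0 broadband PAR (umol photons m^-2 s^-1) the spectrum integrates to.
#' @param grid wavelength grid.
#' @return an irradiance spectrum tibble (umol photons m^-2 s^-1 nm^-1).
#' @export
generate_sunlight_spectrum <- function(date_index, kind = c("clear", "overcast"),
                                       E0 = 1000, grid = default_grid()) {
  kind <- match.arg(kind)
  if (E0 <= 0) abort("`E0` must be positive.")
  # planck-like hump; overcast skies are relatively enriched in blue
  center <- if (kind == "clear") 560 else 500
  tilt <- 0.08 * sin(2 * pi * (date_index %% 14) / 14)
  v <- exp(-0.5 * ((grid - center) / 130)^2) * (1 + tilt * (grid - 550) / 150)
  v <- pmax(v, 1e-6)
  s <- spectrum_on_grid(grid, v)
  s$value <- s$value * (E0 / par_integral(s))
  s
}
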