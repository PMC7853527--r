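#' Fit the diffuse attenuation coefficient, optionally layered
#'
#' Fits the Beer-Lambert decay E(z) = E(0) exp(-Kd z) to a PAR profile by
#' log-linear least squares. When the logarithmic slope changes with depth,
#' the water column is split into two layers at the observed depth that
#' minimises the two-segment residual sum of squares, provided the split is
#' supported by an F test at level `alpha`.
#'
#' @param par_profile data frame with columns `depth` (m, ascending) and
#'   `E` (PAR, umol photons m^-2 s^-1, strictly positive).
#' @param allow_layers if `FALSE`, always fit a single layer.
#' @param alpha significance level of the F test for adopting a breakpoint.
#' @param min_kd floor applied to fitted slopes; a non-attenuating profile
#'   is clamped here and flagged in the result.
#' @return an object of class `kd_fit`: a list with `layer_breaks` (depths
#'   delimiting layers, starting at 0), `kd` (one positive value per layer,
#'   m^-1), `E0` (fitted surface PAR), `clamped`, `rss`, and `n`.
#' @examples
#' prof <- tibble::tibble(depth = 0:10, E = 1630 * exp(-0.433 * (0:10)))
#' fit_kd(prof)$kd
#' @export
fit_kd <- function(par_profile, allow_layers = TRUE, alpha = 0.05,
                   min_kd = 1e-6) {
  d <- as.data.frame(par_profile)
  if (!all(c("depth", "E") %in% names(d))) {
    abort("`par_profile` needs columns `depth` and `E`.")
  }
  d <- d[order(d$depth), , drop = FALSE]
  if (nrow(d) < 3) abort("At least 3 profile points are required.")
  if (any(d$E <= 0)) abort("All PAR values must be strictly positive.")
  if (anyDuplicated(d$depth)) d <- stats::aggregate(E ~ depth, d, mean)

  y <- log(d$E)
  z <- d$depth
  seg_fit <- function(idx) {
    f <- lm(y[idx] ~ z[idx])
    list(kd = -unname(coef(f)[2]), int = unname(coef(f)[1]),
         rss = sum(resid(f)^2))
  }
  one <- seg_fit(seq_along(z))
  n <- length(z)
  tss <- sum((y - mean(y))^2)
  best <- NULL
  # a numerically perfect single line needs no breakpoint
  if (allow_layers && n >= 6 && one$rss > 1e-12 * max(tss, 1)) {
    # candidate breaks keep >= 3 points per segment; on exact ties the
    # deeper break wins (the boundary point belongs to the upper layer)
    cand <- lapply(3:(n - 3), function(k) {
      a <- seg_fit(1:k); b <- seg_fit((k + 1):n)
      list(k = k, a = a, b = b, rss2 = a$rss + b$rss)
    })
    rss2 <- vapply(cand, `[[`, numeric(1), "rss2")
    near <- rss2 <= min(rss2) + 1e-9 * max(tss, 1)
    best <- cand[[max(which(near))]]
  }
  use_two <- FALSE
  if (!is.null(best)) {
    # F test: 2 extra parameters
    df2 <- n - 4
    if (df2 > 0 && best$rss2 < one$rss) {
      f_stat <- ((one$rss - best$rss2) / 2) / (best$rss2 / df2)
      # Bonferroni over the searched candidate breaks keeps the false-split
      # rate near the nominal alpha
      p <- stats::pf(f_stat, 2, df2, lower.tail = FALSE) * (n - 5)
      if (is.finite(p)) use_two <- p < alpha else use_two <- one$rss > 1e-16
    }
  }
  clamp <- function(kd) max(kd, min_kd)
  if (use_two) {
    res <- list(
      layer_breaks = c(0, z[best$k]),
      kd = c(clamp(best$a$kd), clamp(best$b$kd)),
      E0 = exp(best$a$int),
      clamped = any(c(best$a$kd, best$b$kd) < min_kd),
      rss = best$rss2, n = n
    )
  } else {
    res <- list(
      layer_breaks = 0,
      kd = clamp(one$kd),
      E0 = exp(one$int),
      clamped = one$kd < min_kd,
      rss = one$rss, n = n
    )
  }
  structure(res, class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("Layered Kd fit:", length(x$kd), "layer(s)\n")
  for (i in seq_along(x$kd)) {
    top <- x$layer_breaks[i]
    bot <- if (i < length(x$layer_breaks)) x$layer_breaks[i + 1] else Inf
    cat(sprintf("  %g-%s m: Kd = %.4g m^-1\n", top,
                if (is.finite(bot)) format(bot) else "bottom", x$kd[i]))
  }
  invisible(x)
}

#' PAR at depth under a layered attenuation model
#'
#' Continuous downward attenuation: the optical depth accumulates each
#' layer's Kd over the path length within that layer.
#'
#' @param kd_fit a `kd_fit` object, or a list with `layer_breaks` and `kd`.
#' @param z depths (m, >= 0), vectorised.
#' @param E0 surface PAR; defaults to the fitted `E0`.
#' @return PAR at each depth.
#' @export
par_at_depth <- function(kd_fit, z, E0 = kd_fit$E0) {
  breaks <- kd_fit$layer_breaks
  kd <- kd_fit$kd
  vapply(z, function(zz) {
    if (zz < 0) abort("`z` must be non-negative.")
    tau <- 0
    for (i in seq_along(kd)) {
      top <- breaks[i]
      bot <- if (i < length(breaks)) breaks[i + 1] else Inf
      tau <- tau + kd[i] * max(0, min(zz, bot) - top)
    }
    E0 * exp(-tau)
  }, numeric(1))
}

#' CDOM and non-algal particle absorption models
#'
#' Exponential absorption models for coloured dissolved organic matter
#' (anchored at 320 nm, with basin-specific magnitude) and non-algal
#' particles (anchored at 440 nm):
#' a_CDOM(lambda) = a_CDOM(320) exp(-0.017 (lambda - 320)) with
#' a_CDOM(320) = 1.03 m^-1 for the oligotrophic north basin and 2.28 m^-1
#' for the mesotrophic south basin; a_NAP(lambda) =
#' 0.264 exp(-0.004 (lambda - 440)).
#'
#' @param wavelength wavelengths in nm, within 400-700.
#' @param basin `"north"` or `"south"`.
#' @param a320 overrides the basin-specific a_CDOM(320) anchor (m^-1).
#' @param s spectral slope (nm^-1).
#' @return absorption in m^-1, vectorised over `wavelength`.
#' @examples
#' a_cdom(440, "north")  # ~0.134
#' a_nap(440)            # 0.264
#' @export
a_cdom <- function(wavelength, basin = c("north", "south"), a320 = NULL,
                   s = 0.017) {
  basin <- match.arg(basin)
  check_lambda(wavelength)
  if (is.null(a320)) a320 <- c(north = 1.03, south = 2.28)[[basin]]
  a320 * exp(-s * (wavelength - 320))
}

#' @rdname a_cdom
#' @param a440 a_NAP anchor at 440 nm (m^-1).
#' @export
a_nap <- function(wavelength, a440 = 0.264, s = 0.004) {
  check_lambda(wavelength)
  a440 * exp(-s * (wavelength - 440))
}

check_lambda <- function(wavelength) {
  if (any(wavelength < 400 | wavelength > 700)) {
    abort("`wavelength` must lie within 400-700 nm.")
  }
  invisible(wavelength)
}

#' Assemble an absorption budget
#'
#' Collects the four absorbing components of the water column used by
#' [spectral_irradiance()]: pure water, CDOM, non-algal particles, and
#' phytoplankton (chlorophyll-specific spectrum scaled by Chl-a).
#'
#' @param basin `"north"` or `"south"` (sets the CDOM magnitude).
#' @param chl Chl-a concentration in mg m^-3.
#' @param aphy_type `"eukaryote"` or `"cyanobacteria"` a*phy shape.
#' @param grid wavelength grid.
#' @param a_w,a_phy_star optional spectrum overrides.
#' @return a list of class `absorption_budget` with spectra `a_w`, `a_cdom`,
#'   `a_nap`, `a_phy_star` and scalar `chl`.
#' @export
absorption_budget <- function(basin = "north", chl = 2,
                              aphy_type = "eukaryote",
                              grid = default_grid(),
                              a_w = NULL, a_phy_star = NULL) {
  if (chl < 0) abort("`chl` must be non-negative.")
  if (is.null(a_w)) a_w <- water_absorption_spectrum(grid)
  if (is.null(a_phy_star)) {
    a_phy_star <- phytoplankton_absorption_spectrum(aphy_type, grid = grid)
  }
  structure(
    list(
      a_w = a_w,
      a_cdom = spectrum_on_grid(grid, a_cdom(grid, basin)),
      a_nap = spectrum_on_grid(grid, a_nap(grid)),
      a_phy_star = a_phy_star,
      chl = chl
    ),
    class = "absorption_budget"
  )
}

total_absorption <- function(budget) {
  budget$a_w$value + budget$a_cdom$value + budget$a_nap$value +
    budget$chl * budget$a_phy_star$value
}

#' Underwater spectral irradiance at depth
#'
#' Beer-Lambert attenuation of a surface irradiance spectrum through the
#' absorption budget: E(lambda, z) = E0(lambda) exp(-a_total(lambda) z).
#' When `observed_par` is supplied, the attenuated spectrum is rescaled so
#' its PAR integral matches the observed broadband PAR at that depth.
#'
#' @param E0_spectrum surface irradiance spectrum.
#' @param budget an [absorption_budget()].
#' @param z depth (m, >= 0).
#' @param observed_par optional broadband PAR measurement at `z`.
#' @return an irradiance spectrum tibble.
#' @export
spectral_irradiance <- function(E0_spectrum, budget, z, observed_par = NULL) {
  assert_spectrum(E0_spectrum, "E0_spectrum")
  if (z < 0) abort("`z` must be non-negative.")
  assert_same_grid(E0_spectrum, budget$a_w)
  v <- E0_spectrum$value * exp(-total_absorption(budget) * z)
  s <- spectrum_on_grid(E0_spectrum$wavelength, v)
  if (!is.null(observed_par)) {
    p <- par_integral(s)
    if (p <= 0) abort("Attenuated spectrum has zero PAR; cannot rescale.")
    s$value <- s$value * (observed_par / p)
  }
  s
}

#' Spectral correction factor
#'
#' Reconciles the absorption-weighted overlap of the instrument excitation
#' spectrum with the in-situ (or incubator) light field:
#' \deqn{SCF = \frac{\sum a^*_{phy} E_{insitu} \cdot \sum E_{FRRf}}
#'                  {\sum a^*_{phy} E_{FRRf} \cdot \sum E_{insitu}}}
#' with all sums taken over 400-700 nm on the shared grid. The factor is
#' applied multiplicatively to sigma_PSII' and to growth-chamber PAR.
#' It is invariant to rescaling any input spectrum by a positive constant.
#'
#' @param a_phy_star chlorophyll-specific phytoplankton absorption spectrum.
#' @param E_insitu_spectrum ambient (or incubator) light spectrum.
#' @param E_frrf_spectrum instrument excitation spectrum.
#' @return dimensionless scalar.
#' @export
spectral_correction_factor <- function(a_phy_star, E_insitu_spectrum,
                                       E_frrf_spectrum) {
  assert_spectrum(a_phy_star, "a_phy_star")
  assert_spectrum(E_insitu_spectrum, "E_insitu_spectrum")
  assert_spectrum(E_frrf_spectrum, "E_frrf_spectrum")
  assert_same_grid(a_phy_star, E_insitu_spectrum)
  assert_same_grid(a_phy_star, E_frrf_spectrum)
  num <- sum(a_phy_star$value * E_insitu_spectrum$value) *
    sum(E_frrf_spectrum$value)
  den <- sum(a_phy_star$value * E_frrf_spectrum$value) *
    sum(E_insitu_spectrum$value)
  if (den <= 0) abort("SCF denominator is zero; check input spectra.")
  num / den
}
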