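test_that("fit_kd recovers printed attenuation constants from exact profiles", {
  z <- seq(0, 20, 2)
  f <- fit_kd(tibble::tibble(depth = z, E = 1630 * exp(-0.433 * z)))
  expect_length(f$kd, 1)
  expect_lt(abs(f$kd - 0.433), 1e-6)
  expect_lt(abs(f$E0 - 1630) / 1630, 1e-6)
})

test_that("fit_kd recovers a two-layer profile with its break", {
  kdm <- structure(list(layer_breaks = c(0, 2), kd = c(1.727, 0.971),
                        E0 = 650), class = "kd_fit")
  z <- seq(0, 5, 0.5)
  f <- fit_kd(tibble::tibble(depth = z, E = par_at_depth(kdm, z)))
  expect_length(f$kd, 2)
  expect_lt(max(abs(f$kd - c(1.727, 0.971))), 1e-6)
  expect_equal(f$layer_breaks[2], 2)
})

test_that("constant-E profiles clamp Kd at the floor and are flagged", {
  f <- fit_kd(tibble::tibble(depth = 0:6, E = rep(100, 7)))
  expect_true(f$clamped)
  expect_equal(f$kd, 1e-6)
})

test_that("fit_kd rejects unusable profiles", {
  expect_error(fit_kd(tibble::tibble(depth = 0:1, E = c(1, 2))), "3")
  expect_error(fit_kd(tibble::tibble(depth = 0:3, E = c(1, 1, 0, 1))),
               "positive")
})

test_that("fit_kd is unbiased on noisy single-layer profiles", {
  z <- seq(0, 10, 1)
  kds <- withr::with_seed(11, replicate(200, {
    E <- 900 * exp(-0.5 * z) * exp(rnorm(length(z), 0, 0.05))
    fit_kd(tibble::tibble(depth = z, E = E), allow_layers = FALSE)$kd
  }))
  expect_lt(abs(mean(kds) - 0.5), 0.01)
})

test_that("CDOM model anchors at 320 nm with basin-specific magnitude", {
  # formula anchor evaluated outside the PAR window via the anchor constant
  expect_equal(a_cdom(440, "north"), 1.03 * exp(-0.017 * 120))
  expect_equal(round(a_cdom(440, "north"), 4), 0.1339)
  # shared exponent: the basin ratio is constant in wavelength
  r <- a_cdom(c(400, 550, 700), "south") / a_cdom(c(400, 550, 700), "north")
  expect_equal(r, rep(2.28 / 1.03, 3))
  expect_error(a_cdom(440, "east"), "should be one of")
})

test_that("NAP model reproduces its anchor and decays monotonically", {
  expect_equal(a_nap(440), 0.264)
  expect_equal(a_nap(540), 0.264 * exp(-0.4))
  v <- a_nap(400:700)
  expect_true(all(diff(v) < 0))
})

test_that("spectral irradiance obeys Beer-Lambert limits", {
  e0 <- generate_sunlight_spectrum(1, "clear", 1000)
  b <- absorption_budget("north", chl = 3)
  expect_equal(spectral_irradiance(e0, b, 0), e0, tolerance = 1e-12)
  # transparent water: zero absorption at any depth
  zero <- flat_spectrum(0)
  b0 <- absorption_budget("north", chl = 0, a_w = zero, a_phy_star = zero)
  b0$a_cdom$value[] <- 0
  b0$a_nap$value[] <- 0
  expect_equal(spectral_irradiance(e0, b0, 12), e0, tolerance = 1e-12)
})

test_that("a single uniform absorber scales a flat spectrum by exp(-a z)", {
  e0 <- flat_spectrum(2)
  b <- absorption_budget("north", chl = 0, a_w = flat_spectrum(0.1),
                         a_phy_star = flat_spectrum(0))
  b$a_cdom$value[] <- 0
  b$a_nap$value[] <- 0
  out <- spectral_irradiance(e0, b, 10)
  expect_equal(out$value, rep(2 * exp(-1), 301), tolerance = 1e-12)
})

test_that("attenuation is multiplicative in depth", {
  e0 <- generate_sunlight_spectrum(2, "clear", 500)
  b <- absorption_budget("south", chl = 8)
  two_step <- spectral_irradiance(spectral_irradiance(e0, b, 1.2), b, 2.3)
  one_step <- spectral_irradiance(e0, b, 3.5)
  expect_equal(two_step$value, one_step$value, tolerance = 1e-12)
})

test_that("PAR rescaling pins the integral to the observation", {
  e0 <- generate_sunlight_spectrum(2, "clear", 500)
  b <- absorption_budget("south", chl = 8)
  out <- spectral_irradiance(e0, b, 4, observed_par = 55)
  expect_equal(par_integral(out), 55, tolerance = 1e-9)
})

test_that("SCF is 1 for proportional spectra and flat absorption", {
  aphy <- phytoplankton_absorption_spectrum("eukaryote")
  e1 <- generate_sunlight_spectrum(1, "clear", 700)
  e2 <- e1; e2$value <- e1$value * 3.7
  expect_equal(spectral_correction_factor(aphy, e2, e1), 1, tolerance = 1e-12)
  # constant a*phy cancels entirely
  expect_equal(spectral_correction_factor(flat_spectrum(0.02),
                                          generate_sunlight_spectrum(1, "overcast", 300),
                                          led_excitation_spectrum()),
               1, tolerance = 1e-12)
})

test_that("SCF matches a literal implementation of the weighted-overlap ratio", {
  grid <- default_grid()
  aphy <- spectrum_on_grid(grid, exp(-0.5 * ((grid - 440) / 15)^2) + 1e-4)
  e_frrf <- led_excitation_spectrum(444)
  e_insitu <- spectrum_on_grid(grid, pmax(1e-6, (grid - 450) / 250)) # red-shifted
  scf <- spectral_correction_factor(aphy, e_insitu, e_frrf)
  brute <- (sum(aphy$value * e_insitu$value) * sum(e_frrf$value)) /
    (sum(aphy$value * e_frrf$value) * sum(e_insitu$value))
  expect_equal(scf, brute, tolerance = 1e-12)
  expect_lt(scf, 1)
})

test_that("SCF is invariant to rescaling each input spectrum", {
  aphy <- phytoplankton_absorption_spectrum("cyanobacteria")
  ein <- generate_sunlight_spectrum(4, "clear", 900)
  efr <- led_excitation_spectrum(c(444, 633))
  base <- spectral_correction_factor(aphy, ein, efr)
  scale_spec <- function(s, k) { s$value <- s$value * k; s }
  expect_equal(spectral_correction_factor(scale_spec(aphy, 5), ein, efr), base)
  expect_equal(spectral_correction_factor(aphy, scale_spec(ein, 0.1), efr), base)
  expect_equal(spectral_correction_factor(aphy, ein, scale_spec(efr, 9)), base)
})
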