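frrf_row <- function(rs = 0.045, rsp = 0.048, ...) {
  tibble::tibble(Rsigma_PSII = rs, Rsigma_PSII_prime = rsp,
                 excitation = "444+512+633", ...)
}

test_that("qc_filter keeps in-band rows and rejects out-of-band ones", {
  tbl <- dplyr::bind_rows(
    frrf_row(0.045, 0.048),       # kept (the typical three-LED medians)
    frrf_row(0.02, 0.05),         # rejected: dark probability too low
    frrf_row(0.05, 0.081),        # rejected: ambient probability too high
    frrf_row(NA, 0.05)            # rejected: missing
  )
  out <- qc_filter(tbl)
  expect_equal(nrow(out$kept), 1)
  expect_equal(nrow(out$rejected), 3)
  expect_true("missing Rsigma" %in% out$rejected$qc_reason)
})

test_that("qc_filter bounds are inclusive at 0.03 and 0.08", {
  tbl <- dplyr::bind_rows(frrf_row(0.03, 0.03), frrf_row(0.08, 0.08))
  out <- qc_filter(tbl)
  expect_equal(nrow(out$kept), 2)
  expect_equal(nrow(out$rejected), 0)
})

test_that("qc_filter partitions its input without loss or duplication", {
  set.seed(3)
  tbl <- frrf_row(runif(200, 0.02, 0.09), runif(200, 0.02, 0.09))
  tbl$id <- 1:200
  out <- qc_filter(tbl)
  expect_equal(sort(c(out$kept$id, out$rejected$id)), 1:200)
  expect_equal(nrow(out$kept) + nrow(out$rejected), 200)
})

test_that("qc summary reports per-combination medians and ranges", {
  tbl <- dplyr::bind_rows(
    frrf_row(c(0.04, 0.05, 0.06), c(0.04, 0.05, 0.06)),
    frrf_row(0.045, 0.048)
  )
  tbl$excitation <- c(rep("444", 3), "444+633")
  s <- qc_filter(tbl)$summary
  expect_equal(s$n[s$excitation == "444"], 3)
  expect_equal(s$Rsigma_median[s$excitation == "444"], 0.05)
  expect_equal(s$Rsigma_min[s$excitation == "444"], 0.04)
})

test_that("photophysiology derivations hit the endpoints of their definitions", {
  base <- tibble::tibble(Fo = 1, Fm = 2, Fo_prime = 1, Fm_prime = 3,
                         F_prime = c(1, 3, 2))
  out <- derive_photophys(base)
  expect_equal(out$Fv_over_Fm, rep(0.5, 3))       # (2-1)/2
  expect_equal(out$qP, c(0, 1, 0.5))              # F'=Fo' and F'=Fm'
  expect_equal(out$NPQ_NSV, rep(0.5, 3))          # 1/(3-1)
})

test_that("degenerate ambient yields are flagged rather than divided by", {
  bad <- tibble::tibble(Fo = 1, Fm = 2, Fo_prime = 2, Fm_prime = 2,
                        F_prime = 2)
  out <- derive_photophys(bad)
  expect_false(out$photophys_ok)
  expect_true(is.na(out$qP))
})

test_that("RCII concentration evaluates the yield/cross-section quotient", {
  inst <- instrument_config(kr_over_efrrf = 1e12)
  expect_equal(rcii_concentration(0.5, 5, inst), 100)
  expect_equal(rcii_concentration(0, 5, inst), 0)
  # homogeneity: doubling Fo doubles RCII, doubling sigma halves it
  expect_equal(rcii_concentration(1.0, 5, inst),
               2 * rcii_concentration(0.5, 5, inst))
  expect_equal(rcii_concentration(0.5, 10, inst),
               rcii_concentration(0.5, 5, inst) / 2)
  expect_error(rcii_concentration(0.5, 0, inst), "positive")
})

test_that("electron transport vanishes in the dark and with closed centres", {
  inst <- instrument_config()
  expect_equal(electron_transport(0, 5, 0.5, inst), 0)
  expect_equal(electron_transport(500, 5, 0, inst), 0)
  out <- electron_transport(100, 4, 0.5, inst, RCII = 50)
  expect_equal(out$JV_f, out$J_f * 50, tolerance = 1e-12)
})

test_that("JV_f is invariant when Fo and the RCII normalisation scale together", {
  inst <- instrument_config(kr_over_efrrf = 1e12)
  k <- 3.7
  rcii1 <- rcii_concentration(0.4, 5, inst)
  inst2 <- instrument_config(kr_over_efrrf = 1e12 / k)
  rcii2 <- rcii_concentration(0.4 * k, 5, inst2)
  jv1 <- electron_transport(300, 4, 0.6, inst, RCII = rcii1)$JV_f
  jv2 <- electron_transport(300, 4, 0.6, inst2, RCII = rcii2)$JV_f
  expect_equal(jv1, jv2, tolerance = 1e-12)
})
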