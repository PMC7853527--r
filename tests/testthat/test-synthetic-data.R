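test_that("identical seeds give bit-identical campaigns", {
  sc <- synthetic_scenario(seed = 42, n_dates = 4)
  a <- generate_campaign(sc)
  b <- generate_campaign(sc)
  for (nm in c("frrf", "profiles", "incubations", "truth")) {
    expect_identical(a[[nm]], b[[nm]])
  }
})

test_that("different seeds give different campaigns", {
  a <- generate_campaign(synthetic_scenario(seed = 1, n_dates = 2))
  b <- generate_campaign(synthetic_scenario(seed = 2, n_dates = 2))
  expect_false(identical(a$frrf, b$frrf))
})

test_that("generated truth satisfies its structural invariants", {
  camp <- generate_campaign(synthetic_scenario(seed = 3, n_dates = 6))
  expect_true(all(camp$truth$phi_true > 0))
  expect_true(all(camp$truth$RCII > 0))
  expect_true(all(camp$truth$J_f >= 0))
  # E(z) non-increasing with depth within each date
  for (d in unique(camp$profiles$date)) {
    p <- camp$profiles[camp$profiles$date == d, ]
    expect_true(all(diff(p$E_par[order(p$depth)]) <= 1e-12))
  }
})

test_that("scenario validation rejects degenerate settings", {
  expect_error(synthetic_scenario(phi_dispersion = -1), "positive")
  expect_error(synthetic_scenario(frrf_noise_cv = -0.1), "non-negative")
  expect_error(synthetic_scenario(
    true_phi_coefficients = c("(Intercept)" = 1)), "Missing")
})

test_that("noise-free campaigns pass every downstream validator unrejected", {
  camp <- generate_campaign(noise_free_scenario(seed = 4))
  qc <- qc_filter(camp$frrf)
  expect_equal(nrow(qc$rejected), 0)
  ph <- derive_photophys(qc$kept)
  expect_true(all(ph$photophys_ok))
  expect_true(all(ph$qP >= 0 & ph$qP <= 1))
  expect_true(all(ph$Fv_over_Fm > 0 & ph$Fv_over_Fm < 1))
})

test_that("generated quality probabilities keep their medians through the filter", {
  camp <- generate_campaign(synthetic_scenario(seed = 5, n_dates = 14))
  pre <- median(camp$frrf$Rsigma_PSII)
  kept <- qc_filter(camp$frrf)$kept
  expect_lt(abs(median(kept$Rsigma_PSII) - pre), 0.002)
  # configured near the instrument optimum
  expect_lt(abs(median(kept$Rsigma_PSII) - 0.045), 0.005)
  expect_lt(abs(median(kept$Rsigma_PSII_prime) - 0.048), 0.005)
})

test_that("the noise-free pipeline reproduces the truth table exactly", {
  camp <- generate_campaign(noise_free_scenario(seed = 6))
  run <- suppressMessages(run_pipeline(camp, seed = 1))
  tm <- truth_match(run, camp)
  # every truth row is recovered (replicate casts all map onto it)
  expect_setequal(paste(run$phi_records$date, run$phi_records$depth),
                  paste(camp$truth$date, camp$truth$depth))
  expect_lt(max(rel_err(tm$estimate, tm$truth)), 1e-9)
})

test_that("campaign tables round-trip through csv files", {
  camp <- generate_campaign(synthetic_scenario(seed = 7, n_dates = 2))
  dir <- withr::local_tempdir()
  write_campaign(camp, dir)
  back <- read_campaign(dir)
  expect_equal(as.data.frame(back$frrf), as.data.frame(camp$frrf),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$incubations),
               as.data.frame(camp$incubations), tolerance = 1e-12)
})

test_that("a temperature-only truth is recovered by the GLM stage", {
  beta <- default_phi_coefficients()
  beta[] <- 0
  beta[["(Intercept)"]] <- 1.83
  beta[["temperature"]] <- 0.51
  ests <- sapply(1:5, function(s) {
    sc <- synthetic_scenario(seed = 200 + s, true_phi_coefficients = beta,
                             frrf_noise_cv = 0, phi_dispersion = 5)
    run <- suppressMessages(run_pipeline(generate_campaign(sc), seed = s))
    run$glm$terms$estimate[run$glm$terms$term == "temperature"]
  })
  expect_lt(abs(mean(ests) - 0.51), 0.05)
})
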