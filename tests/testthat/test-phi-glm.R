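make_records <- function(n_dates = 2) {
  # minimal record table covering both basins' strata
  north_z <- c(0, 2, 5, 8, 10, 13, 15)
  south_z <- c(0, 0.5, 1.5, 2, 3.5, 4.5)
  purrr::map_dfr(seq_len(n_dates), function(i) {
    if (i %% 2 == 1) {
      tibble::tibble(date = sprintf("d%02d", i), basin = "north",
                     depth = north_z, value = rnorm(length(north_z)))
    } else {
      tibble::tibble(date = sprintf("d%02d", i), basin = "south",
                     depth = south_z, value = rnorm(length(south_z)))
    }
  })
}

test_that("stratified bootstrap yields exact row counts", {
  recs <- withr::with_seed(1, make_records(14))
  boot <- stratified_bootstrap(recs, seed = 5)
  expect_equal(nrow(boot), 3360)
  counts <- table(boot$date)
  expect_true(all(counts == 240))
  expect_equal(as.integer(table(boot$basin)[c("north", "south")]),
               c(1680L, 1680L))
})

test_that("bootstrap is reproducible and order-independent", {
  recs <- withr::with_seed(2, make_records(4))
  b1 <- stratified_bootstrap(recs, seed = 9)
  b2 <- stratified_bootstrap(recs, seed = 9)
  expect_identical(b1, b2)
  shuffled <- withr::with_seed(3, recs[sample(nrow(recs)), ])
  b3 <- stratified_bootstrap(shuffled, seed = 9)
  expect_equal(dplyr::arrange(b3, date, depth, value)$value,
               dplyr::arrange(b1, date, depth, value)$value)
})

test_that("a singleton stratum replicates its only record", {
  recs <- tibble::tibble(date = "d01", basin = "north",
                         depth = c(1, 5, 9, 14), value = 1:4)
  boot <- stratified_bootstrap(recs, seed = 1)
  expect_equal(nrow(boot), 240)
  deep <- boot[boot$depth == 14, ]
  expect_equal(nrow(deep), 60)
  expect_true(all(deep$value == 4))
})

test_that("an empty stratum halts with the date and stratum named", {
  recs <- tibble::tibble(date = "d07", basin = "south",
                         depth = c(0.5, 2), value = 1:2)  # nothing in 3-5.5 m
  expect_error(stratified_bootstrap(recs, seed = 1), "3-5.5.*d07")
})

test_that("collinearity screen flags constructed monotone associations", {
  n <- 400
  x <- withr::with_seed(4, {
    a <- rnorm(n)
    tibble::tibble(temperature = a, PAR = exp(a + rnorm(n, 0, 0.25)),
                   NPQ_NSV = a + rnorm(n, 0, 0.1), turbidity = rnorm(n))
  })
  sc <- collinearity_screen(x)
  expect_true(any(sc$flagged_pairs$var1 == "temperature" &
                    sc$flagged_pairs$var2 == "NPQ_NSV"))
  # rho of a duplicated column is exactly 1
  x$dup <- x$temperature
  sc2 <- collinearity_screen(x)
  i <- sc2$flagged_pairs$var1 == "temperature" & sc2$flagged_pairs$var2 == "dup"
  expect_equal(sc2$flagged_pairs$rho[i], 1)
  # the non-preferred member of a flagged pair is dropped
  expect_true("NPQ_NSV" %in% sc2$dropped)
  expect_true("temperature" %in% sc2$retained)
})

test_that("independent columns are not flagged at n = 1000", {
  x <- withr::with_seed(5, tibble::as_tibble(
    matrix(rnorm(1000 * 6), 1000, 6,
           dimnames = list(NULL, paste0("v", 1:6)))))
  expect_equal(nrow(collinearity_screen(x)$flagged_pairs), 0)
})

test_that("constant columns are reported as undefined, not crashed on", {
  x <- tibble::tibble(a = rnorm(50), b = rep(2, 50))
  expect_warning(sc <- collinearity_screen(x), "Constant")
  expect_false("b" %in% colnames(sc$rho_matrix))
})

test_that("transformation applies detection limits, then log, then z-scores", {
  x <- tibble::tibble(temperature = runif(40, 5, 30),
                      NH4 = c(0.05, NA, runif(38, 0.2, 2)),
                      frac_diatom = c(0.01, runif(39, 1, 90)))
  z <- transform_standardise(x)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  # the substituted values map to log(0.1) before standardisation
  ctr <- attr(z, "center"); scl <- attr(z, "scale")
  expect_equal(z$NH4[1], (log(0.1) - ctr[["NH4"]]) / scl[["NH4"]])
  expect_equal(z$NH4[2], z$NH4[1])
  expect_equal(z$frac_diatom[1], (log(0.1) - ctr[["frac_diatom"]]) / scl[["frac_diatom"]])
})

test_that("standardisation is idempotent up to tolerance", {
  x <- tibble::tibble(temperature = runif(30, 5, 30), chl = runif(30, 1, 40))
  z1 <- transform_standardise(x)
  # re-standardising the exponentiated z-scores reproduces them
  z2 <- transform_standardise(tibble::tibble(temperature = exp(z1$temperature),
                                             chl = exp(z1$chl)))
  expect_equal(as.matrix(z2), as.matrix(z1), tolerance = 1e-12)
})

test_that("degenerate columns fail loudly", {
  expect_error(transform_standardise(tibble::tibble(temperature = rep(3, 10))),
               "variance|standardise")
  expect_error(transform_standardise(tibble::tibble(temperature = c(-1, 2, 3))),
               "Non-positive")
})

test_that("intercept-only gamma GLM recovers the log mean response", {
  y <- withr::with_seed(6, rgamma(500, shape = 4, rate = 4 / 7))
  f <- fit_gamma_glm(y, tibble::tibble())
  expect_equal(unname(f$terms$estimate[1]), log(mean(y)), tolerance = 1e-6)
})

test_that("gamma GLM is consistent under its own generating model", {
  sim_fit <- function(n, seed) {
    withr::with_seed(seed, {
      X <- tibble::tibble(a = rnorm(n), b = rnorm(n))
      mu <- exp(0.5 + 0.3 * X$a - 0.2 * X$b)
      y <- rgamma(n, shape = 5, rate = 5 / mu)
      fit_gamma_glm(y, X)$terms$estimate[2]
    })
  }
  bias_small <- abs(mean(sapply(1:8, function(s) sim_fit(500, s))) - 0.3)
  bias_large <- abs(mean(sapply(1:8, function(s) sim_fit(3360, s))) - 0.3)
  expect_lt(bias_large, bias_small + 0.01)
  expect_lt(bias_large, 0.02)
})

test_that("rank_all_submodels enumerates every subset and is self-consistent", {
  n <- 300
  dat <- withr::with_seed(7, {
    X <- tibble::as_tibble(matrix(rnorm(n * 4), n, 4,
                                  dimnames = list(NULL, c("a", "b", "NH4", "frac_diatom"))))
    mu <- exp(1 + 0.5 * X$a)
    list(X = X, y = rgamma(n, 5, 5 / mu))
  })
  rk <- rank_all_submodels(dat$y, dat$X)
  expect_equal(nrow(rk), 2^4)
  expect_equal(rk$delta_aic[1], 0)
  # full-model AIC equals the direct fit's AIC
  full <- fit_gamma_glm(dat$y, dat$X)
  expect_equal(rk$aic[rk$k == 4], full$aic, tolerance = 1e-6)
  # constrained extracts exclude their term groups
  m2 <- ranking_model(rk, "best_no_nutrients")
  expect_false("NH4" %in% m2$terms$term)
  m3 <- ranking_model(rk, "best_no_nutrients_no_phyto")
  expect_false(any(c("NH4", "frac_diatom") %in% m3$terms$term))
})

test_that("two orthogonal terms give exactly four subsets and drop pure noise", {
  n <- 600
  d <- withr::with_seed(8, {
    X <- tibble::tibble(signal = rnorm(n), noise = rnorm(n))
    list(X = X, y = rgamma(n, 5, 5 / exp(1 + 0.6 * X$signal)))
  })
  rk <- rank_all_submodels(d$y, d$X)
  expect_equal(nrow(rk), 4)
  expect_true(grepl("signal", rk$terms[1]))
})

test_that("strong true terms are selected by AIC across replicate seeds", {
  hits <- sapply(1:10, function(s) {
    d <- withr::with_seed(100 + s, {
      X <- tibble::as_tibble(matrix(rnorm(1200 * 6), 1200, 6,
                                    dimnames = list(NULL, paste0("v", 1:6))))
      mu <- exp(1 + 0.4 * X$v1 - 0.35 * X$v2 + 0.3 * X$v3)
      list(X = X, y = rgamma(1200, 5, 5 / mu))
    })
    best <- rank_all_submodels(d$y, d$X)$terms[1]
    all(c("v1", "v2", "v3") %in% strsplit(best, "+", fixed = TRUE)[[1]])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("VIFs are reported and modest for near-orthogonal designs", {
  d <- withr::with_seed(9, {
    X <- tibble::as_tibble(matrix(rnorm(800 * 5), 800, 5,
                                  dimnames = list(NULL, paste0("v", 1:5))))
    list(X = X, y = rgamma(800, 5, 5 / exp(1 + 0.3 * X$v1)))
  })
  f <- fit_gamma_glm(d$y, d$X)
  expect_length(f$vif, 5)
  expect_true(all(f$vif < 10))
})

test_that("rank-deficient design matrices are rejected with a clear error", {
  X <- tibble::tibble(a = rnorm(50))
  X$b <- 2 * X$a
  expect_error(fit_gamma_glm(rgamma(50, 2, 1), X), "rank")
})
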