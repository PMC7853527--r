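#' Candidate covariates of the electron-requirement model
#'
#' The thirteen explanatory variables carried into the gamma GLM:
#' water temperature, PAR, turbidity, dissolved oxygen saturation, NH4,
#' NO3 + NO2, PO4, Fv/Fm, sigma_PSII, Chl-a, and the biomass fractions of
#' diatoms, cyanobacteria and cryptophytes.
#'
#' @return character vector of column names.
#' @export
phi_covariates <- function() {
  c("temperature", "PAR", "turbidity", "DO", "NH4", "NO3_NO2", "PO4",
    "Fv_over_Fm", "sigma_PSII", "chl",
    "frac_diatom", "frac_cyanobacteria", "frac_cryptophyte")
}

#' Stratified bootstrap schemes for the two basins
#'
#' Depth-stratified resampling with replacement draws the same number of
#' observations per date regardless of how many casts each layer yielded,
#' removing the shallow/deep sampling imbalance caused by high-light
#' measurement dropouts. The default schemes draw 240 observations per
#' date: 60 from each of four layers above the euphotic zone
#' (0-3.75, 3.75-7.5, 7.5-12.5, 12.5-17.5 m) in the deep north basin, and
#' 80 from each of three layers (0-1, 1-3, 3-5.5 m) in the shallow south
#' basin.
#'
#' @param basin `"north"` or `"south"`.
#' @return a list of class `bootstrap_scheme` with a `strata` tibble
#'   (`depth_min`, `depth_max`, `n_resample`) and `n_per_date`.
#' @export
bootstrap_scheme <- function(basin = c("north", "south")) {
  basin <- match.arg(basin)
  strata <- if (basin == "north") {
    tibble(depth_min = c(0, 3.75, 7.5, 12.5),
           depth_max = c(3.75, 7.5, 12.5, 17.5),
           n_resample = 60L)
  } else {
    tibble(depth_min = c(0, 1, 3), depth_max = c(1, 3, 5.5),
           n_resample = 80L)
  }
  structure(list(basin = basin, strata = strata,
                 n_per_date = sum(strata$n_resample)),
            class = "bootstrap_scheme")
}

child_seed <- function(seed, i, j = 0) {
  as.integer((as.numeric(seed) * 48271 + i * 1299709 + j * 15485863) %%
               2147483647)
}

#' Stratified bootstrap of per-observation records
#'
#' For every sampling date, draws `n_resample` rows with replacement from
#' each depth stratum of the scheme for that date's basin. Seeding is
#' derived per (date, stratum) from the global seed, so the draw does not
#' depend on row or date order.
#'
#' @param records tibble with at least `date`, `basin` and `depth` columns.
#' @param seed integer seed driving all resampling.
#' @param schemes named list of [bootstrap_scheme()]s per basin.
#' @return tibble of resampled rows, `n_per_date` per date, with a
#'   `stratum` column added.
#' @export
stratified_bootstrap <- function(records, seed = 1,
                                 schemes = list(north = bootstrap_scheme("north"),
                                                south = bootstrap_scheme("south"))) {
  records <- as_tibble(records)
  if (!all(c("date", "basin", "depth") %in% names(records))) {
    abort("`records` must contain date, basin and depth columns.")
  }
  dates <- sort(unique(records$date))   # seed index independent of row order
  out <- vector("list", 0L)
  for (di in seq_along(dates)) {
    rows_d <- records[records$date == dates[di], , drop = FALSE]
    basin <- rows_d$basin[1]
    scheme <- schemes[[basin]]
    if (is.null(scheme)) abort(paste("No bootstrap scheme for basin", basin))
    for (si in seq_len(nrow(scheme$strata))) {
      st <- scheme$strata[si, ]
      # half-open strata [min, max); the last stratum closes at its maximum
      upper_closed <- si == nrow(scheme$strata)
      in_st <- rows_d$depth >= st$depth_min &
        (rows_d$depth < st$depth_max |
           (upper_closed & rows_d$depth <= st$depth_max))
      pool <- rows_d[in_st, , drop = FALSE]
      # canonical within-stratum ordering makes the draw independent of the
      # input row order
      ord <- tryCatch(do.call(order, as.list(pool)), error = function(e) NULL)
      if (!is.null(ord)) pool <- pool[ord, , drop = FALSE]
      if (nrow(pool) == 0) {
        abort(sprintf("Empty stratum %g-%g m on date %s: cannot resample.",
                      st$depth_min, st$depth_max, as.character(dates[di])))
      }
      rs <- withr::with_seed(child_seed(seed, di, si),
                             sample.int(nrow(pool), st$n_resample,
                                        replace = TRUE))
      drawn <- pool[rs, , drop = FALSE]
      drawn$stratum <- sprintf("%g-%g m", st$depth_min, st$depth_max)
      out[[length(out) + 1]] <- drawn
    }
  }
  bind_rows(out)
}

#' Spearman collinearity screen
#'
#' Computes the full Spearman rank-correlation matrix over the candidate
#' columns and flags every pair with |rho| >= `rho_cutoff` whose large-sample
#' p value is below `p_cutoff`. When a flagged pair contains one column from
#' `keep` (the preferred proxies) and one that is not, the non-preferred
#' member is marked dropped; ties within `keep` are both retained.
#'
#' @param covariate_table tibble of numeric candidate columns (>= 3 rows).
#' @param rho_cutoff absolute Spearman rho above which a pair is collinear.
#' @param p_cutoff significance level of the large-sample t approximation.
#' @param keep columns preferred for retention, default [phi_covariates()].
#' @return a list with `retained` (character), `dropped` (character),
#'   `flagged_pairs` (tibble var1/var2/rho/p) and `rho_matrix`.
#' @export
collinearity_screen <- function(covariate_table, rho_cutoff = 0.7,
                                p_cutoff = 0.05,
                                keep = phi_covariates()) {
  x <- as.data.frame(covariate_table)
  x <- x[vapply(x, is.numeric, logical(1))]
  n <- nrow(x)
  if (n < 3) abort("Need at least 3 rows for the collinearity screen.")
  const <- vapply(x, function(v) stats::sd(v, na.rm = TRUE) == 0, logical(1))
  if (any(const)) {
    warn(paste("Constant columns have undefined rho and are dropped:",
               paste(names(x)[const], collapse = ", ")))
    x <- x[!const]
  }
  rho <- cor(x, method = "spearman", use = "pairwise.complete.obs")
  vars <- colnames(rho)
  if (length(vars) < 2) {
    return(list(retained = vars, dropped = character(0),
                flagged_pairs = tibble(var1 = character(0),
                                       var2 = character(0),
                                       rho = numeric(0), p = numeric(0)),
                rho_matrix = rho))
  }
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  flagged <- purrr::map_dfr(pairs, function(p) {
    r <- rho[p[1], p[2]]
    # large-sample t approximation for Spearman's rho
    tval <- r * sqrt((n - 2) / (1 - r^2 + 1e-300))
    pv <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
    tibble(var1 = p[1], var2 = p[2], rho = r, p = pv)
  }) %>%
    filter(abs(.data$rho) >= rho_cutoff, .data$p < p_cutoff)
  dropped <- character(0)
  for (i in seq_len(nrow(flagged))) {
    a <- flagged$var1[i]; b <- flagged$var2[i]
    if (a %in% keep && !(b %in% keep)) dropped <- union(dropped, b)
    else if (b %in% keep && !(a %in% keep)) dropped <- union(dropped, a)
  }
  list(retained = setdiff(vars, dropped), dropped = dropped,
       flagged_pairs = flagged, rho_matrix = rho)
}

#' Log-transform and standardise the explanatory variables
#'
#' Applies detection-limit substitution (NH4 below `nh4_lod` becomes
#' `nh4_lod` = 0.1 umol L^-1; phytoplankton biomass fractions below
#' `frac_lod` become `frac_lod` = 0.1%), then the natural log, then
#' per-column standardisation to mean 0 and standard deviation 1.
#'
#' @param covariate_table tibble of positive covariates.
#' @param columns columns to transform, default [phi_covariates()]
#'   intersected with what is present.
#' @param nh4_lod,frac_lod detection limits substituted into `NH4` and the
#'   `frac_*` columns (NA or smaller values are raised to the limit).
#' @param center,scale optional named vectors of pre-computed log-scale
#'   means/sds (to standardise new data on a reference scale).
#' @return a tibble of standardised columns, with attributes `center` and
#'   `scale` holding the log-scale moments used.
#' @export
transform_standardise <- function(covariate_table, columns = NULL,
                                  nh4_lod = 0.1, frac_lod = 0.1,
                                  center = NULL, scale = NULL) {
  x <- as_tibble(covariate_table)
  if (is.null(columns)) columns <- intersect(phi_covariates(), names(x))
  x <- x[columns]
  if ("NH4" %in% columns) {
    v <- x$NH4
    v[is.na(v) | v < nh4_lod] <- nh4_lod
    x$NH4 <- v
  }
  for (fc in grep("^frac_", columns, value = TRUE)) {
    v <- x[[fc]]
    v[is.na(v) | v < frac_lod] <- frac_lod
    x[[fc]] <- v
  }
  bad <- vapply(x, function(v) any(!is.finite(v) | v <= 0), logical(1))
  if (any(bad)) {
    abort(paste("Non-positive values after detection-limit substitution in:",
                paste(columns[bad], collapse = ", ")))
  }
  logged <- lapply(x, log)
  if (is.null(center)) center <- vapply(logged, mean, numeric(1))
  if (is.null(scale)) scale <- vapply(logged, stats::sd, numeric(1))
  if (any(scale == 0)) {
    abort(paste("Zero variance (cannot standardise):",
                paste(columns[scale == 0], collapse = ", ")))
  }
  out <- purrr::imap(logged, function(v, nm) (v - center[[nm]]) / scale[[nm]])
  out <- as_tibble(out)
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Gamma GLM with log link for the electron requirement
#'
#' Maximum-likelihood fit of \eqn{\Phi_{e,C}} on the (already standardised)
#' explanatory variables with gamma errors and a log link. Reports
#' coefficients with standard errors, t and p values, AIC, two pseudo-R^2
#' conventions (squared Pearson correlation of observed and fitted response;
#' 1 - residual/null deviance), and the variance inflation factor of every
#' non-intercept term.
#'
#' @param phi positive response vector.
#' @param X data frame / tibble of standardised explanatory variables.
#' @return an object of class `phi_glm`: list with `fit` (the glm), `terms`,
#'   `aic`, `pseudo_r2`, `pseudo_r2_deviance`, `vif`, `n`.
#' @export
fit_gamma_glm <- function(phi, X) {
  if (any(!is.finite(phi) | phi <= 0)) {
    abort("`phi` must be strictly positive and finite.")
  }
  X <- as.data.frame(X)
  if (ncol(X) == 0) X <- data.frame(matrix(nrow = length(phi), ncol = 0))
  if (nrow(X) != length(phi)) abort("`phi` and `X` sizes differ.")
  if (ncol(X) > 0 && qr(as.matrix(X))$rank < ncol(X)) {
    abort("`X` is rank deficient; remove aliased terms.")
  }
  dat <- cbind(data.frame(.phi = phi), X)
  fml <- if (ncol(X) == 0) .phi ~ 1 else
    stats::reformulate(colnames(X), response = ".phi")
  fit <- glm(fml, family = Gamma(link = "log"), data = dat)
  sm <- summary(fit)
  terms_tbl <- tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    std_error = sm$coefficients[, 2],
    t_value = sm$coefficients[, 3],
    p_value = sm$coefficients[, 4]
  )
  vif <- if (ncol(X) >= 2) car::vif(fit) else
    setNames(rep(1, ncol(X)), colnames(X))
  structure(
    list(fit = fit, terms = terms_tbl, aic = AIC(fit),
         pseudo_r2 = if (stats::sd(fitted(fit)) == 0) NA_real_ else
           cor(phi, fitted(fit))^2,
         pseudo_r2_deviance = 1 - fit$deviance / fit$null.deviance,
         vif = vif, n = length(phi)),
    class = "phi_glm"
  )
}

#' @export
print.phi_glm <- function(x, ...) {
  cat(sprintf("Gamma GLM (log link), n = %d, AIC = %.1f, R2 = %.3f (corr) / %.3f (dev)\n",
              x$n, x$aic, x$pseudo_r2, x$pseudo_r2_deviance))
  print(x$terms)
  invisible(x)
}

#' @export
tidy.phi_glm <- function(x, ...) x$terms

#' @export
glance.phi_glm <- function(x, ...) {
  tibble(aic = x$aic, pseudo_r2 = x$pseudo_r2,
         pseudo_r2_deviance = x$pseudo_r2_deviance, n = x$n,
         max_vif = if (length(x$vif)) max(x$vif) else NA_real_)
}

#' All-subsets AIC ranking of gamma GLM sub-models
#'
#' Enumerates every subset of the candidate terms (2^k models including the
#' intercept-only model), fits each by gamma GLM with log link on the same
#' data, and ranks the sub-models by AIC. Besides the global best model,
#' the ranking records the best sub-model excluding the nutrient terms
#' ("model 2" analogue, for campaigns without nutrient chemistry) and the
#' best excluding nutrients and phytoplankton-composition terms
#' ("model 3" analogue).
#'
#' @param phi positive response vector.
#' @param X standardised explanatory variables (data frame).
#' @param candidate_terms columns of `X` to enumerate (k <= 16).
#' @param nutrient_terms,phyto_terms term groups used for the constrained
#'   extracts.
#' @return an object of class `phi_ranking`: a tibble with one row per
#'   sub-model (`terms`, `k`, `aic`, `delta_aic`, `pseudo_r2`), sorted by
#'   AIC, with attributes `best`, `best_no_nutrients`,
#'   `best_no_nutrients_no_phyto` (fitted [fit_gamma_glm()] objects) and
#'   `failed` (character vector of failed subsets, normally empty).
#' @export
rank_all_submodels <- function(phi, X,
                               candidate_terms = colnames(X),
                               nutrient_terms = c("NH4", "NO3_NO2", "PO4"),
                               phyto_terms = c("frac_diatom",
                                               "frac_cyanobacteria",
                                               "frac_cryptophyte", "chl")) {
  X <- as.data.frame(X)
  k <- length(candidate_terms)
  if (k > 16) abort("At most 16 candidate terms (2^k enumeration).")
  if (!all(candidate_terms %in% colnames(X))) {
    abort("All candidate terms must be columns of `X`.")
  }
  y <- phi
  n <- length(y)
  base <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  xall <- as.matrix(X[candidate_terms])
  subsets <- lapply(0:(2^k - 1), function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  failed <- character(0)
  rows <- purrr::map_dfr(subsets, function(idx) {
    xmat <- cbind(base, xall[, idx, drop = FALSE])
    aic <- tryCatch({
      # glm.fit's aic already includes 2 x (rank + dispersion), matching
      # stats::AIC on the equivalent glm object
      f <- glm.fit(xmat, y, family = Gamma(link = "log"))
      r2 <- if (stats::sd(f$fitted.values) == 0) NA_real_ else
        cor(y, f$fitted.values)^2
      c(f$aic, r2)
    }, error = function(e) c(NA_real_, NA_real_))
    tibble(terms = paste(candidate_terms[idx], collapse = "+"),
           k = length(idx), aic = aic[1], pseudo_r2 = aic[2])
  })
  if (anyNA(rows$aic)) {
    failed <- rows$terms[is.na(rows$aic)]
    warn(paste("Sub-model fits failed and were excluded:",
               paste(failed, collapse = "; ")))
    rows <- rows[!is.na(rows$aic), ]
  }
  rows <- rows %>%
    arrange(.data$aic) %>%
    mutate(delta_aic = .data$aic - .data$aic[1])
  split_terms <- function(s) if (s == "") character(0) else strsplit(s, "+", fixed = TRUE)[[1]]
  best_under <- function(excluded) {
    ok <- vapply(rows$terms, function(s) !any(split_terms(s) %in% excluded),
                 logical(1))
    rows$terms[ok][1]
  }
  refit <- function(terms_str) {
    fit_gamma_glm(y, X[split_terms(terms_str)])
  }
  out <- rows
  attr(out, "best") <- refit(rows$terms[1])
  attr(out, "best_no_nutrients") <- refit(best_under(nutrient_terms))
  attr(out, "best_no_nutrients_no_phyto") <-
    refit(best_under(c(nutrient_terms, phyto_terms)))
  attr(out, "failed") <- failed
  class(out) <- c("phi_ranking", class(out))
  out
}

#' @export
tidy.phi_ranking <- function(x, ...) {
  as_tibble(x)
}

#' Extract a named model from a ranking
#' @param ranking a `phi_ranking`.
#' @param which `"best"`, `"best_no_nutrients"` or
#'   `"best_no_nutrients_no_phyto"`.
#' @return a `phi_glm` object.
#' @export
ranking_model <- function(ranking, which = "best") {
  m <- attr(ranking, which)
  if (is.null(m)) abort(paste("No model named", which, "in this ranking."))
  m
}
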