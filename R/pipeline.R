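#' Run the full analysis chain on a campaign
#'
#' Executes every stage in order on a (synthetic or ingested) campaign:
#' FRRf quality control, photophysiology, spectral correction and electron
#' transport; layered attenuation fits; incubation rates (oxygen and 13C);
#' P-E curve fits per date; the per-observation electron requirement
#' \eqn{\Phi_{e,C}}; the stratified bootstrap, collinearity screen and
#' gamma GLM (optionally the all-subsets AIC ranking); and daily
#' depth-integrated productivity with the FRRf/13C comparison.
#'
#' @param campaign a `phiec_campaign` (from [generate_campaign()] or
#'   [read_campaign()]).
#' @param instrument an [instrument_config()]; defaults to the campaign
#'   scenario's instrument when available.
#' @param seed seed for the bootstrap stage.
#' @param rank_submodels fit the full 2^13 sub-model ranking (slower); when
#'   `FALSE` only the full GLM is fitted and used as "best".
#' @param pe_model P-E model selection rule passed to [fit_pe_curve()].
#' @param cyano_threshold biomass-% of cyanobacteria above which the
#'   cyanobacteria-type a*phy spectrum is used for a date.
#' @param outdir optional directory; when given, every stage's output table
#'   (QC summary, phi records, bootstrap table, sub-model ranking, daily
#'   GPP) and the run manifest are written there as csv/json.
#' @return a list of class `phiec_run` with elements `qc`, `phi_records`,
#'   `kd_fits`, `pe_fits`, `bootstrap`, `screen`, `glm`, `ranking`
#'   (or NULL), `gpp`, `manifest`.
#' @export
run_pipeline <- function(campaign, instrument = NULL, seed = 1,
                         rank_submodels = FALSE, pe_model = "auto",
                         cyano_threshold = 30, outdir = NULL) {
  if (is.null(instrument)) {
    sc <- attr(campaign, "scenario")
    instrument <- if (!is.null(sc)) sc$instrument else instrument_config()
  }
  profiles <- campaign$profiles

  ## 1. quality control ------------------------------------------------
  qc <- qc_filter(campaign$frrf)
  frrf <- derive_photophys(qc$kept) %>% filter(.data$photophys_ok)

  ## 2. spectral correction and electron transport ---------------------
  date_meta <- profiles %>%
    group_by(.data$date, .data$date_index, .data$station, .data$basin,
             .data$sky, .data$E0, .data$day_length) %>%
    summarise(mean_cyano = mean(.data$frac_cyanobacteria), .groups = "drop") %>%
    mutate(aphy_type = ifelse(.data$mean_cyano > cyano_threshold,
                              "cyanobacteria", "eukaryote"))
  frrf <- frrf %>%
    left_join(profiles %>% select("date", "depth", "chl", "temperature",
                                  "DO", "turbidity", "NH4", "NO3_NO2", "PO4",
                                  dplyr::starts_with("frac_")),
              by = c("date", "depth")) %>%
    left_join(date_meta %>% select("date", "sky", "E0", "day_length",
                                   "aphy_type"),
              by = "date")
  cyano_dates <- date_meta$date[date_meta$aphy_type == "cyanobacteria"]
  if (length(cyano_dates)) {
    rlang::inform(paste0(
      "Cyanobacteria-dominated date(s) ", paste(cyano_dates, collapse = ", "),
      ": dark-state transition can bias Fo (and hence RCII) upward;",
      " flagged, not corrected."))
  }
  frrf$SCF <- compute_scf(frrf, instrument)
  frrf <- frrf %>%
    mutate(
      sigma_PSII_prime_scf = .data$sigma_PSII_prime * .data$SCF,
      RCII = rcii_concentration(.data$Fo, .data$sigma_PSII, instrument),
      J_f = electron_transport(.data$E, .data$sigma_PSII_prime_scf,
                               .data$qP, instrument),
      JV_f = .data$J_f * .data$RCII
    )

  ## 3. attenuation ----------------------------------------------------
  kd_fits <- lapply(split(profiles, profiles$date), function(p) {
    fit_kd(tibble(depth = p$depth, E = p$E_par))
  })

  ## 4. incubation rates ------------------------------------------------
  inc <- campaign$incubations %>%
    left_join(date_meta %>% select("date", "E0", "aphy_type"), by = "date",
              suffix = c("", ".meta")) %>%
    oxygen_rates() %>%
    gp_13c()
  inc$E_chamber <- inc$light_level * inc$E0 *
    vapply(inc$aphy_type, function(tp) scf_chamber(tp, instrument), numeric(1))
  # replicate casts per depth: use their median RCII for the bottle's depth
  rcii_at <- frrf %>%
    group_by(.data$date, .data$depth) %>%
    summarise(RCII = median(.data$RCII), .groups = "drop")
  inc <- inc %>%
    left_join(rcii_at, by = c("date", "source_depth" = "depth")) %>%
    mutate(PB_C = pb_c(.data$GP_C, .data$RCII))

  ## 5. P-E fits and the electron requirement ---------------------------
  pe_fits <- lapply(split(inc, inc$date), function(b) {
    fit_pe_curve(b$E_chamber, b$PB_C, model = pe_model)
  })
  frrf$PB_C_at_E <- vapply(seq_len(nrow(frrf)), function(i) {
    predict(pe_fits[[frrf$date[i]]], frrf$E[i])
  }, numeric(1))
  phi_records <- frrf %>%
    mutate(phi_e_c = phi_e_c(.data$J_f, .data$PB_C_at_E),
           apparent = .data$phi_e_c < 4,
           PAR = .data$E) %>%
    filter(is.finite(.data$phi_e_c), .data$phi_e_c > 0)
  n_app <- sum(phi_records$apparent)
  if (n_app > 0) {
    rlang::inform(paste0(n_app, " of ", nrow(phi_records),
                         " records have apparent phi_e_c < 4",
                         " (kept in the analysis)."))
  }

  ## 6. bootstrap, screen, GLM ------------------------------------------
  boot <- stratified_bootstrap(phi_records, seed = seed)
  screen_cols <- c(phi_covariates(), "NPQ_NSV", "RCII", "frac_zygnematophyte")
  screen <- collinearity_screen(boot[intersect(screen_cols, names(boot))])
  Z <- transform_standardise(boot)
  glm_fit <- fit_gamma_glm(boot$phi_e_c, Z)
  ranking <- NULL
  models <- list(best = glm_fit)
  if (rank_submodels) {
    ranking <- rank_all_submodels(boot$phi_e_c, Z)
    models <- list(best = ranking_model(ranking, "best"),
                   model2 = ranking_model(ranking, "best_no_nutrients"),
                   model3 = ranking_model(ranking, "best_no_nutrients_no_phyto"))
  }

  ## 7. daily productivity ----------------------------------------------
  gpp <- daily_gpp_table(phi_records, pe_fits, kd_fits, date_meta, models,
                         center = attr(Z, "center"), scale = attr(Z, "scale"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("phiec")),
    seed = seed,
    n_frrf_in = nrow(campaign$frrf), n_frrf_kept = nrow(frrf),
    n_phi = nrow(phi_records), n_boot = nrow(boot),
    hash = rlang::hash(list(seed, campaign$frrf, campaign$profiles,
                            campaign$incubations))
  )
  out <- structure(
    list(qc = qc, phi_records = phi_records, kd_fits = kd_fits,
         pe_fits = pe_fits, bootstrap = boot, screen = screen,
         glm = glm_fit, models = models, ranking = ranking, gpp = gpp,
         manifest = manifest),
    class = "phiec_run"
  )
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

write_run <- function(run, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wr <- function(x, nm) utils::write.csv(x, file.path(outdir, nm),
                                         row.names = FALSE)
  wr(run$qc$summary, "qc_summary.csv")
  wr(run$qc$rejected, "qc_rejected.csv")
  wr(run$phi_records, "phi_records.csv")
  wr(run$bootstrap, "bootstrap.csv")
  wr(run$glm$terms, "glm_terms.csv")
  if (!is.null(run$ranking)) wr(as_tibble(run$ranking), "ranking.csv")
  wr(run$gpp, "gpp.csv")
  writeLines(vapply(names(run$manifest),
                    function(k) paste0(k, ": ", run$manifest[[k]]),
                    character(1)),
             file.path(outdir, "manifest.txt"))
  invisible(outdir)
}

# per-record in-situ SCF (shared by generator and pipeline)
compute_scf <- function(records, instrument) {
  key <- paste(records$date, records$depth)
  uniq <- !duplicated(key)
  scf_u <- vapply(which(uniq), function(i) {
    drow <- list(date_index = records$date_index[i], sky = records$sky[i],
                 E0 = records$E0[i], basin = records$basin[i])
    scf_in_situ(drow, records$depth[i], records$chl[i],
                records$aphy_type[i], instrument)
  }, numeric(1))
  scf_u[match(key, key[uniq])]
}

predict_phi <- function(model, newdata, center, scale) {
  terms <- setdiff(model$terms$term, "(Intercept)")
  Z <- transform_standardise(newdata, columns = intersect(phi_covariates(),
                                                          names(newdata)),
                             center = center, scale = scale)
  eta <- model$terms$estimate[model$terms$term == "(Intercept)"]
  for (tm in terms) eta <- eta + Z[[tm]] *
      model$terms$estimate[model$terms$term == tm]
  exp(eta)
}

daily_gpp_table <- function(phi_records, pe_fits, kd_fits, date_meta, models,
                            center, scale) {
  purrr::map_dfr(date_meta$date, function(d) {
    meta <- date_meta[date_meta$date == d, ]
    recs <- phi_records[phi_records$date == d, ]
    if (nrow(recs) < 3) return(tibble())
    basin <- meta$basin
    grid_step <- if (basin == "north") 1.25 else 0.5
    z_bottom <- max(recs$depth)
    zg <- seq(0, z_bottom, by = grid_step)
    kd <- kd_fits[[d]]
    L <- meta$day_length
    E0_t <- hourly_surface_par(meta$E0, L)
    # E(z, t): layered attenuation of the hourly surface PAR
    atten <- par_at_depth(kd, zg, E0 = 1)
    E_zt <- outer(atten, E0_t)
    RCII_z <- approx(recs$depth, recs$RCII, zg, rule = 2, ties = mean)$y

    pe_13c <- pe_fits[[d]]
    PB13_zt <- matrix(predict(pe_13c, as.vector(E_zt)), nrow = length(zg))
    gpp_13c <- daily_gpp(zg, RCII_z, PB13_zt)

    row <- tibble(date = d, basin = basin, gpp_13c = gpp_13c)
    for (mn in names(models)) {
      phi_hat <- predict_phi(models[[mn]], recs, center, scale)
      pb_f <- pb_f_from_phi(recs$J_f, phi_hat)
      ok <- is.finite(pb_f)
      fit_f <- tryCatch(fit_pe_curve(recs$E[ok], pb_f[ok]),
                        error = function(e) NULL)
      g <- if (is.null(fit_f)) NA_real_ else {
        PBf_zt <- matrix(predict(fit_f, as.vector(E_zt)), nrow = length(zg))
        daily_gpp(zg, RCII_z, PBf_zt)
      }
      row[[paste0("gpp_f_", mn)]] <- g
      row[[paste0("ratio_", mn)]] <- relative_gpp(g, gpp_13c)
    }
    row
  })
}

#' @export
print.phiec_run <- function(x, ...) {
  cat("phiec pipeline run\n")
  cat(sprintf("  FRRf records kept: %d; phi records: %d; bootstrap rows: %d\n",
              x$manifest$n_frrf_kept, x$manifest$n_phi, x$manifest$n_boot))
  cat(sprintf("  GLM AIC %.1f, pseudo-R2 %.3f\n", x$glm$aic, x$glm$pseudo_r2))
  if (nrow(x$gpp)) {
    cat(sprintf("  median GPP_f/GPP_13C (best): %.3f\n",
                median(x$gpp$ratio_best, na.rm = TRUE)))
  }
  invisible(x)
}

#' Annual mean electron requirement per basin and pooled
#'
#' Date-level means of \eqn{\Phi_{e,C}} aggregated to basin annual means
#' and the pooled all-station mean. With the same number of observations
#' per date and dates per basin, the pooled mean equals the average of the
#' two basin means.
#'
#' @param phi_records tibble with `basin` and `phi_e_c` columns.
#' @return tibble with rows `north`, `south`, `all` and their mean phi.
#' @export
phi_annual_means <- function(phi_records) {
  by_basin <- phi_records %>%
    group_by(.data$basin) %>%
    summarise(mean_phi = mean(.data$phi_e_c), n = n(), .groups = "drop")
  bind_rows(by_basin,
            tibble(basin = "all", mean_phi = mean(phi_records$phi_e_c),
                   n = nrow(phi_records)))
}

#' Excitation-combination comparison report
#'
#' Summarises FRRf data quality and signal per excitation wavelength
#' combination: N after quality control and the median/range of both RCII
#' closure probabilities (the instrument-evaluation table layout), median
#' Fo depth profiles, and volumetric electron transport per combination
#' (for overlay against the oxygen-based rate when `jv_o_table` is given).
#'
#' @param frrf_combined FRRf records from >= 2 combinations, with an
#'   `excitation` label column (see [frrf_by_combination()]).
#' @param instrument an [instrument_config()].
#' @param jv_o_table optional tibble with `E` and `JV_O` columns.
#' @return list with `quality` (per-combination QC summary), `fo_profiles`
#'   (median Fo per excitation and depth), `jv` (per-record JV_f with
#'   excitation label) and `jv_o` (the overlay table, possibly NULL).
#' @export
excitation_report <- function(frrf_combined, instrument = instrument_config(),
                              jv_o_table = NULL) {
  if (length(unique(frrf_combined$excitation)) < 2) {
    abort("Need at least two excitation combinations to compare.")
  }
  qc <- qc_filter(frrf_combined)
  ph <- derive_photophys(qc$kept) %>% filter(.data$photophys_ok)
  ph <- ph %>%
    mutate(RCII = rcii_concentration(.data$Fo, .data$sigma_PSII, instrument),
           J_f = electron_transport(.data$E, .data$sigma_PSII_prime,
                                    .data$qP, instrument),
           JV_f = .data$J_f * .data$RCII)
  fo_profiles <- ph %>%
    group_by(.data$excitation, .data$depth) %>%
    summarise(Fo_median = median(.data$Fo), .groups = "drop")
  list(quality = qc$summary, fo_profiles = fo_profiles,
       jv = ph %>% select("excitation", "date", "depth", "E", "JV_f"),
       jv_o = jv_o_table)
}
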