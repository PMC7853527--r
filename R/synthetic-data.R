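#' Default true coefficients of the synthetic electron-requirement model
#'
#' Log-link scale coefficients over the 13 candidate covariates plus
#' intercept used by the synthetic campaign generator. The defaults are the
#' field-scale best-model values (temperature dominant at 0.51, PAR absent,
#' cyanobacteria negative), so recovery tests run at realistic effect sizes.
#'
#' @return named numeric vector (`(Intercept)` plus [phi_covariates()]).
#' @export
default_phi_coefficients <- function() {
  c("(Intercept)" = 1.83,
    temperature = 0.51, PAR = 0, turbidity = 0.10, DO = 0.13,
    NH4 = -0.02, NO3_NO2 = 0.13, PO4 = -0.02,
    Fv_over_Fm = -0.10, sigma_PSII = 0.17, chl = 0.10,
    frac_diatom = -0.11, frac_cyanobacteria = -0.20,
    frac_cryptophyte = 0.14)
}

#' Define a synthetic campaign scenario
#'
#' A scenario fixes everything the generator needs: the station/date plan
#' (14 dates by default, seven per basin, matching a two-basin seasonal
#' campaign), the true electron-requirement model on the log-link scale,
#' the gamma dispersion of the requirement, the fluorescence measurement
#' noise, and the instrument constants. With `frrf_noise_cv = 0` and
#' `phi_dispersion = Inf` the campaign is noise-free and the full pipeline
#' reproduces the truth table exactly.
#'
#' @param seed integer; the single global seed. Every internal stream is
#'   derived from it by a counter-based splitting rule, so generation order
#'   does not affect reproducibility.
#' @param n_dates number of sampling dates (alternating north/south).
#' @param true_phi_coefficients named coefficient vector, see
#'   [default_phi_coefficients()].
#' @param phi_dispersion gamma shape of the multiplicative (mean 1) noise on
#'   the electron requirement; `Inf` switches the noise off. Must be > 0.
#' @param frrf_noise_cv coefficient of variation of multiplicative
#'   lognormal noise applied to stored fluorescence yields and cross
#'   sections; 0 switches measurement noise off.
#' @param photoinhibition_dates integer indices of dates whose true P-E
#'   curve carries exponential photoinhibition (the two brightest summer
#'   dates by default).
#' @param n_casts replicate FRRf acquisitions per depth (the acquisition
#'   protocol repeats each excitation sequence several times per depth).
#' @param instrument an [instrument_config()].
#' @return a list of class `phiec_scenario`.
#' @export
synthetic_scenario <- function(seed = 1, n_dates = 14,
                               true_phi_coefficients = default_phi_coefficients(),
                               phi_dispersion = 5,
                               frrf_noise_cv = 0.03,
                               photoinhibition_dates = c(1, 3),
                               n_casts = 5,
                               instrument = instrument_config()) {
  if (n_casts < 1) abort("`n_casts` must be at least 1.")
  if (!is.finite(phi_dispersion) && !is.infinite(phi_dispersion)) {
    abort("`phi_dispersion` must be a positive number or Inf.")
  }
  if (is.finite(phi_dispersion) && phi_dispersion <= 0) {
    abort("`phi_dispersion` must be positive (gamma shape), or Inf for no noise.")
  }
  if (frrf_noise_cv < 0) abort("`frrf_noise_cv` must be non-negative.")
  if (n_dates < 2) abort("Need at least two dates (one per basin).")
  cov_names <- phi_covariates()
  miss <- setdiff(c("(Intercept)", cov_names), names(true_phi_coefficients))
  if (length(miss)) {
    abort(paste("Missing coefficients:", paste(miss, collapse = ", ")))
  }
  structure(
    list(seed = as.integer(seed), n_dates = as.integer(n_dates),
         beta = true_phi_coefficients[c("(Intercept)", cov_names)],
         phi_dispersion = phi_dispersion,
         frrf_noise_cv = frrf_noise_cv,
         n_casts = as.integer(n_casts),
         photoinhibition_dates = photoinhibition_dates,
         instrument = instrument),
    class = "phiec_scenario"
  )
}

# depth plans mirroring a deep (bucket + rosette) and shallow (pump) station
station_depths <- function(station) {
  switch(station,
         "12B" = , "17B" = c(0, 1, 2, 2.5, 4, 5, 6, 8, 10, 12.5, 15, 17.5, 20),
         "9B" = seq(0, 5.5, by = 0.5),
         "6B" = seq(0, 4, by = 0.5))
}

incubation_source_depths <- function(station) {
  # depth feeding each chamber light level: 100, 65, 30, 10, 1.6 % of surface
  switch(station,
         "12B" = , "17B" = c(0, 0, 2.5, 5, 10),
         "9B" = c(0, 0, 2, 2, 4),
         "6B" = c(0, 0, 2, 2, 3))
}

incubation_light_levels <- function() c(1.00, 0.65, 0.30, 0.10, 0.016)

# date-level design: stations alternate between basins through the seasons
date_plan <- function(scenario) {
  n <- scenario$n_dates
  seed <- scenario$seed
  idx <- seq_len(n)
  basin <- ifelse(idx %% 2 == 1, "north", "south")
  station <- ifelse(basin == "north",
                    ifelse((idx %/% 2) %% 2 == 0, "12B", "17B"),
                    ifelse((idx %/% 2) %% 2 == 0, "9B", "6B"))
  doy <- round(seq(200, 200 + 320, length.out = n)) %% 365  # Jul through May
  withr::with_seed(child_seed(seed, 1), {
    E0 <- runif(n, 150, 1700)
    sky <- sample(c("clear", "overcast"), n, replace = TRUE, prob = c(.7, .3))
    kd1 <- ifelse(basin == "north", runif(n, 0.25, 0.55), runif(n, 0.6, 1.9))
    two_layer <- runif(n) < 0.35
    kd2 <- ifelse(two_layer, kd1 * runif(n, 0.3, 0.6), kd1)
    z_break <- ifelse(basin == "north", 2, 2) * 1.0
    alpha_C <- runif(n, 0.012, 0.03)
    Ps_C <- runif(n, 1.2, 2.5)
  })
  # photoinhibited dates get a decline that is unambiguous at the brightest
  # incubator level (~25% below the observed peak), solved per date
  beta_C <- rep(0, n)
  pin <- intersect(scenario$photoinhibition_dates, idx)
  for (i in pin) {
    beta_C[i] <- solve_photoinhibition_beta(alpha_C[i], Ps_C[i], E0[i])
  }
  day_length <- round(12 + 2.5 * sin(2 * pi * (doy - 80) / 365))
  tibble(
    date_index = idx,
    date = sprintf("d%02d", idx),
    station = station, basin = basin, doy = doy,
    E0 = E0, sky = sky,
    kd1 = kd1, kd2 = kd2, z_break = z_break, two_layer = two_layer,
    alpha_C = alpha_C, Ps_C = Ps_C, beta_C = beta_C,
    day_length = day_length
  )
}

# beta such that the response at the brightest incubator light level sits
# `decline` below the maximum over the five levels (deterministic root find)
solve_photoinhibition_beta <- function(alpha, Ps, E0, decline = 0.25) {
  E <- incubation_light_levels() * E0
  h <- function(b) {
    p <- platt3(E, alpha, Ps, b)
    (1 - decline) * max(p) - p[1]
  }
  stats::uniroot(h, c(1e-10, 20 * Ps / E0), tol = 1e-12)$root
}

kd_model_for_date <- function(drow) {
  if (drow$two_layer) {
    structure(list(layer_breaks = c(0, drow$z_break),
                   kd = c(drow$kd1, drow$kd2), E0 = drow$E0),
              class = "kd_fit")
  } else {
    structure(list(layer_breaks = 0, kd = drow$kd1, E0 = drow$E0),
              class = "kd_fit")
  }
}

pe_curve_for_date <- function(drow) {
  if (drow$beta_C > 0) {
    function(E) platt3(E, drow$alpha_C, drow$Ps_C, drow$beta_C)
  } else {
    function(E) webb2(E, drow$alpha_C, drow$Ps_C)
  }
}

aphy_type_for <- function(mean_cyano_frac, threshold = 30) {
  if (mean_cyano_frac > threshold) "cyanobacteria" else "eukaryote"
}

# SCF of the ambient light field at one depth, and of the growth chamber
scf_in_situ <- function(drow, depth, chl, aphy_type, instrument) {
  grid <- instrument$e_frrf_spectrum$wavelength
  aphy <- phytoplankton_absorption_spectrum(aphy_type, grid = grid)
  e0 <- generate_sunlight_spectrum(drow$date_index, drow$sky, drow$E0, grid)
  budget <- absorption_budget(drow$basin, chl, aphy_type, grid = grid,
                              a_phy_star = aphy)
  e_insitu <- spectral_irradiance(e0, budget, depth)
  spectral_correction_factor(aphy, e_insitu, instrument$e_frrf_spectrum)
}

scf_chamber <- function(aphy_type, instrument) {
  grid <- instrument$e_frrf_spectrum$wavelength
  aphy <- phytoplankton_absorption_spectrum(aphy_type, grid = grid)
  lamp <- chamber_lamp_spectrum(grid)
  spectral_correction_factor(aphy, lamp, instrument$e_frrf_spectrum)
}

lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

# covariate profile for one date: smooth vertical structure + seasonality
generate_profile_for_date <- function(drow, scenario) {
  z <- station_depths(drow$station)
  nz <- length(z)
  season <- sin(2 * pi * (drow$doy - 110) / 365)
  kdm <- kd_model_for_date(drow)
  withr::with_seed(child_seed(scenario$seed, 2, drow$date_index), {
    t_surf <- 19 + 11 * season + rnorm(1, 0, 0.8)
    strat <- max(0, season) * 0.6            # summer stratification gradient
    temperature <- pmax(7.5, t_surf - strat * z + rnorm(nz, 0, 0.15))
    DO <- runif(1, 85, 125) + rnorm(nz, 0, 2)
    turbidity <- exp(rnorm(nz, log(ifelse(drow$basin == "south", 1.5, 0.5)), 0.4))
    chl_surf <- exp(rnorm(1, log(ifelse(drow$basin == "south", 12, 5)), 0.4))
    chl <- pmax(0.5, chl_surf * exp(-0.03 * z) * exp(rnorm(nz, 0, 0.1)))
    NH4 <- pmax(0.02, exp(rnorm(nz, log(0.4 - 0.25 * season + 0.1), 0.5)))
    NO3_NO2 <- pmax(0.05, exp(rnorm(nz, log(1.5 - 1.2 * season + 0.3), 0.5)))
    PO4 <- runif(nz, 0.01, 0.04)
    Fv_over_Fm <- runif(nz, 0.3, 0.65)
    sigma_PSII <- runif(nz, 3, 8)
    # biomass fractions via normalised gamma draws (natural sum constraint)
    conc <- c(diatom = 3, cyanobacteria = ifelse(drow$basin == "south" &
                                                   season > 0.6, 4, 0.6),
              cryptophyte = 0.8, zygnematophyte = 2, other = 1)
    g <- matrix(rgamma(nz * 5, shape = rep(conc, each = nz), rate = 1), nz, 5)
    frac <- 100 * g / rowSums(g)
  })
  tibble(
    date = drow$date, date_index = drow$date_index, station = drow$station,
    basin = drow$basin, sky = drow$sky, E0 = drow$E0,
    day_length = drow$day_length, depth = z,
    E_par = par_at_depth(kdm, z),
    temperature = temperature, DO = DO, turbidity = turbidity, chl = chl,
    NH4 = NH4, NO3_NO2 = NO3_NO2, PO4 = PO4,
    Fv_over_Fm = Fv_over_Fm, sigma_PSII = sigma_PSII,
    frac_diatom = frac[, 1], frac_cyanobacteria = frac[, 2],
    frac_cryptophyte = frac[, 3], frac_zygnematophyte = frac[, 4],
    frac_other = frac[, 5]
  )
}

#' Generate a complete synthetic campaign
#'
#' Produces internally consistent tables for a whole sampling campaign with
#' known ground truth: an FRRf cast table (fluorescence yields, cross
#' sections, quality statistics), a water-column profile table (PAR and the
#' 13 candidate covariates), an incubation table (light-dark oxygen pairs
#' and 13C tracer observables at five chamber light levels), and a truth
#' table holding every latent value (the electron requirement, electron
#' transport and carbon fixation rates, RCII, spectral correction factors,
#' and the generating P-E and attenuation parameters).
#'
#' The construction inverts the analysis chain: each date owns a true P-E
#' curve for the RCII-specific carbon fixation rate, the true electron
#' requirement follows the log-link gamma model on the standardised log
#' covariates, and the electron transport rate is back-computed so that
#' every stage of the forward pipeline recovers its input exactly when
#' noise is off.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a list of class `phiec_campaign` with tibbles `frrf`, `profiles`,
#'   `incubations`, `truth`, and attributes `scenario` and `dates` (the
#'   date-level design table).
#' @examples
#' camp <- generate_campaign(synthetic_scenario(seed = 42, n_dates = 4))
#' names(camp)
#' @export
generate_campaign <- function(scenario = synthetic_scenario()) {
  if (!inherits(scenario, "phiec_scenario")) {
    abort("`scenario` must come from synthetic_scenario().")
  }
  plan <- date_plan(scenario)
  profiles <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    generate_profile_for_date(plan[i, ], scenario)
  })

  # truth: standardised covariates over the whole raw campaign
  cov_raw <- profiles %>% rename(PAR = "E_par")
  Z <- transform_standardise(cov_raw)
  beta <- scenario$beta
  lp <- beta[["(Intercept)"]] +
    as.vector(as.matrix(Z) %*% beta[phi_covariates()])
  n <- nrow(profiles)
  withr::with_seed(child_seed(scenario$seed, 3), {
    phi_noise <- if (is.infinite(scenario$phi_dispersion)) rep(1, n)
    else rgamma(n, shape = scenario$phi_dispersion,
                rate = scenario$phi_dispersion)
    rcii_noise <- lognorm_noise(n, 0.2)
    qp_jitter <- runif(n, 0.9, 1.0)
  })
  phi_true <- exp(lp) * phi_noise

  inst <- scenario$instrument
  truth <- profiles %>%
    select("date", "date_index", "station", "basin", "depth", "E_par", "chl")
  truth$phi_true <- phi_true
  truth$RCII <- 6 * profiles$chl * rcii_noise

  # per-date pieces: SCF, P-E curve, back-computed rates
  by_date <- split(seq_len(n), profiles$date_index)
  truth$SCF <- NA_real_
  truth$PB_C <- NA_real_
  for (di in names(by_date)) {
    ii <- by_date[[di]]
    drow <- plan[plan$date_index == as.integer(di), ]
    aphy_type <- aphy_type_for(mean(profiles$frac_cyanobacteria[ii]))
    pe <- pe_curve_for_date(drow)
    truth$PB_C[ii] <- pe(profiles$E_par[ii])
    truth$SCF[ii] <- vapply(ii, function(j) {
      scf_in_situ(drow, profiles$depth[j], profiles$chl[j], aphy_type, inst)
    }, numeric(1))
  }
  truth$J_f <- truth$phi_true * truth$PB_C / phi_conversion_factor()
  truth$qP <- 0.98 / (1 + profiles$E_par /
                        (plan$Ps_C[profiles$date_index] /
                           plan$alpha_C[profiles$date_index])) * qp_jitter
  truth$sigma_PSII_prime_scf <-
    truth$J_f / (profiles$E_par * truth$qP * inst$sigma_scale)
  truth$JV_f <- truth$J_f * truth$RCII
  truth$GP_C <- truth$PB_C * truth$RCII

  # FRRf table: invert the yield definitions, add measurement noise.
  # The acquisition protocol repeats each depth several times, so the cast
  # table carries `n_casts` replicate acquisitions per (date, depth), each
  # with its own noise and quality draw.
  R <- scenario$n_casts
  nr <- n * R
  withr::with_seed(child_seed(scenario$seed, 4), {
    npq <- pmax(0.2, 0.3 + 0.0015 * profiles$E_par *
                  lognorm_noise(n, 0.15))          # latent, per depth
    rsig <- pmin(0.079, pmax(0.031, rnorm(nr, 0.045, 0.006)))
    rsigp <- pmin(0.079, pmax(0.031, rnorm(nr, 0.048, 0.006)))
    if (scenario$frrf_noise_cv > 0) {
      flip <- runif(nr) < 0.02         # occasional out-of-band quality
      rsig[flip] <- runif(sum(flip), 0.01, 0.029)
    }
    # yield noise is common-mode within an acquisition (gain and biomass in
    # the chamber), one multiplier per light state; the cross sections carry
    # independent retrieval noise
    meas <- replicate(4, lognorm_noise(nr, scenario$frrf_noise_cv))
  })
  sigma_dark <- profiles$sigma_PSII
  Fo <- truth$RCII * sigma_dark / (inst$kr_over_efrrf * 1e-9)
  Fm <- Fo / (1 - profiles$Fv_over_Fm)
  Fo_p <- 0.9 * Fo
  Fm_p <- Fo_p * (1 + 1 / npq)
  F_p <- Fo_p + truth$qP * (Fm_p - Fo_p)
  sigma_prime_raw <- truth$sigma_PSII_prime_scf / truth$SCF

  rep_idx <- rep(seq_len(n), times = R)
  frrf <- tibble(
    date = profiles$date[rep_idx], date_index = profiles$date_index[rep_idx],
    station = profiles$station[rep_idx], basin = profiles$basin[rep_idx],
    excitation = paste(inst$leds, collapse = "+"),
    cast = rep(seq_len(R), each = n),
    depth = profiles$depth[rep_idx], E = profiles$E_par[rep_idx],
    Fo = Fo[rep_idx] * meas[, 1], Fm = Fm[rep_idx] * meas[, 1],
    Fo_prime = Fo_p[rep_idx] * meas[, 2], F_prime = F_p[rep_idx] * meas[, 2],
    Fm_prime = Fm_p[rep_idx] * meas[, 2],
    sigma_PSII = sigma_dark[rep_idx] * meas[, 3],
    sigma_PSII_prime = sigma_prime_raw[rep_idx] * meas[, 4],
    Rsigma_PSII = rsig, Rsigma_PSII_prime = rsigp
  )

  incubations <- generate_incubations(plan, profiles, truth, scenario)

  structure(list(frrf = frrf, profiles = profiles,
                 incubations = incubations, truth = truth),
            class = "phiec_campaign",
            scenario = scenario, dates = plan,
            standardisation = list(center = attr(Z, "center"),
                                   scale = attr(Z, "scale")))
}

generate_incubations <- function(plan, profiles, truth, scenario) {
  inst <- scenario$instrument
  purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    drow <- plan[i, ]
    ii <- which(profiles$date_index == drow$date_index)
    aphy_type <- aphy_type_for(mean(profiles$frac_cyanobacteria[ii]))
    scf_ch <- scf_chamber(aphy_type, inst)
    pe <- pe_curve_for_date(drow)
    levels <- incubation_light_levels()
    src <- incubation_source_depths(drow$station)
    E_ch <- levels * drow$E0 * scf_ch
    # latent rates at the source depth of each bottle
    j <- vapply(src, function(s) ii[which.min(abs(profiles$depth[ii] - s))],
                integer(1))
    RCII_src <- truth$RCII[j]
    PB_bottle <- pe(E_ch)
    GP_bottle <- PB_bottle * RCII_src
    JV_bottle <- truth$phi_true[j] * PB_bottle / phi_conversion_factor() *
      RCII_src
    duration <- 3
    withr::with_seed(child_seed(scenario$seed, 5, drow$date_index), {
      R_d <- runif(5, 5, 30)
      O2_start <- rep(8000, 5) + rnorm(5, 0, 20)
      POC <- 40 * profiles$chl[j] * lognorm_noise(5, 0.1)
      DIC <- runif(5, 400, 600)
    })
    NP_O <- R_d + JV_bottle / jv_o_factor()
    atom_nat <- 1.1
    atom_dic <- 0.9 * atom_nat + 0.1 * 99
    atom_inc <- atom_nat + GP_bottle * duration / POC * (atom_dic - atom_nat)
    tibble(
      date = drow$date, date_index = drow$date_index,
      station = drow$station, basin = drow$basin,
      light_level = levels, source_depth = src, duration = duration,
      O2_start_light = O2_start,
      O2_end_light = O2_start + NP_O * duration,
      O2_start_dark = O2_start,
      O2_end_dark = O2_start - R_d * duration,
      atom13C_natural = atom_nat, atom13C_DIC_enriched = atom_dic,
      atom13C_incubated = atom_inc, POC = POC, DIC = DIC
    )
  })
}

#' @export
print.phiec_campaign <- function(x, ...) {
  cat(sprintf("Synthetic campaign: %d dates, %d FRRf records, %d bottles\n",
              length(unique(x$frrf$date)), nrow(x$frrf), nrow(x$incubations)))
  invisible(x)
}

#' Write campaign tables to delimited text
#'
#' Writes `frrf.csv`, `profiles.csv`, `incubations.csv` and `truth.csv`
#' (comma-separated, UTF-8, one header row) into `dir`.
#'
#' @param campaign a `phiec_campaign`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("frrf", "profiles", "incubations", "truth")) {
    utils::write.csv(campaign[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read campaign tables back from a directory
#' @param dir directory holding the csv tables written by [write_campaign()].
#' @return a `phiec_campaign` (without scenario attributes).
#' @export
read_campaign <- function(dir) {
  out <- lapply(c("frrf", "profiles", "incubations", "truth"), function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) as_tibble(utils::read.csv(f)) else NULL
  })
  names(out) <- c("frrf", "profiles", "incubations", "truth")
  structure(out, class = "phiec_campaign")
}

#' Per-combination FRRf tables with excitation sensitivity
#'
#' Emulates the dependence of the fluorescence signal on the excitation
#' wavelength combination: combinations lacking the orange (633 nm) LED
#' undersample phycobilin-containing cells, scaling both the minimum yield
#' Fo and the ambient cross section in proportion to the cyanobacterial
#' biomass fraction.
#'
#' @param campaign a `phiec_campaign`.
#' @param combos list of LED combinations (numeric vectors).
#' @param sensitivity_633 relative sensitivity to cyanobacterial biomass of
#'   combinations without the 633 nm LED (0.5 = half signal from a pure
#'   cyanobacterial population).
#' @return one tibble of FRRf records with an `excitation` label column.
#' @export
frrf_by_combination <- function(campaign,
                                combos = list(444, c(444, 512),
                                              c(444, 633), c(444, 512, 633)),
                                sensitivity_633 = 0.5) {
  frrf <- campaign$frrf
  pk <- paste(campaign$profiles$date, campaign$profiles$depth)
  cy <- campaign$profiles$frac_cyanobacteria[
    match(paste(frrf$date, frrf$depth), pk)] / 100
  purrr::map_dfr(combos, function(cmb) {
    s <- if (633 %in% cmb) rep(1, nrow(frrf)) else
      1 - (1 - sensitivity_633) * cy
    out <- frrf
    out$excitation <- paste(cmb, collapse = "+")
    out$Fo <- frrf$Fo * s
    out$Fm <- frrf$Fm * s
    out$Fo_prime <- frrf$Fo_prime * s
    out$F_prime <- frrf$F_prime * s
    out$Fm_prime <- frrf$Fm_prime * s
    out$sigma_PSII_prime <- frrf$sigma_PSII_prime * s
    out
  })
}
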