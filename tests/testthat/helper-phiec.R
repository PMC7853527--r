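# shared fixtures, all generated in code

noise_free_scenario <- function(seed = 1, n_dates = 4, ...) {
  synthetic_scenario(seed = seed, n_dates = n_dates,
                     frrf_noise_cv = 0, phi_dispersion = Inf, ...)
}

# match pipeline phi records back to the truth table by (date, depth)
truth_match <- function(run, campaign) {
  key <- function(d) paste(d$date, d$depth)
  m <- match(key(run$phi_records), key(campaign$truth))
  list(estimate = run$phi_records$phi_e_c,
       truth = campaign$truth$phi_true[m])
}

rel_err <- function(x, y) abs(x - y) / abs(y)

flat_spectrum <- function(value = 1) {
  spectrum_on_grid(default_grid(), rep(value, 301))
}
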