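# shared fixtures, built in code

# a single-spectrum long tibble
spec_tbl <- function(wavenumbers, absorbances, id = "S1", well = 1L, scan = 1L) {
  tibble::tibble(patient_id = id, well = well, scan = scan,
                 wavenumber = wavenumbers, absorbance = absorbances)
}

# small noiseless configuration: spectra equal the band sum exactly
noiseless_config <- function(...) {
  sim_config(noise_additive_sd = 0, baseline_amp = 0, mult_scale_sd = 0,
             well_effect_sd = 0, ...)
}

# a compact cohort for classifier tests: modest grid, tweakable effect
quick_cohort <- function(n_patients, effect_size, seed,
                         prevalence = 0.5, n_points = 120,
                         noise_additive_sd = 0.002, mult_scale_sd = 0.02) {
  simulate_cohort(sim_config(
    n_patients = n_patients, prevalence = prevalence, n_points = n_points,
    effect_size = effect_size, noise_additive_sd = noise_additive_sd,
    mult_scale_sd = mult_scale_sd, seed = seed
  ))
}

# per-spectrum probability tibble for hand-built consensus cases
probs_tbl <- function(patient_id, p) {
  tibble::tibble(patient_id = patient_id,
                 well = 1L, scan = seq_along(p), p_cancer = p) |>
    dplyr::group_by(patient_id) |>
    dplyr::mutate(scan = dplyr::row_number()) |>
    dplyr::ungroup()
}

# random vote tibble: each of n patients casts 9 votes, cancer w.p. q
vote_cohort <- function(n, q, ids = sprintf("V%04d", seq_len(n))) {
  tibble::tibble(
    patient_id = rep(ids, each = 9),
    vote = runif(n * 9) < q
  )
}
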