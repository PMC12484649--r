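# shared fixtures, memoized so expensive generations run once per session

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# full-length default record (1 h), by seed
full_record <- function(seed, ...) {
  memo(paste0("rec_", seed, "_", paste(c(...), collapse = "_")), {
    generate_record(sim_params(seed = seed, ...))
  })
}

# short toy record for fast unit tests, assembled from the generator
# components (below the one-hour minimum that generate_record enforces)
toy_record <- function(seed = 1, duration_s = 600, cuff_interval_s = 120,
                       feature_noise_sd = 1, cuff_noise_sigma = 3.1) {
  memo(paste0("toy_", seed, "_", duration_s, "_", cuff_interval_s, "_",
              feature_noise_sd, "_", cuff_noise_sigma), {
    pars <- sim_params(duration_s = duration_s,
                       cuff_interval_s = cuff_interval_s,
                       feature_noise_sd = feature_noise_sd,
                       cuff_noise_sigma = cuff_noise_sigma, seed = seed)
    map <- simulate_map_trajectory(pars, seed = seed + 1L)
    fe <- simulate_latent_features(map, pars$true_mech_params,
                                   feature_noise_sd, seed = seed + 2L)
    wv <- synthesize_waveforms(fe$latent_hr, fe$latent_pi, fe$latent_nra,
                               seed = seed + 3L)
    cu <- synthesize_cuff(map, cuff_interval_s, 0, cuff_noise_sigma,
                          seed = seed + 4L)
    list(record = physio_record(
      patient_id = sprintf("toy-%03d", seed),
      ppg = wv$ppg, ecg = wv$ecg, hr = fe$hr, pi = fe$pi, nra = fe$nra,
      map_ref = map, cuff_events = cu, duration_s = duration_s),
      truth = list(map_1hz = map, beat_times = wv$beat_times,
                   latent_hr = fe$latent_hr, latent_pi = fe$latent_pi,
                   latent_nra = fe$latent_nra,
                   true_mech_params = pars$true_mech_params))
  })
}

# constant-feature waveform snippet: n seconds at fixed HR/PI/NRA
const_waveform <- function(hr = 75, pi = 5, nra = 0.4, n = 60, seed = 1) {
  synthesize_waveforms(rep(hr, n), rep(pi, n), rep(nra, n), seed = seed)
}
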