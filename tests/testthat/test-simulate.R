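test_that("MAP trajectory: zero-noise case, determinism, stationarity", {
  p0 <- sim_params(map_volatility = 0, map_reversion_rate = 0,
                   episode_rate = 0, map_baseline = 80, duration_s = 3600)
  x <- simulate_map_trajectory(p0, seed = 1)
  expect_equal(x, rep(80, 3600))

  p <- sim_params(duration_s = 3600)
  expect_identical(simulate_map_trajectory(p, seed = 5),
                   simulate_map_trajectory(p, seed = 5))

  # long-run sample mean near baseline, variability present
  means <- vapply(1:20, function(s) {
    x <- simulate_map_trajectory(sim_params(duration_s = 10000), seed = s)
    expect_gt(stats::sd(x), 0)
    mean(x)
  }, numeric(1))
  expect_true(all(abs(means - 80) < 5))

  expect_error(sim_params(duration_s = 0), "duration_s")
})

test_that("latent features invert the mechanistic formula exactly at zero noise", {
  p <- sim_params(seed = 3)
  map <- simulate_map_trajectory(p, seed = 3)
  fe <- simulate_latent_features(map, p$true_mech_params,
                                 feature_noise_sd = 0, seed = 4)
  pred <- mechanistic_predict(fe$hr, fe$pi, fe$nra, p$true_mech_params)
  expect_lt(max(abs(pred - map)), 1e-9)
  # observed == latent when noise is off
  expect_identical(fe$hr, fe$latent_hr)

  expect_error(
    simulate_latent_features(map, mechanistic_params(alpha = 0), 0, 1),
    "alpha")
})

test_that("feature noise of 1.0 yields ~1 mmHg of MAP-scale residual", {
  sds <- vapply(1:20, function(s) {
    p <- sim_params(seed = s)
    map <- simulate_map_trajectory(p, seed = s)
    fe <- simulate_latent_features(map, p$true_mech_params,
                                   feature_noise_sd = 1, seed = s + 100)
    stats::sd(map - mechanistic_predict(fe$hr, fe$pi, fe$nra,
                                        p$true_mech_params))
  }, numeric(1))
  expect_true(all(sds > 0.8 & sds < 1.2))
})

test_that("waveform synthesis encodes HR, PI and NRA per beat", {
  wv <- const_waveform(hr = 75, pi = 5, nra = 0.4, n = 60)
  # R-spike interval = 60/75 s within one sample
  spikes <- which(wv$ecg > 0.5)
  expect_true(all(abs(diff(spikes) - 0.8 * 125) <= 1))

  # per-beat PI measured directly on the template
  ft <- round(wv$beat_times * 125) + 1
  b1 <- wv$ppg[ft[10]:(ft[11] - 1)]
  pi_meas <- 100 * (max(b1) - min(b1)) / mean(b1)
  expect_lt(abs(pi_meas / 5 - 1), 0.05)

  # notch relative height on the falling edge
  pk <- which.max(b1)
  trough <- min(b1[pk:length(b1)][
    which(diff(sign(diff(b1[pk:length(b1)]))) == 2) + 1])
  nra_meas <- (trough - min(b1)) / (max(b1) - min(b1))
  expect_lt(abs(nra_meas - 0.40), 0.02)

  expect_error(synthesize_waveforms(c(60, 0), c(5, 5), c(0.4, 0.4)),
               "positive")
})

test_that("cuff synthesis: timing grid and exact values at sigma = 0", {
  map <- rep(90, 3600)
  cu <- synthesize_cuff(map, 300, 0, 0, seed = 1)
  expect_equal(nrow(cu), 13)           # t = 0, 300, ..., 3600
  expect_equal(cu$time_s, seq(0, 3600, 300))
  expect_equal(cu$map_mmHg, rep(90, 13))

  map2 <- simulate_map_trajectory(sim_params(seed = 8), seed = 8)
  cu2 <- synthesize_cuff(map2, 300, 0, 0, seed = 2)
  expect_equal(cu2$map_mmHg[2], map2[301])

  expect_error(synthesize_cuff(map, 0, 0, 3.1), "positive")
  expect_error(synthesize_cuff(map, 300, 0, -1), "non-negative")
})

test_that("generate_record enforces the one-hour minimum and is seed-sensitive", {
  expect_error(generate_record(sim_params(duration_s = 3599)), "3600")
  r1 <- full_record(21)$record
  r2 <- full_record(22)$record
  expect_false(identical(r1$ppg$value, r2$ppg$value))
  expect_length(r1$ppg$value, 450000)
  expect_length(r1$map_ref$value, 3600)
  # record passes its own container validation round
  expect_s3_class(r1, "physio_record")
})

test_that("artifact injection modifies only the requested window", {
  rec <- toy_record(seed = 31)$record
  expect_identical(inject_artifacts(rec, list()), rec)

  art <- list(list(type = "missing_run", channel = "map_ref",
                   start_s = 100, length_s = 50))
  rec2 <- inject_artifacts(rec, art)
  expect_true(all(rec2$map_ref$missing[101:150]))
  expect_identical(rec2$map_ref$value[-(101:150)],
                   rec$map_ref$value[-(101:150)])
  expect_identical(rec2$ppg, rec$ppg)

  expect_error(
    inject_artifacts(rec, list(list(type = "missing_run", channel = "hr",
                                    start_s = 580, length_s = 100))),
    "outside record")
})
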