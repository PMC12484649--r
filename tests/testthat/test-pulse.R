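test_that("pulse detection recovers beat count on clean synthetic signal", {
  wv <- const_waveform(hr = 72, pi = 5, nra = 0.4, n = 60)
  lm <- detect_pulses(wv$ppg)
  expect_lte(abs(nrow(lm) - length(wv$beat_times)), 1)
  expect_true(all(diff(lm$foot_time) > 0))
  expect_true(all(lm$foot_time < lm$peak_time))
  expect_true(all(lm$notch_time[lm$has_notch] > lm$peak_time[lm$has_notch]))
})

test_that("degenerate inputs yield empty landmark sets, not errors", {
  expect_equal(nrow(detect_pulses(rep(1, 1000))), 0)        # flatline
  expect_equal(nrow(detect_pulses(rep(NA_real_, 1000))), 0) # all missing
  expect_error(detect_pulses(rnorm(100)), "2 s")            # too short
})

test_that("HR, PI and NRA are recovered from clean waveforms", {
  wv <- const_waveform(hr = 75, pi = 5, nra = 0.4, n = 60)
  lm <- detect_pulses(wv$ppg)
  hr <- compute_hr(lm, 60)
  expect_true(all(abs(hr$value[!hr$missing] - 75) < 1))

  pi_ <- compute_pi(wv$ppg, lm, 60)
  expect_true(all(abs(pi_$value[!pi_$missing] / 5 - 1) < 0.05))

  nra <- compute_nra(wv$ppg, lm, 60)
  expect_true(all(abs(nra$value[!nra$missing] - 0.40) < 0.02))
})

test_that("HR tracks a ramp and stays within 2 bpm of the latent rate", {
  n <- 120
  hr_target <- seq(60, 90, length.out = n)
  wv <- synthesize_waveforms(hr_target, rep(5, n), rep(0.4, n), seed = 2)
  lm <- detect_pulses(wv$ppg)
  hr <- compute_hr(lm, n)
  ok <- !hr$missing
  frac <- mean(abs(hr$value[ok] - hr_target[ok]) < 2)
  expect_gt(frac, 0.95)
})

test_that("landmark-level feature definitions match their formulas", {
  lm <- structure(data.frame(
    foot_time = c(0, 1), peak_time = c(0.3, 1.3), notch_time = c(0.5, 1.5),
    foot_value = c(1, 1), peak_value = c(3, 3), notch_value = c(2, 1),
    has_notch = c(TRUE, TRUE), beat_end_time = c(1, NA)),
    class = c("pulse_landmarks", "data.frame"))
  nra <- compute_nra(NULL, lm, 3)
  expect_equal(nra$value[2], 0.5)   # notch midway between foot and peak
  expect_equal(nra$value[3], 0.0)   # notch at foot level

  # degenerate beat (peak == foot) is masked
  lm$peak_value <- c(1, 3)
  nra2 <- compute_nra(NULL, lm, 3)
  expect_true(nra2$missing[2])

  # single beat: no complete interval, HR fully masked
  hr1 <- compute_hr(lm[1, ], 10)
  expect_true(all(hr1$missing))
})

test_that("PI masks beats whose DC is not positive", {
  wv <- const_waveform(hr = 75, pi = 5, nra = 0.4, n = 10)
  lm <- detect_pulses(wv$ppg)
  pi_ <- compute_pi(wv$ppg - 2, lm, 10)  # negative baseline, DC < 0
  expect_true(all(pi_$missing))
})

test_that("masked waveform spans never produce fresh features", {
  rec <- toy_record(seed = 51)$record
  rec <- inject_artifacts(rec, list(
    list(type = "missing_run", channel = "ppg", start_s = 200, length_s = 60)))
  fs <- compute_features(rec)
  # staleness horizon: beyond 5 s into the gap every feature is masked
  expect_true(all(fs$hr$missing[206:260]))
  expect_true(all(fs$pi$missing[206:260]))
  expect_true(all(fs$nra$missing[206:260]))
})

test_that("features from clean records track the latent values closely", {
  g <- full_record(23)
  fs <- memo("features_23", compute_features(g$record))
  ok <- !fs$hr$missing
  expect_gt(mean(abs(fs$hr$value[ok] - g$truth$latent_hr[ok]) < 2), 0.95)
  rec2 <- g$record
  rec2$hr <- fs$hr; rec2$pi <- fs$pi; rec2$nra <- fs$nra
  mt <- mechanistic_track(rec2, params = g$truth$true_mech_params)
  e <- mt$pred - g$record$map_ref$value
  expect_lt(mean(abs(e[is.finite(e)])), 2)
})
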