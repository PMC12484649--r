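test_that("mechanistic formula evaluates pointwise and respects masks", {
  # alpha = 0 collapses to the intercept
  p0 <- mechanistic_params(alpha = 0, beta = 2, beta_prime = -1, delta = 42)
  expect_equal(mechanistic_predict(c(60, 120), c(1, 9), c(0.2, 0.8), p0),
               c(42, 42))

  # analytic construction: ln(1 + 1/PI) = 1 at PI = 1/(e - 1)
  p1 <- mechanistic_params(alpha = 1, beta = 0, beta_prime = 0, delta = 0)
  expect_equal(
    mechanistic_predict(120, 1 / (exp(1) - 1), 0.5, p1), 60, tolerance = 1e-12)

  # independent hand evaluation of the printed formula
  p2 <- mechanistic_params(alpha = 2, beta = 0.1, beta_prime = 0.2, delta = 10)
  by_hand <- 2 * (log(2) + 0.1) * (0.3 + 0.2) * 60 + 10
  expect_equal(mechanistic_predict(60, 1, 0.3, p2), by_hand)
  expect_equal(by_hand, 57.588, tolerance = 1e-3)

  # masked samples propagate, pi <= 0 masks
  out <- mechanistic_predict(c(60, NA, 60), c(1, 1, 0), c(0.3, 0.3, 0.3), p2)
  expect_true(is.na(out[2]) && is.na(out[3]))
  expect_false(is.na(out[1]))
})

test_that("a noise-free five-cuff calibration is near-interpolated", {
  g <- full_record(11, feature_noise_sd = 0, cuff_noise_sigma = 0)
  r <- g$record
  t5 <- r$cuff_events$time_s[1:5]
  idx <- pmin(t5, r$meta$duration_s - 1) + 1   # 1 Hz sample covering the cuff
  feats <- data.frame(hr = r$hr$value[idx], pi = r$pi$value[idx],
                      nra = r$nra$value[idx])
  f <- fit_mechanistic(feats, r$cuff_events$map_mmHg[1:5])
  expect_lt(max(abs(f$residuals)), 0.1)
  expect_equal(f$n, 5)
  expect_length(f$flags, 0)
})

test_that("degenerate and short calibration histories are handled", {
  const_feats <- data.frame(hr = rep(75, 5), pi = rep(5, 5), nra = rep(0.4, 5))
  f <- fit_mechanistic(const_feats, rep(80, 5))
  expect_true("degenerate_features" %in% f$flags)
  expect_equal(predict(f, const_feats), rep(80, 5))

  vary <- data.frame(hr = c(70, 75, 80), pi = c(4, 5, 6),
                     nra = c(0.35, 0.4, 0.45))
  f3 <- fit_mechanistic(vary, c(78, 80, 83))
  expect_equal(f3$n, 3)
  expect_true("short_history" %in% f3$flags)

  expect_error(fit_mechanistic(vary[0, ], numeric(0)), "no usable")
})

test_that("tracking with true parameters reproduces noise-free records", {
  for (s in c(5, 6)) {
    g <- full_record(s, feature_noise_sd = 0)
    mt <- mechanistic_track(g$record, params = g$truth$true_mech_params)
    e <- mt$pred - g$record$map_ref$value
    expect_lt(mean(abs(e[is.finite(e)])), 2)
  }
})

test_that("tracking is causal: future data never changes past predictions", {
  g <- full_record(9)
  r <- g$record
  mt1 <- mechanistic_track(r)
  # perturb everything after t = 3000 s (features and the final cuffs)
  r2 <- r
  sel <- 3001:3600
  r2$hr$value[sel] <- r2$hr$value[sel] + 10
  r2$nra$value[sel] <- pmin(0.9, r2$nra$value[sel] + 0.1)
  r2$cuff_events$map_mmHg[r2$cuff_events$time_s >= 3000] <- 100
  mt2 <- mechanistic_track(r2)
  expect_identical(mt1$pred[1:3000], mt2$pred[1:3000])
})

test_that("single-segment records produce one fit covering that segment", {
  rec <- toy_record(seed = 71, duration_s = 600, cuff_interval_s = 600)$record
  expect_equal(nrow(rec$cuff_events), 2)
  mt <- mechanistic_track(rec)
  expect_true(all(is.finite(mt$pred[1:600])))
  expect_equal(nrow(mt$fits), 1)
})
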