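test_that("configuration governs shape: fingerprint, parameters, padding", {
  c1 <- net_config(profile = "test")
  c2 <- net_config(profile = "test")
  expect_identical(config_fingerprint(c1), config_fingerprint(c2))
  expect_equal(count_params(build_network(c1, seed = 1)),
               count_params(build_network(c2, seed = 99)))

  # receptive field closed form and the per-layer dilation schedule
  expect_equal(receptive_field(net_config(n_conv_layers = 8)), 3571)
  m <- build_network(net_config(n_conv_layers = 4, conv_channels = 2), 1)
  dil <- vapply(m$weights$conv, function(l) l$dilation, numeric(1))
  expect_equal(dil, c(1, 2, 4, 8))
  # left pad per layer is (k - 1) * d: 112 samples at d = 8
  expect_equal((15 - 1) * dil[4], 112)

  expect_error(net_config(n_conv_layers = 0), ">= 1")
})

test_that("encoder emits one embedding step per second, causally", {
  m <- build_network(net_config(profile = "test"), seed = 3)
  n <- 20 * 125
  ppg <- rep(1, n); ecg <- rep(0, n)
  E0 <- encode_highfreq(m, ppg, ecg)
  expect_equal(dim(E0), c(m$config$conv_channels, 20))
  # constant input: bias-only response, constant embedding after the
  # receptive-field warm-up
  expect_lt(max(abs(E0[, 15] - E0[, 20])), 1e-10)

  # 5-minute window: 37500 samples -> 300 steps
  E5 <- encode_highfreq(m, rep(1, 37500), rep(0, 37500))
  expect_equal(ncol(E5), 300)

  # impulse at sample s only affects embeddings from second ceiling(s/125) on
  s <- 1500 + 60
  ppg2 <- ppg; ppg2[s] <- 5
  E1 <- encode_highfreq(m, ppg2, ecg)
  first_hit <- ceiling(s / 125)
  expect_identical(E1[, seq_len(first_hit - 1)], E0[, seq_len(first_hit - 1)])
  expect_gt(max(abs(E1[, first_hit] - E0[, first_hit])), 0)

  expect_warning(encode_highfreq(m, rep(1, 130), rep(0, 130)), "partial")
})

test_that("calibration state is the normalized cuff broadcast to all units", {
  cfg <- net_config(profile = "test")
  s80 <- init_calibration_state(80, cfg)
  expect_equal(s80$h0, rep(0, cfg$lstm_hidden))
  expect_equal(s80$c0, rep(0, cfg$lstm_hidden))
  s100 <- init_calibration_state(100, cfg)
  expect_equal(s100$h0, rep(1, cfg$lstm_hidden))
  expect_identical(init_calibration_state(80, cfg),
                   init_calibration_state(80, cfg))
  expect_error(init_calibration_state(10, cfg), "\\[20, 250\\]")

  # recalibration replaces the state and never touches weights
  m <- build_network(cfg, seed = 1)
  w_before <- m$weights
  expect_identical(recalibrate(s80, 80, cfg), init_calibration_state(80, cfg))
  expect_identical(m$weights, w_before)
})

test_that("segment prediction is deterministic, causal and shape-correct", {
  g <- full_record(21)
  segs <- segment_record(g$record)
  m <- build_network(net_config(profile = "test"), seed = 5)
  seg <- segs[[3]]

  p1 <- predict_segment(m, seg)
  p2 <- predict_segment(m, seg)
  expect_identical(p1$pred, p2$pred)
  expect_length(p1$pred, seg$end_s - seg$start_s)
  expect_true(all(is.finite(p1$pred)))

  # perturb the last 10 s of every input channel: first 280 s unchanged
  seg2 <- seg
  n1 <- length(seg2$hr$value)
  nw <- length(seg2$ppg$value)
  seg2$ppg$value[(nw - 10 * 125 + 1):nw] <- 0
  seg2$hr$value[(n1 - 9):n1] <- 120
  seg2$pi$value[(n1 - 9):n1] <- 1
  p3 <- predict_segment(m, seg2)
  expect_identical(p1$pred[1:290], p3$pred[1:290])
  expect_false(identical(p1$pred[291:300], p3$pred[291:300]))

  # streaming with per-cuff resets == independent per-segment prediction
  pr <- predict_record(m, g$record)
  expect_equal(pr[(seg$start_s + 1):seg$end_s], p1$pred)
})

test_that("patient splits are seeded, disjoint and exhaustive", {
  ids <- sprintf("p%03d", 1:100)
  sp <- split_patients(ids, seed = 1)
  expect_length(sp$test, 10)
  expect_length(sp$val, 9)
  expect_length(sp$train, 81)
  expect_identical(sp, split_patients(ids, seed = 1))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_error(split_patients(ids[1:9], seed = 1), "at least 10")
})
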