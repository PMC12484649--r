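make_rec_with_cuffs <- function(times, duration_s = 900) {
  n <- duration_s
  physio_record("seg-test",
                ppg = rep(1, 125 * n), ecg = rep(0, 125 * n),
                hr = rep(75, n), pi = rep(5, n), nra = rep(0.4, n),
                map_ref = rep(80, n),
                cuff_events = data.frame(time_s = times,
                                         map_mmHg = rep(80, length(times))),
                duration_s = n)
}

test_that("segmentation cuts half-open inter-cuff windows", {
  segs <- segment_record(make_rec_with_cuffs(c(0, 300, 600)))
  expect_length(segs, 2)
  expect_equal(segs[[1]]$start_s, 0)
  expect_equal(segs[[1]]$end_s, 300)
  expect_length(segs[[1]]$map_ref$value, 300)
  expect_length(segs[[1]]$ppg$value, 300 * 125)
  expect_equal(segs[[2]]$opening_cuff$time_s, 300)

  segs12 <- segment_record(full_record(21)$record)
  expect_length(segs12, 12)

  expect_warning(out <- segment_record(make_rec_with_cuffs(0)), "fewer than 2")
  expect_length(out, 0)

  # partition property: contiguous, disjoint tiling of [first, last)
  starts <- vapply(segs12, function(s) s$start_s, numeric(1))
  ends <- vapply(segs12, function(s) s$end_s, numeric(1))
  expect_equal(starts[-1], ends[-length(ends)])
  expect_equal(min(starts), 0)
  expect_equal(max(ends), 3600)
})

test_that("quality metrics compute the documented statistics", {
  seg <- segment_record(make_rec_with_cuffs(c(0, 300)))[[1]]
  m <- compute_quality_metrics(seg)
  expect_equal(m$map_mean, 80)
  expect_equal(m$map_dispersion, 0)
  expect_equal(m$map_sd, 0)
  expect_equal(m$map_gradient, 0)
  expect_equal(m$pi_unique, 1L)

  # ramp 80 -> 110 over 300 s: max gradient = 0.1 mmHg/s
  rec <- make_rec_with_cuffs(c(0, 300), duration_s = 300)
  rec$map_ref$value <- seq(80, 110, length.out = 300)
  m2 <- compute_quality_metrics(segment_record(rec)[[1]])
  expect_equal(m2$map_gradient, 30 / 299, tolerance = 1e-6)

  # 30% missing run measured as a proportion
  rec3 <- toy_record(seed = 61)$record
  rec3 <- inject_artifacts(rec3, list(
    list(type = "missing_run", channel = "map_ref", start_s = 0,
         length_s = 36)))
  m3 <- compute_quality_metrics(segment_record(rec3)[[1]])
  expect_equal(m3$map_missing, 0.30, tolerance = 0.01)
})

test_that("filtering requires all nine criteria and reports every failure", {
  rec <- toy_record(seed = 63)$record
  base <- filter_segments(segment_record(rec))
  expect_true(all(vapply(base$reports, function(r) r$overall, logical(1))))

  # shift the whole first segment's MAP up: mean criterion alone fails
  rec_mean <- inject_artifacts(rec, list(
    list(type = "level_shift", channel = "map_ref", start_s = 0,
         length_s = 120, magnitude = 90)))
  rep1 <- filter_segments(segment_record(rec_mean))$reports[[1]]
  expect_false(rep1$overall)
  expect_identical(rep1$reasons, "map_mean")

  # flatline: sd criterion fails (dispersion/gradient pass at < thresholds)
  rec_sd <- inject_artifacts(rec, list(
    list(type = "flatline", channel = "map_ref", start_s = 0, length_s = 120)))
  rep2 <- filter_segments(segment_record(rec_sd))$reports[[1]]
  expect_true("map_sd" %in% rep2$reasons)

  # three distinct PI values
  seg <- segment_record(rec)[[1]]
  seg$pi$value <- rep(c(4, 5, 6), length.out = length(seg$pi$value))
  rep3 <- filter_segments(list(seg))$reports[[1]]
  expect_identical(rep3$reasons, "pi_unique")

  # two simultaneous defects: both reasons listed
  rec_two <- inject_artifacts(rec, list(
    list(type = "level_shift", channel = "map_ref", start_s = 0,
         length_s = 120, magnitude = 90),
    list(type = "missing_run", channel = "hr", start_s = 0, length_s = 40)))
  rep4 <- filter_segments(segment_record(rec_two))$reports[[1]]
  expect_setequal(rep4$reasons, c("map_mean", "hr_missing"))
})

test_that("inference mode skips reference-MAP criteria with a flag", {
  rec <- toy_record(seed = 63)$record
  rec <- inject_artifacts(rec, list(
    list(type = "flatline", channel = "map_ref", start_s = 0, length_s = 120)))
  res <- filter_segments(segment_record(rec), use_reference = FALSE)
  rep1 <- res$reports[[1]]
  expect_true(rep1$overall)
  expect_true("map_sd" %in% rep1$skipped)
})

test_that("thresholds follow the printed directions exactly", {
  crit <- filter_criteria()
  ev <- asNamespace("anesthnet")$.evaluate_criteria
  m <- list(map_mean = 80, map_dispersion = 10, map_gradient = 0.5,
            map_sd = 5, map_missing = 0, pi_missing = 0, pi_unique = 100,
            hr_missing = 0, ppg_missing = 0)
  expect_true(all(ev(m, crit)$pass))
  # boundary cases: sd must be strictly greater than 1, mean strictly inside
  m$map_sd <- 1
  expect_false(ev(m, crit)$pass[["map_sd"]])
  m$map_sd <- 5; m$map_mean <- 150
  expect_false(ev(m, crit)$pass[["map_mean"]])
  m$map_mean <- 80; m$pi_unique <- 5
  expect_false(ev(m, crit)$pass[["pi_unique"]])
})
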