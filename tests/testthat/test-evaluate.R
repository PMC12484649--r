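test_that("error summaries follow their definitions and fixed conventions", {
  ref <- c(80, 85, 90, 95)
  s0 <- compute_errors(ref, ref)
  expect_equal(c(s0$me, s0$mae, s0$sd_error), c(0, 0, 0))

  s3 <- compute_errors(ref + 3, ref)
  expect_equal(c(s3$me, s3$mae, s3$sd_error), c(3, 3, 0))

  # population-sd convention: errors {+2, -2} give sd exactly 2
  s2 <- compute_errors(c(82, 78), c(80, 80))
  expect_equal(c(s2$me, s2$mae, s2$sd_error), c(0, 2, 2))

  # masks: NA pairs are dropped; all-NA rejected
  sm <- compute_errors(c(81, NA, 83), c(80, 80, NA))
  expect_equal(sm$n_samples, 1)
  expect_error(compute_errors(c(NA, NA), c(1, 2)), "no overlapping")
})

test_that("metric identities hold on random inputs", {
  for (s in 1:20) {
    set.seed(s)
    ref <- rnorm(50, 80, 10)
    pred <- ref + rnorm(50, 1, 4)
    es <- compute_errors(pred, ref)
    expect_gte(es$mae, abs(es$me))
    shifted <- compute_errors(pred + 2.5, ref)
    expect_equal(shifted$me, es$me + 2.5)
    expect_equal(shifted$sd_error, es$sd_error)
  }
})

test_that("cumulative error percentages count thresholds inclusively", {
  expect_equal(unname(cumulative_error_pct(c(1, 4, 6, 12, 20))),
               c(40, 60, 80))
  expect_equal(unname(cumulative_error_pct(rep(0, 5))), c(100, 100, 100))
  expect_equal(unname(cumulative_error_pct(rep(50, 5))), c(0, 0, 0))
  p <- cumulative_error_pct(abs(rnorm(100, 0, 8)))
  expect_true(p[1] <= p[2] && p[2] <= p[3])
})

test_that("BHS grading reproduces its worked examples exactly", {
  expect_equal(bhs_grade(c(65.7, 88.3, 96.1)), "A")
  expect_equal(bhs_grade(c(57.7, 83.5, 93.4)), "B")
  expect_equal(bhs_grade(c(40.8, 70.1, 86.3)), "C")
  expect_equal(bhs_grade(c(31.8, 59.2, 79.4)), "below_C")
  # boundary: all three thresholds must be met simultaneously
  expect_equal(bhs_grade(c(60, 85, 95)), "A")
  expect_equal(bhs_grade(c(60, 84.9, 95)), "B")
})

test_that("raising any cumulative percentage never lowers the BHS grade", {
  rank <- c(below_C = 0, C = 1, B = 2, A = 3)
  set.seed(7)
  for (i in 1:50) {
    p <- sort(runif(3, 20, 100))
    g0 <- rank[[bhs_grade(p)]]
    j <- sample(3, 1)
    p2 <- p
    p2[j:3] <- pmin(100, p2[j:3] + runif(1, 0, 15))
    expect_gte(rank[[bhs_grade(p2)]], g0)
  }
})

test_that("AAMI verdicts use inclusive bounds and subject-count floor", {
  expect_true(aami_check(list(me = 0.3, sd_error = 6.3), 284)$pass)
  v <- aami_check(list(me = 5.1, sd_error = 6.0), 100)
  expect_false(v$pass)
  expect_false(v$me_ok)
  expect_true(v$sd_ok && v$n_ok)
  expect_true(aami_check(list(me = 0, sd_error = 8.0), 85)$pass)
  expect_false(aami_check(list(me = 0, sd_error = 8.0), 84)$pass)
})

test_that("per-patient aggregation pools within, then averages across", {
  one <- data.frame(patient_id = "a", error = c(2, -2, 4))
  agg1 <- aggregate_per_patient(one)
  expect_equal(agg1$study$mae, mean(abs(one$error)))
  expect_equal(agg1$study$n_patients, 1)

  two <- rbind(data.frame(patient_id = "a", error = c(2, 2)),
               data.frame(patient_id = "b", error = c(4, -4)))
  agg2 <- aggregate_per_patient(two)
  expect_equal(agg2$study$mae, 3)

  # order invariance
  perm <- two[c(3, 1, 4, 2), ]
  expect_equal(aggregate_per_patient(perm)$per_patient, agg2$per_patient)
})

test_that("the sweep recovers a perfect predictor and degrades carry-forward", {
  # oracle stub with noise-free cuffs: zero error at every interval
  oracle <- function(rec) rec$map_ref$value
  sw0 <- calibration_sweep(oracle, intervals = c(180, 300),
                           base_params = sim_params(cuff_noise_sigma = 0),
                           seeds = 1)
  expect_equal(sw0$table$mae, c(0, 0))
  expect_equal(sw0$table$bhs_grade, c("A", "A"))

  # the cuff-hold baseline loses accuracy as the calibration interval grows
  sw <- calibration_sweep(carry_forward_track, seeds = 1:20)
  expect_equal(sw$table$interval_s, c(180, 300, 600))
  expect_true(all(diff(sw$table$mae) > 0))
})

test_that("the latency harness times batches and rejects empty input", {
  g <- full_record(21)
  segs <- segment_record(g$record)
  sleepy <- function(seg) Sys.sleep(0.004)
  batches <- rep(list(segs[1:2]), 15)
  rep_ <- latency_benchmark(sleepy, batches)
  expect_equal(rep_$n_batches, 15)
  expect_length(rep_$batch_ms, 15)
  expect_lt(abs(rep_$batch_ms_mean / 8 - 1), 0.2)  # 2 x 4 ms per batch
  expect_error(latency_benchmark(sleepy, list()), "no batches")
})
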