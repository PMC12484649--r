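#' Error summary of predictions against the arterial reference
#'
#' Signed error is `prediction - reference` on samples where both are
#' unmasked and finite. Reports mean error (ME), mean absolute error (MAE),
#' the standard deviation of the signed error and of the absolute error.
#' Dispersion uses the population convention (divide by n), fixed throughout
#' the package.
#'
#' @param predictions,reference aligned 1 Hz numeric vectors (`NA` = masked).
#' @return object of class `error_summary`: `me`, `mae`, `sd_error`,
#'   `mae_sd`, `n_samples`.
#' @export
compute_errors <- function(predictions, reference) {
  stopifnot(length(predictions) == length(reference))
  e <- predictions - reference
  e <- e[is.finite(e)]
  if (!length(e)) stop("no overlapping unmasked samples")
  structure(list(me = mean(e), mae = mean(abs(e)), sd_error = sd_pop(e),
                 mae_sd = sd_pop(abs(e)), n_samples = length(e)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("ME %.2f (+/- %.2f) mmHg | MAE %.2f (+/- %.2f) mmHg | n=%d\n",
              x$me, x$sd_error, x$mae, x$mae_sd, x$n_samples))
  invisible(x)
}

#' Cumulative error percentages at 5/10/15 mmHg
#'
#' Percentage of absolute errors at or below each threshold; monotone
#' non-decreasing across thresholds by construction.
#'
#' @param abs_errors non-empty numeric vector of absolute errors, mmHg.
#' @param thresholds thresholds in mmHg (default 5, 10, 15).
#' @return named numeric vector of percentages (`pct_le_5` etc.).
#' @export
cumulative_error_pct <- function(abs_errors, thresholds = c(5, 10, 15)) {
  abs_errors <- abs_errors[is.finite(abs_errors)]
  if (!length(abs_errors)) stop("no errors supplied")
  out <- vapply(thresholds, function(th) 100 * mean(abs_errors <= th),
                numeric(1))
  names(out) <- paste0("pct_le_", thresholds)
  out
}

# BHS band thresholds: percentage of |error| <= 5 / 10 / 15 mmHg required
.bhs_bands <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))

#' British Hypertension Society grade from cumulative percentages
#'
#' Grade A requires at least 60 / 85 / 95 % of absolute errors within
#' 5 / 10 / 15 mmHg; grade B 50 / 75 / 90; grade C 40 / 65 / 85. The grade is
#' the best one whose all three band thresholds are met; otherwise
#' `"below_C"`.
#'
#' @param pcts numeric length-3 vector (pct <= 5, <= 10, <= 15 mmHg), e.g.
#'   from [cumulative_error_pct()].
#' @return character scalar: `"A"`, `"B"`, `"C"` or `"below_C"`.
#' @export
bhs_grade <- function(pcts) {
  pcts <- as.numeric(pcts)
  stopifnot(length(pcts) == 3, all(is.finite(pcts)))
  for (g in c("A", "B", "C")) {
    if (all(pcts >= .bhs_bands[[g]])) return(g)
  }
  "below_C"
}

#' AAMI standard verdict
#'
#' Pass requires |ME| <= 5 mmHg, error SD <= 8 mmHg and at least 85 test
#' subjects (inclusive bounds). Component verdicts are reported separately.
#'
#' @param summary an [compute_errors()] `error_summary` (or any list with
#'   `me` and `sd_error`).
#' @param n_subjects number of test subjects.
#' @return list with `pass` and component flags `me_ok`, `sd_ok`, `n_ok`.
#' @export
aami_check <- function(summary, n_subjects) {
  me_ok <- is.finite(summary$me) && abs(summary$me) <= 5
  sd_ok <- is.finite(summary$sd_error) && summary$sd_error <= 8
  n_ok <- n_subjects >= 85
  list(pass = me_ok && sd_ok && n_ok, me_ok = me_ok, sd_ok = sd_ok,
       n_ok = n_ok)
}

#' Aggregate per-segment errors into a per-patient study table
#'
#' Errors are pooled within each patient, per-patient summaries (ME, MAE,
#' error SD, cumulative percentages) are computed, and the study row reports
#' the across-patient mean (with across-patient SD). Patients contributing
#' zero samples are excluded. The table is invariant to input row order.
#'
#' @param results data.frame with columns `patient_id` and `error` (one row
#'   per 1 Hz sample; signed error in mmHg).
#' @return list with `per_patient` (one row per patient) and `study` (one
#'   row: across-patient mean and sd of each metric, plus the BHS grade of
#'   the pooled errors and an [aami_check()] on the across-patient summary).
#' @export
aggregate_per_patient <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("patient_id", "error") %in% names(results)))
  results <- results[is.finite(results$error), , drop = FALSE]
  if (!nrow(results)) stop("no finite errors to aggregate")
  ids <- sort(unique(results$patient_id))
  rows <- lapply(ids, function(id) {
    e <- results$error[results$patient_id == id]
    pct <- cumulative_error_pct(abs(e))
    data.frame(patient_id = id, n = length(e), me = mean(e),
               mae = mean(abs(e)), sd_error = sd_pop(e),
               pct_le_5 = pct[[1]], pct_le_10 = pct[[2]],
               pct_le_15 = pct[[3]])
  })
  per_patient <- do.call(rbind, rows)
  pooled_pct <- cumulative_error_pct(abs(results$error))
  study <- data.frame(
    n_patients = nrow(per_patient),
    me = mean(per_patient$me), me_sd = sd_pop(per_patient$me),
    mae = mean(per_patient$mae), mae_sd = sd_pop(per_patient$mae),
    sd_error = mean(per_patient$sd_error),
    pct_le_5 = mean(per_patient$pct_le_5),
    pct_le_10 = mean(per_patient$pct_le_10),
    pct_le_15 = mean(per_patient$pct_le_15),
    bhs_grade = bhs_grade(pooled_pct))
  aami <- aami_check(list(me = study$me, sd_error = study$sd_error),
                     study$n_patients)
  list(per_patient = per_patient, study = study, aami = aami)
}

#' Sweep performance over cuff calibration intervals
#'
#' Regenerates synthetic records at each cuff interval (3/5/10 minutes by
#' default), runs a record-level predictor, and reports ME/MAE/SD, cumulative
#' percentages and the BHS grade per interval, plus a per-seed MAE table for
#' paired comparisons.
#'
#' @param predict_fun function(record) returning a 1 Hz prediction vector
#'   aligned to the record (e.g. `function(r) predict_record(model, r)` or
#'   [carry_forward_track()]).
#' @param intervals cuff intervals in seconds.
#' @param base_params a [sim_params()]; its `cuff_interval_s` and `seed` are
#'   overridden per run.
#' @param seeds integer vector; one record is generated per seed and
#'   interval (same seeds across intervals, so MAP trajectories are paired).
#' @param cohort optional list of [sim_params()] (e.g. from
#'   [cohort_params()]) used instead of `base_params`/`seeds`; each entry is
#'   re-run at every interval, pairing patients across intervals.
#' @return list with `table` (one row per interval) and `per_seed`
#'   (interval x seed MAE rows; `seed` indexes the cohort entry when a
#'   cohort is supplied).
#' @export
calibration_sweep <- function(predict_fun, intervals = c(180, 300, 600),
                              base_params = sim_params(), seeds = 1:10,
                              cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- lapply(seeds, function(s) {
      p <- base_params
      p$seed <- as.integer(s)
      p
    })
  } else {
    seeds <- seq_along(cohort)
  }
  rows <- list()
  per_seed <- list()
  for (iv in intervals) {
    pooled <- numeric(0)
    for (ci in seq_along(cohort)) {
      sd_i <- seeds[ci]
      pars <- cohort[[ci]]
      pars$cuff_interval_s <- as.integer(iv)
      rec <- generate_record(pars)$record
      pred <- predict_fun(rec)
      e <- pred - rec$map_ref$value
      e <- e[is.finite(e)]
      pooled <- c(pooled, e)
      per_seed[[length(per_seed) + 1L]] <-
        data.frame(interval_s = iv, seed = sd_i, mae = mean(abs(e)))
    }
    pct <- cumulative_error_pct(abs(pooled))
    rows[[length(rows) + 1L]] <- data.frame(
      interval_s = iv, me = mean(pooled), mae = mean(abs(pooled)),
      sd_error = sd_pop(pooled), pct_le_5 = pct[[1]], pct_le_10 = pct[[2]],
      pct_le_15 = pct[[3]], bhs_grade = bhs_grade(pct))
  }
  list(table = do.call(rbind, rows), per_seed = do.call(rbind, per_seed))
}

#' Inference latency harness
#'
#' Wall-clock timing of a segment-level predictor over batches of segments:
#' per-batch mean and sd, and per-sample time (batch time divided by the
#' number of 1 Hz samples in the batch). Reporting only; latency is
#' hardware-dependent and never an acceptance surface.
#'
#' @param predict_fun function(segment) performing one inference.
#' @param batches non-empty list of batches, each a list of `map_segment`s
#'   (15 batches is the conventional count; fewer triggers a warning).
#' @return list of class `latency_report`: `n_batches`, `batch_ms_mean`,
#'   `batch_ms_sd`, `per_sample_ms_mean`, `batch_ms` (raw measurements).
#' @export
latency_benchmark <- function(predict_fun, batches) {
  if (length(batches) == 0) stop("no batches supplied")
  if (length(batches) < 15) {
    warning("fewer than 15 batches: latency summary will be unstable")
  }
  batch_ms <- numeric(length(batches))
  per_sample <- numeric(length(batches))
  for (i in seq_along(batches)) {
    n_samp <- sum(vapply(batches[[i]],
                         function(s) s$end_s - s$start_s, numeric(1)))
    t0 <- proc.time()[["elapsed"]]
    for (s in batches[[i]]) predict_fun(s)
    dt <- (proc.time()[["elapsed"]] - t0) * 1000
    batch_ms[i] <- dt
    per_sample[i] <- dt / max(1, n_samp)
  }
  structure(list(n_batches = length(batches),
                 batch_ms_mean = mean(batch_ms),
                 batch_ms_sd = sd_pop(batch_ms),
                 per_sample_ms_mean = mean(per_sample),
                 batch_ms = batch_ms), class = "latency_report")
}

#' @export
print.latency_report <- function(x, ...) {
  cat(sprintf("latency over %d batches: %.2f (+/- %.2f) ms/batch, %.4f ms/sample\n",
              x$n_batches, x$batch_ms_mean, x$batch_ms_sd,
              x$per_sample_ms_mean))
  invisible(x)
}
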