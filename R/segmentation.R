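#' Quality-filter thresholds for inter-cuff segments
#'
#' The nine acceptance criteria applied to every inter-cuff segment, with
#' thresholds fixed to the values used throughout the package. Directions are
#' exact (strict where stated): a segment passes iff
#' 50 < MAP mean < 150 mmHg; MAP dispersion (range, max - min) < 40 mmHg;
#' max MAP gradient < 2 mmHg/s; MAP sd > 1 mmHg; MAP missing < 20%;
#' PI missing < 20%; distinct unmasked PI values > 5; HR missing < 20%;
#' PPG missing < 1%.
#'
#' @param map_mean_low,map_mean_high bounds on segment MAP mean, mmHg.
#' @param map_dispersion_max max MAP range within segment, mmHg.
#' @param map_gradient_max max absolute 1 Hz first difference, mmHg/s.
#' @param map_sd_min minimum MAP standard deviation, mmHg.
#' @param map_missing_max,pi_missing_max,hr_missing_max,ppg_missing_max
#'   maximum missing proportions per channel.
#' @param pi_unique_min minimum count of distinct unmasked PI values.
#' @return an object of class `filter_criteria`.
#' @export
filter_criteria <- function(map_mean_low = 50, map_mean_high = 150,
                            map_dispersion_max = 40, map_gradient_max = 2,
                            map_sd_min = 1, map_missing_max = 0.20,
                            pi_missing_max = 0.20, pi_unique_min = 5,
                            hr_missing_max = 0.20, ppg_missing_max = 0.01) {
  structure(list(
    map_mean_low = map_mean_low, map_mean_high = map_mean_high,
    map_dispersion_max = map_dispersion_max,
    map_gradient_max = map_gradient_max, map_sd_min = map_sd_min,
    map_missing_max = map_missing_max, pi_missing_max = pi_missing_max,
    pi_unique_min = pi_unique_min, hr_missing_max = hr_missing_max,
    ppg_missing_max = ppg_missing_max), class = "filter_criteria")
}

.criterion_names <- c("map_mean", "map_dispersion", "map_gradient", "map_sd",
                      "map_missing", "pi_missing", "pi_unique", "hr_missing",
                      "ppg_missing")

#' Cut a record into inter-cuff segments
#'
#' One segment per consecutive cuff pair, half-open `[cuff_i, cuff_{i+1})`,
#' carrying the opening cuff as calibration; trailing data after the last
#' cuff is discarded, and segments shorter than `min_segment_s` (irregular
#' cuff timing) are dropped. With fewer than two cuff events an empty list is
#' returned with a warning.
#'
#' @param record a [physio_record()].
#' @param min_segment_s minimum retained segment length, seconds.
#' @return list of `map_segment` objects (each with `patient_id`, `start_s`,
#'   `end_s`, `opening_cuff`, and channel slices `ppg`, `ecg`, `hr`, `pi`,
#'   `nra`, `map_ref`).
#' @export
segment_record <- function(record, min_segment_s = 60) {
  stopifnot(inherits(record, "physio_record"))
  cuffs <- record$cuff_events
  if (nrow(cuffs) < 2L) {
    warning("fewer than 2 cuff events: no segments")
    return(list())
  }
  dur <- record$meta$duration_s
  fs <- record$meta$fs_wave
  segs <- list()
  for (i in seq_len(nrow(cuffs) - 1L)) {
    start <- as.integer(cuffs$time_s[i])
    end <- min(as.integer(cuffs$time_s[i + 1L]), dur)
    if (end - start < min_segment_s) next
    lo1 <- start + 1L; hi1 <- end
    low <- start * fs + 1L; hiw <- end * fs
    slice <- function(ch, a, b) list(value = ch$value[a:b],
                                     missing = ch$missing[a:b])
    segs[[length(segs) + 1L]] <- structure(list(
      patient_id = record$patient_id, start_s = start, end_s = end,
      opening_cuff = list(time_s = cuffs$time_s[i],
                          map_mmHg = cuffs$map_mmHg[i]),
      ppg = slice(record$ppg, low, hiw), ecg = slice(record$ecg, low, hiw),
      hr = slice(record$hr, lo1, hi1), pi = slice(record$pi, lo1, hi1),
      nra = slice(record$nra, lo1, hi1),
      map_ref = slice(record$map_ref, lo1, hi1),
      fs_wave = fs), class = "map_segment")
  }
  segs
}

#' @export
print.map_segment <- function(x, ...) {
  cat(sprintf("<map_segment %s [%d, %d) s> opening cuff %.1f mmHg\n",
              x$patient_id, x$start_s, x$end_s, x$opening_cuff$map_mmHg))
  invisible(x)
}

#' Compute segment quality metrics
#'
#' Values only (no pass/fail): MAP mean, dispersion (range, max - min),
#' maximum absolute 1 Hz gradient, standard deviation, missing proportions
#' for MAP/PI/HR/PPG and the count of distinct unmasked PI values. MAP
#' statistics are computed on unmasked samples; a fully masked MAP yields
#' missing proportion 1 and `NA` (failing) statistics. Gradients spanning a
#' masked sample are excluded.
#'
#' @param segment a `map_segment`.
#' @return named list of class `quality_metrics`.
#' @export
compute_quality_metrics <- function(segment) {
  stopifnot(inherits(segment, "map_segment"))
  mv <- segment$map_ref$value
  mv[segment$map_ref$missing] <- NA_real_
  m_ok <- mv[!is.na(mv)]
  grads <- abs(diff(mv))
  pi_ok <- segment$pi$value[!segment$pi$missing]
  pi_ok <- pi_ok[!is.na(pi_ok)]
  structure(list(
    map_mean = if (length(m_ok)) mean(m_ok) else NA_real_,
    map_dispersion = if (length(m_ok)) diff(range(m_ok)) else NA_real_,
    map_gradient = if (any(!is.na(grads))) max(grads, na.rm = TRUE) else NA_real_,
    map_sd = if (length(m_ok) > 1) stats::sd(m_ok) else NA_real_,
    map_missing = mean(segment$map_ref$missing | is.na(segment$map_ref$value)),
    pi_missing = mean(segment$pi$missing | is.na(segment$pi$value)),
    pi_unique = length(unique(pi_ok)),
    hr_missing = mean(segment$hr$missing | is.na(segment$hr$value)),
    ppg_missing = mean(segment$ppg$missing | is.na(segment$ppg$value))
  ), class = "quality_metrics")
}

# evaluate the nine criteria on a metrics list; NA metrics fail
.evaluate_criteria <- function(m, criteria, use_reference = TRUE) {
  chk <- function(x) !is.na(x) && x
  pass <- c(
    map_mean = chk(m$map_mean > criteria$map_mean_low &&
                     m$map_mean < criteria$map_mean_high),
    map_dispersion = chk(m$map_dispersion < criteria$map_dispersion_max),
    map_gradient = chk(m$map_gradient < criteria$map_gradient_max),
    map_sd = chk(m$map_sd > criteria$map_sd_min),
    map_missing = chk(m$map_missing < criteria$map_missing_max),
    pi_missing = chk(m$pi_missing < criteria$pi_missing_max),
    pi_unique = chk(m$pi_unique > criteria$pi_unique_min),
    hr_missing = chk(m$hr_missing < criteria$hr_missing_max),
    ppg_missing = chk(m$ppg_missing < criteria$ppg_missing_max))
  skipped <- character(0)
  if (!use_reference) {
    # pure inference: the arterial reference is unavailable, MAP-based
    # criteria cannot be evaluated and are skipped with a flag
    skipped <- c("map_mean", "map_dispersion", "map_gradient", "map_sd",
                 "map_missing")
    pass[skipped] <- TRUE
  }
  list(pass = pass, skipped = skipped)
}

#' Apply the nine-criterion quality filter to segments
#'
#' A segment is accepted iff all nine criteria pass; rejected segments carry
#' the complete list of failed criteria (never just the first). With
#' `use_reference = FALSE` (pure inference time, no arterial line) the five
#' MAP-based criteria are skipped and flagged in each report.
#'
#' @param segments list of `map_segment` objects.
#' @param criteria a [filter_criteria()] object.
#' @param use_reference whether reference-MAP criteria are evaluated.
#' @return list with `accepted`, `rejected` (lists of segments), `reports`
#'   (per-segment `quality_report`: metrics, per-criterion pass flags,
#'   overall flag, reasons, skipped), and `table` (one summary row per
#'   segment).
#' @export
filter_segments <- function(segments, criteria = filter_criteria(),
                            use_reference = TRUE) {
  reports <- vector("list", length(segments))
  ok <- logical(length(segments))
  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    m <- compute_quality_metrics(segments[[i]])
    ev <- .evaluate_criteria(m, criteria, use_reference)
    reasons <- names(ev$pass)[!ev$pass]
    reports[[i]] <- structure(
      list(metrics = m, pass = ev$pass, overall = all(ev$pass),
           reasons = reasons, skipped = ev$skipped),
      class = "quality_report")
    ok[i] <- all(ev$pass)
    rows[[i]] <- data.frame(
      patient_id = segments[[i]]$patient_id,
      start_s = segments[[i]]$start_s, end_s = segments[[i]]$end_s,
      accepted = ok[i],
      reasons = paste(reasons, collapse = ";"))
  }
  list(accepted = segments[ok], rejected = segments[!ok],
       reports = reports,
       table = if (length(rows)) do.call(rbind, rows) else data.frame())
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s\n",
              if (x$overall) "ACCEPTED" else
                paste("REJECTED:", paste(x$reasons, collapse = ", "))))
  for (nm in names(x$pass)) {
    cat(sprintf("  %-15s %-6s (%.4g)\n", nm,
                ifelse(x$pass[[nm]], "pass", "FAIL"),
                as.numeric(x$metrics[[nm]] %||% NA)))
  }
  if (length(x$skipped)) {
    cat("  skipped (no reference):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
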