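# local-extremum search used by the pulse detector; returns indices of maxima
# at least `min_dist` samples apart whose prominence (height above the higher
# of the two flanking minima gaps) exceeds `min_prom`
.find_peaks <- function(x, min_dist, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # candidate maxima: rising before, falling after (plateaus take last index)
  cand <- which(d[-1] < 0 & d[-(n - 1)] >= 0) + 1L
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  taken <- rep(FALSE, n)
  for (i in ord) {
    lo <- max(1L, i - min_dist); hi <- min(n, i + min_dist)
    if (!any(taken[lo:hi])) {
      keep[i] <- TRUE
      taken[i] <- TRUE
    }
  }
  peaks <- sort(which(keep))
  if (!length(peaks)) return(integer(0))
  # prominence relative to neighbouring peaks' valleys
  prom <- vapply(seq_along(peaks), function(j) {
    i <- peaks[j]
    lo <- if (j == 1L) 1L else peaks[j - 1L]
    hi <- if (j == length(peaks)) n else peaks[j + 1L]
    min(x[i] - min(x[lo:i]), x[i] - min(x[i:hi]))
  }, numeric(1))
  peaks[prom >= min_prom]
}

#' Detect pulse landmarks on a PPG waveform
#'
#' Per-beat landmark detection: feet as the local minima preceding each
#' systolic upstroke, peaks as the per-beat maximum, and the dicrotic notch
#' as the most prominent interior local minimum of the falling edge between a
#' peak and the next foot. Beats with no detectable notch are flagged. Runs
#' of missing samples split the signal; detection happens independently per
#' contiguous run. Flat or all-missing input yields an empty landmark set,
#' not an error.
#'
#' @param ppg numeric PPG vector at 125 Hz (`NA` where missing) or a record
#'   channel `list(value, missing)`.
#' @param fs sampling rate, Hz (default 125).
#' @return data.frame of class `pulse_landmarks` with per-beat columns
#'   `foot_time`, `peak_time`, `notch_time` (s), `foot_value`, `peak_value`,
#'   `notch_value`, `has_notch`, and `beat_end_time` (time of the next foot,
#'   `NA` for the final, incomplete beat).
#' @export
detect_pulses <- function(ppg, fs = 125) {
  fs <- as.integer(fs)
  if (is.list(ppg)) {
    v <- ppg$value
    v[ppg$missing] <- NA_real_
  } else {
    v <- as.numeric(ppg)
  }
  if (length(v) < 2 * fs) stop("need at least 2 s of signal")
  empty <- data.frame(foot_time = numeric(0), peak_time = numeric(0),
                      notch_time = numeric(0), foot_value = numeric(0),
                      peak_value = numeric(0), notch_value = numeric(0),
                      has_notch = logical(0), beat_end_time = numeric(0))
  ok <- !is.na(v)
  if (!any(ok)) return(structure(empty, class = c("pulse_landmarks", "data.frame")))
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in which(runs$values & runs$lengths >= 2 * fs)) {
    i0 <- starts[r]
    x <- v[i0:ends[r]]
    rng <- diff(range(x))
    if (rng <= 0) next
    peaks <- .find_peaks(x, min_dist = round(0.33 * fs), min_prom = 0.25 * rng)
    if (length(peaks) < 1) next
    # foot: last minimum between the previous peak (or up to 2 s back) and peak
    feet <- vapply(seq_along(peaks), function(j) {
      lo <- if (j == 1L) max(1L, peaks[1] - 2L * fs) else peaks[j - 1L]
      seg <- x[lo:peaks[j]]
      lo + max(which(seg == min(seg))) - 1L
    }, integer(1))
    n_b <- length(peaks)
    notch_i <- rep(NA_integer_, n_b)
    for (j in seq_len(n_b)) {
      hi <- if (j < n_b) feet[j + 1L] else length(x)
      if (hi - peaks[j] < 3) next
      seg <- x[peaks[j]:hi]
      m <- length(seg)
      d <- diff(seg)
      cands <- which(d[-1] > 0 & d[-(m - 1)] <= 0) + 1L
      cands <- cands[cands > 1 & cands < m]
      if (!length(cands)) next
      amp <- x[peaks[j]] - x[feet[j]]
      prom <- vapply(cands, function(i) {
        min(max(seg[1:i]) - seg[i], max(seg[i:m]) - seg[i])
      }, numeric(1))
      best <- cands[which.max(prom)]
      if (max(prom) >= 0.02 * amp) notch_i[j] <- peaks[j] + best - 1L
    }
    t_of <- function(i) (i0 + i - 2) / fs
    out[[length(out) + 1L]] <- data.frame(
      foot_time = t_of(feet), peak_time = t_of(peaks),
      notch_time = ifelse(is.na(notch_i), NA_real_, t_of(notch_i)),
      foot_value = x[feet], peak_value = x[peaks],
      notch_value = ifelse(is.na(notch_i), NA_real_, x[notch_i]),
      has_notch = !is.na(notch_i),
      beat_end_time = c(t_of(feet)[-1], NA_real_))
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$foot_time), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("pulse_landmarks", "data.frame"))
}

# hold the latest per-beat value on the 1 Hz grid; second s (1-based, covering
# [s-1, s)) takes the most recent value whose availability time <= s - 1 and
# is no older than `staleness_s`
.hold_1hz <- function(avail_time, value, duration_s, staleness_s = 5) {
  val <- rep(NA_real_, duration_s)
  ok <- !is.na(avail_time) & !is.na(value)
  avail_time <- avail_time[ok]; value <- value[ok]
  if (length(avail_time)) {
    ts <- seq_len(duration_s) - 1
    idx <- findInterval(ts, avail_time)
    use <- idx >= 1
    use[use] <- (ts[use] - avail_time[idx[use]]) <= staleness_s
    val[use] <- value[idx[use]]
  }
  list(value = val, missing = is.na(val))
}

#' Heart rate at 1 Hz from pulse landmarks
#'
#' `HR(t) = 60 / (latest inter-foot interval)`, held on the 1 Hz grid and
#' masked wherever no beat occurred within the last 5 s. A single beat (no
#' complete interval) yields a fully masked series.
#'
#' @param landmarks a [detect_pulses()] result.
#' @param duration_s record duration, seconds.
#' @return channel `list(value, missing)` of length `duration_s`, bpm.
#' @export
compute_hr <- function(landmarks, duration_s) {
  ft <- landmarks$foot_time
  if (length(ft) < 2) {
    return(list(value = rep(NA_real_, duration_s),
                missing = rep(TRUE, duration_s)))
  }
  iv <- diff(ft)
  .hold_1hz(avail_time = ft[-1], value = 60 / iv, duration_s = duration_s)
}

#' Perfusion index at 1 Hz from pulse landmarks
#'
#' Per beat, `PI = 100 * (peak - foot) / DC` with DC the beat mean of the raw
#' PPG over \[foot, next foot); values become available at the beat's end and
#' are held on the 1 Hz grid (5 s staleness mask). Beats whose DC is not
#' positive, or that contain missing samples, are masked.
#'
#' @param ppg PPG channel (numeric with `NA`, or `list(value, missing)`).
#' @param landmarks a [detect_pulses()] result.
#' @param duration_s record duration, seconds.
#' @param fs sampling rate, Hz.
#' @return channel `list(value, missing)` of length `duration_s`, percent.
#' @export
compute_pi <- function(ppg, landmarks, duration_s, fs = 125) {
  v <- if (is.list(ppg)) {
    tmp <- ppg$value; tmp[ppg$missing] <- NA_real_; tmp
  } else as.numeric(ppg)
  lm <- landmarks[!is.na(landmarks$beat_end_time), , drop = FALSE]
  if (!nrow(lm)) {
    return(list(value = rep(NA_real_, duration_s),
                missing = rep(TRUE, duration_s)))
  }
  pi_beat <- vapply(seq_len(nrow(lm)), function(j) {
    i0 <- round(lm$foot_time[j] * fs) + 1
    i1 <- round(lm$beat_end_time[j] * fs)
    dc <- mean(v[i0:i1])
    if (is.na(dc) || dc <= 0) return(NA_real_)
    100 * (lm$peak_value[j] - lm$foot_value[j]) / dc
  }, numeric(1))
  .hold_1hz(lm$beat_end_time, pi_beat, duration_s)
}

#' Notch relative amplitude at 1 Hz from pulse landmarks
#'
#' Per beat, `NRA = (notch - foot) / (peak - foot)`, clipped to \[0, 1\];
#' beats without a detected notch, or degenerate beats with `peak == foot`,
#' are masked. Values are held on the 1 Hz grid with a 5 s staleness mask.
#'
#' @inheritParams compute_pi
#' @return channel `list(value, missing)` of length `duration_s`,
#'   dimensionless in \[0, 1\].
#' @export
compute_nra <- function(ppg, landmarks, duration_s, fs = 125) {
  lm <- landmarks
  amp <- lm$peak_value - lm$foot_value
  nra <- ifelse(lm$has_notch & amp > 0,
                clip((lm$notch_value - lm$foot_value) / amp, 0, 1), NA_real_)
  avail <- ifelse(is.na(lm$beat_end_time), lm$notch_time, lm$beat_end_time)
  .hold_1hz(avail, nra, duration_s)
}

#' Compute the full derived-feature set of a record from its PPG
#'
#' Runs [detect_pulses()] and derives (HR, PI, NRA) at 1 Hz with per-series
#' missing masks. A masked input second never yields an unmasked feature.
#'
#' @param record a [physio_record()].
#' @return object of class `feature_set`: list with channels `hr`, `pi`,
#'   `nra` (each `list(value, missing)`) and the `landmarks` table.
#' @export
compute_features <- function(record) {
  stopifnot(inherits(record, "physio_record"))
  dur <- record$meta$duration_s
  lm <- detect_pulses(record$ppg, fs = record$meta$fs_wave)
  structure(list(
    hr = compute_hr(lm, dur),
    pi = compute_pi(record$ppg, lm, dur, fs = record$meta$fs_wave),
    nra = compute_nra(record$ppg, lm, dur, fs = record$meta$fs_wave),
    landmarks = lm), class = "feature_set")
}
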