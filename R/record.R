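#' Construct a synchronized multichannel physiological record
#'
#' The package's central container: one patient's synchronized channels on a
#' common time origin (t = 0 at record start). Waveform channels (PPG, ECG)
#' are sampled at 125 Hz; derived channels (HR, PI, NRA) and the arterial
#' reference MAP at 1 Hz; cuff events are a strictly time-increasing table.
#' Every channel carries an explicit boolean missing mask (never sentinel
#' values), so "missing proportion" quality filters are unambiguous. The
#' 1 Hz sample with index i (1-based) covers the second \[i-1, i).
#'
#' @param patient_id character scalar.
#' @param ppg,ecg numeric vectors of length `125 * duration_s` (may contain
#'   `NA` where missing) or lists `list(value, missing)`.
#' @param hr,pi,nra,map_ref numeric vectors of length `duration_s` or
#'   `list(value, missing)` channels.
#' @param cuff_events data.frame with columns `time_s` and `map_mmHg`.
#' @param duration_s record duration in seconds.
#' @param device free-text device label stored in metadata.
#' @return an object of class `physio_record`.
#' @export
physio_record <- function(patient_id, ppg, ecg, hr, pi, nra, map_ref,
                          cuff_events, duration_s, device = "synthetic") {
  as_channel <- function(x, len, name) {
    if (is.list(x) && all(c("value", "missing") %in% names(x))) {
      ch <- list(value = as.numeric(x$value), missing = as.logical(x$missing))
    } else {
      x <- as.numeric(x)
      ch <- list(value = x, missing = is.na(x))
    }
    if (length(ch$value) != len || length(ch$missing) != len) {
      stop(sprintf("channel `%s` must have length %d, got %d",
                   name, len, length(ch$value)))
    }
    ch$value[ch$missing] <- NA_real_
    ch
  }
  duration_s <- as.integer(duration_s)
  stopifnot_scalar(duration_s, "duration_s", lo = 1)
  nw <- 125L * duration_s
  cuff_events <- as.data.frame(cuff_events)
  stopifnot(all(c("time_s", "map_mmHg") %in% names(cuff_events)))
  cuff_events$time_s <- as.numeric(cuff_events$time_s)
  cuff_events$map_mmHg <- as.numeric(cuff_events$map_mmHg)
  if (nrow(cuff_events) > 1L && any(diff(cuff_events$time_s) <= 0)) {
    stop("cuff_events must be strictly increasing in time")
  }
  if (nrow(cuff_events) &&
      (any(cuff_events$time_s < 0) || any(cuff_events$time_s > duration_s))) {
    stop("cuff_events times must lie within [0, duration_s]")
  }
  if (nrow(cuff_events) &&
      (any(cuff_events$map_mmHg < 20) || any(cuff_events$map_mmHg > 250))) {
    stop("cuff MAP values must lie within [20, 250] mmHg")
  }
  structure(list(
    patient_id = as.character(patient_id),
    ppg = as_channel(ppg, nw, "ppg"),
    ecg = as_channel(ecg, nw, "ecg"),
    hr = as_channel(hr, duration_s, "hr"),
    pi = as_channel(pi, duration_s, "pi"),
    nra = as_channel(nra, duration_s, "nra"),
    map_ref = as_channel(map_ref, duration_s, "map_ref"),
    cuff_events = cuff_events[, c("time_s", "map_mmHg")],
    meta = list(duration_s = duration_s, fs_wave = 125L, fs_derived = 1L,
                device = device)
  ), class = "physio_record")
}

#' @export
print.physio_record <- function(x, ...) {
  cat(sprintf("<physio_record %s> %d s, %d cuff events, device: %s\n",
              x$patient_id, x$meta$duration_s, nrow(x$cuff_events),
              x$meta$device))
  for (ch in c("ppg", "ecg", "hr", "pi", "nra", "map_ref")) {
    m <- mean(x[[ch]]$missing)
    cat(sprintf("  %-8s n=%-8d missing=%.1f%%\n", ch,
                length(x[[ch]]$value), 100 * m))
  }
  invisible(x)
}

.record_groups <- list(
  waveforms = c("ppg", "ecg"),
  derived = c("hr", "pi", "nra", "map_ref")
)

#' Write a record to disk / read it back
#'
#' Records are stored as a hierarchical plain-text container: a directory
#' with groups `waveforms/` (`ppg.csv`, `ecg.csv`), `derived/` (`hr.csv`,
#' `pi.csv`, `nra.csv`, `map_ref.csv`), a `cuff.csv` table and a `meta.json`
#' attribute file carrying sampling rates, duration and device label. Each
#' channel CSV has columns `time,value,missing`; values are written with
#' round-trippable precision, so `read_record(write_record(r))` equals `r`
#' channel-by-channel including missing masks.
#'
#' @param record a [physio_record()].
#' @param path directory to create (overwritten if present).
#' @return `write_record` returns `path` invisibly; `read_record` returns a
#'   [physio_record()].
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "physio_record"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (grp in names(.record_groups)) {
    gdir <- file.path(path, grp)
    dir.create(gdir, showWarnings = FALSE)
    fs <- if (grp == "waveforms") record$meta$fs_wave else record$meta$fs_derived
    for (ch in .record_groups[[grp]]) {
      v <- record[[ch]]
      dt <- data.table::data.table(
        time = (seq_along(v$value) - 1) / fs,
        value = sprintf("%.17g", v$value),   # bit-exact double round-trip
        missing = v$missing)
      data.table::fwrite(dt, file.path(gdir, paste0(ch, ".csv")),
                         quote = FALSE)
    }
  }
  data.table::fwrite(
    data.table::data.table(
      time_s = record$cuff_events$time_s,
      map_mmHg = sprintf("%.17g", record$cuff_events$map_mmHg)),
    file.path(path, "cuff.csv"), quote = FALSE)
  jsonlite::write_json(
    list(patient_id = record$patient_id, duration_s = record$meta$duration_s,
         fs_wave = record$meta$fs_wave, fs_derived = record$meta$fs_derived,
         device = record$meta$device),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  if (!dir.exists(path)) stop(sprintf("record container not found: %s", path))
  need <- c("waveforms", "derived", "cuff.csv", "meta.json")
  for (g in need) {
    if (!file.exists(file.path(path, g))) {
      stop(sprintf("malformed record container: missing group `%s`",
                   sub("\\.csv$|\\.json$", "", g)))
    }
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  read_ch <- function(grp, ch) {
    f <- file.path(path, grp, paste0(ch, ".csv"))
    if (!file.exists(f)) {
      stop(sprintf("malformed record container: missing group `%s/%s`", grp, ch))
    }
    dt <- data.table::fread(f)
    list(value = as.numeric(dt$value), missing = as.logical(dt$missing))
  }
  cuff <- as.data.frame(data.table::fread(file.path(path, "cuff.csv")))
  physio_record(
    patient_id = meta$patient_id,
    ppg = read_ch("waveforms", "ppg"), ecg = read_ch("waveforms", "ecg"),
    hr = read_ch("derived", "hr"), pi = read_ch("derived", "pi"),
    nra = read_ch("derived", "nra"), map_ref = read_ch("derived", "map_ref"),
    cuff_events = cuff, duration_s = meta$duration_s, device = meta$device)
}

#' Resample a waveform channel to 125 Hz
#'
#' Anti-aliased decimation from a supported native rate (125, 250 or 500 Hz)
#' to the package's common 125 Hz waveform rate. A native rate of 125 Hz
#' returns the input unchanged (bitwise identity); higher rates are reduced
#' with a zero-phase FIR low-pass (cutoff at the target Nyquist) followed by
#' integer downsampling, so output length is `length(x) * 125 / native_fs`.
#'
#' @param x numeric waveform vector.
#' @param native_fs native sampling rate in Hz; one of 125, 250, 500.
#' @return numeric vector at 125 Hz.
#' @export
resample_to_125hz <- function(x, native_fs) {
  if (!native_fs %in% c(125, 250, 500)) {
    stop("unsupported native sampling rate: must be one of 125, 250, 500 Hz")
  }
  if (native_fs == 125) return(x)
  q <- as.integer(native_fs / 125)
  # linear-phase FIR anti-aliasing (cutoff 0.8x target Nyquist), applied by
  # convolution with edge replication and group-delay compensation
  n <- 64L
  h <- as.numeric(signal::fir1(n, 0.8 / q))
  xp <- c(rep(x[1], n), x, rep(x[length(x)], n))
  yc <- stats::filter(xp, h, method = "convolution", sides = 1)
  y <- as.numeric(yc)[n + n / 2 + seq_along(x)]
  y[seq(1, length(y), by = q)]
}

#' Export one channel of a record as CSV
#'
#' @param record a [physio_record()].
#' @param channel one of `"ppg"`, `"ecg"`, `"hr"`, `"pi"`, `"nra"`,
#'   `"map_ref"`.
#' @param file output CSV path (columns `time,value,missing`).
#' @return `file`, invisibly.
#' @export
export_channel_csv <- function(record, channel, file) {
  stopifnot(inherits(record, "physio_record"),
            channel %in% c("ppg", "ecg", "hr", "pi", "nra", "map_ref"))
  fs <- if (channel %in% c("ppg", "ecg")) record$meta$fs_wave else
    record$meta$fs_derived
  v <- record[[channel]]
  data.table::fwrite(
    data.table::data.table(time = (seq_along(v$value) - 1) / fs,
                           value = v$value, missing = v$missing),
    file)
  invisible(file)
}
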