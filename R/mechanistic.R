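#' Parameters of the mechanistic Ohm-Poiseuille MAP model
#'
#' The mechanistic model ties mean arterial pressure to three pulse-derived
#' features via
#' \deqn{\widehat{MAP} = \alpha (\ln(1 + 1/PI) + \beta)(NRA + \beta') HR + \delta}
#' where `PI` is the perfusion index (%), `NRA` the dicrotic notch relative
#' amplitude (dimensionless in \[0, 1\]) and `HR` the heart rate (bpm). The
#' form follows from Ohm's law applied to the systemic circulation
#' (pressure = flow x resistance, flow = stroke volume x heart rate), with
#' the log-perfusion term standing in for vascular resistance and the notch
#' amplitude for stroke volume.
#'
#' @param alpha scale, mmHg per bpm; must be finite.
#' @param beta dimensionless offset inside the log-perfusion term.
#' @param beta_prime dimensionless offset added to NRA.
#' @param delta intercept, mmHg.
#' @return an object of class `mechanistic_params`.
#' @export
#' @examples
#' p <- mechanistic_params(alpha = 1, beta = 0.5, beta_prime = 0.6, delta = 30)
#' mechanistic_predict(hr = 75, pi = 5, nra = 0.4, params = p)
mechanistic_params <- function(alpha = 1, beta = 0.5, beta_prime = 0.6, delta = 30) {
  stopifnot_scalar(alpha, "alpha")
  stopifnot_scalar(beta, "beta")
  stopifnot_scalar(beta_prime, "beta_prime")
  stopifnot_scalar(delta, "delta")
  structure(list(alpha = alpha, beta = beta, beta_prime = beta_prime,
                 delta = delta),
            class = "mechanistic_params")
}

#' @export
print.mechanistic_params <- function(x, ...) {
  cat(sprintf(
    "Ohm-Poiseuille MAP parameters: alpha=%.4g beta=%.4g beta'=%.4g delta=%.4g\n",
    x$alpha, x$beta, x$beta_prime, x$delta))
  invisible(x)
}

#' Evaluate the mechanistic MAP formula
#'
#' Vectorized, pointwise evaluation of the Ohm-Poiseuille formula. Samples
#' where any input is `NA`, or where `pi <= 0` (the log term is undefined),
#' are returned as `NA` ("masked"): masks propagate, they never raise.
#'
#' @param hr heart rate, bpm.
#' @param pi perfusion index, %; must be positive to contribute.
#' @param nra notch relative amplitude, dimensionless.
#' @param params a [mechanistic_params()] object.
#' @return numeric vector of predicted MAP in mmHg, `NA` where masked.
#' @export
mechanistic_predict <- function(hr, pi, nra, params) {
  stopifnot(inherits(params, "mechanistic_params"))
  n <- max(length(hr), length(pi), length(nra))
  hr <- rep_len(as.numeric(hr), n)
  pi <- rep_len(as.numeric(pi), n)
  nra <- rep_len(as.numeric(nra), n)
  out <- rep(NA_real_, n)
  ok <- !is.na(hr) & !is.na(pi) & !is.na(nra) & pi > 0
  out[ok] <- params$alpha * (log(1 + 1 / pi[ok]) + params$beta) *
    (nra[ok] + params$beta_prime) * hr[ok] + params$delta
  out
}

#' Fit the mechanistic model to a rolling cuff history
#'
#' Bounded nonlinear least squares of the Ohm-Poiseuille formula against the
#' last five (or all available, if fewer) cuff MAP values, each paired with
#' the concurrent feature values (conventionally the mean over the 30 s
#' preceding the cuff). Initialization is fixed and deterministic
#' (`alpha = 1`, `beta = 0`, `beta_prime = 0`, `delta = mean(cuff)`), with
#' box bounds `alpha` in \[0.01, 10\], `beta`, `beta_prime` in \[-5, 5\] and
#' `delta` in \[-100, 200\]. With quasi-constant features the four parameters
#' are not jointly identifiable; the fit is judged by its predictions, not by
#' parameter recovery, and degenerate feature histories fall back to an
#' intercept-only fit (`delta` = mean cuff) with a flag.
#'
#' The least-squares problem on at most five quasi-collinear points is
#' rank-deficient: many parameter vectors fit the cuffs equally well, and the
#' unpenalized solution amplifies cuff noise into wild extrapolation. A weak
#' Tikhonov pull toward the initialization (`ridge` pseudo-residuals per
#' parameter, scaled by `ridge_scale`) selects the closest member of the
#' near-solution set; at the default strength it leaves a consistent
#' (noise-free) calibration essentially interpolated.
#'
#' @param features data.frame with columns `hr`, `pi`, `nra`, one row per
#'   calibration point (time-ordered, oldest first).
#' @param cuff_map numeric vector of cuff MAP values, mmHg, same length.
#' @param window number of most recent calibration points used (default 5).
#' @param ridge regularization strength (pseudo-residual weight, mmHg per
#'   `ridge_scale` unit of parameter deviation from the start).
#' @param ridge_scale per-parameter deviation scales (alpha, beta,
#'   beta_prime, delta).
#' @param start optional warm-start parameter vector (alpha, beta,
#'   beta_prime, delta); defaults to the fixed initialization.
#' @return an object of class `mechanistic_fit` with elements `params`,
#'   `fitted`, `residuals`, `n`, `flags`.
#' @seealso [mechanistic_track()] for whole-record tracking.
#' @export
fit_mechanistic <- function(features, cuff_map, window = 5L, ridge = 0.05,
                            ridge_scale = c(1, 0.2, 0.2, 10), start = NULL) {
  stopifnot(is.data.frame(features),
            all(c("hr", "pi", "nra") %in% names(features)),
            nrow(features) == length(cuff_map))
  keep <- !is.na(features$hr) & !is.na(features$pi) & !is.na(features$nra) &
    !is.na(cuff_map) & features$pi > 0
  features <- features[keep, , drop = FALSE]
  cuff_map <- cuff_map[keep]
  n_all <- nrow(features)
  if (n_all < 1L) stop("no usable calibration points")
  idx <- seq.int(max(1L, n_all - window + 1L), n_all)
  features <- features[idx, , drop = FALSE]
  cuff_map <- cuff_map[idx]
  n <- nrow(features)
  flags <- character(0)
  if (n < window) flags <- c(flags, "short_history")

  degen <- n < 2L ||
    (sd(features$hr) < 1e-8 && sd(features$pi) < 1e-8 && sd(features$nra) < 1e-8)
  if (degen) {
    # delta-only fallback: intercept = mean cuff, no feature contribution
    params <- mechanistic_params(alpha = 0, beta = 0, beta_prime = 0,
                                 delta = mean(cuff_map))
    fitted <- mechanistic_predict(features$hr, features$pi, features$nra, params)
    return(structure(list(params = params, fitted = fitted,
                          residuals = cuff_map - fitted, n = n,
                          flags = c(flags, "degenerate_features")),
                     class = "mechanistic_fit"))
  }

  hr <- features$hr; pi <- features$pi; nra <- features$nra
  if (is.null(start)) {
    start <- c(alpha = 1, beta = 0, beta_prime = 0, delta = mean(cuff_map))
  } else {
    start <- stats::setNames(as.numeric(start),
                             c("alpha", "beta", "beta_prime", "delta"))
  }
  resid_fun <- function(p) {
    c(p[1] * (log(1 + 1 / pi) + p[2]) * (nra + p[3]) * hr + p[4] - cuff_map,
      ridge * (p - start) / ridge_scale)
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = c(0.01, -5, -5, -100), upper = c(10, 5, 5, 200),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  params <- mechanistic_params(alpha = p[[1]], beta = p[[2]],
                               beta_prime = p[[3]], delta = p[[4]])
  fitted <- mechanistic_predict(hr, pi, nra, params)
  structure(list(params = params, fitted = fitted,
                 residuals = cuff_map - fitted, n = n, flags = flags),
            class = "mechanistic_fit")
}

#' @export
coef.mechanistic_fit <- function(object, ...) {
  unlist(object$params[c("alpha", "beta", "beta_prime", "delta")])
}

#' @export
print.mechanistic_fit <- function(x, ...) {
  cat(sprintf("Mechanistic MAP fit on %d calibration point(s)\n", x$n))
  print(x$params)
  cat(sprintf("  residual RMS: %.3g mmHg", sqrt(mean(x$residuals^2))))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
predict.mechanistic_fit <- function(object, newdata, ...) {
  mechanistic_predict(newdata$hr, newdata$pi, newdata$nra, object$params)
}

#' Track MAP over a record with rolling five-cuff recalibration
#'
#' At each cuff event the model is refitted on the trailing five cuff
#' measurements (all available, if fewer) and then predicts forward at 1 Hz
#' within the following inter-cuff segment, using the record's derived
#' feature channels. Predictions are strictly causal: the fit at cuff i uses
#' only cuffs and features at times <= cuff i.
#'
#' Rolling refits are stabilized three ways, reflecting how little
#' information a handful of cuffs carries: (i) with fewer than three cuffs
#' the slope cannot be separated from the level, so the opening cuff is
#' carried forward (flagged `short_history`); (ii) each refit warm-starts
#' from the previous fit with a Tikhonov pull toward it (`ridge = 2`), so
#' parameters evolve smoothly instead of re-interpolating every noisy
#' five-point window; (iii) predictions are clipped to the physiological
#' 40-160 mmHg range.
#'
#' @param record a [physio_record()].
#' @param params optional fixed [mechanistic_params()]; if supplied, no
#'   fitting is performed (useful to evaluate known/true parameters).
#' @param feature_window_s averaging window, seconds, for the feature value
#'   attached to a cuff (default 30).
#' @param ridge regularization strength passed to [fit_mechanistic()] for
#'   the rolling refits.
#' @param min_history minimum cuff count before the model is fitted; below
#'   it the opening cuff is carried forward.
#' @return list with `pred` (1 Hz numeric, `NA` where not predicted or
#'   masked), `fits` (data.frame log of refits: time, parameters, flags).
#' @export
mechanistic_track <- function(record, params = NULL, feature_window_s = 30L,
                              ridge = 2, min_history = 3L) {
  stopifnot(inherits(record, "physio_record"))
  cuffs <- record$cuff_events
  dur <- record$meta$duration_s
  pred <- rep(NA_real_, dur)
  fits <- list()
  if (nrow(cuffs) < 2L) {
    warning("fewer than 2 cuff events: nothing to track")
    return(list(pred = pred, fits = data.frame()))
  }
  # feature summary over the window preceding each cuff
  feat_at <- function(t) {
    lo <- max(0L, as.integer(t) - feature_window_s) + 1L
    hi <- max(1L, min(dur, as.integer(t)))
    if (lo > hi) lo <- hi
    win <- function(ch) {
      v <- record[[ch]]$value[lo:hi]
      v <- v[!record[[ch]]$missing[lo:hi] & !is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }
    data.frame(hr = win("hr"), pi = win("pi"), nra = win("nra"))
  }
  cal_feats <- do.call(rbind, lapply(cuffs$time_s, feat_at))

  warm <- NULL
  for (i in seq_len(nrow(cuffs) - 1L)) {
    start <- as.integer(cuffs$time_s[i])
    end <- min(as.integer(cuffs$time_s[i + 1L]), dur)
    if (end <= start) next
    sel <- (start + 1L):end     # 1-based indices for seconds [start, end)
    if (is.null(params)) {
      if (i < min_history) {
        pred[sel] <- cuffs$map_mmHg[i]
        fits[[length(fits) + 1L]] <- data.frame(
          time_s = cuffs$time_s[i], alpha = 0, beta = 0, beta_prime = 0,
          delta = cuffs$map_mmHg[i], flags = "short_history")
        next
      }
      hist_idx <- seq_len(i)
      fit <- tryCatch(
        fit_mechanistic(cal_feats[hist_idx, , drop = FALSE],
                        cuffs$map_mmHg[hist_idx], ridge = ridge,
                        start = warm),
        error = function(e) NULL)
      if (is.null(fit)) next
      p <- fit$params
      warm <- c(p$alpha, p$beta, p$beta_prime, p$delta)
      fits[[length(fits) + 1L]] <- data.frame(
        time_s = cuffs$time_s[i], alpha = p$alpha, beta = p$beta,
        beta_prime = p$beta_prime, delta = p$delta,
        flags = paste(fit$flags, collapse = ";"))
    } else {
      p <- params
    }
    hr <- record$hr$value[sel]; hr[record$hr$missing[sel]] <- NA
    pi <- record$pi$value[sel]; pi[record$pi$missing[sel]] <- NA
    nra <- record$nra$value[sel]; nra[record$nra$missing[sel]] <- NA
    pred[sel] <- mechanistic_predict(hr, pi, nra, p)
    if (is.null(params)) pred[sel] <- clip(pred[sel], 40, 160)
  }
  list(pred = pred,
       fits = if (length(fits)) do.call(rbind, fits) else data.frame())
}

#' Carry-forward cuff baseline
#'
#' The natural clinical comparator: hold the most recent cuff MAP value
#' constant until the next cuff. Predictions cover \[first cuff, last cuff).
#'
#' @param record a [physio_record()].
#' @return 1 Hz numeric vector of predictions, `NA` outside covered spans.
#' @export
carry_forward_track <- function(record) {
  stopifnot(inherits(record, "physio_record"))
  cuffs <- record$cuff_events
  dur <- record$meta$duration_s
  pred <- rep(NA_real_, dur)
  if (nrow(cuffs) < 2L) return(pred)
  for (i in seq_len(nrow(cuffs) - 1L)) {
    start <- as.integer(cuffs$time_s[i])
    end <- min(as.integer(cuffs$time_s[i + 1L]), dur)
    if (end > start) pred[(start + 1L):end] <- cuffs$map_mmHg[i]
  }
  pred
}
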