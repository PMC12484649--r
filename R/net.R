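#' AnesthNet architecture hyperparameters
#'
#' Configuration of the AnesthNet network: a stack of dilated causal 1-D
#' convolutions over the 125 Hz waveform channels (kernel 15, stride 1,
#' dropout 0.2 after each layer, dilation doubling per layer, left padding
#' `(k - 1) * d` per layer so no operation mixes information backward in
#' time), causal trailing-window average pooling down to 1 Hz, channel-axis
#' fusion with the derived features (HR, PI, NRA), an LSTM whose initial
#' hidden state is seeded from the opening cuff MAP, and a per-timestep
#' affine head. The encoder receptive field is `1 + (k - 1)(2^L - 1)`
#' samples.
#'
#' Input normalization constants are fixed in the config and logged with it:
#' MAP-scale quantities (cuff seed, output head) use
#' `(x - map_norm_center) / map_norm_scale`; waveform and feature channels
#' use the per-channel centers/scales below.
#'
#' @param kernel_size convolution kernel size (default 15).
#' @param stride convolution stride; fixed at 1 throughout the dilated stack.
#' @param dropout dropout probability after each conv layer (default 0.2).
#' @param dilation_base dilation growth factor per layer (default 2).
#' @param n_conv_layers encoder depth L (default 8; the `"test"` profile uses
#'   4 for speed).
#' @param conv_channels channels per conv layer.
#' @param lstm_hidden LSTM hidden units.
#' @param lstm_layers LSTM layers (1 supported).
#' @param map_norm_center,map_norm_scale MAP normalization, mmHg.
#' @param feature_center,feature_scale normalization for (HR, PI, NRA).
#' @param wave_center,wave_scale normalization for (PPG, ECG).
#' @param profile `"default"` or `"test"`; the test profile shrinks depth and
#'   width (L = 4, 4 conv channels, 32 hidden units) for fast CPU runs.
#' @return an object of class `net_config`.
#' @export
net_config <- function(kernel_size = 15, stride = 1, dropout = 0.2,
                       dilation_base = 2, n_conv_layers = 8,
                       conv_channels = 32, lstm_hidden = 64, lstm_layers = 1,
                       map_norm_center = 80, map_norm_scale = 20,
                       feature_center = c(hr = 80, pi = 5, nra = 0.5),
                       feature_scale = c(hr = 20, pi = 4, nra = 0.2),
                       wave_center = c(ppg = 1, ecg = 0),
                       wave_scale = c(ppg = 0.05, ecg = 1),
                       profile = c("default", "test")) {
  profile <- match.arg(profile)
  if (profile == "test") {
    if (missing(n_conv_layers)) n_conv_layers <- 4
    if (missing(conv_channels)) conv_channels <- 4
    if (missing(lstm_hidden)) lstm_hidden <- 32
  }
  if (n_conv_layers < 1) stop("n_conv_layers must be >= 1")
  if (stride != 1) stop("stride is fixed at 1 in the dilated stack")
  if (lstm_layers != 1) stop("only lstm_layers = 1 is supported")
  structure(list(
    kernel_size = as.integer(kernel_size), stride = 1L, dropout = dropout,
    dilation_base = as.integer(dilation_base),
    n_conv_layers = as.integer(n_conv_layers),
    conv_channels = as.integer(conv_channels),
    lstm_hidden = as.integer(lstm_hidden), lstm_layers = 1L,
    map_norm_center = map_norm_center, map_norm_scale = map_norm_scale,
    feature_center = feature_center, feature_scale = feature_scale,
    wave_center = wave_center, wave_scale = wave_scale,
    n_wave_channels = 2L, n_feat_channels = 3L, fs_wave = 125L,
    profile = profile), class = "net_config")
}

#' Fingerprint of a network configuration
#'
#' Deterministic string identifying the architecture-relevant fields; equal
#' fingerprints imply equal parameter counts.
#'
#' @param config a [net_config()].
#' @return character scalar.
#' @export
config_fingerprint <- function(config) {
  f <- config[c("kernel_size", "stride", "dropout", "dilation_base",
                "n_conv_layers", "conv_channels", "lstm_hidden",
                "lstm_layers", "map_norm_center", "map_norm_scale")]
  paste(names(f), vapply(f, function(x) paste(format(x), collapse = ","),
                         character(1)),
        sep = "=", collapse = "|")
}

#' Encoder receptive field in samples
#'
#' Closed form `1 + (k - 1)(b^L - 1)/(b - 1) * (b - 1)` for dilation base 2:
#' `1 + (k - 1)(2^L - 1)` input samples can influence one encoder output
#' sample.
#'
#' @param config a [net_config()].
#' @return integer number of samples.
#' @export
receptive_field <- function(config) {
  k <- config$kernel_size
  L <- config$n_conv_layers
  b <- config$dilation_base
  as.integer(1 + (k - 1) * sum(b^(seq_len(L) - 1)))
}

#' Build an AnesthNet network with seeded initial weights
#'
#' Weight initialization is deterministic for a given `(config, seed)`: He
#' initialization for convolution kernels, uniform fan-in scaling for the
#' LSTM (forget-gate bias 1), zeros for biases and head offset.
#'
#' @param config a [net_config()].
#' @param seed integer seed for initialization.
#' @return object of class `anesthnet_model` with elements `config`,
#'   `weights`, `trained`, `history`.
#' @export
build_network <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  k <- config$kernel_size
  L <- config$n_conv_layers
  C <- config$conv_channels
  H <- config$lstm_hidden
  In <- C + config$n_feat_channels
  with_seed(seed, {
    conv <- vector("list", L)
    cin <- config$n_wave_channels
    for (l in seq_len(L)) {
      conv[[l]] <- list(
        W = array(rnorm(C * cin * k, 0, sqrt(2 / (cin * k))), dim = c(C, cin, k)),
        b = numeric(C),
        dilation = config$dilation_base^(l - 1L))
      cin <- C
    }
    r <- 1 / sqrt(H)
    lstm <- list(
      Wx = matrix(runif(4 * H * In, -r, r), 4 * H, In),
      Wh = matrix(runif(4 * H * H, -r, r), 4 * H, H),
      b = c(numeric(H), rep(1, H), numeric(2 * H)))  # forget bias 1
    head <- list(w = matrix(runif(H, -r, r), 1, H), b = 0)
    structure(list(config = config,
                   weights = list(conv = conv, lstm = lstm, head = head),
                   trained = FALSE, history = NULL,
                   fingerprint = config_fingerprint(config)),
              class = "anesthnet_model")
  })
}

#' Number of trainable parameters
#' @param model an `anesthnet_model`.
#' @return integer.
#' @export
count_params <- function(model) {
  w <- model$weights
  sum(vapply(w$conv, function(l) length(l$W) + length(l$b), numeric(1))) +
    length(w$lstm$Wx) + length(w$lstm$Wh) + length(w$lstm$b) +
    length(w$head$w) + 1L
}

#' @export
print.anesthnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<anesthnet_model> L=%d conv layers (k=%d, %d ch, dilation x%d), LSTM %d\n",
    cfg$n_conv_layers, cfg$kernel_size, cfg$conv_channels, cfg$dilation_base,
    cfg$lstm_hidden))
  cat(sprintf("  receptive field: %d samples (%.1f s at 125 Hz)\n",
              receptive_field(cfg), receptive_field(cfg) / 125))
  cat(sprintf("  parameters: %d | trained: %s\n", count_params(x), x$trained))
  invisible(x)
}

# ---- forward primitives ----------------------------------------------------

# causal dilated conv: X (Cin x T) -> (Cout x T); implicit left zero pad
# (k-1)*d, evaluated by the compiled tap loop
.conv_causal_fwd <- function(X, W, b, d) {
  conv_causal_fwd_cpp(X, W, as.numeric(b), as.integer(d))
}

# encoder over one segment's waveform matrix (2 x Tw); returns 1 Hz embedding
# (C x T) plus caches needed for backprop when train = TRUE
.encoder_fwd <- function(Xw, weights, config, train = FALSE) {
  L <- config$n_conv_layers
  p <- config$dropout
  caches <- if (train) vector("list", L) else NULL
  A <- Xw
  for (l in seq_len(L)) {
    ly <- weights$conv[[l]]
    Y <- .conv_causal_fwd(A, ly$W, ly$b, ly$dilation)
    relu_mask <- Y > 0
    Z <- Y * relu_mask
    if (train && p > 0) {
      drop_mask <- matrix(runif(length(Z)) >= p, nrow(Z), ncol(Z))
      Zd <- Z * drop_mask / (1 - p)
    } else {
      drop_mask <- NULL
      Zd <- Z
    }
    if (train) caches[[l]] <- list(X = A, relu = relu_mask, drop = drop_mask)
    A <- Zd
  }
  fs <- config$fs_wave
  Tn <- ncol(A) %/% fs
  arr <- array(A[, seq_len(Tn * fs), drop = FALSE],
               dim = c(nrow(A), fs, Tn))
  E <- colMeans(aperm(arr, c(2, 1, 3)), dims = 1)
  if (Tn == 1L) E <- matrix(E, ncol = 1L)
  list(E = E, A_last = A, caches = caches)
}

# batched LSTM forward: Z (In x T x B), h0 (H x B) -> outputs + caches
.lstm_fwd <- function(Z, weights, h0, train = FALSE) {
  In <- dim(Z)[1]; Tn <- dim(Z)[2]; B <- dim(Z)[3]
  H <- ncol(weights$Wh)
  sigm <- function(x) 1 / (1 + exp(-x))
  h <- h0
  cc <- matrix(0, H, B)
  hs <- array(0, c(H, Tn, B))
  cache <- if (train) {
    list(i = array(0, c(H, Tn, B)), f = array(0, c(H, Tn, B)),
         o = array(0, c(H, Tn, B)), g = array(0, c(H, Tn, B)),
         tc = array(0, c(H, Tn, B)), cprev = array(0, c(H, Tn, B)),
         hprev = array(0, c(H, Tn, B)))
  } else NULL
  for (t in seq_len(Tn)) {
    Xt <- matrix(Z[, t, ], In, B)
    G <- weights$Wx %*% Xt + weights$Wh %*% h + weights$b
    i <- sigm(G[seq_len(H), , drop = FALSE])
    f <- sigm(G[H + seq_len(H), , drop = FALSE])
    o <- sigm(G[2 * H + seq_len(H), , drop = FALSE])
    g <- tanh(G[3 * H + seq_len(H), , drop = FALSE])
    if (train) {
      cache$cprev[, t, ] <- cc
      cache$hprev[, t, ] <- h
    }
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    hs[, t, ] <- h
    if (train) {
      cache$i[, t, ] <- i; cache$f[, t, ] <- f; cache$o[, t, ] <- o
      cache$g[, t, ] <- g; cache$tc[, t, ] <- tc
    }
  }
  list(hs = hs, cache = cache)
}

# ---- input preparation -----------------------------------------------------

# normalized tensors for one segment: waveform matrix, feature matrix,
# target vector + mask, h0 scalar
.prepare_segment <- function(segment, config) {
  cfg <- config
  Tn <- segment$end_s - segment$start_s
  ch_fill <- function(ch, center, scale) {
    v <- (ch$value - center) / scale
    v[ch$missing | is.na(v)] <- 0
    v
  }
  Xw <- rbind(ch_fill(segment$ppg, cfg$wave_center[["ppg"]],
                      cfg$wave_scale[["ppg"]]),
              ch_fill(segment$ecg, cfg$wave_center[["ecg"]],
                      cfg$wave_scale[["ecg"]]))
  Fm <- rbind(ch_fill(segment$hr, cfg$feature_center[["hr"]],
                      cfg$feature_scale[["hr"]]),
              ch_fill(segment$pi, cfg$feature_center[["pi"]],
                      cfg$feature_scale[["pi"]]),
              ch_fill(segment$nra, cfg$feature_center[["nra"]],
                      cfg$feature_scale[["nra"]]))
  y <- (segment$map_ref$value - cfg$map_norm_center) / cfg$map_norm_scale
  valid <- !segment$map_ref$missing & !is.na(segment$map_ref$value)
  y[!valid] <- 0
  list(Xw = Xw, Fm = Fm, y = y, valid = valid, Tn = Tn,
       cuff = segment$opening_cuff$map_mmHg)
}

# ---- calibration state -----------------------------------------------------

#' Cuff-seeded LSTM calibration state
#'
#' Rather than zeros or random values, the LSTM initial hidden state is set
#' from the most recent cuff MAP: the normalized scalar
#' `(cuff_map - map_norm_center) / map_norm_scale` broadcast to every hidden
#' unit; the cell state starts at zero. Constructing twice from the same cuff
#' value yields identical states.
#'
#' @param cuff_map cuff MAP, mmHg, in \[20, 250\].
#' @param config a [net_config()].
#' @return object of class `calibrated_state`: list `h0` (numeric, length
#'   `lstm_hidden`), `c0` (zeros), `cuff_map`.
#' @export
init_calibration_state <- function(cuff_map, config) {
  stopifnot(inherits(config, "net_config"))
  if (!is.finite(cuff_map) || cuff_map < 20 || cuff_map > 250) {
    stop("cuff_map must lie within [20, 250] mmHg")
  }
  v <- (cuff_map - config$map_norm_center) / config$map_norm_scale
  structure(list(h0 = rep(v, config$lstm_hidden),
                 c0 = rep(0, config$lstm_hidden),
                 cuff_map = cuff_map), class = "calibrated_state")
}

#' Reset the calibration state from a new cuff measurement
#'
#' Replaces the hidden state wholesale with the state induced by the new
#' cuff value; network weights are untouched (dynamic recalibration without
#' retraining). Equals `init_calibration_state(new_cuff, config)` exactly.
#'
#' @param state an existing `calibrated_state` (only its shape is relevant).
#' @param new_cuff new cuff MAP, mmHg.
#' @param config a [net_config()].
#' @return a new `calibrated_state`.
#' @export
recalibrate <- function(state, new_cuff, config) {
  stopifnot(inherits(state, "calibrated_state"))
  init_calibration_state(new_cuff, config)
}

# ---- inference -------------------------------------------------------------

#' Encode high-frequency waveforms into a 1 Hz embedding sequence
#'
#' Runs the dilated causal convolution stack and the causal trailing-window
#' average pooling (mean over the trailing 125 samples at stride 125),
#' yielding exactly one embedding step per second. The embedding at second t
#' depends only on samples at times <= t. A trailing partial second is
#' dropped with a warning.
#'
#' @param model an `anesthnet_model`.
#' @param ppg,ecg numeric waveform vectors at 125 Hz (raw units; the config's
#'   normalization is applied internally).
#' @return matrix `conv_channels x T` of embeddings.
#' @export
encode_highfreq <- function(model, ppg, ecg) {
  stopifnot(inherits(model, "anesthnet_model"))
  cfg <- model$config
  n <- length(ppg)
  stopifnot(length(ecg) == n)
  if (n %% cfg$fs_wave != 0) {
    warning("waveform length not a multiple of 125: trailing partial second dropped")
    n <- (n %/% cfg$fs_wave) * cfg$fs_wave
  }
  norm <- function(x, c0, s0) {
    x <- (x - c0) / s0
    x[is.na(x)] <- 0
    x
  }
  Xw <- rbind(norm(ppg[seq_len(n)], cfg$wave_center[["ppg"]], cfg$wave_scale[["ppg"]]),
              norm(ecg[seq_len(n)], cfg$wave_center[["ecg"]], cfg$wave_scale[["ecg"]]))
  .encoder_fwd(Xw, model$weights, cfg, train = FALSE)$E
}

#' Predict the MAP sequence of one inter-cuff segment
#'
#' Full causal forward pass: waveform encoding, channel-axis fusion with the
#' derived features, cuff-calibrated LSTM, per-timestep affine head,
#' denormalization to mmHg. Dropout is disabled: repeated calls are
#' identical. Predictions at second t depend only on inputs at times <= t.
#'
#' @param model a (typically trained) `anesthnet_model`.
#' @param segment a `map_segment` (from [segment_record()]).
#' @param zero_h0 if TRUE, ignore the cuff and start from `h0 = 0` (the
#'   calibration-ablation variant; weights unchanged).
#' @return object of class `prediction_series`: list with `pred` (numeric
#'   mmHg, one per second), `patient_id`, `start_s`, `end_s`,
#'   `opening_cuff`, `model_fingerprint`.
#' @export
predict_segment <- function(model, segment, zero_h0 = FALSE) {
  stopifnot(inherits(model, "anesthnet_model"),
            inherits(segment, "map_segment"))
  cfg <- model$config
  inp <- .prepare_segment(segment, cfg)
  E <- .encoder_fwd(inp$Xw, model$weights, cfg, train = FALSE)$E
  Z <- array(rbind(E, inp$Fm), dim = c(nrow(E) + nrow(inp$Fm), inp$Tn, 1L))
  h0 <- if (zero_h0) {
    matrix(0, cfg$lstm_hidden, 1L)
  } else {
    matrix(init_calibration_state(inp$cuff, cfg)$h0, ncol = 1L)
  }
  hs <- .lstm_fwd(Z, model$weights$lstm, h0, train = FALSE)$hs
  yn <- as.numeric(model$weights$head$w %*% matrix(hs, cfg$lstm_hidden)) +
    model$weights$head$b
  structure(list(
    pred = cfg$map_norm_center + cfg$map_norm_scale * yn,
    patient_id = segment$patient_id, start_s = segment$start_s,
    end_s = segment$end_s, opening_cuff = segment$opening_cuff,
    model_fingerprint = model$fingerprint), class = "prediction_series")
}

#' @export
predict.anesthnet_model <- function(object, newdata, ...) {
  if (inherits(newdata, "map_segment")) return(predict_segment(object, newdata, ...))
  if (inherits(newdata, "physio_record")) return(predict_record(object, newdata, ...))
  stop("`newdata` must be a map_segment or physio_record")
}

#' Predict a whole record, segment by segment
#'
#' Segments the record at its cuff events and predicts each segment with its
#' own opening-cuff calibration (equivalent to streaming with a state reset
#' at every cuff). Returns a 1 Hz vector aligned to the record, `NA` outside
#' predicted spans.
#'
#' @param model an `anesthnet_model`.
#' @param record a [physio_record()].
#' @param zero_h0 calibration-ablation switch (see [predict_segment()]).
#' @param min_segment_s passed to [segment_record()].
#' @return numeric vector of length `duration_s`.
#' @export
predict_record <- function(model, record, zero_h0 = FALSE, min_segment_s = 60) {
  segs <- segment_record(record, min_segment_s = min_segment_s)
  pred <- rep(NA_real_, record$meta$duration_s)
  for (s in segs) {
    p <- predict_segment(model, s, zero_h0 = zero_h0)
    pred[(s$start_s + 1L):s$end_s] <- p$pred
  }
  pred
}

#' Patient-level train/validation/test split
#'
#' Splits patient identifiers (never segments) into disjoint, exhaustive
#' sets: 10% held out as test, the remainder split 90/10 into train and
#' validation. Seeded and deterministic.
#'
#' @param patient_ids character vector of unique ids (>= 10).
#' @param seed integer seed.
#' @return list with `train`, `val`, `test` id vectors.
#' @export
split_patients <- function(patient_ids, seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  if (n < 10) stop("need at least 10 patients for a patient-level split")
  with_seed(seed, {
    ids <- sample(patient_ids)
    n_test <- max(1L, round(0.1 * n))
    rest <- n - n_test
    n_val <- max(1L, round(0.1 * rest))
    list(test = sort(ids[seq_len(n_test)]),
         val = sort(ids[n_test + seq_len(n_val)]),
         train = sort(ids[(n_test + n_val + 1L):n]))
  })
}
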