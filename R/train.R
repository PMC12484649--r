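# Training engine for the AnesthNet network: full backpropagation through
# the affine head, the cuff-initialized LSTM (BPTT), the channel fusion, the
# causal average pooling and the dilated causal convolution stack, with Adam
# updates and global-norm gradient clipping. Everything is seeded.

#' Training configuration
#'
#' @param batch_size segments per minibatch (segments are bucketed by length
#'   so a batch shares one duration).
#' @param max_epochs maximum number of passes over the training segments.
#' @param patience early-stopping patience, epochs without validation-MAE
#'   improvement.
#' @param lr Adam step size.
#' @param clip_norm global gradient-norm clip.
#' @param seed integer seed governing shuffling, dropout and any other
#'   randomness during training.
#' @param verbose print one line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, max_epochs = 30L, patience = 5L,
                         lr = 1e-3, clip_norm = 5, seed = 1L,
                         verbose = FALSE) {
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 clip_norm = clip_norm, seed = as.integer(seed),
                 verbose = isTRUE(verbose)), class = "train_config")
}

# zero-filled gradient tree matching the weight tree
.zero_grads <- function(weights) {
  list(
    conv = lapply(weights$conv, function(l) {
      list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
    }),
    lstm = list(Wx = matrix(0, nrow(weights$lstm$Wx), ncol(weights$lstm$Wx)),
                Wh = matrix(0, nrow(weights$lstm$Wh), ncol(weights$lstm$Wh)),
                b = numeric(length(weights$lstm$b))),
    head = list(w = matrix(0, 1, ncol(weights$head$w)), b = 0))
}

# conv layer backward: returns dX plus parameter grads (compiled tap loop)
.conv_causal_bwd <- function(dY, X, W, d) {
  conv_causal_bwd_cpp(dY, X, W, as.integer(d))
}

# encoder backward through pooling + conv stack for one segment
.encoder_bwd <- function(dE, caches, weights, config, grads) {
  fs <- config$fs_wave
  Tn <- ncol(dE)
  p <- config$dropout
  dA <- (dE / fs)[, rep(seq_len(Tn), each = fs), drop = FALSE]
  for (l in rev(seq_len(config$n_conv_layers))) {
    cc <- caches[[l]]
    if (!is.null(cc$drop)) dA <- dA * cc$drop / (1 - p)
    dY <- dA * cc$relu
    bw <- .conv_causal_bwd(dY, cc$X, weights$conv[[l]]$W,
                           weights$conv[[l]]$dilation)
    grads$conv[[l]]$W <- grads$conv[[l]]$W + bw$dW
    grads$conv[[l]]$b <- grads$conv[[l]]$b + bw$db
    dA <- bw$dX
  }
  grads
}

# forward + backward over one length-homogeneous minibatch of prepared
# segments; returns loss and accumulated grads
.train_batch <- function(prep_list, weights, config, grads) {
  B <- length(prep_list)
  Tn <- prep_list[[1]]$Tn
  H <- config$lstm_hidden
  C <- config$conv_channels
  In <- C + config$n_feat_channels

  enc <- vector("list", B)
  Z <- array(0, c(In, Tn, B))
  h0 <- matrix(0, H, B)
  y <- matrix(0, Tn, B)
  valid <- matrix(FALSE, Tn, B)
  for (b in seq_len(B)) {
    pr <- prep_list[[b]]
    enc[[b]] <- .encoder_fwd(pr$Xw, weights, config, train = TRUE)
    Z[, , b] <- rbind(enc[[b]]$E, pr$Fm)
    h0[, b] <- (pr$cuff - config$map_norm_center) / config$map_norm_scale
    y[, b] <- pr$y
    valid[, b] <- pr$valid
  }
  lf <- .lstm_fwd(Z, weights$lstm, h0, train = TRUE)
  hs <- lf$hs
  hmat <- matrix(hs, H)                       # H x (T*B)
  yn <- matrix(as.numeric(weights$head$w %*% hmat) + weights$head$b, Tn, B)

  n_valid <- sum(valid)
  err <- (yn - y) * valid
  loss <- sum(err^2) / max(1, n_valid)
  dy <- 2 * err / max(1, n_valid)             # T x B

  # head
  dy_flat <- matrix(as.numeric(dy), 1, Tn * B)
  grads$head$w <- grads$head$w + dy_flat %*% t(hmat)
  grads$head$b <- grads$head$b + sum(dy)

  # BPTT
  lw <- weights$lstm
  cache <- lf$cache
  dh_next <- matrix(0, H, B)
  dc_next <- matrix(0, H, B)
  dZ <- array(0, c(In, Tn, B))
  w_head <- as.numeric(weights$head$w)
  for (t in rev(seq_len(Tn))) {
    dh <- outer(w_head, dy[t, ]) + dh_next
    i <- matrix(cache$i[, t, ], H, B); f <- matrix(cache$f[, t, ], H, B)
    o <- matrix(cache$o[, t, ], H, B); g <- matrix(cache$g[, t, ], H, B)
    tc <- matrix(cache$tc[, t, ], H, B)
    cprev <- matrix(cache$cprev[, t, ], H, B)
    hprev <- matrix(cache$hprev[, t, ], H, B)
    do_ <- dh * tc
    dc <- dc_next + dh * o * (1 - tc^2)
    di <- dc * g
    dg <- dc * i
    df <- dc * cprev
    dG <- rbind(di * i * (1 - i), df * f * (1 - f), do_ * o * (1 - o),
                dg * (1 - g^2))
    Xt <- matrix(Z[, t, ], In, B)
    grads$lstm$Wx <- grads$lstm$Wx + dG %*% t(Xt)
    grads$lstm$Wh <- grads$lstm$Wh + dG %*% t(hprev)
    grads$lstm$b <- grads$lstm$b + rowSums(dG)
    dZ[, t, ] <- crossprod(lw$Wx, dG)
    dh_next <- crossprod(lw$Wh, dG)
    dc_next <- dc * f
  }
  for (b in seq_len(B)) {
    dE <- matrix(dZ[seq_len(C), , b], C, Tn)
    grads <- .encoder_bwd(dE, enc[[b]]$caches, weights, config, grads)
  }
  list(loss = loss, grads = grads, n_valid = n_valid)
}

# Adam with bias correction over the nested weight/grad trees
.adam_init <- function(weights) {
  zero_like <- .zero_grads(weights)
  list(m = zero_like, v = .zero_grads(weights), t = 0L)
}

.walk_update <- function(weights, grads, state, lr, clip_norm) {
  gnorm2 <- 0
  acc <- function(g) sum(g^2)
  for (l in seq_along(grads$conv)) {
    gnorm2 <- gnorm2 + acc(grads$conv[[l]]$W) + acc(grads$conv[[l]]$b)
  }
  gnorm2 <- gnorm2 + acc(grads$lstm$Wx) + acc(grads$lstm$Wh) +
    acc(grads$lstm$b) + acc(grads$head$w) + grads$head$b^2
  scale <- if (sqrt(gnorm2) > clip_norm) clip_norm / sqrt(gnorm2) else 1
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  upd <- function(w, g, m, v) {
    g <- g * scale
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    w <- w - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(w = w, m = m, v = v)
  }
  for (l in seq_along(weights$conv)) {
    u <- upd(weights$conv[[l]]$W, grads$conv[[l]]$W,
             state$m$conv[[l]]$W, state$v$conv[[l]]$W)
    weights$conv[[l]]$W <- u$w; state$m$conv[[l]]$W <- u$m
    state$v$conv[[l]]$W <- u$v
    u <- upd(weights$conv[[l]]$b, grads$conv[[l]]$b,
             state$m$conv[[l]]$b, state$v$conv[[l]]$b)
    weights$conv[[l]]$b <- u$w; state$m$conv[[l]]$b <- u$m
    state$v$conv[[l]]$b <- u$v
  }
  for (nm in c("Wx", "Wh", "b")) {
    u <- upd(weights$lstm[[nm]], grads$lstm[[nm]],
             state$m$lstm[[nm]], state$v$lstm[[nm]])
    weights$lstm[[nm]] <- u$w; state$m$lstm[[nm]] <- u$m
    state$v$lstm[[nm]] <- u$v
  }
  for (nm in c("w", "b")) {
    u <- upd(weights$head[[nm]], grads$head[[nm]],
             state$m$head[[nm]], state$v$head[[nm]])
    weights$head[[nm]] <- u$w; state$m$head[[nm]] <- u$m
    state$v$head[[nm]] <- u$v
  }
  list(weights = weights, state = state)
}

#' Train an AnesthNet network on quality-filtered segments
#'
#' Minimizes the 1 Hz mean-squared error between predicted and reference MAP
#' (on the normalized scale, masked samples excluded from the loss) with
#' Adam, early stopping on validation MAE, length-bucketed minibatching, and
#' full seeding of shuffling and dropout. The returned model carries the
#' weights of the best validation epoch and a per-epoch history.
#'
#' @param model an `anesthnet_model` from [build_network()].
#' @param train_segments,val_segments non-empty lists of `map_segment`s.
#' @param config a [train_config()].
#' @return the trained `anesthnet_model`, with `history` (data.frame: epoch,
#'   train_loss, val_mae) and `trained = TRUE`.
#' @export
train_model <- function(model, train_segments, val_segments,
                        config = train_config()) {
  stopifnot(inherits(model, "anesthnet_model"),
            inherits(config, "train_config"),
            length(train_segments) > 0, length(val_segments) > 0)
  cfg <- model$config
  prep <- lapply(train_segments, .prepare_segment, config = cfg)
  lens <- vapply(prep, function(p) p$Tn, numeric(1))

  val_mae <- function(weights) {
    m2 <- model
    m2$weights <- weights
    errs <- unlist(lapply(val_segments, function(s) {
      p <- predict_segment(m2, s)
      ref <- s$map_ref$value
      ok <- !s$map_ref$missing & !is.na(ref)
      (p$pred - ref)[ok]
    }))
    mean(abs(errs))
  }

  weights <- model$weights
  adam <- .adam_init(weights)
  best <- list(weights = weights, mae = Inf, epoch = 0L)
  history <- list()
  wait <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(seq_along(prep))
      # bucket by length, then cut into batches
      buckets <- split(ord, lens[ord])
      batches <- unlist(lapply(buckets, function(ix) {
        split(ix, ceiling(seq_along(ix) / config$batch_size))
      }), recursive = FALSE)
      batches <- batches[sample(seq_along(batches))]
      ep_loss <- 0
      ep_n <- 0
      for (bt in batches) {
        grads <- .zero_grads(weights)
        res <- .train_batch(prep[bt], weights, cfg, grads)
        if (!is.finite(res$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        }
        up <- .walk_update(weights, res$grads, adam, config$lr,
                           config$clip_norm)
        weights <- up$weights
        adam <- up$state
        ep_loss <- ep_loss + res$loss * length(bt)
        ep_n <- ep_n + length(bt)
      }
      vm <- val_mae(weights)
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = ep_loss / ep_n,
                                     val_mae = vm)
      if (config$verbose) {
        message(sprintf("epoch %2d  train_mse %.4f  val_mae %.2f mmHg",
                        epoch, ep_loss / ep_n, vm))
      }
      if (vm < best$mae - 1e-6) {
        best <- list(weights = weights, mae = vm, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$weights <- best$weights
  model$trained <- TRUE
  model$history <- do.call(rbind, history)
  model$best_epoch <- best$epoch
  model
}
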