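#' CNN-LSTM model configuration
#'
#' Per-frame spatial features from a convolutional backbone are smoothed by
#' temporal adaptive pooling to one feature per contrast phase, passed
#' through a two-layer LSTM whose first layer is bidirectional, average
#' pooled over steps and mapped to a malignancy probability by a sigmoid
#' head.
#'
#' The `small_cnn` backbone (three 3x3 conv + ReLU + 2x2 max-pool blocks,
#' global average pooling, feature dimension 64, random init) trains on a
#' plain CPU. `resnet18_frozen5` marks a residual backbone initialised from
#' externally supplied image-classification pretraining with its first 5
#' parameterized layers frozen; no pretrained weights ship with the package,
#' so selecting it requires a `pretrained` weight tree from the caller.
#' `freeze_prefix_layers` freezes the first n parameterized modules of the
#' backbone in forward order for either backbone.
#'
#' @param backbone `"small_cnn"` or `"resnet18_frozen5"`.
#' @param freeze_prefix_layers parameterized backbone modules (forward
#'   order) excluded from gradient updates; default 5 for resnet, 0 for
#'   small_cnn.
#' @param lstm_hidden LSTM hidden size (default 128).
#' @param lstm_layers number of LSTM layers (default 2).
#' @param first_layer_bidirectional run layer 1 in both directions
#'   (default TRUE); layer 2 is unidirectional over the concatenated output.
#' @param pooled_len pooled sequence length (default 3: one per phase).
#' @param input_size crop size `c(rows, cols)`, each divisible by 8.
#' @param cnn_channels channels of the three small_cnn blocks.
#' @return An object of class `model_config`.
#' @export
model_config <- function(backbone = c("small_cnn", "resnet18_frozen5"),
                         freeze_prefix_layers = NULL, lstm_hidden = 128L,
                         lstm_layers = 2L, first_layer_bidirectional = TRUE,
                         pooled_len = 3L, input_size = c(224L, 224L),
                         cnn_channels = c(16L, 32L, 64L)) {
  backbone <- match.arg(backbone)
  if (is.null(freeze_prefix_layers))
    freeze_prefix_layers <- if (backbone == "resnet18_frozen5") 5L else 0L
  if (any(input_size %% 8L != 0L))
    stop("input_size must be divisible by 8 (three 2x2 pooling stages)")
  structure(list(backbone = backbone,
                 freeze_prefix_layers = as.integer(freeze_prefix_layers),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 first_layer_bidirectional = isTRUE(first_layer_bidirectional),
                 pooled_len = as.integer(pooled_len),
                 input_size = as.integer(input_size),
                 cnn_channels = as.integer(cnn_channels),
                 feature_dim = as.integer(cnn_channels[3L])),
            class = "model_config")
}

#' Training configuration
#'
#' Stochastic gradient descent on the binary cross-entropy of the sigmoid
#' output, 6 epochs, learning rate 0.01 for the first 4 epochs and 0.001 for
#' the remainder.
#'
#' @param epochs number of epochs (>= 1, default 6).
#' @param lr_early,lr_late learning rates before/after the switch.
#' @param lr_switch_epoch last epoch using `lr_early` (default 4).
#' @param batch_size mini-batch size (default 16).
#' @param momentum heavy-ball momentum of the SGD solver (default 0.9).
#' @param seed RNG seed covering shuffling and weight init.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 6L, lr_early = 0.01, lr_late = 0.001,
                         lr_switch_epoch = 4L, batch_size = 16L,
                         momentum = 0.9, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lr_early <= 0 || lr_late <= 0) stop("learning rates must be positive")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  structure(list(epochs = as.integer(epochs), lr_early = lr_early,
                 lr_late = lr_late, lr_switch_epoch = as.integer(lr_switch_epoch),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param tcfg a `train_config`.
#' @param epoch epoch number (1-based).
#' @return `epoch_lr()`: the learning rate used in that epoch.
#' @export
epoch_lr <- function(tcfg, epoch) {
  if (epoch <= tcfg$lr_switch_epoch) tcfg$lr_early else tcfg$lr_late
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Initialise CNN-LSTM weights
#'
#' He-normal init for convolutions, uniform `+-1/sqrt(hidden)` for LSTM and
#' head weights, forget-gate bias 1. Fully determined by `seed`.
#'
#' @param config a [model_config()].
#' @param seed RNG seed.
#' @param pretrained backbone weight tree for `resnet18_frozen5` (the
#'   package bundles none).
#' @return Weight tree (class `cnn_lstm_weights`).
#' @export
init_weights <- function(config, seed = 1L, pretrained = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (config$backbone == "resnet18_frozen5" && is.null(pretrained))
    stop("resnet18_frozen5 requires externally supplied pretrained weights; ",
         "use backbone = 'small_cnn' for a self-contained model")
  .with_seed(seed, {
    ch <- c(3L, config$cnn_channels)
    backbone <- lapply(seq_len(3L), function(l) {
      fan_in <- 9L * ch[l]
      list(W = matrix(stats::rnorm(fan_in * ch[l + 1L], 0,
                                   sqrt(2 / fan_in)), fan_in, ch[l + 1L]),
           b = numeric(ch[l + 1L]))
    })
    names(backbone) <- paste0("conv", 1:3)
    nh <- config$lstm_hidden
    d <- config$feature_dim
    lstm_init <- function(n_in) {
      r <- 1 / sqrt(nh)
      b <- numeric(4L * nh)
      b[nh + 1:nh] <- 1 # forget-gate bias
      list(W = matrix(stats::runif(4L * nh * n_in, -r, r), 4L * nh, n_in),
           U = matrix(stats::runif(4L * nh * nh, -r, r), 4L * nh, nh),
           b = b)
    }
    w <- list(backbone = backbone, lstm1f = lstm_init(d))
    if (config$first_layer_bidirectional) w$lstm1b <- lstm_init(d)
    l2_in <- if (config$first_layer_bidirectional) 2L * nh else nh
    w$lstm2 <- lstm_init(l2_in)
    r <- 1 / sqrt(nh)
    w$head <- list(W = matrix(stats::runif(nh, -r, r), 1L, nh),
                   b = 0)
    structure(w, class = "cnn_lstm_weights")
  })
}

# backbone forward for one crop (rows x cols x 3, values in [0, 1])
.cnn_forward <- function(x, backbone) {
  caches <- vector("list", 3L)
  for (l in seq_len(3L)) {
    cv <- .conv3x3_forward(x, backbone[[l]])
    rl <- .relu_forward(cv$out)
    mp <- .maxpool2_forward(rl$out)
    caches[[l]] <- list(conv = cv$cache, mask = rl$mask, pool = mp$cache)
    x <- mp$out
  }
  dm <- dim(x)
  feat <- colMeans(matrix(x, dm[1L] * dm[2L]))
  list(feat = feat, caches = caches, top_dim = dm)
}

.cnn_backward <- function(dfeat, fw, backbone) {
  dm <- fw$top_dim
  dx <- array(rep(dfeat / (dm[1L] * dm[2L]), each = dm[1L] * dm[2L]), dm)
  grads <- vector("list", 3L)
  for (l in 3:1) {
    ca <- fw$caches[[l]]
    dx <- .maxpool2_backward(dx, ca$pool)
    dx <- .relu_backward(dx, ca$mask)
    cb <- .conv3x3_backward(dx, ca$conv, backbone[[l]], need_dx = l > 1L)
    grads[[l]] <- list(W = cb$dW, b = cb$db)
    dx <- cb$dx
  }
  names(grads) <- paste0("conv", 1:3)
  grads
}

#' Extract per-crop spatial features from a mini-loop
#'
#' One backbone feature vector per crop, in mini-loop order (AP, PVP, LP).
#' Evaluation is deterministic: identical crops give identical features.
#'
#' @param miniloop a `mini_loop`.
#' @param config a [model_config()].
#' @param weights a weight tree from [init_weights()] or [train_cnn_lstm()].
#' @return A `feature_sequence`: `features` (`3F x d` matrix) plus
#'   `phase_labels`.
#' @export
extract_spatial_features <- function(miniloop, config, weights) {
  stopifnot(inherits(miniloop, "mini_loop"), inherits(config, "model_config"))
  dm <- dim(miniloop$crops)
  if (!identical(dm[1:2], config$input_size))
    stop("crop size ", dm[1L], "x", dm[2L], " does not match config input_size")
  n <- dm[3L]
  feats <- matrix(0, n, config$feature_dim)
  for (k in seq_len(n)) {
    # grayscale replicated to 3 channels, pixels centred to [-1, 1]
    x3 <- array(miniloop$crops[, , k] / 127.5 - 1, c(dm[1L], dm[2L], 3L))
    feats[k, ] <- .cnn_forward(x3, weights$backbone)$feat
  }
  structure(list(features = feats, phase_labels = miniloop$phase_labels),
            class = "feature_sequence")
}

# adaptive pooling bin bounds (PyTorch convention)
.adaptive_bins <- function(L, P) {
  lapply(seq_len(P), function(k)
    (floor((k - 1) * L / P) + 1L):ceiling(k * L / P))
}

#' Temporal adaptive average pooling
#'
#' Averages a length-`L` feature sequence into `pooled_len` bins along the
#' temporal axis. With `L = 3F` and `pooled_len = 3`, bin `k` is the mean of
#' frames `[kF, (k+1)F)` - one smoothed feature per contrast phase, which
#' also damps residual respiratory jitter across the frames of a phase.
#'
#' @param seq a `feature_sequence` or a numeric matrix (time in rows).
#' @param pooled_len output length (default 3).
#' @return `pooled_len x d` matrix.
#' @export
temporal_adaptive_pool <- function(seq, pooled_len = 3L) {
  X <- if (inherits(seq, "feature_sequence")) seq$features else as.matrix(seq)
  L <- nrow(X)
  if (pooled_len > L)
    stop("pooled_len (", pooled_len, ") exceeds sequence length (", L, ")")
  bins <- .adaptive_bins(L, pooled_len)
  out <- t(vapply(bins, function(b) colMeans(X[b, , drop = FALSE]),
                  numeric(ncol(X))))
  out
}

# LSTM stack + head over a pooled sequence; returns logit and caches.
# Each pooled step and the pooled LSTM output are layer-normalised
# (parameter-free) so activation scales stay O(1) through the short
# 6-epoch schedule.
.seq_forward <- function(pooled, weights, config) {
  ln_in <- apply(pooled, 1L, .layernorm_forward, simplify = FALSE)
  pooled_n <- t(vapply(ln_in, `[[`, numeric(ncol(pooled)), "out"))
  f1 <- .lstm_forward(pooled_n, weights$lstm1f)
  if (config$first_layer_bidirectional) {
    b1 <- .lstm_forward(pooled_n, weights$lstm1b, reverse = TRUE)
    h1 <- cbind(f1$H, b1$H)
  } else {
    b1 <- NULL
    h1 <- f1$H
  }
  f2 <- .lstm_forward(h1, weights$lstm2)
  hbar_raw <- colMeans(f2$H) # adaptive average pooling over LSTM steps
  ln_h <- .layernorm_forward(hbar_raw)
  hbar <- ln_h$out
  logit <- as.numeric(weights$head$W %*% hbar + weights$head$b)
  list(logit = logit, f1 = f1, b1 = b1, f2 = f2, hbar = hbar, h1 = h1,
       ln_in = ln_in, ln_h = ln_h, Tn = nrow(pooled))
}

.seq_backward <- function(dlogit, fw, weights, config) {
  nh <- length(fw$hbar)
  g_head <- list(W = dlogit * matrix(fw$hbar, 1L), b = dlogit)
  dhbar <- .layernorm_backward(dlogit * as.vector(weights$head$W),
                               fw$ln_h$cache)
  dH2 <- matrix(rep(dhbar / fw$Tn, each = fw$Tn), fw$Tn)
  b2 <- .lstm_backward(dH2, fw$f2, weights$lstm2)
  g <- list(lstm2 = b2[c("dW", "dU", "db")])
  names(g$lstm2) <- c("W", "U", "b")
  dh1 <- b2$dX
  nh1 <- ncol(fw$f1$H)
  bf <- .lstm_backward(dh1[, 1:nh1, drop = FALSE], fw$f1, weights$lstm1f)
  g$lstm1f <- bf[c("dW", "dU", "db")]; names(g$lstm1f) <- c("W", "U", "b")
  dpooled <- bf$dX
  if (config$first_layer_bidirectional) {
    bb <- .lstm_backward(dh1[, nh1 + 1:nh1, drop = FALSE], fw$b1,
                         weights$lstm1b)
    g$lstm1b <- bb[c("dW", "dU", "db")]; names(g$lstm1b) <- c("W", "U", "b")
    dpooled <- dpooled + bb$dX
  }
  g$head <- g_head
  for (t in seq_len(nrow(dpooled)))
    dpooled[t, ] <- .layernorm_backward(dpooled[t, ], fw$ln_in[[t]]$cache)
  list(grads = g, dpooled = dpooled)
}

# full forward over one mini-loop; caches everything needed for backward
.net_forward <- function(miniloop, weights, config) {
  dm <- dim(miniloop$crops)
  n <- dm[3L]
  feats <- matrix(0, n, config$feature_dim)
  cnn_caches <- vector("list", n)
  for (k in seq_len(n)) {
    x3 <- array(miniloop$crops[, , k] / 127.5 - 1, c(dm[1L], dm[2L], 3L))
    fw <- .cnn_forward(x3, weights$backbone)
    feats[k, ] <- fw$feat
    cnn_caches[[k]] <- fw
  }
  bins <- .adaptive_bins(n, config$pooled_len)
  pooled <- t(vapply(bins, function(b) colMeans(feats[b, , drop = FALSE]),
                     numeric(config$feature_dim)))
  sq <- .seq_forward(pooled, weights, config)
  list(prob = .sigmoid(sq$logit), logit = sq$logit, seq = sq, bins = bins,
       cnn_caches = cnn_caches, n = n)
}

.net_backward <- function(dlogit, fw, weights, config) {
  sb <- .seq_backward(dlogit, fw$seq, weights, config)
  grads <- sb$grads
  gb <- NULL
  for (k in seq_len(fw$n)) {
    bin <- which(vapply(fw$bins, function(b) k %in% b, logical(1L)))
    dfeat <- sb$dpooled[bin, ] / length(fw$bins[[bin]])
    gk <- .cnn_backward(dfeat, fw$cnn_caches[[k]], weights$backbone)
    gb <- if (is.null(gb)) gk else .wt_axpy(gb, gk)
  }
  grads$backbone <- gb
  grads[names(weights)]
}

#' Malignancy probability of one mini-loop
#'
#' Backbone features, temporal adaptive pooling to `pooled_len` steps, the
#' two-layer LSTM (bidirectional first layer), average pooling over LSTM
#' outputs, linear head, sigmoid. Deterministic in evaluation.
#'
#' @param miniloop a `mini_loop`, or an already pooled `pooled_len x d`
#'   matrix.
#' @param weights weight tree.
#' @param config a [model_config()].
#' @return Probability in (0, 1).
#' @export
predict_miniloop <- function(miniloop, weights, config) {
  if (inherits(miniloop, "mini_loop"))
    return(.net_forward(miniloop, weights, config)$prob)
  pooled <- as.matrix(miniloop)
  if (nrow(pooled) != config$pooled_len)
    stop("pooled sequence must have ", config$pooled_len, " steps")
  .sigmoid(.seq_forward(pooled, weights, config)$logit)
}

#' Train the CNN-LSTM on labelled mini-loops
#'
#' Mini-batch SGD on binary cross-entropy, with the epoch-wise learning-rate
#' switch of [train_config()]. The first `freeze_prefix_layers` backbone
#' modules receive no updates. All randomness (init, shuffling) derives from
#' `tcfg$seed`.
#'
#' @param miniloops list of `mini_loop`s with labels 0/1.
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param weights optional starting weights (default fresh init from seed).
#' @return List with `weights`, `history` (per-epoch mean training loss) and
#'   the configs.
#' @export
train_cnn_lstm <- function(miniloops, mcfg, tcfg, weights = NULL) {
  stopifnot(inherits(mcfg, "model_config"), inherits(tcfg, "train_config"))
  labels <- vapply(miniloops, function(m) {
    if (is.null(m$label)) stop("all mini-loops must be labelled for training")
    as.numeric(m$label)
  }, numeric(1L))
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  if (is.null(weights)) weights <- init_weights(mcfg, seed = tcfg$seed)
  n <- length(miniloops)
  history <- numeric(tcfg$epochs)
  velocity <- NULL
  .with_seed(tcfg$seed + 1L, {
    for (ep in seq_len(tcfg$epochs)) {
      lr <- epoch_lr(tcfg, ep)
      ord <- sample.int(n)
      losses <- numeric(n)
      bstart <- seq(1L, n, by = tcfg$batch_size)
      for (bs in bstart) {
        idx <- ord[bs:min(bs + tcfg$batch_size - 1L, n)]
        acc <- NULL
        for (i in idx) {
          fw <- .net_forward(miniloops[[i]], weights, mcfg)
          y <- labels[i]
          p <- min(max(fw$prob, 1e-12), 1 - 1e-12)
          losses[match(i, ord)] <- -(y * log(p) + (1 - y) * log(1 - p))
          g <- .net_backward(fw$prob - y, fw, weights, mcfg)
          acc <- if (is.null(acc)) g else .wt_axpy(acc, g)
        }
        if (mcfg$freeze_prefix_layers > 0L) {
          keep <- seq_len(min(mcfg$freeze_prefix_layers,
                              length(acc$backbone)))
          for (l in keep) acc$backbone[[l]] <- .wt_zero_like(acc$backbone[[l]])
        }
        # heavy-ball SGD: v <- momentum * v + mean batch gradient
        acc <- .wt_axpy(acc, acc, 1 / length(idx) - 1) # acc / batch size
        velocity <- if (is.null(velocity)) acc
        else .wt_axpy(acc, velocity, tcfg$momentum)
        weights <- .wt_axpy(weights, velocity, -lr)
      }
      history[ep] <- mean(losses)
    }
  })
  list(weights = weights, history = history, mcfg = mcfg, tcfg = tcfg)
}

#' Majority-vote case aggregation
#'
#' Each mini-loop votes malignant iff its probability is at least
#' `threshold`; the case label is the majority, a tie resolving to the mean
#' probability compared against the threshold. The case probability (used
#' for ROC analysis) is the mean of the mini-loop probabilities.
#'
#' @param probs mini-loop probabilities (>= 1).
#' @param threshold vote threshold (default 0.5).
#' @param case_id optional identifier.
#' @return A `case_prediction`: `case_id`, `miniloop_probs`, `case_prob`,
#'   `case_label`, `threshold`.
#' @export
aggregate_case <- function(probs, threshold = 0.5, case_id = NULL) {
  if (!length(probs)) stop("no mini-loop probabilities to aggregate")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  votes <- sum(probs >= threshold)
  n <- length(probs)
  case_prob <- mean(probs)
  label <- if (votes * 2L == n) as.integer(case_prob >= threshold)
  else as.integer(votes > n / 2)
  structure(list(case_id = case_id, miniloop_probs = probs,
                 case_prob = case_prob, case_label = label,
                 threshold = threshold),
            class = "case_prediction")
}
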