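# Native neural-network primitives: 3x3 convolution (im2col), 2x2 max
# pooling, global average pooling, LSTM cells and a linear head, each with
# hand-written backward passes. Shapes are small (32x32 to 224x224 crops,
# 3-step sequences), so plain matrix algebra is sufficient; correctness of
# every backward pass is pinned by finite-difference tests.

.im2col_cache <- new.env(parent = emptyenv())

# column-index matrix mapping a padded H+2 x W+2 x C array to (H*W) x (9C)
# patch rows, cached per shape
.im2col_idx <- function(H, W, C) {
  key <- paste(H, W, C, sep = "x")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L; Wp <- W + 2L
  out_pos <- as.vector(outer(seq_len(H), seq_len(W), function(i, j)
    i + Hp * (j - 1L))) # top-left corner of each patch in the padded array
  offs <- as.vector(outer(0:2, 0:2, function(di, dj) di + Hp * dj))
  offs <- as.vector(outer(offs, (seq_len(C) - 1L) * Hp * Wp, `+`))
  idx <- outer(out_pos, offs, `+`)
  .im2col_cache[[key]] <- idx
  idx
}

# x: H x W x C array; wts: list(W = (9C) x K, b = K)
.conv3x3_forward <- function(x, wts) {
  dm <- dim(x)
  H <- dm[1L]; W <- dm[2L]; C <- dm[3L]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  idx <- .im2col_idx(H, W, C)
  cols <- matrix(xp[idx], nrow = H * W)
  out <- sweep(cols %*% wts$W, 2L, wts$b, `+`)
  list(out = array(out, c(H, W, ncol(wts$W))),
       cache = list(cols = cols, H = H, W = W, C = C))
}

# permutation turning a (9C x K) kernel into its flipped transpose
# (9K x C), cached per channel pair; used for the input gradient
.convT_perm_cache <- new.env(parent = emptyenv())

.convT_perm <- function(C, K) {
  key <- paste(C, K, sep = "x")
  got <- .convT_perm_cache[[key]]
  if (!is.null(got)) return(got)
  P <- integer(9L * K * C)
  for (cc in seq_len(C)) for (k in seq_len(K))
    for (dj in 0:2) for (di in 0:2) {
      dst <- 9L * (k - 1L) + 3L * dj + di + 1L + 9L * K * (cc - 1L)
      src <- 9L * (cc - 1L) + 3L * (2L - dj) + (2L - di) + 1L +
        9L * C * (k - 1L)
      P[dst] <- src
    }
  .convT_perm_cache[[key]] <- P
  P
}

.conv3x3_backward <- function(dout, cache, wts, need_dx = TRUE) {
  H <- cache$H; W <- cache$W; C <- cache$C
  K <- ncol(wts$W)
  dmat <- matrix(dout, nrow = H * W)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dx <- NULL
  if (need_dx) {
    # input gradient = same-padded convolution of dout with the spatially
    # flipped, channel-transposed kernels
    dp <- array(0, c(H + 2L, W + 2L, K))
    dp[2:(H + 1L), 2:(W + 1L), ] <- dout
    cols <- matrix(dp[.im2col_idx(H, W, K)], nrow = H * W)
    Wrot <- matrix(as.vector(wts$W)[.convT_perm(C, K)], 9L * K, C)
    dx <- array(cols %*% Wrot, c(H, W, C))
  }
  list(dW = dW, db = db, dx = dx)
}

.relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
.relu_backward <- function(dout, mask) dout * mask

# 2x2 stride-2 max pooling; ties route to the first of the four slots
.maxpool2_forward <- function(x) {
  dm <- dim(x)
  H <- dm[1L]; W <- dm[2L]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  a <- x[io, jo, , drop = FALSE]; b <- x[io + 1L, jo, , drop = FALSE]
  cc <- x[io, jo + 1L, , drop = FALSE]; d <- x[io + 1L, jo + 1L, , drop = FALSE]
  out <- pmax(a, b, cc, d)
  m1 <- a == out
  m2 <- !m1 & (b == out)
  m3 <- !m1 & !m2 & (cc == out)
  m4 <- !m1 & !m2 & !m3
  list(out = out, cache = list(m = list(m1, m2, m3, m4), H = H, W = W))
}

.maxpool2_backward <- function(dout, cache) {
  H <- cache$H; W <- cache$W
  dx <- array(0, c(H, W, dim(dout)[3L]))
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  m <- cache$m
  dx[io, jo, ] <- dout * m[[1L]]
  dx[io + 1L, jo, ] <- dout * m[[2L]]
  dx[io, jo + 1L, ] <- dout * m[[3L]]
  dx[io + 1L, jo + 1L, ] <- dout * m[[4L]]
  dx
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# parameter-free layer normalization of a vector
.layernorm_forward <- function(x, eps = 1e-5) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  sd_ <- sqrt(v + eps)
  xhat <- (x - mu) / sd_
  list(out = xhat, cache = list(xhat = xhat, sd = sd_))
}

.layernorm_backward <- function(dout, cache) {
  xhat <- cache$xhat
  (dout - mean(dout) - xhat * mean(dout * xhat)) / cache$sd
}

# ---- LSTM ----------------------------------------------------------------
# Gate order i, f, g, o. wts: W (4H x n_in), U (4H x n_h), b (4H).

.lstm_forward <- function(X, wts, reverse = FALSE) {
  Tn <- nrow(X)
  nh <- ncol(wts$U)
  steps <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  h <- numeric(nh); cst <- numeric(nh)
  H <- matrix(0, Tn, nh)
  caches <- vector("list", Tn)
  for (s in seq_len(Tn)) {
    t <- steps[s]
    x <- X[t, ]
    z <- as.vector(wts$W %*% x + wts$U %*% h + wts$b)
    i <- .sigmoid(z[1:nh]); f <- .sigmoid(z[nh + 1:nh])
    g <- tanh(z[2 * nh + 1:nh]); o <- .sigmoid(z[3 * nh + 1:nh])
    c_new <- f * cst + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    caches[[s]] <- list(x = x, h_prev = h, c_prev = cst, i = i, f = f, g = g,
                        o = o, c = c_new, tc = tc)
    h <- h_new; cst <- c_new
    H[t, ] <- h_new
  }
  list(H = H, caches = caches, steps = steps)
}

.lstm_backward <- function(dH, fw, wts) {
  Tn <- nrow(dH)
  nh <- ncol(wts$U)
  dW <- matrix(0, nrow(wts$W), ncol(wts$W))
  dU <- matrix(0, nrow(wts$U), ncol(wts$U))
  db <- numeric(length(wts$b))
  dX <- matrix(0, Tn, ncol(wts$W))
  dh_next <- numeric(nh); dc_next <- numeric(nh)
  for (s in rev(seq_len(Tn))) {
    t <- fw$steps[s]
    ca <- fw$caches[[s]]
    dh <- dH[t, ] + dh_next
    dc <- dc_next + dh * ca$o * (1 - ca$tc^2)
    do_ <- dh * ca$tc * ca$o * (1 - ca$o)
    di <- dc * ca$g * ca$i * (1 - ca$i)
    df <- dc * ca$c_prev * ca$f * (1 - ca$f)
    dg <- dc * ca$i * (1 - ca$g^2)
    dz <- c(di, df, dg, do_)
    dW <- dW + tcrossprod(dz, ca$x)
    dU <- dU + tcrossprod(dz, ca$h_prev)
    db <- db + dz
    dX[t, ] <- as.vector(crossprod(wts$W, dz))
    dh_next <- as.vector(crossprod(wts$U, dz))
    dc_next <- dc * ca$f
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# ---- weight-tree helpers -------------------------------------------------

.wt_zero_like <- function(w) {
  if (is.list(w)) lapply(w, .wt_zero_like) else w * 0
}

.wt_axpy <- function(acc, g, a = 1) { # acc + a * g, matching structure
  if (is.list(acc)) {
    for (nm in seq_along(acc)) acc[[nm]] <- .wt_axpy(acc[[nm]], g[[nm]], a)
    acc
  } else acc + a * g
}

.wt_flatten <- function(w) {
  if (is.list(w)) unlist(lapply(w, .wt_flatten), use.names = FALSE)
  else as.vector(w)
}
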