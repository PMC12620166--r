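# Small convolutional denoiser (two 3x3 conv layers, ReLU in between,
# residual connection) with hand-written forward/backward passes. Real and
# imaginary parts of each echo are stacked in the channel dimension. The
# full-scale trained network is not shippable; this stands in as a compact
# learnable denoiser with the same role in the unrolled alternation.

# im2col for 3x3 kernels with zero padding 1: [H, W, C] -> [(H*W), 9*C].
im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  M <- matrix(0, H * W, 9 * C)
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    blk <- xp[di + seq_len(H), dj + seq_len(W), , drop = FALSE]
    M[, (k - 1) * C + seq_len(C)] <- matrix(blk, H * W, C)
  }
  M
}

# Adjoint of im2col3: scatter-add [(H*W), 9*C] back to [H, W, C].
col2im3 <- function(M, H, W, C) {
  xp <- array(0, c(H + 2, W + 2, C))
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    xp[di + seq_len(H), dj + seq_len(W), ] <-
      xp[di + seq_len(H), dj + seq_len(W), , drop = FALSE] +
      array(M[, (k - 1) * C + seq_len(C)], c(H, W, C))
  }
  xp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

#' Initialize per-iteration weights of the conv denoiser
#'
#' He-initialized first layer, zero second layer so that every denoiser
#' starts as the identity (residual connection), which keeps the initial
#' unrolled reconstruction equal to the plain DC iteration.
#'
#' @param n_echoes number of echoes (channels are 2 per echo).
#' @param n_iterations unrolled iterations, one weight set each.
#' @param n_features hidden feature maps (default 16).
#' @param seed integer seed.
#' @return List of `n_iterations` weight sets `(W1, b1, W2, b2)`.
#' @export
cnn_init_weights <- function(n_echoes, n_iterations = 5, n_features = 16,
                             seed = 0) {
  Cin <- 2L * n_echoes
  with_seed(seed, lapply(seq_len(n_iterations), function(k) {
    list(W1 = matrix(stats::rnorm(9 * Cin * n_features,
                                  sd = sqrt(2 / (9 * Cin))), 9 * Cin, n_features),
         b1 = numeric(n_features),
         W2 = matrix(0, 9 * n_features, Cin),
         b2 = numeric(Cin))
  }))
}

# Complex stack [pe, ro, S, E] -> per-slice real channel arrays and back.
stack_to_channels <- function(x, s) {
  d <- dim(x)
  ch <- array(0, c(d[1], d[2], 2L * d[4]))
  ch[, , seq_len(d[4])] <- Re(x[, , s, ])
  ch[, , d[4] + seq_len(d[4])] <- Im(x[, , s, ])
  ch
}

channels_to_complex <- function(ch, n_echo) {
  d <- dim(ch)
  ch[, , seq_len(n_echo), drop = FALSE] +
    1i * ch[, , n_echo + seq_len(n_echo), drop = FALSE]
}

# Forward pass of one denoiser application on a whole stack.
cnn_denoise <- function(x, w, cache = FALSE) {
  d <- dim(x); n_echo <- d[4]; H <- d[1]; W <- d[2]
  out <- x
  ctx <- if (cache) vector("list", d[3]) else NULL
  for (s in seq_len(d[3])) {
    ch <- stack_to_channels(x, s)
    M1 <- im2col3(ch)
    A1 <- sweep(M1 %*% w$W1, 2, w$b1, "+")
    Z1 <- pmax(A1, 0)
    M2 <- im2col3(array(Z1, c(H, W, ncol(w$W1))))
    A2 <- sweep(M2 %*% w$W2, 2, w$b2, "+")
    res <- channels_to_complex(array(A2, c(H, W, 2L * n_echo)), n_echo)
    out[, , s, ] <- x[, , s, ] + res[, , , drop = TRUE]
    if (cache) ctx[[s]] <- list(M1 = M1, relu = A1 > 0, M2 = M2)
  }
  list(out = out, ctx = ctx)
}

# Backward pass: gradient w.r.t. the input stack and the weights.
cnn_denoise_backward <- function(g, ctx, w) {
  d <- dim(g); n_echo <- d[4]; H <- d[1]; W <- d[2]
  nf <- ncol(w$W1); Cin <- 2L * n_echo
  gx <- g # residual path
  gW1 <- w$W1 * 0; gb1 <- w$b1 * 0; gW2 <- w$W2 * 0; gb2 <- w$b2 * 0
  for (s in seq_len(d[3])) {
    gch <- array(0, c(H, W, Cin))
    gch[, , seq_len(n_echo)] <- Re(g[, , s, ])
    gch[, , n_echo + seq_len(n_echo)] <- Im(g[, , s, ])
    gA2 <- matrix(gch, H * W, Cin)
    cx <- ctx[[s]]
    gW2 <- gW2 + crossprod(cx$M2, gA2)
    gb2 <- gb2 + colSums(gA2)
    gZ1 <- col2im3(gA2 %*% t(w$W2), H, W, nf)
    gA1 <- matrix(gZ1, H * W, nf) * cx$relu
    gW1 <- gW1 + crossprod(cx$M1, gA1)
    gb1 <- gb1 + colSums(gA1)
    gin <- col2im3(gA1 %*% t(w$W1), H, W, Cin)
    gx[, , s, ] <- gx[, , s, ] +
      (gin[, , seq_len(n_echo), drop = TRUE] +
         1i * gin[, , n_echo + seq_len(n_echo), drop = TRUE])
  }
  list(gx = gx, gw = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}
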