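#' Mono-exponential multi-echo signal model
#'
#' Signal magnitude at echo time TE for effective transverse relaxation:
#' `s(TE) = s0 * exp(-TE / T2*)`.
#'
#' @param s0 signal magnitude at TE = 0 (arbitrary units, >= 0).
#' @param t2star_ms effective relaxation time in ms (> 0).
#' @param te_ms echo times in ms.
#' @return Numeric vector of magnitudes, one per echo. `s0` and `t2star_ms`
#'   may be vectors (voxelwise use); then a matrix `[voxel, echo]` is
#'   returned.
#' @examples
#' predict_signal(100, 50, 5) # 100 * exp(-0.1)
#' @export
predict_signal <- function(s0, t2star_ms, te_ms) {
  if (any(s0 < 0)) stop("s0 must be non-negative")
  if (any(t2star_ms <= 0)) stop("t2star_ms must be positive")
  if (length(s0) == 1L && length(t2star_ms) == 1L)
    return(s0 * exp(-te_ms / t2star_ms))
  outer(s0, rep(1, length(te_ms))) *
    exp(-outer(1 / t2star_ms, te_ms))
}

#' Voxelwise log-linear least-squares T2* fit
#'
#' Fits `ln s = ln s0 - TE / T2*` per voxel by unweighted linear least
#' squares on `ln(max(s, eps))`, the differentiable closed form used inside
#' the physics-informed loss. Degenerate voxels (non-negative slope, e.g.
#' all-zero signal) are flagged invalid and their exported T2* set to the
#' clamp maximum; the fitted magnitudes themselves stay unclamped so that
#' gradients are preserved.
#'
#' @param stack magnitude array `[pe, ro, slice, echo]` (or matrix
#'   `[voxel, echo]`).
#' @param te_ms echo times (ms), length equal to the echo dimension.
#' @param mask optional logical array `[pe, ro, slice]` selecting voxels to
#'   fit; others get NA maps and zero fitted signal.
#' @param clamp_ms exported T2* range, default `c(1, 1000)` ms.
#' @param eps_rel floor on the log argument, relative to `max(stack)`.
#' @return A list of class `relaxometry_fit`: `t2star_ms`, `s0`, `valid`
#'   (maps shaped like a slice stack or vectors for matrix input), `fitted`
#'   (same shape as `stack`), `te_ms`.
#' @export
fit_monoexp <- function(stack, te_ms, mask = NULL, clamp_ms = c(1, 1000),
                        eps_rel = 1e-6) {
  d <- dim(stack)
  as_matrix <- length(d) == 2L
  n_echo <- d[length(d)]
  if (n_echo != length(te_ms)) stop("echo dimension must match length(te_ms)")
  if (n_echo < 2L) stop("need at least two echoes")
  S <- matrix(stack, ncol = n_echo)
  if (!is.null(mask)) {
    sel <- which(as.logical(mask))
  } else sel <- seq_len(nrow(S))
  eps <- eps_rel * max(S, 0)
  if (eps <= 0) eps <- eps_rel
  u <- log(pmax(S[sel, , drop = FALSE], eps))
  te <- as.numeric(te_ms)
  mt <- mean(te); ct <- te - mt; vt <- sum(ct^2)
  slope <- as.vector(u %*% ct) / vt
  icept <- rowMeans(u) - slope * mt
  t2 <- ifelse(slope < 0, -1 / slope, Inf)
  valid <- is.finite(t2)
  t2c <- pmin(pmax(t2, clamp_ms[1]), clamp_ms[2])
  fitted_sel <- exp(outer(icept, rep(1, n_echo)) + outer(slope, te))

  vox_shape <- if (as_matrix) nrow(S) else d[-length(d)]
  t2_map <- array(NA_real_, vox_shape); s0_map <- array(NA_real_, vox_shape)
  ok_map <- array(FALSE, vox_shape); fit_full <- array(0, dim(stack) %||% length(stack))
  t2_map[sel] <- t2c; s0_map[sel] <- exp(icept); ok_map[sel] <- valid
  Ffit <- matrix(0, nrow(S), n_echo); Ffit[sel, ] <- fitted_sel
  fit_full <- array(Ffit, if (as_matrix) dim(S) else d)
  structure(list(t2star_ms = t2_map, s0 = s0_map, valid = ok_map,
                 fitted = fit_full, te_ms = te, clamp_ms = clamp_ms),
            class = "relaxometry_fit")
}

#' @export
print.relaxometry_fit <- function(x, ...) {
  cat(sprintf("<relaxometry_fit> %d voxels fitted, %d valid; T2* median %.1f ms\n",
              sum(!is.na(x$t2star_ms)), sum(x$valid),
              stats::median(x$t2star_ms[x$valid], na.rm = TRUE)))
  invisible(x)
}

# Symmetric hat matrix of the log-linear fit: projects a voxel's log-signal
# onto span{1, TE}. fitted = exp(P %*% log s).
fit_hat_matrix <- function(te_ms) {
  X <- cbind(1, as.numeric(te_ms))
  X %*% solve(crossprod(X), t(X))
}

#' Physics-informed loss: deviation from mono-exponential decay
#'
#' Per voxel, one minus the empirical correlation coefficient across echoes
#' between the reconstructed magnitudes and their own mono-exponential
#' least-squares fit; averaged over brain-mask voxels. Motion-induced B0
#' changes disturb the mono-exponential decay and raise the loss, which is
#' what makes it a self-supervised detection signal. Voxels whose signal (or
#' fit) has zero variance across echoes are excluded from the average rather
#' than scored 0, so wiping out signal is never rewarded.
#'
#' @param stack magnitude array `[pe, ro, slice, echo]` or matrix
#'   `[voxel, echo]`.
#' @param te_ms echo times (ms).
#' @param brain_mask logical array `[pe, ro, slice]` (or voxel vector);
#'   `NULL` uses all voxels.
#' @return Scalar loss in `[0, 2]`.
#' @export
physics_loss <- function(stack, te_ms, brain_mask = NULL) {
  physics_loss_full(stack, te_ms, brain_mask)$loss
}

# Shared forward pass; returns intermediates needed by the gradient.
physics_loss_full <- function(stack, te_ms, brain_mask = NULL,
                              eps_rel = 1e-6) {
  n_echo <- length(te_ms)
  S <- matrix(stack, ncol = n_echo)
  sel <- if (is.null(brain_mask)) seq_len(nrow(S)) else which(as.logical(brain_mask))
  if (length(sel) == 0L) stop("empty brain mask")
  A <- S[sel, , drop = FALSE]
  eps <- eps_rel * max(S, 0); if (eps <= 0) eps <- eps_rel
  P <- fit_hat_matrix(te_ms)
  U <- log(pmax(A, eps))
  B <- exp(U %*% P) # P symmetric
  ac <- A - rowMeans(A); bc <- B - rowMeans(B)
  na <- sqrt(rowSums(ac^2)); nb <- sqrt(rowSums(bc^2))
  valid <- na > 0 & nb > 0
  corr <- rep(NA_real_, nrow(A))
  corr[valid] <- rowSums(ac * bc)[valid] / (na[valid] * nb[valid])
  loss <- mean(1 - corr[valid])
  list(loss = loss, A = A, B = B, ac = ac, bc = bc, na = na, nb = nb,
       corr = corr, valid = valid, sel = sel, eps = eps, P = P,
       n_vox = nrow(S))
}

# Weighted physics loss and gradient on an already-selected voxel matrix
# A [voxel, echo]; w are per-voxel multiplicities (batch sampling with
# replacement). Returns the loss and dL/dA.
physics_matrix_obj <- function(A, te_ms, w = NULL, eps_rel = 1e-6,
                               want_grad = TRUE) {
  n_echo <- length(te_ms)
  w <- w %||% rep(1, nrow(A))
  eps <- eps_rel * max(A, 0); if (eps <= 0) eps <- eps_rel
  P <- fit_hat_matrix(te_ms)
  B <- exp(log(pmax(A, eps)) %*% P)
  ac <- A - rowMeans(A); bc <- B - rowMeans(B)
  na <- sqrt(rowSums(ac^2)); nb <- sqrt(rowSums(bc^2))
  valid <- na > 0 & nb > 0
  wv <- w * valid
  sw <- sum(wv)
  if (sw == 0) return(list(loss = NA_real_, gA = A * 0, sw = 0))
  corr <- rep(0, nrow(A))
  corr[valid] <- rowSums(ac * bc)[valid] / (na[valid] * nb[valid])
  loss <- sum(wv * (1 - corr)) / sw
  if (!want_grad) return(list(loss = loss, gA = NULL, sw = sw))
  G <- A * 0
  v <- which(valid)
  if (length(v)) {
    acv <- ac[v, , drop = FALSE]; bcv <- bc[v, , drop = FALSE]
    nav <- na[v]; nbv <- nb[v]; cv <- corr[v]
    dcorr_dA <- bcv / (nav * nbv) - cv / nav^2 * acv
    dcorr_dB <- acv / (nav * nbv) - cv / nbv^2 * bcv
    Av <- A[v, , drop = FALSE]; Bv <- B[v, , drop = FALSE]
    uprime <- ifelse(Av > eps, 1 / Av, 0)
    dA_fit <- ((Bv * dcorr_dB) %*% P) * uprime
    G[v, ] <- -(wv[v] / sw) * (dcorr_dA + dA_fit)
  }
  list(loss = loss, gA = G, sw = sw)
}

# Reverse-mode gradient of physics_loss with respect to the input
# magnitudes, including the dependence of the per-voxel fit on the voxel's
# own signal (the fit is recomputed inside the loss). Returns an array
# shaped like `stack`.
physics_loss_grad <- function(stack, te_ms, brain_mask = NULL,
                              eps_rel = 1e-6) {
  f <- physics_loss_full(stack, te_ms, brain_mask, eps_rel)
  n_echo <- length(te_ms)
  G <- matrix(0, f$n_vox, n_echo)
  v <- f$valid
  if (any(v)) {
    nv <- sum(v)
    ac <- f$ac[v, , drop = FALSE]; bc <- f$bc[v, , drop = FALSE]
    na <- f$na[v]; nb <- f$nb[v]; corr <- f$corr[v]
    A <- f$A[v, , drop = FALSE]; B <- f$B[v, , drop = FALSE]
    # dL/dcorr = -1/nv for each valid voxel
    dcorr_dA <- bc / (na * nb) - corr / na^2 * ac
    dcorr_dB <- ac / (na * nb) - corr / nb^2 * bc
    # chain through B = exp(P log(max(A, eps)))
    uprime <- ifelse(A > f$eps, 1 / A, 0)
    dA_fit <- ((B * dcorr_dB) %*% f$P) * uprime
    G[f$sel[v], ] <- -(dcorr_dA + dA_fit) / nv
  }
  array(G, dim(stack) %||% length(stack))
}
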