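#' Configuration of the unrolled data-consistent reconstruction
#'
#' The reconstruction alternates a denoiser and a gradient-descent data
#' consistency (DC) step `n_iterations` times, starting from the zero-filled
#' adjoint image. Real and imaginary parts of every echo form the channel
#' dimension for the learned denoiser.
#'
#' @param n_iterations number of denoiser/DC alternations (default 5).
#' @param eta DC step size; with unit-RSS coil maps the operator norm of
#'   `A^H A` is at most 1, so the default 1 is stable.
#' @param denoiser one of `"identity"`, `"gaussian_smooth"`, `"cnn"`.
#' @param keepcenter force the central 2x2 k-space block into the data term.
#' @param smooth_sigma Gaussian width (voxels) for the smoothing denoiser.
#' @return An object of class `unrolled_config`.
#' @export
unrolled_config <- function(n_iterations = 5, eta = 1,
                            denoiser = c("identity", "gaussian_smooth", "cnn"),
                            keepcenter = TRUE, smooth_sigma = 0.8) {
  denoiser <- match.arg(denoiser)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (eta <= 0) stop("eta must be positive")
  structure(list(n_iterations = as.integer(n_iterations), eta = eta,
                 denoiser = denoiser, keepcenter = keepcenter,
                 smooth_sigma = smooth_sigma),
            class = "unrolled_config")
}

#' Normalize a volume by its maximum image magnitude
#'
#' Scales so that the maximum voxel magnitude of the (zero-filled, coil
#' combined) image volume is 1, as done per 3D volume before reconstruction
#' and detection; the scale is returned for inversion.
#'
#' @param x either an image stack `[pe, ro, slice, echo]`, or a
#'   [kspace_volume()] / 5D k-space array (then `csm` is required to form
#'   the zero-filled image).
#' @param csm [coil_sensitivities()] for k-space input.
#' @return List `data` (normalized, same type as input) and `scale` (the
#'   divisor).
#' @export
normalize_volume <- function(x, csm = NULL) {
  if (inherits(x, "kspace_volume")) {
    if (is.null(csm)) stop("csm required to normalize k-space")
    img <- sense_adjoint(x$data, csm)
    scale <- max(Mod(img))
    if (scale == 0) stop("all-zero volume")
    out <- x; out$data <- x$data / scale
    return(list(data = out, scale = scale))
  }
  if (length(dim(x)) == 5L) {
    if (is.null(csm)) stop("csm required to normalize k-space")
    img <- sense_adjoint(x, csm)
    scale <- max(Mod(img))
  } else scale <- max(Mod(x))
  if (scale == 0) stop("all-zero volume")
  list(data = x / scale, scale = scale)
}

# Multiply a 5D k-space array by a weight plane ([pe,ro] or [pe,ro,slice]).
weight_kspace <- function(y, W) {
  d <- dim(y)
  if (is.matrix(W)) {
    y * as.vector(W)
  } else if (length(dim(W)) == 3L) {
    y * as.vector(array(W, d[1:3])) # recycled over coil, echo
  } else stop("weight plane must be [pe, ro] or [pe, ro, slice]")
}

#' One gradient-descent data-consistency step
#'
#' `x' = x - eta * A^H (W * (A x - y))` with `A` the static multicoil
#' Fourier operator and `W` the (possibly soft) k-space weight plane.
#' Continuous weights down-weight the contribution of motion-affected
#' lines to the data term.
#'
#' @param x image stack `[pe, ro, slice, echo]`.
#' @param y measured (already weighted) k-space `[pe, ro, slice, coil, echo]`.
#' @param weight_plane numeric `[pe, ro]` or `[pe, ro, slice]` weights.
#' @param csm [coil_sensitivities()].
#' @param eta step size.
#' @return Updated image stack.
#' @export
dc_gradient_step <- function(x, y, weight_plane, csm, eta = 1) {
  r <- sense_forward(x, csm) - y
  x - eta * sense_adjoint(weight_kspace(r, weight_plane), csm)
}

denoiser_apply <- function(x, cfg, weights = NULL, iter = 1L, cache = FALSE) {
  switch(cfg$denoiser,
    identity = list(out = x, ctx = NULL),
    gaussian_smooth = list(out = smooth_stack(x, cfg$smooth_sigma), ctx = NULL),
    cnn = {
      if (is.null(weights)) stop("cnn denoiser requested without weights")
      cnn_denoise(x, weights[[iter]], cache = cache)
    })
}

denoiser_backward <- function(g, ctx, cfg, weights = NULL, iter = 1L) {
  switch(cfg$denoiser,
    identity = list(gx = g, gw = NULL),
    gaussian_smooth = list(gx = smooth_stack(g, cfg$smooth_sigma), gw = NULL),
    cnn = cnn_denoise_backward(g, ctx, weights[[iter]]))
}

# Plain (uncentered, unnormalized) batched 2D FFT over the first two dims.
plain_fft2_batch <- function(a, inverse = FALSE) {
  d <- dim(a); k <- prod(d[-c(1L, 2L)])
  m <- array(a, c(d[1L], d[2L], k))
  out <- array(0i, dim(m))
  for (j in seq_len(k))
    out[, , j] <- stats::fft(m[, , j], inverse = inverse)
  array(out, d)
}

# Linear, self-adjoint complex Gaussian smoothing (circular convolution via
# FFT) of an image stack; a simple non-learned denoiser. The wrapped
# symmetric kernel has a real transfer function, which makes the operator
# its own adjoint.
smooth_stack <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  d <- dim(x)
  k1 <- stats::dnorm(ang_dist(d[1]), sd = sigma_vox)
  k2 <- stats::dnorm(ang_dist(d[2]), sd = sigma_vox)
  K <- outer(k1, k2); K <- K / sum(K)
  H <- Re(stats::fft(K))
  X <- plain_fft2_batch(x)
  plain_fft2_batch(X * as.vector(H), inverse = TRUE) / (d[1] * d[2])
}

#' Unrolled data-consistent reconstruction
#'
#' Starts from the zero-filled adjoint of the weighted k-space and
#' alternates denoiser and DC gradient step `cfg$n_iterations` times. The
#' whole map is differentiable with respect to the line weights (used by the
#' self-supervised mask optimization) when the denoiser is.
#'
#' @param y_weighted k-space `[pe, ro, slice, coil, echo]`, already
#'   multiplied by the exclusion-mask weight plane.
#' @param weight_plane the same weights, `[pe, ro]` or `[pe, ro, slice]`
#'   (typically from [expand_mask_keepcenter()]).
#' @param csm [coil_sensitivities()].
#' @param cfg an [unrolled_config()].
#' @param weights per-iteration denoiser weights (cnn only).
#' @param cache keep intermediates for a subsequent backward pass.
#' @return Complex image stack `[pe, ro, slice, echo]`; with `cache = TRUE`
#'   a list `x`, `cache`.
#' @export
unrolled_reconstruct <- function(y_weighted, weight_plane, csm, cfg,
                                 weights = NULL, cache = FALSE) {
  if (inherits(y_weighted, "kspace_volume")) y_weighted <- y_weighted$data
  x <- sense_adjoint(y_weighted, csm)
  zs <- list(); rs <- list(); ctxs <- list()
  for (k in seq_len(cfg$n_iterations)) {
    dn <- denoiser_apply(x, cfg, weights, iter = k, cache = cache)
    z <- dn$out
    r <- sense_forward(z, csm) - y_weighted
    x <- z - cfg$eta * sense_adjoint(weight_kspace(r, weight_plane), csm)
    if (cache) { zs[[k]] <- z; rs[[k]] <- r; ctxs[[k]] <- dn$ctx }
  }
  if (cache) list(x = x, cache = list(zs = zs, rs = rs, ctxs = ctxs))
  else x
}

# Reverse-mode pass of unrolled_reconstruct. `gx` is dL/dx_out under the
# convention dL = Re<g, dx>. Returns the gradient with respect to the 2D
# weight plane (accumulated over coils/echoes/slices as appropriate), to
# the weighted k-space input, and to cnn denoiser weights if present.
unrolled_backward <- function(gx, fwd, y_weighted, weight_plane, csm, cfg,
                              weights = NULL) {
  d <- dim(y_weighted)
  per_slice <- !is.matrix(weight_plane)
  gW <- if (per_slice) array(0, d[1:3]) else matrix(0, d[1], d[2])
  g_ym <- array(0i, d)
  gw_list <- if (identical(cfg$denoiser, "cnn"))
    vector("list", cfg$n_iterations) else NULL
  g <- gx
  for (k in rev(seq_len(cfg$n_iterations))) {
    ag <- sense_forward(g, csm)
    # dL/dW from  x_k = z_k - eta A^H (W r_k)
    contrib <- -cfg$eta * Re(Conj(ag) * fwd$cache$rs[[k]])
    gW <- gW + reduce_to_plane(contrib, per_slice)
    g_ym <- g_ym + cfg$eta * weight_kspace(ag, weight_plane)
    gz <- g - cfg$eta * sense_adjoint(weight_kspace(ag, weight_plane), csm)
    bk <- denoiser_backward(gz, fwd$cache$ctxs[[k]], cfg, weights, iter = k)
    if (!is.null(gw_list)) gw_list[[k]] <- bk$gw
    g <- bk$gx
  }
  g_ym <- g_ym + sense_forward(g, csm) # x_0 = A^H y_m
  list(gW = gW, g_ym = g_ym, g_weights = gw_list)
}

reduce_to_plane <- function(a, per_slice) {
  d <- dim(a)
  if (per_slice) {
    apply(array(a, c(d[1] * d[2] * d[3], prod(d[4:5]))), 1, sum) |>
      array(d[1:3])
  } else {
    matrix(rowSums(matrix(a, d[1] * d[2], prod(d[3:5]))), d[1], d[2])
  }
}
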