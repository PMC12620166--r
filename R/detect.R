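#' Configuration of the self-supervised line detection
#'
#' Hyperparameters of the exclusion-mask optimization: Adam with learning
#' rate 0.01 for 100 epochs on a batch of 20 slices, regularization weights
#' `lambda_reg = 0.005` and `lambda_center = 2`, slice selection by mean
#' susceptibility gradient below 80 uT/m among the most inferior eight
#' slices with over 20% brain voxels.
#'
#' @param lr Adam learning rate.
#' @param epochs optimization steps (one slice batch each).
#' @param batch_slices slices per step, sampled with replacement from the
#'   selected set.
#' @param lambda_reg,lambda_center exclusion-regularizer weights.
#' @param sg_threshold susceptibility-gradient cutoff (uT/m) for slice
#'   selection.
#' @param brain_fraction_min minimum brain fraction of a usable slice.
#' @param n_select_slices number of (most inferior) slices to optimize on.
#' @param keepcenter apply the KeepCenter override inside the optimization.
#' @param squash_gain gain of the logistic squashing
#'   `mask = sigmoid(gain * p)`. Adam moves each parameter by at most about
#'   `lr * epochs` = 1.0 under the default budget; the default gain of 6
#'   makes that span cover the usable mask range (0.95 down to 0.05), so a
#'   line with a consistently corrupted gradient can be fully excluded
#'   within the budget.
#' @param init_mask initial mask value (near keep-all).
#' @param seed integer seed; the optimization is deterministic given it.
#' @return An object of class `detect_config`.
#' @export
detect_config <- function(lr = 0.01, epochs = 100, batch_slices = 20,
                          lambda_reg = 0.005, lambda_center = 2,
                          sg_threshold = 80, brain_fraction_min = 0.2,
                          n_select_slices = 8, keepcenter = TRUE,
                          squash_gain = 6, init_mask = 0.95, seed = 0) {
  stopifnot(lr > 0, epochs >= 1, batch_slices >= 1, lambda_center >= 0,
            squash_gain > 0, init_mask > 0, init_mask < 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_slices = as.integer(batch_slices),
                 lambda_reg = lambda_reg, lambda_center = lambda_center,
                 sg_threshold = sg_threshold,
                 brain_fraction_min = brain_fraction_min,
                 n_select_slices = as.integer(n_select_slices),
                 keepcenter = keepcenter, squash_gain = squash_gain,
                 init_mask = init_mask, seed = seed),
            class = "detect_config")
}

#' Regularizer against unnecessary line exclusion
#'
#' `L = lambda_reg * [(1 - mean(w)) + lambda_center * (1 - mean(w_central))]`
#' where the central window covers the ten central PE lines (half-open
#' `[Y/2 - 5, Y/2 + 5)` in 0-based indices). Penalizes excluded lines
#' overall and the k-space centre more strongly.
#'
#' @param mask_weights mask values in `[0, 1]`, length Y (even, >= 10).
#' @param lambda_reg,lambda_center regularizer weights.
#' @return Scalar penalty.
#' @examples
#' exclusion_regularizer(rep(0, 92), 0.005, 2) # 0.005 * (1 + 2)
#' @export
exclusion_regularizer <- function(mask_weights, lambda_reg = 0.005,
                                  lambda_center = 2) {
  Y <- length(mask_weights)
  if (Y < 10L) stop("need at least 10 PE lines")
  ctr <- central_window_10(Y)
  lambda_reg * ((1 - mean(mask_weights)) +
                  lambda_center * (1 - mean(mask_weights[ctr])))
}

# 0-based [Y/2 - 5, Y/2 + 5) -> 1-based Y/2 - 4 .. Y/2 + 5 (10 lines).
central_window_10 <- function(Y) seq.int(Y %/% 2L - 4L, Y %/% 2L + 5L)

exclusion_regularizer_grad <- function(mask_weights, lambda_reg, lambda_center) {
  Y <- length(mask_weights)
  g <- rep(-lambda_reg / Y, Y)
  g[central_window_10(Y)] <- g[central_window_10(Y)] -
    lambda_reg * lambda_center / 10
  g
}

#' Select slices for the mask optimization
#'
#' Keeps slices (ordered inferior to superior) with more than the minimum
#' brain fraction and mean susceptibility gradient below the threshold, and
#' returns the most inferior `n_select_slices` of them.
#'
#' @param per_slice_mean_sg mean susceptibility gradient (uT/m) per slice.
#' @param brain_fraction_per_slice fraction of brain voxels per slice.
#' @param cfg a [detect_config()].
#' @return Integer vector of selected slice indices (1-based).
#' @export
select_optimization_slices <- function(per_slice_mean_sg,
                                       brain_fraction_per_slice,
                                       cfg = detect_config()) {
  ok <- which(brain_fraction_per_slice > cfg$brain_fraction_min &
                per_slice_mean_sg < cfg$sg_threshold)
  if (length(ok) == 0L)
    stop(sprintf(
      "no slice passes selection (brain fraction > %.2f, mean sg < %g uT/m)",
      cfg$brain_fraction_min, cfg$sg_threshold))
  ok[seq_len(min(cfg$n_select_slices, length(ok)))]
}

slice_parity <- function(s) if ((s - 1L) %% 2L == 0L) "even" else "odd"

#' Self-supervised optimization of Even/Odd exclusion masks
#'
#' Optimizes one continuous exclusion mask per interleaved slice package by
#' minimizing the physics-informed loss of the reconstruction plus the
#' exclusion regularizer, with the reconstruction (and any denoiser
#' weights) frozen. The parameter vector of length 2Y is squashed to (0, 1)
#' by a gain-logistic and updated with Adam; gradients flow through the
#' k-space multiplication, the DC weights, the unrolled reconstruction, the
#' magnitude, and the differentiable log-linear fit inside the loss.
#' The returned masks are continuous (not binarized).
#'
#' @param y_corrupt a [kspace_volume()] with the motion-corrupted data.
#' @param csm [coil_sensitivities()].
#' @param recon_cfg an [unrolled_config()] (weights frozen).
#' @param brain_mask logical array `[pe, ro, slice]`.
#' @param sg_map susceptibility-gradient map (uT/m), same shape.
#' @param cfg a [detect_config()].
#' @param denoiser_weights frozen cnn weights if `recon_cfg$denoiser == "cnn"`.
#' @return List of class `mask_optimization`: `mask_even`, `mask_odd`
#'   ([exclusion_mask()]), `loss_history` (data.frame epoch/physics/reg/total),
#'   `selected_slices`, `scale`, `config`.
#' @export
optimize_exclusion_masks <- function(y_corrupt, csm, recon_cfg = unrolled_config(),
                                     brain_mask, sg_map, cfg = detect_config(),
                                     denoiser_weights = NULL) {
  d <- dim(y_corrupt$data)
  Y <- d[1L]; n_slices <- d[3L]
  te <- y_corrupt$te_ms
  nz <- normalize_volume(y_corrupt, csm)
  y <- nz$data$data
  csm_arr <- if (inherits(csm, "coil_sensitivities")) csm$csm else csm

  bfrac <- vapply(seq_len(n_slices), function(s) mean(brain_mask[, , s]),
                  numeric(1))
  msg <- vapply(seq_len(n_slices), function(s) {
    b <- brain_mask[, , s]
    if (!any(b)) return(Inf)
    mean(sg_map[, , s][b])
  }, numeric(1))
  selected <- select_optimization_slices(msg, bfrac, cfg)

  gain <- cfg$squash_gain
  p <- rep(logit(cfg$init_mask) / gain, 2L * Y) # [even | odd]
  opt <- adam_init(list(p = p))
  hist <- data.frame(epoch = seq_len(cfg$epochs), physics = NA_real_,
                     reg = NA_real_, total = NA_real_)

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      batch <- sample(selected, cfg$batch_slices, replace = TRUE)
      counts <- table(batch)
      gp <- numeric(2L * Y)
      phys_num <- 0; phys_den <- 0
      for (pkg in c("even", "odd")) {
        idx <- if (pkg == "even") seq_len(Y) else Y + seq_len(Y)
        m <- sigmoid(gain * p[idx])
        sl <- as.integer(names(counts))
        sl <- sl[vapply(sl, slice_parity, character(1)) == pkg]
        if (length(sl) > 0L) {
          w_cnt <- as.numeric(counts[as.character(sl)])
          res <- package_loss_and_grad(y, csm_arr, sl, w_cnt, m, te,
                                       recon_cfg, cfg$keepcenter,
                                       denoiser_weights, brain_mask)
          if (!is.finite(res$loss)) {
            warning("non-finite physics loss; aborting optimization")
            attr(hist, "aborted") <- TRUE
            break
          }
          phys_num <- phys_num + res$loss * res$sw
          phys_den <- phys_den + res$sw
          gl <- res$g_line
        } else gl <- numeric(Y)
        gl <- gl + exclusion_regularizer_grad(m, cfg$lambda_reg,
                                              cfg$lambda_center)
        gp[idx] <- gl * gain * m * (1 - m)
      }
      m_even <- sigmoid(gain * p[seq_len(Y)])
      m_odd <- sigmoid(gain * p[Y + seq_len(Y)])
      reg <- exclusion_regularizer(m_even, cfg$lambda_reg, cfg$lambda_center) +
        exclusion_regularizer(m_odd, cfg$lambda_reg, cfg$lambda_center)
      hist$physics[ep] <- phys_num / max(phys_den, 1)
      hist$reg[ep] <- reg
      hist$total[ep] <- hist$physics[ep] + reg
      upd <- adam_step(opt, list(p = p), list(p = gp), cfg$lr)
      opt <- upd$state; p <- upd$params$p
    }
  })

  structure(list(
    mask_even = exclusion_mask(sigmoid(gain * p[seq_len(Y)]), "even"),
    mask_odd = exclusion_mask(sigmoid(gain * p[Y + seq_len(Y)]), "odd"),
    loss_history = hist, selected_slices = selected, scale = nz$scale,
    config = cfg), class = "mask_optimization")
}

#' @export
print.mask_optimization <- function(x, ...) {
  cat(sprintf("<mask_optimization> %d epochs; final total loss %.4f\n",
              nrow(x$loss_history), utils::tail(x$loss_history$total, 1)))
  cat(sprintf("  even mask: mean %.3f, %d lines < 0.5\n",
              mean(x$mask_even$line_weights),
              sum(x$mask_even$line_weights < 0.5)))
  cat(sprintf("  odd  mask: mean %.3f, %d lines < 0.5\n",
              mean(x$mask_odd$line_weights),
              sum(x$mask_odd$line_weights < 0.5)))
  invisible(x)
}

# Physics loss and its gradient w.r.t. one package's line weights, for the
# given slices (with multiplicities) of the normalized corrupt k-space.
package_loss_and_grad <- function(y, csm_arr, slices, w_cnt, m, te,
                                  recon_cfg, keepcenter, denoiser_weights,
                                  brain_mask) {
  d <- dim(y)
  Wp <- expand_mask_keepcenter(m, d[2L], keepcenter)
  yg <- y[, , slices, , , drop = FALSE]
  cs <- coil_sensitivities(csm_arr[, , slices, , drop = FALSE],
                           normalize = FALSE)
  ym <- weight_kspace(yg, Wp)
  fwd <- unrolled_reconstruct(ym, Wp, cs, recon_cfg, denoiser_weights,
                              cache = TRUE)
  mag <- Mod(fwd$x) # [pe, ro, nsl, echo]
  dm <- dim(mag)
  bm <- brain_mask[, , slices, drop = FALSE]
  vox <- which(bm)
  A <- matrix(mag, ncol = dm[4L])[vox, , drop = FALSE]
  slice_of_vox <- ((vox - 1L) %/% (dm[1L] * dm[2L])) + 1L
  wv <- w_cnt[slice_of_vox]
  obj <- physics_matrix_obj(A, te, w = wv)
  if (!is.finite(obj$loss))
    return(list(loss = obj$loss, sw = obj$sw, g_line = numeric(d[1L])))
  gs <- matrix(0, prod(dm[1:3]), dm[4L])
  gs[vox, ] <- obj$gA
  gs <- array(gs, dm)
  xr <- fwd$x
  amp <- Mod(xr); amp[amp == 0] <- 1
  gx <- gs * xr / amp
  bk <- unrolled_backward(gx, fwd, ym, Wp, cs, recon_cfg, denoiser_weights)
  gW <- bk$gW + reduce_to_plane(Re(Conj(bk$g_ym) * yg), per_slice = FALSE)
  if (keepcenter) { # forced pixels carry no line-weight gradient
    Y <- d[1L]
    gW[c(Y %/% 2L, Y %/% 2L + 1L), c(d[2L] %/% 2L, d[2L] %/% 2L + 1L)] <- 0
  }
  list(loss = obj$loss, sw = obj$sw, g_line = rowSums(gW))
}

#' Assign the Even/Odd masks to every slice
#'
#' Slice `s` (0-based) receives the even-package mask when `s` is even,
#' the odd-package mask otherwise; `parity_flip` inverts the convention.
#'
#' @param mask_even,mask_odd [exclusion_mask()] objects.
#' @param n_slices number of slices.
#' @param parity_flip invert the package labelling.
#' @return List of `n_slices` exclusion masks.
#' @export
masks_for_all_slices <- function(mask_even, mask_odd, n_slices,
                                 parity_flip = FALSE) {
  if (n_slices < 1) stop("n_slices must be >= 1")
  lapply(seq_len(n_slices), function(s) {
    even <- ((s - 1L) %% 2L == 0L)
    if (parity_flip) even <- !even
    if (even) mask_even else mask_odd
  })
}

#' Reconstruct a volume under per-package exclusion masks
#'
#' Expands the Even/Odd masks to per-slice weight planes (KeepCenter as
#' configured), multiplies them into the k-space, and runs the unrolled
#' reconstruction jointly over all slices.
#'
#' @param y a [kspace_volume()] (normalized or raw).
#' @param mask_even,mask_odd [exclusion_mask()] objects, or a single mask
#'   passed as `mask_even` to be used for all slices.
#' @param csm [coil_sensitivities()].
#' @param recon_cfg an [unrolled_config()].
#' @param denoiser_weights cnn weights when configured.
#' @param keepcenter override; defaults to `recon_cfg$keepcenter`.
#' @return Complex image stack `[pe, ro, slice, echo]`.
#' @export
reconstruct_with_masks <- function(y, mask_even, mask_odd = mask_even, csm,
                                   recon_cfg = unrolled_config(),
                                   denoiser_weights = NULL,
                                   keepcenter = recon_cfg$keepcenter) {
  yd <- if (inherits(y, "kspace_volume")) y$data else y
  d <- dim(yd)
  masks <- masks_for_all_slices(mask_even, mask_odd, d[3L])
  Wp <- array(0, d[1:3])
  for (s in seq_len(d[3L]))
    Wp[, , s] <- expand_mask_keepcenter(masks[[s]], d[2L], keepcenter)
  ym <- weight_kspace(yd, Wp)
  unrolled_reconstruct(ym, Wp, csm, recon_cfg, denoiser_weights)
}
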