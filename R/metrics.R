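#' Line-detection metrics against a reference mask
#'
#' MAE on the continuous weights, plus classification metrics after
#' thresholding: a line with weight below the threshold counts as predicted
#' motion-corrupted (the positive class). Precision and recall are reported
#' for that class, together with a precision-recall curve over 101 evenly
#' spaced thresholds.
#'
#' @param pred an [exclusion_mask()] or numeric weight vector (1 = keep).
#' @param ref binary reference mask (1 = motion-free), same length.
#' @param threshold classification threshold on the predicted weights.
#' @return List of class `mask_metrics`: `mae`, `accuracy`, `precision`,
#'   `recall`, `pr_curve` (data.frame `threshold`, `precision`, `recall`).
#' @export
mask_metrics <- function(pred, ref, threshold = 0.5) {
  p <- if (inherits(pred, "exclusion_mask")) pred$line_weights else as.numeric(pred)
  r <- if (inherits(ref, "exclusion_mask")) ref$line_weights else as.numeric(ref)
  if (length(p) != length(r)) stop("mask length mismatch")
  if (!all(r %in% c(0, 1))) stop("reference mask must be binary")
  mae <- mean(abs(p - r))
  cls <- prec_recall(p, r, threshold)
  thr <- seq(0, 1, length.out = 101)
  curve <- do.call(rbind, lapply(thr, function(tt) {
    m <- prec_recall(p, r, tt)
    data.frame(threshold = tt, precision = m$precision, recall = m$recall)
  }))
  structure(list(mae = mae, accuracy = cls$accuracy,
                 precision = cls$precision, recall = cls$recall,
                 pr_curve = curve), class = "mask_metrics")
}

prec_recall <- function(p, r, threshold) {
  pred_pos <- p < threshold
  ref_pos <- r < 0.5
  tp <- sum(pred_pos & ref_pos)
  acc <- mean(pred_pos == ref_pos)
  precision <- if (sum(pred_pos) == 0) 1 else tp / sum(pred_pos)
  recall <- if (sum(ref_pos) == 0) 1 else tp / sum(ref_pos)
  list(accuracy = acc, precision = precision, recall = recall)
}

#' @export
print.mask_metrics <- function(x, ...) {
  cat(sprintf("<mask_metrics> MAE %.3f | accuracy %.3f | precision %.3f | recall %.3f\n",
              x$mae, x$accuracy, x$precision, x$recall))
  invisible(x)
}

#' Per-slice T2* map quality relative to a motion-free reference
#'
#' Evaluates MAE (ms) and SSIM per slice over brain-tissue voxels whose
#' susceptibility gradient is below `sg_threshold` (strong gradients
#' confound T2* and are excluded). Both maps are clamped to the fixed
#' dynamic range and zeroed outside the evaluation mask before SSIM.
#' Slices with an empty evaluation mask are skipped with a warning.
#'
#' @param map_ms,ref_map_ms T2* maps `[pe, ro, slice]` in ms.
#' @param brain_mask logical array of brain-tissue voxels.
#' @param sg_map susceptibility-gradient map (uT/m).
#' @param sg_threshold evaluation cutoff (uT/m), default 100.
#' @param dynamic_range SSIM dynamic range in ms (default 200).
#' @return data.frame with one row per evaluated slice: `slice`, `n_vox`,
#'   `mae_ms`, `ssim`.
#' @export
t2star_map_metrics <- function(map_ms, ref_map_ms, brain_mask, sg_map,
                               sg_threshold = 100, dynamic_range = 200) {
  d <- dim(map_ms)
  rows <- list()
  for (s in seq_len(d[3])) {
    ev <- brain_mask[, , s] & (sg_map[, , s] < sg_threshold)
    if (!any(ev)) {
      warning(sprintf("slice %d: empty evaluation mask, skipped", s))
      next
    }
    a <- pmin(pmax(map_ms[, , s], 0), dynamic_range)
    b <- pmin(pmax(ref_map_ms[, , s], 0), dynamic_range)
    mae <- mean(abs(map_ms[, , s][ev] - ref_map_ms[, , s][ev]))
    a[!ev] <- 0; b[!ev] <- 0
    sm <- ssim_map(a, b, dynamic_range)
    rows[[length(rows) + 1L]] <-
      data.frame(slice = s, n_vox = sum(ev), mae_ms = mae,
                 ssim = mean(sm[ev]))
  }
  do.call(rbind, rows)
}

# Separable "same" convolution with zero padding.
conv_sep_same <- function(x, k) {
  n <- length(k); h <- (n - 1L) %/% 2L
  d <- dim(x)
  xp <- matrix(0, d[1] + 2 * h, d[2] + 2 * h)
  xp[h + seq_len(d[1]), h + seq_len(d[2])] <- x
  tmp <- matrix(0, d[1], d[2] + 2 * h)
  for (i in seq_len(n))
    tmp <- tmp + k[i] * xp[(i - 1) + seq_len(d[1]), ]
  out <- matrix(0, d[1], d[2])
  for (j in seq_len(n))
    out <- out + k[j] * tmp[, (j - 1) + seq_len(d[2])]
  out
}

#' Structural similarity index map
#'
#' Standard SSIM with a Gaussian window (size 7, sigma 1.5) and the usual
#' stabilizers K1 = 0.01, K2 = 0.03 on a fixed dynamic range.
#'
#' @param a,b images (same size) on the scale of `dynamic_range`.
#' @param dynamic_range value range L of the data.
#' @param window window size (odd).
#' @param sigma Gaussian window width.
#' @return Matrix of local SSIM values.
#' @export
ssim_map <- function(a, b, dynamic_range, window = 7, sigma = 1.5) {
  k <- stats::dnorm(seq(-(window %/% 2), window %/% 2), sd = sigma)
  k <- k / sum(k)
  c1 <- (0.01 * dynamic_range)^2; c2 <- (0.03 * dynamic_range)^2
  mu_a <- conv_sep_same(a, k); mu_b <- conv_sep_same(b, k)
  va <- conv_sep_same(a * a, k) - mu_a^2
  vb <- conv_sep_same(b * b, k) - mu_b^2
  cab <- conv_sep_same(a * b, k) - mu_a * mu_b
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

#' T2* map from reconstructed images
#'
#' Convenience wrapper: magnitude of the reconstruction, log-linear fit,
#' clamped T2* map.
#'
#' @param images complex or magnitude stack `[pe, ro, slice, echo]`.
#' @param te_ms echo times (ms).
#' @param mask optional fitting mask.
#' @param clamp_ms clamp range for the exported map.
#' @return The [fit_monoexp()] result.
#' @export
t2star_from_images <- function(images, te_ms, mask = NULL,
                               clamp_ms = c(1, 1000)) {
  fit_monoexp(if (is.complex(images)) Mod(images) else images, te_ms,
              mask = mask, clamp_ms = clamp_ms)
}
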