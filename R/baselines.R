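#' Outlier-rejecting bootstrap-aggregation reconstruction
#'
#' Reconstructs the same k-space under `n_masks` independent
#' variable-density exclusion masks (fixed exclusion rate, KeepCenter) and
#' returns the voxelwise mean of the reconstructions. Motion events are
#' treated as a probabilistic undersampling problem: each bootstrap mask
#' excludes some lines as potential corruption, and averaging suppresses
#' their influence at the cost of blurring.
#'
#' @param y a [kspace_volume()] or 5D k-space array.
#' @param csm [coil_sensitivities()].
#' @param recon_cfg an [unrolled_config()].
#' @param denoiser_weights cnn weights when configured.
#' @param n_masks number of bootstrap masks (default 15).
#' @param exclusion_rate exclusion rate of each mask (default 0.5).
#' @param keepcenter apply the KeepCenter override (default TRUE).
#' @param seed integer seed; mask seeds are derived deterministically.
#' @return Complex image stack `[pe, ro, slice, echo]`.
#' @export
orba_reconstruct <- function(y, csm, recon_cfg = unrolled_config(),
                             denoiser_weights = NULL, n_masks = 15,
                             exclusion_rate = 0.5, keepcenter = TRUE,
                             seed = 0) {
  if (n_masks < 1) stop("n_masks must be >= 1")
  yd <- if (inherits(y, "kspace_volume")) y$data else y
  d <- dim(yd)
  acc <- NULL
  for (k in seq_len(n_masks)) {
    m <- variable_density_line_mask(d[1L], exclusion_rate,
                                    seed = seed * 100003L + k,
                                    keepcenter = keepcenter)
    Wp <- expand_mask_keepcenter(m, d[2L], keepcenter)
    xk <- unrolled_reconstruct(weight_kspace(yd, Wp), Wp, csm, recon_cfg,
                               denoiser_weights)
    acc <- if (is.null(acc)) xk else acc + xk
  }
  acc / n_masks
}

#' Combine full-, half- and quarter-resolution acquisitions
#'
#' Weighted per-line average of redundant acquisitions of the k-space
#' centre: lines in the central quarter average all three acquisitions,
#' lines in the central half (outside the quarter) average full and half,
#' and peripheral lines are taken from the full acquisition unchanged -
#' which is why corruption confined to the periphery passes through
#' uncorrected.
#'
#' @param y_full a [kspace_volume()] covering all Y lines.
#' @param y_half k-space of the half-resolution acquisition on the same
#'   grid (central Y/2 lines meaningful).
#' @param y_quarter likewise for the central quarter.
#' @param weights length-3 weights `(full, half, quarter)`, normalized per
#'   line over the acquisitions present.
#' @return A [kspace_volume()] with the combined data.
#' @export
hrqr_combine <- function(y_full, y_half, y_quarter, weights = c(1, 1, 1)) {
  yf <- if (inherits(y_full, "kspace_volume")) y_full$data else y_full
  yh <- if (inherits(y_half, "kspace_volume")) y_half$data else y_half
  yq <- if (inherits(y_quarter, "kspace_volume")) y_quarter$data else y_quarter
  if (!identical(dim(yf), dim(yh)) || !identical(dim(yf), dim(yq)))
    stop("acquisitions must share one k-space grid (coverage mismatch)")
  Y <- dim(yf)[1L]
  half <- central_band(Y, Y %/% 2L)
  quarter <- central_band(Y, Y %/% 4L)
  out <- yf
  half_only <- setdiff(half, quarter)
  wfh <- weights[1] + weights[2]
  out[half_only, , , , ] <- (weights[1] * yf[half_only, , , , , drop = FALSE] +
                               weights[2] * yh[half_only, , , , , drop = FALSE]) / wfh
  wall <- sum(weights[1:3])
  out[quarter, , , , ] <- (weights[1] * yf[quarter, , , , , drop = FALSE] +
                             weights[2] * yh[quarter, , , , , drop = FALSE] +
                             weights[3] * yq[quarter, , , , , drop = FALSE]) / wall
  if (inherits(y_full, "kspace_volume")) {
    res <- y_full; res$data <- out; res
  } else out
}
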