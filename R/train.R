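#' Train the unrolled reconstruction on randomly undersampled motion-free data
#'
#' Each step draws a variable-density line mask (fixed exclusion rate,
#' KeepCenter as configured) and one slice of the motion-free dataset,
#' multiplies the clean k-space by the mask, reconstructs with the current
#' conv-denoiser weights, and minimizes the mean squared error to the fully
#' sampled image with Adam. Masks produced under KeepCenter always retain
#' the central 2x2 k-space block, already during training.
#'
#' @param clean_images motion-free image stack `[pe, ro, slice, echo]`
#'   (normalized, see [normalize_volume()]).
#' @param csm [coil_sensitivities()].
#' @param cfg an [unrolled_config()] with `denoiser = "cnn"`.
#' @param epochs number of optimization steps.
#' @param lr Adam learning rate.
#' @param exclusion_rate exclusion rate of the training masks.
#' @param keepcenter apply the KeepCenter override to every training mask.
#' @param n_features hidden features of the denoiser.
#' @param seed integer seed; runs are bit-reproducible.
#' @param slices optional subset of slice indices to train on.
#' @param resample_masks draw a fresh mask every step (default). With
#'   `FALSE` a single mask is drawn up front, which turns the run into a
#'   pure overfit of one undersampled example.
#' @return List `weights` (per-iteration denoiser weights), `loss_history`,
#'   `config`.
#' @export
train_unrolled <- function(clean_images, csm, cfg = unrolled_config(denoiser = "cnn"),
                           epochs = 100, lr = 1e-3, exclusion_rate = 0.5,
                           keepcenter = TRUE, n_features = 16, seed = 0,
                           slices = NULL, resample_masks = TRUE) {
  d <- dim(clean_images)
  if (prod(d) == 0) stop("empty training dataset")
  if (!identical(cfg$denoiser, "cnn"))
    stop("train_unrolled optimizes the cnn denoiser; set denoiser = 'cnn'")
  slices <- slices %||% seq_len(d[3])
  y_full <- sense_forward(clean_images, csm)
  weights <- cnn_init_weights(d[4], cfg$n_iterations, n_features, seed = seed)
  flat <- flatten_weights(weights)
  opt <- adam_init(flat)
  history <- numeric(epochs)
  csm_arr <- if (inherits(csm, "coil_sensitivities")) csm$csm else csm

  fixed_mask <- if (!resample_masks)
    variable_density_line_mask(d[1], exclusion_rate, seed = seed,
                               keepcenter = keepcenter)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      s <- slices[sample.int(length(slices), 1L)]
      m <- if (resample_masks)
        variable_density_line_mask(d[1], exclusion_rate,
                                   seed = sample.int(.Machine$integer.max, 1L),
                                   keepcenter = keepcenter)
      else fixed_mask
      Wp <- expand_mask_keepcenter(m, d[2], keepcenter)
      ys <- y_full[, , s, , , drop = FALSE]
      ym <- weight_kspace(ys, Wp)
      cs <- coil_sensitivities(csm_arr[, , s, , drop = FALSE], normalize = FALSE)
      weights <- unflatten_weights(flat, weights)
      fwd <- unrolled_reconstruct(ym, Wp, cs, cfg, weights, cache = TRUE)
      target <- clean_images[, , s, , drop = FALSE]
      diffc <- fwd$x - target
      n <- length(diffc)
      history[ep] <- mean(Mod(diffc)^2)
      gx <- 2 * diffc / n
      bk <- unrolled_backward(gx, fwd, ym, Wp, cs, cfg, weights)
      gflat <- flatten_weights(bk$g_weights)
      upd <- adam_step(opt, flat, gflat, lr)
      opt <- upd$state; flat <- upd$params
    }
  })
  list(weights = unflatten_weights(flat, weights), loss_history = history,
       config = list(cfg = cfg, epochs = epochs, lr = lr,
                     exclusion_rate = exclusion_rate,
                     keepcenter = keepcenter, n_features = n_features,
                     seed = seed))
}

flatten_weights <- function(w) {
  out <- list()
  for (k in seq_along(w)) for (nm in names(w[[k]]))
    out[[paste0("it", k, "_", nm)]] <- w[[k]][[nm]]
  out
}

unflatten_weights <- function(flat, template) {
  for (k in seq_along(template)) for (nm in names(template[[k]]))
    template[[k]][[nm]] <- flat[[paste0("it", k, "_", nm)]]
  template
}

#' Save / load denoiser weights
#'
#' Weights are stored as a raw little-endian double payload next to a JSON
#' sidecar describing shapes and the training configuration.
#'
#' @param weights per-iteration weight list from [train_unrolled()].
#' @param path file path for the binary payload (`.bin`); the sidecar gets
#'   the extension `.json`.
#' @param config optional configuration list stored in the sidecar.
#' @return `write_denoiser_weights()` returns `path` invisibly;
#'   `read_denoiser_weights()` returns the weight list.
#' @export
write_denoiser_weights <- function(weights, path, config = NULL) {
  flat <- flatten_weights(weights)
  shapes <- lapply(flat, function(p) dim(p) %||% length(p))
  con <- file(path, "wb"); on.exit(close(con))
  for (p in flat) writeBin(as.numeric(p), con, size = 8, endian = "little")
  meta <- list(names = names(flat), shapes = shapes,
               n_iterations = length(weights), config = config)
  jsonlite::write_json(meta, paste0(sub("\\.bin$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_denoiser_weights
#' @export
read_denoiser_weights <- function(path) {
  meta <- jsonlite::read_json(paste0(sub("\\.bin$", "", path), ".json"),
                              simplifyVector = TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  flat <- list()
  for (i in seq_along(meta$names)) {
    sh <- unlist(meta$shapes[[i]])
    v <- readBin(con, "numeric", n = prod(sh), size = 8, endian = "little")
    flat[[meta$names[i]]] <- if (length(sh) > 1L) array(v, sh) else v
  }
  template <- lapply(seq_len(meta$n_iterations), function(k) {
    nms <- c("W1", "b1", "W2", "b2")
    stats::setNames(vector("list", 4L), nms)
  })
  unflatten_weights(flat, template)
}
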