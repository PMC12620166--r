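#' Plot an exclusion mask against an optional reference
#'
#' Line weights versus PE index, with reference-corrupted lines shaded.
#'
#' @param mask an [exclusion_mask()].
#' @param ref optional binary reference mask (1 = motion-free).
#' @param threshold decision threshold drawn as a horizontal line.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `mask`.
#' @export
plot_exclusion_mask <- function(mask, ref = NULL, threshold = 0.5, ...) {
  w <- mask$line_weights
  graphics::plot(seq_along(w) - 1L, w, type = "s", ylim = c(0, 1),
                 xlab = "PE line", ylab = "mask weight",
                 main = sprintf("exclusion mask (%s package)", mask$package),
                 ...)
  if (!is.null(ref)) {
    rw <- if (inherits(ref, "exclusion_mask")) ref$line_weights else ref
    bad <- which(rw < 0.5) - 1L
    if (length(bad))
      graphics::rect(bad - 0.5, 0, bad + 0.5, 1,
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  invisible(mask)
}

#' Display a map slice
#'
#' Grey-level display of one slice of a parameter map or magnitude image,
#' with sensible orientation for `[pe, ro]` arrays.
#'
#' @param map 2D or 3D array.
#' @param slice slice index for 3D input.
#' @param zlim display range (default data range).
#' @param main title.
#' @return Invisibly, the displayed matrix.
#' @export
plot_map_slice <- function(map, slice = 1L, zlim = NULL, main = "") {
  m <- if (length(dim(map)) == 3L) map[, , slice] else map
  m[!is.finite(m)] <- 0
  zlim <- zlim %||% range(m)
  graphics::image(t(m)[, nrow(m):1], col = grDevices::grey.colors(128),
                  zlim = zlim, axes = FALSE, main = main, useRaster = TRUE)
  invisible(m)
}

#' Plot the optimization loss history
#'
#' Physics and total objective per epoch of a mask optimization.
#'
#' @param opt a `mask_optimization` result.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the loss history data.frame.
#' @export
plot_loss_history <- function(opt, ...) {
  h <- opt$loss_history
  graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch",
                 ylab = "loss", main = "mask optimization", ...)
  graphics::lines(h$epoch, h$physics, lty = 2)
  graphics::legend("topright", c("total", "physics"), lty = c(1, 2),
                   bty = "n")
  invisible(h)
}
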