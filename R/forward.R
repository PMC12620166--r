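#' Apply a rigid motion state (plus B0 phase) to an image plane
#'
#' Realizes the per-time-point motion transform of the corrupted-acquisition
#' model: the plane is rigidly resampled (in-plane rotation about the plane
#' centre, then translation) and multiplied voxelwise by the off-resonance
#' phase `exp(-g * 1i * omega * TE)` that a motion-induced field perturbation
#' `omega` (rad/s) imprints on an echo acquired at `te_ms`. For 2D
#' multi-slice data only the in-plane components (`tx`, `ty`, `rz`) act on
#' the image; through-plane components still count towards displacement
#' metrics but cannot be resampled in a single slice.
#'
#' @param plane complex image-space matrix `[pe, ro]`.
#' @param state a [rigid_state()]; `state$omega` may be `NULL`, a scalar, or
#'   a matrix matching `plane`.
#' @param te_ms echo time of this echo in ms.
#' @param spacing_mm in-plane voxel spacing `(pe, ro)` in mm.
#' @param interp interpolation scheme; only `"bilinear"` is supported
#'   (zero-fill outside the field of view).
#' @param phase_gain multiplier `g` on `omega * TE` inside the phase factor.
#'   The default 2 follows the forward model as printed; set 1 for the
#'   conventional off-resonance phase.
#' @return Transformed complex plane of the same size.
#' @export
apply_motion_operator <- function(plane, state, te_ms, spacing_mm = c(2, 2),
                                  interp = "bilinear", phase_gain = 2) {
  if (!identical(interp, "bilinear"))
    stop(sprintf("unsupported interpolation scheme '%s'", interp))
  d <- dim(plane)
  out <- plane
  if (state$t[1] != 0 || state$t[2] != 0 || state$r[3] != 0) {
    out <- resample_rigid_2d(plane, tx_mm = state$t[1], ty_mm = state$t[2],
                             rz_deg = state$r[3], spacing_mm = spacing_mm)
  }
  if (!is.null(state$omega)) {
    om <- state$omega
    if (length(om) == 1L) om <- matrix(om, d[1L], d[2L])
    if (!all(dim(om) == d)) stop("omega field does not match the plane shape")
    te_s <- te_ms / 1000
    out <- out * exp(-phase_gain * 1i * om * te_s)
  }
  out
}

# Bilinear rigid resampling of a [pe, ro] plane. Physical axes: x runs along
# readout (dim 2), y along phase encode (dim 1); rotation rz about the plane
# centre, then translation. Output(p) = input(R^{-1}(p - t)); zero outside.
resample_rigid_2d <- function(plane, tx_mm, ty_mm, rz_deg, spacing_mm) {
  pe <- nrow(plane); ro <- ncol(plane)
  cy <- (pe + 1) / 2; cx <- (ro + 1) / 2
  yy <- (rep(seq_len(pe), times = ro) - cy) * spacing_mm[1]
  xx <- (rep(seq_len(ro), each = pe) - cx) * spacing_mm[2]
  a <- -rz_deg * pi / 180 # inverse rotation
  xs <- cos(a) * (xx - tx_mm) - sin(a) * (yy - ty_mm)
  ys <- sin(a) * (xx - tx_mm) + cos(a) * (yy - ty_mm)
  fi <- ys / spacing_mm[1] + cy
  fj <- xs / spacing_mm[2] + cx
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  vals <- complex(real = numeric(pe * ro), imaginary = numeric(pe * ro))
  at <- function(i, j) {
    ok <- i >= 1 & i <= pe & j >= 1 & j <= ro
    v <- vals
    v[ok] <- plane[cbind(i[ok], j[ok])]
    v
  }
  v <- (1 - wi) * (1 - wj) * at(i0, j0) +
       (1 - wi) * wj       * at(i0, j0 + 1) +
       wi       * (1 - wj) * at(i0 + 1, j0) +
       wi       * wj       * at(i0 + 1, j0 + 1)
  matrix(v, pe, ro)
}

# Static multicoil forward operator A: image stack [pe, ro, slice, echo] ->
# k-space [pe, ro, slice, coil, echo]; and its adjoint A^H. With unit-RSS
# coil maps and full sampling, A^H A = identity.
sense_forward <- function(x, csm) {
  if (inherits(csm, "coil_sensitivities")) csm <- csm$csm
  dx <- dim(x); dc <- dim(csm)
  y <- array(0i, c(dc, dx[4L]))
  for (e in seq_len(dx[4L]))
    y[, , , , e] <- csm * as.vector(x[, , , e, drop = FALSE])
  fft2c_batch(y)
}

sense_adjoint <- function(y, csm) {
  if (inherits(csm, "coil_sensitivities")) csm <- csm$csm
  dy <- dim(y)
  img <- fft2c_batch(y, inverse = TRUE)
  n_vox <- prod(dy[1:3]); n_coil <- dy[4L]; n_echo <- dy[5L]
  out <- array(0i, c(dy[1:3], n_echo))
  cc <- Conj(csm)
  for (e in seq_len(n_echo)) {
    z <- cc * as.vector(img[, , , , e])
    out[, , , e] <- array(rowSums(matrix(z, n_vox, n_coil)), dy[1:3])
  }
  out
}

# Slices (1-based indices) belonging to one interleaved package. 0-based
# even slices form the "even" package.
slices_of_package <- function(n_slices, package) {
  s0 <- seq_len(n_slices) - 1L
  which(if (package == "even") s0 %% 2L == 0L else s0 %% 2L == 1L)
}

#' Motion-aware multicoil acquisition of a multi-echo image stack
#'
#' Implements the time-resolved forward model: at every scheme entry
#' (PE line, slice package) the motion-free image is transformed by that
#' entry's rigid state, coil-weighted, Fourier transformed, and the single
#' PE line is sampled. Summed over entries, every line of every package is
#' covered exactly once.
#'
#' @param images complex image stack `[pe, ro, slice, echo]`.
#' @param csm [coil_sensitivities()] or a raw 4D array.
#' @param scheme an [acquisition_times()] scheme with `Y == dim(images)[1]`.
#' @param states list of [rigid_state()], one per scheme entry (row of
#'   `scheme$entries`), or a single state recycled for all entries.
#' @param te_ms echo times (ms).
#' @param tr_ms repetition time stored in the result.
#' @param spacing_mm,phase_gain passed to [apply_motion_operator()].
#' @return A [kspace_volume()].
#' @export
forward_acquire <- function(images, csm, scheme, states, te_ms,
                            tr_ms = scheme$tr_ms, spacing_mm = c(2, 2),
                            phase_gain = 2) {
  if (inherits(csm, "coil_sensitivities")) csm <- csm$csm
  entries <- scheme$entries
  if (inherits(states, "rigid_state")) states <- rep(list(states), nrow(entries))
  if (length(states) != nrow(entries))
    stop("need one rigid state per scheme entry")
  d <- dim(images)
  if (d[1L] != scheme$Y) stop("image PE size does not match the scheme")
  n_coil <- dim(csm)[4L]; n_echo <- d[4L]
  y <- array(0i, c(d[1L], d[2L], d[3L], n_coil, n_echo))

  keys <- vapply(states, state_key, character(1))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    st <- states[[idx[1L]]]
    ks <- kspace_under_state(images, csm, st, te_ms, spacing_mm, phase_gain)
    for (i in idx) {
      pe <- entries$pe_index[i]
      sl <- slices_of_package(d[3L], entries$package[i])
      y[pe, , sl, , ] <- ks[pe, , sl, , ]
    }
  }
  kspace_volume(y, te_ms = te_ms, tr_ms = tr_ms)
}

state_key <- function(s) {
  paste(c(format(c(s$t, s$r), digits = 17),
          if (is.null(s$omega)) "static" else format(sum(s$omega) + sum(s$omega^2), digits = 17)),
        collapse = "|")
}

# Full k-space of the image stack under one rigid state (all slices).
kspace_under_state <- function(images, csm, state, te_ms, spacing_mm,
                               phase_gain) {
  d <- dim(images)
  if (is_identity_state(state) && is.null(state$omega))
    return(sense_forward(images, csm))
  moved <- images
  for (s in seq_len(d[3L])) {
    om <- slice_omega(state$omega, s, d)
    st_s <- rigid_state(state$t, state$r, om)
    for (e in seq_len(d[4L]))
      moved[, , s, e] <- apply_motion_operator(images[, , s, e], st_s,
                                               te_ms[e], spacing_mm,
                                               phase_gain = phase_gain)
  }
  sense_forward(moved, csm)
}

slice_omega <- function(omega, s, d) {
  if (is.null(omega)) return(NULL)
  if (is.matrix(omega) || length(omega) == 1L) return(omega)
  omega[, , s]
}

#' Expand a line mask to a 2D k-space weight plane, with KeepCenter
#'
#' Broadcasts per-PE-line weights along the readout direction. With
#' `keepcenter = TRUE` the 2x2 pixel block around the k-space centre (the
#' smallest symmetric group containing the DC sample on an even grid) is
#' forced to 1 regardless of the line weights, so the mean image intensity
#' survives even when central lines are excluded.
#'
#' @param mask an [exclusion_mask()] or a bare numeric weight vector.
#' @param ro_size readout size (even).
#' @param keepcenter force the central 2x2 block to 1.
#' @return Numeric `[Y, ro_size]` weight plane.
#' @export
expand_mask_keepcenter <- function(mask, ro_size, keepcenter = TRUE) {
  w <- if (inherits(mask, "exclusion_mask")) mask$line_weights else as.numeric(mask)
  Y <- length(w)
  if (Y %% 2L != 0L || ro_size %% 2L != 0L) stop("pe and ro sizes must be even")
  plane <- matrix(w, Y, ro_size)
  if (keepcenter)
    plane[c(Y %/% 2L, Y %/% 2L + 1L), c(ro_size %/% 2L, ro_size %/% 2L + 1L)] <- 1
  plane
}

#' Variable-density random line exclusion mask
#'
#' Draws a binary per-line mask with exactly `round(exclusion_rate * Y)`
#' excluded lines. The probability of exclusion grows linearly from the
#' k-space centre to the periphery (`prob ~ |k_pe| / (Y/2)`), so central
#' lines are rarely dropped; the DC line itself has zero exclusion
#' probability. Used both to train the reconstruction on randomly
#' undersampled motion-free data and by the bootstrap-aggregation baseline.
#'
#' @param Y number of PE lines (even).
#' @param exclusion_rate fraction of lines to exclude, in `[0, 1)`.
#' @param seed integer seed; identical seeds give identical masks.
#' @param keepcenter logical, stored on the mask and used as the default
#'   when expanding to 2D.
#' @param package package label for the resulting mask.
#' @return An [exclusion_mask()] with attribute `keepcenter`.
#' @export
variable_density_line_mask <- function(Y, exclusion_rate, seed = NULL,
                                       keepcenter = TRUE, package = "odd") {
  if (exclusion_rate < 0 || exclusion_rate >= 1)
    stop("exclusion_rate must be in [0, 1)")
  n_excl <- round(exclusion_rate * Y)
  w <- rep(1, Y)
  if (n_excl > 0) {
    kk <- abs(seq_len(Y) - (Y %/% 2L + 1L)) / (Y / 2)
    drop_idx <- with_seed(seed, sample.int(Y, n_excl, prob = kk))
    w[drop_idx] <- 0
  }
  m <- exclusion_mask(w, package = package)
  attr(m, "keepcenter") <- keepcenter
  m
}
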