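#' Digital multi-echo brain phantom
#'
#' Generates a piecewise-elliptical brain-like 2D multi-slice phantom with
#' white matter, cortical grey matter and CSF compartments, smooth synthetic
#' coil sensitivities (unit RSS), a smooth B0 field whose spatial gradient
#' yields the susceptibility-gradient map, mono-exponential multi-echo
#' images, and the corresponding static multicoil k-space. Acquisition
#' defaults mirror a 12-echo GRE protocol (TE1 = dTE = 5 ms, TR = 2300 ms,
#' 92 PE lines); the slice count and readout size default to a desk-scale
#' geometry.
#'
#' Tissue T2* values are design choices in plausible ranges (WM ~45 ms,
#' GM ~60 ms, CSF ~250 ms) with smooth within-compartment variation. The
#' most superior two slices carry deliberately strong field gradients so
#' that susceptibility-based slice selection has something to reject.
#'
#' @param pe,ro matrix size (even).
#' @param n_slices number of slices (inferior to superior).
#' @param n_echoes number of echoes (>= 3).
#' @param te1_ms,dte_ms first echo time and echo spacing (ms).
#' @param tr_ms repetition time (ms).
#' @param n_coils number of synthetic receive coils.
#' @param spacing_mm in-plane voxel size (mm).
#' @param seed integer seed; the dataset is deterministic given it.
#' @return An object of class `phantom_dataset` with fields `s0_map`,
#'   `t2star_map`, `b0_map` (rad/s), `csm`, `brain_mask`, `sg_map` (uT/m),
#'   `images`, `kspace`, `te_ms`, `tr_ms`, `spacing_mm`, `seed`.
#' @export
make_digital_phantom <- function(pe = 92, ro = 64, n_slices = 8,
                                 n_echoes = 12, te1_ms = 5, dte_ms = 5,
                                 tr_ms = 2300, n_coils = 4,
                                 spacing_mm = c(2, 2), seed = 0) {
  if (pe %% 2L != 0L || ro %% 2L != 0L) stop("pe and ro must be even")
  if (n_echoes < 3L) stop("need at least 3 echoes")
  te_ms <- te1_ms + dte_ms * (seq_len(n_echoes) - 1)
  u <- matrix(seq(-1, 1, length.out = pe), pe, ro)
  v <- matrix(seq(-1, 1, length.out = ro), pe, ro, byrow = TRUE)

  shp <- c(pe, ro, n_slices)
  t2 <- array(NA_real_, shp); s0 <- array(0, shp)
  brain <- array(FALSE, shp); b0 <- array(0, shp)

  tex <- with_seed(seed, gaussian_filter_2d(matrix(stats::rnorm(pe * ro), pe, ro), 5))
  tex <- tex / max(abs(tex))

  for (s in seq_len(n_slices)) {
    # brain outline shrinks towards both ends of the slab
    g <- sin(pi * (s - 0.25) / n_slices)
    a <- 0.55 + 0.30 * g; b <- 0.45 + 0.28 * g
    rr <- (u / a)^2 + (v / b)^2
    bs <- rr < 1
    wm <- (u / (0.62 * a))^2 + (v / (0.60 * b))^2 < 1
    csf <- ((u - 0.12) / 0.10)^2 + (v / (0.16 * b / 0.45))^2 < 1 |
           ((u + 0.12) / 0.10)^2 + (v / (0.16 * b / 0.45))^2 < 1
    csf <- csf & bs
    t2s <- matrix(NA_real_, pe, ro)
    t2s[bs] <- 60   # cortical ribbon
    t2s[wm & bs] <- 45
    t2s[csf] <- 250
    t2s <- t2s * (1 + 0.08 * tex) # smooth within-compartment variation
    s0s <- matrix(0, pe, ro)
    s0s[bs] <- 1.0; s0s[wm & bs] <- 0.9; s0s[csf] <- 1.4
    s0s <- s0s * (1 + 0.05 * tex)
    brain[, , s] <- bs
    t2[, , s] <- t2s
    s0[, , s] <- s0s
    # smooth field: linear/quadratic shim residual plus a focal gradient
    # that grows sharply for the two most superior slices
    amp <- if (s >= n_slices - 1) 10.5 else 2.2 + 0.35 * s
    b0[, , s] <- 250 * amp *
      (0.4 * u + 0.25 * v + 0.5 * u * v + 0.6 * exp(-(((u + 0.45) / 0.35)^2 +
                                                       (v / 0.45)^2)))
  }
  t2[is.na(t2)] <- 1000 # background: irrelevant, masked out everywhere

  sg <- sg_from_b0(b0, spacing_mm)

  csm <- synth_csm(pe, ro, n_slices, n_coils)

  images <- array(0i, c(pe, ro, n_slices, n_echoes))
  phi0 <- 0.3 * tex * pi
  for (e in seq_len(n_echoes)) {
    te_s <- te_ms[e] / 1000
    mag <- s0 * exp(-te_ms[e] / t2)
    mag[!brain] <- 0
    images[, , , e] <- mag * exp(1i * (as.vector(phi0) + b0 * te_s))
  }

  kspace <- kspace_volume(sense_forward(images, csm), te_ms, tr_ms)
  structure(list(s0_map = s0, t2star_map = t2, b0_map = b0, csm = csm,
                 brain_mask = brain, sg_map = sg, images = images,
                 kspace = kspace, te_ms = te_ms, tr_ms = tr_ms,
                 spacing_mm = spacing_mm, seed = seed),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<phantom_dataset> %d x %d, %d slices, %d echoes, %d coils\n",
              d[1], d[2], d[3], d[4], dim(x$csm$csm)[4]))
  cat(sprintf("  brain fraction %.2f-%.2f; mean sg %.0f-%.0f uT/m\n",
              min(apply(x$brain_mask, 3, mean)),
              max(apply(x$brain_mask, 3, mean)),
              min(slice_mean_sg(x)), max(slice_mean_sg(x))))
  invisible(x)
}

slice_mean_sg <- function(ph) {
  vapply(seq_len(dim(ph$sg_map)[3]), function(s) {
    b <- ph$brain_mask[, , s]
    if (!any(b)) return(Inf)
    mean(ph$sg_map[, , s][b])
  }, numeric(1))
}

slice_brain_fraction <- function(ph) apply(ph$brain_mask, 3, mean)

# Susceptibility-gradient magnitude map (uT/m) from a B0 map in rad/s, via
# central finite differences and the proton gyromagnetic ratio.
sg_from_b0 <- function(b0, spacing_mm) {
  gamma <- 2.675e8 # rad/s/T
  d <- dim(b0)
  gx <- b0 * 0; gy <- b0 * 0
  gx[2:(d[1] - 1), , ] <- (b0[3:d[1], , ] - b0[1:(d[1] - 2), , ]) / 2
  gy[, 2:(d[2] - 1), ] <- (b0[, 3:d[2], ] - b0[, 1:(d[2] - 2), ]) / 2
  gmag <- sqrt((gx / (spacing_mm[1] / 1000))^2 +
                 (gy / (spacing_mm[2] / 1000))^2)
  gmag / gamma * 1e6
}

# Smooth complex coil profiles: Gaussian magnitude lobes around the FOV
# with gentle phase ramps; normalized to unit RSS by the constructor.
synth_csm <- function(pe, ro, n_slices, n_coils) {
  u <- matrix(seq(-1, 1, length.out = pe), pe, ro)
  v <- matrix(seq(-1, 1, length.out = ro), pe, ro, byrow = TRUE)
  csm <- array(0i, c(pe, ro, n_slices, n_coils))
  for (c in seq_len(n_coils)) {
    ang <- 2 * pi * (c - 1) / n_coils
    cu <- 1.1 * cos(ang); cv <- 1.1 * sin(ang)
    mag <- exp(-(((u - cu) / 1.1)^2 + ((v - cv) / 1.1)^2))
    ph <- 0.7 * (u * sin(ang) - v * cos(ang))
    for (s in seq_len(n_slices))
      csm[, , s, c] <- mag * exp(1i * (ph + 0.05 * s))
  }
  coil_sensitivities(csm)
}
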