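#' Multi-echo multicoil k-space volume
#'
#' Container for Cartesian 2D multi-slice multi-echo k-space together with
#' the acquisition metadata needed by the motion forward model and the
#' reconstruction. Data are stored in R's column-major order as
#' `[pe, ro, slice, coil, echo]` so that one k-space plane is a contiguous
#' matrix slice.
#'
#' @param data complex 5D array `[pe, ro, slice, coil, echo]`.
#' @param te_ms strictly increasing echo times in milliseconds, one per echo.
#' @param tr_ms repetition time in milliseconds.
#' @param packages labelling convention of the two interleaved slice
#'   packages; `"odd_first"` means slice 1 (0-based slice 0) belongs to the
#'   package acquired first.
#' @return An object of class `kspace_volume`.
#' @export
kspace_volume <- function(data, te_ms, tr_ms, packages = "odd_first") {
  d <- dim(data)
  if (length(d) != 5L) stop("data must be a 5D array [pe, ro, slice, coil, echo]")
  if (d[5L] != length(te_ms)) stop("number of echoes must equal length(te_ms)")
  if (any(diff(te_ms) <= 0)) stop("te_ms must be strictly increasing")
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L)
    stop("pe and ro sizes must be even")
  stopifnot_finite(data, "k-space data")
  if (!is.complex(data)) storage.mode(data) <- "complex"
  structure(
    list(data = data, te_ms = as.numeric(te_ms), tr_ms = as.numeric(tr_ms),
         packages = packages),
    class = "kspace_volume")
}

#' @export
print.kspace_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<kspace_volume> %d PE x %d RO, %d slices, %d coils, %d echoes\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  TE = %s ms, TR = %g ms, packages = %s\n",
              paste(x$te_ms, collapse = ", "), x$tr_ms, x$packages))
  invisible(x)
}

#' @export
dim.kspace_volume <- function(x) dim(x$data)

#' Coil sensitivity maps
#'
#' Complex sensitivity maps `[pe, ro, slice, coil]`, normalized on
#' construction to unit root-sum-of-squares wherever the coils carry signal
#' (so the SENSE-style combined operator satisfies `A^H A = I` under full
#' sampling).
#'
#' @param csm complex 4D array `[pe, ro, slice, coil]`.
#' @param normalize normalize to unit RSS where RSS > 0 (default `TRUE`).
#' @return An object of class `coil_sensitivities`.
#' @export
coil_sensitivities <- function(csm, normalize = TRUE) {
  d <- dim(csm)
  if (length(d) != 4L) stop("csm must be a 4D array [pe, ro, slice, coil]")
  stopifnot_finite(csm, "coil sensitivities")
  if (!is.complex(csm)) storage.mode(csm) <- "complex"
  if (normalize) {
    rss <- sqrt(apply(Mod(csm)^2, c(1, 2, 3), sum))
    rss[rss == 0] <- 1
    csm <- csm / as.vector(rss) # recycles over the coil dimension
  }
  structure(list(csm = csm), class = "coil_sensitivities")
}

#' @export
dim.coil_sensitivities <- function(x) dim(x$csm)

#' Rigid-body motion state
#'
#' One 6-DOF rigid head pose: translations in millimetres, rotations in
#' degrees about the volume centre (applied in z-y-x order), plus an
#' optional in-plane B0 perturbation field `omega` in rad/s that phase-taints
#' later echoes via `exp(-2i * omega * TE)`.
#'
#' @param t numeric length-3 translation `(tx, ty, tz)` in mm.
#' @param r numeric length-3 rotation `(rx, ry, rz)` in degrees.
#' @param omega optional in-plane field perturbation (matrix, rad/s), or a
#'   `[pe, ro, slice]` array for per-slice fields.
#' @return An object of class `rigid_state`.
#' @export
rigid_state <- function(t = c(0, 0, 0), r = c(0, 0, 0), omega = NULL) {
  t <- as.numeric(t); r <- as.numeric(r)
  if (length(t) != 3L || length(r) != 3L) stop("t and r must have length 3")
  if (!all(is.finite(c(t, r)))) stop("non-finite rigid parameters")
  if (!is.null(omega)) stopifnot_finite(omega, "omega field")
  structure(list(t = t, r = r, omega = omega), class = "rigid_state")
}

is_identity_state <- function(s) all(s$t == 0) && all(s$r == 0)

# 3x3 rotation matrix, z-y-x intrinsic order, angles in degrees.
rotation_matrix <- function(r_deg) {
  a <- r_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Euler angles (degrees, z-y-x convention) from a rotation matrix.
euler_from_matrix <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock; fold everything into rz
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  }
  c(rx, ry, rz) * 180 / pi
}

# Compose s1 o s2 as maps p -> R p + t.
compose_states <- function(s1, s2) {
  R1 <- rotation_matrix(s1$r); R2 <- rotation_matrix(s2$r)
  R <- R1 %*% R2
  t <- as.vector(R1 %*% s2$t) + s1$t
  rigid_state(t = t, r = euler_from_matrix(R), omega = s1$omega)
}

invert_state <- function(s) {
  R <- rotation_matrix(s$r)
  rigid_state(t = as.vector(-t(R) %*% s$t), r = euler_from_matrix(t(R)),
              omega = s$omega)
}

#' Line-wise acquisition scheme of the interleaved 2D multi-slice sequence
#'
#' Assigns every (PE line, slice package) pair an acquisition time. The
#' sequence acquires all slices of one package within each TR, so a single
#' motion state applies to a PE line of a whole package. By default the two
#' packages of the same order index are separated by half a TR.
#'
#' @param Y number of PE lines.
#' @param tr_ms repetition time in ms.
#' @param ordering PE line ordering; only `"linear"` (ascending PE index) is
#'   built in.
#' @param package_offset_fraction fraction of TR separating the second
#'   package from the first at the same order index (default 0.5).
#' @return An object of class `acquisition_scheme`: a data.frame of entries
#'   `(pe_index, package, time_s)` plus `tr_ms` and `scan_duration_s`.
#' @examples
#' sch <- acquisition_times(92, 2300)
#' sch$scan_duration_s # 92 * 2.3
#' @export
acquisition_times <- function(Y, tr_ms, ordering = "linear",
                              package_offset_fraction = 0.5) {
  if (Y <= 0) stop("Y must be positive")
  order_idx <- switch(ordering,
    linear = seq_len(Y),
    stop(sprintf("unknown PE ordering '%s'", ordering)))
  tr_s <- tr_ms / 1000
  entries <- rbind(
    data.frame(pe_index = order_idx, package = "odd",
               time_s = (seq_len(Y) - 1) * tr_s),
    data.frame(pe_index = order_idx, package = "even",
               time_s = (seq_len(Y) - 1 + package_offset_fraction) * tr_s))
  entries <- entries[order(entries$time_s), ]
  rownames(entries) <- NULL
  structure(list(entries = entries, tr_ms = tr_ms, ordering = ordering,
                 scan_duration_s = Y * tr_s, Y = as.integer(Y)),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("<acquisition_scheme> %d PE lines x 2 packages, TR = %g ms, %s ordering, %.1f s\n",
              x$Y, x$tr_ms, x$ordering, x$scan_duration_s))
  invisible(x)
}

# Acquisition time of line pe (1-based) in a given package.
line_time <- function(scheme, pe, package) {
  e <- scheme$entries
  hit <- e$pe_index == pe & e$package == package
  if (!any(hit)) stop("no such (pe, package) entry")
  e$time_s[hit]
}

#' Per-line k-space exclusion mask
#'
#' Continuous weights in `[0, 1]` per PE line (1 = keep, 0 = exclude) for one
#' slice package. Multiplied into k-space to down-weight motion-corrupted
#' lines.
#'
#' @param line_weights numeric vector of length Y with entries in `[0, 1]`.
#' @param package package label, `"odd"` or `"even"`.
#' @return An object of class `exclusion_mask`.
#' @export
exclusion_mask <- function(line_weights, package = "odd") {
  w <- as.numeric(line_weights)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("line weights must be finite and in [0, 1]")
  structure(list(line_weights = w, package = package), class = "exclusion_mask")
}

#' @export
print.exclusion_mask <- function(x, ...) {
  cat(sprintf("<exclusion_mask> %d lines (%s package), mean %.3f, %d below 0.5\n",
              length(x$line_weights), x$package, mean(x$line_weights),
              sum(x$line_weights < 0.5)))
  invisible(x)
}
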