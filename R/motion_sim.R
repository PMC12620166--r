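#' Rigid-body motion curve
#'
#' A time series of 6-DOF head poses: translations (mm) and rotations
#' (degrees) sampled at strictly increasing times.
#'
#' @param times_s strictly increasing times in seconds.
#' @param params numeric matrix `[n_time, 6]` with columns
#'   `tx_mm, ty_mm, tz_mm, rx_deg, ry_deg, rz_deg`.
#' @return An object of class `motion_curve`.
#' @export
motion_curve <- function(times_s, params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("params must have 6 columns")
  if (length(times_s) != nrow(params)) stop("times and params misaligned")
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(params))) stop("non-finite motion parameters")
  colnames(params) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  structure(list(times_s = as.numeric(times_s), params = params),
            class = "motion_curve")
}

#' @export
print.motion_curve <- function(x, ...) {
  d <- curve_displacements(x)
  cat(sprintf("<motion_curve> %d states over %.1f s; displacement max %.2f mm, median %.2f mm\n",
              length(x$times_s), max(x$times_s), max(d), stats::median(d)))
  invisible(x)
}

curve_state <- function(curve, i) {
  rigid_state(t = curve$params[i, 1:3], r = curve$params[i, 4:6])
}

state_at_time <- function(curve, time_s) {
  i <- which.min(abs(curve$times_s - time_s))
  curve_state(curve, i)
}

# Fixed quasi-uniform Halton point set inside the unit sphere, shared by all
# displacement computations for determinism.
halton_1d <- function(n, base) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1; r <- 0; k <- i
    while (k > 0) {
      f <- f / base
      r <- r + f * (k %% base)
      k <- k %/% base
    }
    out[i] <- r
  }
  out
}

.sphere_cache <- new.env(parent = emptyenv())

sphere_points <- function(n_points = 4096L) {
  key <- as.character(n_points)
  if (!is.null(.sphere_cache[[key]])) return(.sphere_cache[[key]])
  got <- matrix(0, 0, 3)
  m <- 1L
  while (nrow(got) < n_points) {
    n_try <- ceiling((n_points - nrow(got)) * 2.2)
    idx <- seq.int(m, m + n_try - 1L)
    pts <- 2 * cbind(halton_1d(max(idx), 2)[idx],
                     halton_1d(max(idx), 3)[idx],
                     halton_1d(max(idx), 5)[idx]) - 1
    keep <- rowSums(pts^2) <= 1
    got <- rbind(got, pts[keep, , drop = FALSE])
    m <- m + n_try
  }
  got <- got[seq_len(n_points), , drop = FALSE]
  .sphere_cache[[key]] <- got
  got
}

#' Average displacement of a rigid state over a head-sized sphere
#'
#' Scalar severity of a motion state: the mean displacement `|R p + t - p|`
#' over points quasi-uniformly distributed in a sphere of radius
#' `radius_mm` (64 mm models the head) centred on the rotation centre. A
#' fixed low-discrepancy point set makes the value deterministic.
#'
#' @param state a [rigid_state()].
#' @param radius_mm sphere radius in mm.
#' @param n_points number of interior sample points.
#' @return Mean displacement in mm.
#' @examples
#' average_displacement(rigid_state(t = c(3, 0, 0))) # exactly 3
#' @export
average_displacement <- function(state, radius_mm = 64, n_points = 4096L) {
  if (radius_mm <= 0) stop("radius must be positive")
  P <- sphere_points(n_points) * radius_mm
  R <- rotation_matrix(state$r)
  D <- P %*% (t(R) - diag(3))
  D <- sweep(D, 2, state$t, "+")
  mean(sqrt(rowSums(D^2)))
}

curve_displacements <- function(curve, radius_mm = 64) {
  vapply(seq_along(curve$times_s),
         function(i) average_displacement(curve_state(curve, i), radius_mm),
         numeric(1))
}

#' Centre a motion curve on its median motion state
#'
#' Finds the state whose average displacement is the median over the curve
#' and composes every state with its inverse, so that the median head pose
#' becomes the identity. Reconstructions of the corrupted data are then
#' aligned with the motion-free reference without registration.
#'
#' @param curve a [motion_curve()].
#' @return The centred [motion_curve()], with attribute `median_index`.
#' @export
center_on_median_state <- function(curve) {
  n <- length(curve$times_s)
  if (n == 0L) stop("empty curve")
  d <- curve_displacements(curve)
  m <- order(d)[floor((n + 1) / 2)]
  inv <- invert_state(curve_state(curve, m))
  params <- curve$params
  for (i in seq_len(n)) {
    s <- compose_states(curve_state(curve, i), inv)
    params[i, ] <- c(s$t, s$r)
  }
  out <- motion_curve(curve$times_s, params)
  attr(out, "median_index") <- m
  out
}

#' PCA model and augmentation of motion curves
#'
#' Fits a principal component model to training curves (resampled to a
#' common time grid), then synthesizes new curves as the mean curve plus the
#' leading components weighted by zero-mean normal scores whose standard
#' deviation matches the training scores (scaled by `alpha_scale`). Only the
#' largest `ceiling(component_fraction * N)` components are used, with `N`
#' the number of training curves.
#'
#' @param curves list of [motion_curve()] objects on a common time grid.
#' @param component_fraction fraction of components to keep (default 0.2).
#' @param n_out number of augmented curves to generate (default 90).
#' @param seed integer seed for the random scores.
#' @param alpha_scale multiplier on the training score standard deviations.
#' @return List with `curves` (list of `n_out` motion curves), `model`
#'   (mean, components, score standard deviations, kept indices).
#' @export
pca_augment <- function(curves, component_fraction = 0.2, n_out = 90,
                        seed = NULL, alpha_scale = 1) {
  N <- length(curves)
  if (N < 2L) stop("need at least two training curves")
  tgrid <- curves[[1]]$times_s
  for (cv in curves)
    if (!isTRUE(all.equal(cv$times_s, tgrid)))
      stop("curves must share a common time grid")
  M <- t(vapply(curves, function(cv) as.vector(cv$params), numeric(length(tgrid) * 6)))
  mu <- colMeans(M)
  Cc <- sweep(M, 2, mu)
  sv <- svd(Cc)
  sdev <- sv$d / sqrt(N - 1)
  n_keep <- min(ceiling(component_fraction * N), sum(sv$d > 1e-12))
  comps <- t(sv$v) # rows are components
  alphas <- with_seed(seed, matrix(stats::rnorm(n_out * n_keep), n_out, n_keep))
  alphas <- sweep(alphas, 2, alpha_scale * sdev[seq_len(n_keep)], "*")
  out <- vector("list", n_out)
  for (j in seq_len(n_out)) {
    vec <- mu + as.vector(t(comps[seq_len(n_keep), , drop = FALSE]) %*% alphas[j, ])
    out[[j]] <- motion_curve(tgrid, matrix(vec, length(tgrid), 6))
  }
  model <- list(mean = mu, components = comps, sdev = sdev, n_keep = n_keep,
                scores = Cc %*% sv$v, times_s = tgrid)
  list(curves = out, model = model)
}

#' Per-package reference mask of motion-free lines
#'
#' Marks a (PE line, package) as motion-corrupted when the average
#' displacement of the head pose at its acquisition time exceeds the
#' threshold (default 2 mm, the voxel size). The returned masks use the
#' exclusion-mask convention: 1 = motion-free, 0 = corrupted.
#'
#' @param curve a centred [motion_curve()].
#' @param scheme an [acquisition_times()] scheme.
#' @param threshold_mm displacement threshold in mm.
#' @param radius_mm sphere radius for the displacement metric.
#' @return Named list `odd`, `even` of binary [exclusion_mask()] objects.
#' @export
mark_corrupted_lines <- function(curve, scheme, threshold_mm = 2,
                                 radius_mm = 64) {
  d <- curve_displacements(curve, radius_mm)
  out <- list()
  for (pkg in c("odd", "even")) {
    w <- rep(1, scheme$Y)
    for (pe in seq_len(scheme$Y)) {
      tt <- line_time(scheme, pe, pkg)
      i <- which.min(abs(curve$times_s - tt))
      if (d[i] > threshold_mm) w[pe] <- 0
    }
    out[[pkg]] <- exclusion_mask(w, package = pkg)
  }
  out
}

#' Reference masks from known motion timings
#'
#' Converts instructed/simulated motion intervals into per-package line
#' masks using the known acquisition schedule: a line is corrupted iff its
#' acquisition time falls inside any interval.
#'
#' @param intervals_s list of `c(start, end)` interval pairs in seconds.
#' @param scheme an [acquisition_times()] scheme.
#' @return Named list `odd`, `even` of binary [exclusion_mask()] objects.
#' @export
reference_mask_from_timings <- function(intervals_s, scheme) {
  in_any <- function(tt) {
    for (iv in intervals_s) if (tt >= iv[1] && tt <= iv[2]) return(TRUE)
    FALSE
  }
  out <- list()
  for (pkg in c("odd", "even")) {
    w <- rep(1, scheme$Y)
    for (pe in seq_len(scheme$Y))
      if (in_any(line_time(scheme, pe, pkg))) w[pe] <- 0
    out[[pkg]] <- exclusion_mask(w, package = pkg)
  }
  out
}

#' Smooth random B0 perturbation field
#'
#' White noise low-pass filtered with a Gaussian kernel of width
#' `smoothness_vox` (circular convolution via FFT), rescaled so that the
#' maximum absolute value equals `amplitude_rad_s`. Models the in-plane
#' field change that accompanies a change of head pose.
#'
#' @param shape `c(pe, ro)` of the field.
#' @param amplitude_rad_s peak |omega| in rad/s; 0 gives the zero field.
#' @param smoothness_vox Gaussian width in voxels.
#' @param seed integer seed.
#' @return Numeric matrix `[pe, ro]`.
#' @export
sample_b0_perturbation <- function(shape, amplitude_rad_s, smoothness_vox = 4,
                                   seed = NULL) {
  if (amplitude_rad_s < 0) stop("amplitude must be non-negative")
  if (amplitude_rad_s == 0) return(matrix(0, shape[1], shape[2]))
  z <- with_seed(seed, matrix(stats::rnorm(prod(shape)), shape[1], shape[2]))
  sm <- gaussian_filter_2d(z, smoothness_vox)
  sm * (amplitude_rad_s / max(abs(sm)))
}

# Circular Gaussian smoothing of a real matrix via FFT.
gaussian_filter_2d <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  d <- dim(x)
  k1 <- stats::dnorm(ang_dist(d[1]), sd = sigma_vox)
  k2 <- stats::dnorm(ang_dist(d[2]), sd = sigma_vox)
  K <- outer(k1, k2); K <- K / sum(K)
  Re(stats::fft(stats::fft(x) * stats::fft(K), inverse = TRUE)) / length(x)
}

ang_dist <- function(n) {
  i <- seq_len(n) - 1
  pmin(i, n - i)
}

#' Synthetic motion curve with discrete movement events
#'
#' Emulates a subject who lies still apart from `n_events` brief movements
#' (random onset, duration drawn from `event_duration_s_range`, pairwise
#' disjoint). Each event holds a random rigid pose scaled so its average
#' displacement matches `amplitude_mm`.
#'
#' @param scan_duration_s total scan duration in seconds.
#' @param n_events number of movement events (>= 0).
#' @param event_duration_s_range duration range `c(min, max)` in seconds.
#' @param amplitude_mm target average displacement during events.
#' @param seed integer seed.
#' @param dt_s curve sampling interval in seconds.
#' @param rot_per_mm degrees of rotation mixed in per mm of translation in
#'   the raw (pre-scaling) event pose.
#' @return A [motion_curve()] with attribute `events` (matrix of
#'   onset/offset times).
#' @export
synthetic_motion_curve <- function(scan_duration_s, n_events,
                                   event_duration_s_range = c(5, 10),
                                   amplitude_mm = 3, seed = NULL,
                                   dt_s = 0.5, rot_per_mm = 0.5) {
  times <- seq(0, scan_duration_s, by = dt_s)
  params <- matrix(0, length(times), 6)
  events <- matrix(numeric(0), 0, 2)
  if (n_events > 0) {
    res <- with_seed(seed, {
      durs <- stats::runif(n_events, event_duration_s_range[1],
                           event_duration_s_range[2])
      if (sum(durs) >= scan_duration_s)
        stop("events cannot fit into the scan duration without overlap")
      placed <- matrix(0, 0, 2)
      for (kdur in durs) {
        ok <- FALSE
        for (try in seq_len(2000)) {
          onset <- stats::runif(1, 0, scan_duration_s - kdur)
          iv <- c(onset, onset + kdur)
          if (nrow(placed) == 0 ||
              all(iv[2] < placed[, 1] | iv[1] > placed[, 2])) {
            placed <- rbind(placed, iv); ok <- TRUE; break
          }
        }
        if (!ok) stop("events cannot fit into the scan duration without overlap")
      }
      poses <- lapply(seq_len(n_events), function(k) {
        tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
        rdir <- stats::rnorm(3); rdir <- rdir / sqrt(sum(rdir^2))
        c(tdir, rdir * rot_per_mm)
      })
      list(placed = placed, poses = poses)
    })
    events <- res$placed
    for (k in seq_len(n_events)) {
      pose <- scale_pose_to_displacement(res$poses[[k]], amplitude_mm)
      sel <- times >= events[k, 1] & times <= events[k, 2]
      params[sel, ] <- matrix(pose, sum(sel), 6, byrow = TRUE)
    }
  }
  out <- motion_curve(times, params)
  attr(out, "events") <- events
  out
}

#' Motion curve with events at prescribed timings
#'
#' Like [synthetic_motion_curve()] but with explicit event intervals, for
#' experiments where the corrupted lines must be known exactly (the analog
#' of instructed-motion timing experiments).
#'
#' @param intervals_s list of `c(start, end)` event intervals in seconds.
#' @param amplitude_mm target average displacement during events.
#' @param scan_duration_s scan duration in seconds.
#' @param seed seed for the random event poses.
#' @param dt_s curve sampling interval.
#' @param rot_per_mm rotation-translation mixing of the raw pose.
#' @return A [motion_curve()] with attribute `events`.
#' @export
event_motion_curve <- function(intervals_s, amplitude_mm, scan_duration_s,
                               seed = NULL, dt_s = 0.5, rot_per_mm = 0.5) {
  times <- seq(0, scan_duration_s, by = dt_s)
  params <- matrix(0, length(times), 6)
  poses <- with_seed(seed, lapply(seq_along(intervals_s), function(k) {
    tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
    rdir <- stats::rnorm(3); rdir <- rdir / sqrt(sum(rdir^2))
    c(tdir, rdir * rot_per_mm)
  }))
  events <- matrix(0, length(intervals_s), 2)
  for (k in seq_along(intervals_s)) {
    iv <- intervals_s[[k]]
    events[k, ] <- iv
    pose <- scale_pose_to_displacement(poses[[k]], amplitude_mm)
    sel <- times >= iv[1] & times <= iv[2]
    params[sel, ] <- matrix(pose, sum(sel), 6, byrow = TRUE)
  }
  out <- motion_curve(times, params)
  attr(out, "events") <- events
  out
}

# Scale a raw 6-vector pose so average_displacement hits the target (a few
# fixed-point iterations; displacement is near-linear in the parameters).
scale_pose_to_displacement <- function(pose, target_mm) {
  if (target_mm == 0) return(rep(0, 6))
  sc <- 1
  for (i in 1:4) {
    d <- average_displacement(rigid_state(pose[1:3] * sc, pose[4:6] * sc))
    if (d == 0) break
    sc <- sc * target_mm / d
  }
  pose * sc
}

#' Simulate a motion-corrupted acquisition
#'
#' Applies the motion forward model line by line: PE lines whose head pose
#' stays within `threshold_mm` average displacement sample the static
#' k-space; lines acquired during motion sample the k-space of the
#' transformed image, including an off-resonance phase from a random B0
#' perturbation field scaled linearly by `displacement / threshold`,
#' coupling the severity of the field change to that of the pose. Also
#' returns the per-package reference masks implied by the same threshold.
#'
#' @param clean_images motion-free image stack `[pe, ro, slice, echo]`.
#' @param csm [coil_sensitivities()].
#' @param curve a centred [motion_curve()].
#' @param scheme an [acquisition_times()] scheme.
#' @param te_ms echo times (ms).
#' @param b0_cfg list with `amplitude_rad_s`, `smoothness_vox`, `seed` for
#'   the perturbation field; `NULL` disables the B0 component.
#' @param threshold_mm displacement threshold (mm).
#' @param tr_ms,spacing_mm,phase_gain forwarded to the forward model.
#' @return List `kspace` ([kspace_volume()]) and `ref_mask` (list `odd`,
#'   `even` of binary masks, 1 = motion-free).
#' @export
simulate_corrupted_kspace <- function(clean_images, csm, curve, scheme, te_ms,
                                      b0_cfg = list(amplitude_rad_s = 5,
                                                    smoothness_vox = 6,
                                                    seed = 0),
                                      threshold_mm = 2,
                                      tr_ms = scheme$tr_ms,
                                      spacing_mm = c(2, 2), phase_gain = 2) {
  d <- dim(clean_images)
  if (d[1L] != scheme$Y) stop("image PE size does not match the scheme")
  disp <- curve_displacements(curve)
  omega0 <- if (!is.null(b0_cfg) && b0_cfg$amplitude_rad_s > 0)
    sample_b0_perturbation(c(d[1L], d[2L]), b0_cfg$amplitude_rad_s,
                           b0_cfg$smoothness_vox %||% 6, b0_cfg$seed %||% 0)
  else NULL
  entries <- scheme$entries
  states <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    ci <- which.min(abs(curve$times_s - entries$time_s[i]))
    if (disp[ci] > threshold_mm) {
      om <- if (is.null(omega0)) NULL else
        omega0 * (disp[ci] / threshold_mm)
      states[[i]] <- rigid_state(curve$params[ci, 1:3], curve$params[ci, 4:6],
                                 omega = om)
    } else {
      states[[i]] <- rigid_state()
    }
  }
  ks <- forward_acquire(clean_images, csm, scheme, states, te_ms,
                        tr_ms = tr_ms, spacing_mm = spacing_mm,
                        phase_gain = phase_gain)
  list(kspace = ks,
       ref_mask = mark_corrupted_lines(curve, scheme, threshold_mm))
}
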