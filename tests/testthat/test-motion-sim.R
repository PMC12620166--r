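test_that("average displacement: identity, pure translation, rotation oracle", {
  expect_equal(average_displacement(rigid_state()), 0)
  expect_equal(average_displacement(rigid_state(t = c(3, 0, 0))), 3)

  # 10 degree rotation about z: Monte-Carlo oracle over uniform interior
  st <- rigid_state(r = c(0, 0, 10))
  mc <- withr::with_seed(42, {
    p <- matrix(stats::runif(3e6, -1, 1), ncol = 3)
    p <- p[rowSums(p^2) <= 1, , drop = FALSE] * 64
    R <- t2moco:::rotation_matrix(c(0, 0, 10))
    d <- p %*% (t(R) - diag(3))
    mean(sqrt(rowSums(d^2)))
  })
  expect_lt(abs(average_displacement(st) - mc) / mc, 0.005)
})

test_that("median-state centering", {
  idc <- motion_curve(0:4, matrix(0, 5, 6))
  expect_equal(center_on_median_state(idc)$params, idc$params)

  cst <- motion_curve(0:4, matrix(rep(c(2, -1, 0.5, 3, -2, 1), each = 5), 5, 6))
  cc <- center_on_median_state(cst)
  expect_lt(max(abs(cc$params)), 1e-10)

  cv <- synthetic_motion_curve(60, 2, c(5, 8), amplitude_mm = 4, seed = 3)
  cen <- center_on_median_state(cv)
  d <- t2moco:::curve_displacements(cen)
  expect_lt(stats::median(d), 1e-8)
})

test_that("PCA augmentation: mean curve, completeness, count, variance bound", {
  tg <- seq(0, 10, 0.5)
  curves <- withr::with_seed(5, lapply(1:10, function(i) {
    base <- outer(sin(tg / 2 + i), c(1, 0.5, 0.2, 0.1, 0.3, 0.05))
    motion_curve(tg, base + 0.1 * matrix(stats::rnorm(length(tg) * 6),
                                         length(tg)))
  }))
  # zero scores -> every output is the mean curve
  out0 <- pca_augment(curves, n_out = 4, seed = 1, alpha_scale = 0)
  mu <- Reduce(`+`, lapply(curves, function(cv) cv$params)) / 10
  for (cv in out0$curves) expect_equal(cv$params, mu, tolerance = 1e-10)

  # reconstructing a training curve from all components with its own scores
  aug <- pca_augment(curves, n_out = 90, seed = 2)
  expect_length(aug$curves, 90)
  md <- aug$model
  rec <- md$mean + as.vector(t(md$components) %*% md$scores[3, ])
  expect_lt(max(abs(rec - as.vector(curves[[3]]$params))), 1e-8)

  # retained-subspace variance of augmented curves stays bounded
  alpha_scale <- 1
  big <- pca_augment(curves, n_out = 500, seed = 3,
                     alpha_scale = alpha_scale)
  Maug <- t(vapply(big$curves, function(cv) as.vector(cv$params),
                   numeric(length(tg) * 6)))
  proj_aug <- sweep(Maug, 2, md$mean) %*% t(md$components[seq_len(md$n_keep), , drop = FALSE])
  v_aug <- apply(proj_aug, 2, stats::var)
  v_train <- md$sdev[seq_len(md$n_keep)]^2
  expect_true(all(v_aug <= v_train * (1 + alpha_scale^2)))
  expect_error(pca_augment(curves[1]), "at least two")
})

test_that("B0 perturbation field: zero amplitude, determinism, smoothness", {
  z <- sample_b0_perturbation(c(16, 12), 0, 4, seed = 1)
  expect_equal(z, matrix(0, 16, 12))
  a <- sample_b0_perturbation(c(16, 12), 30, 3, seed = 2)
  b <- sample_b0_perturbation(c(16, 12), 30, 3, seed = 2)
  expect_identical(a, b)
  expect_equal(max(abs(a)), 30)

  lag1 <- function(f) stats::cor(as.vector(f[-1, ]), as.vector(f[-nrow(f), ]))
  ac_smooth <- mean(sapply(1:100, function(s)
    lag1(sample_b0_perturbation(c(32, 32), 1, 6, seed = s))))
  ac_rough <- mean(sapply(1:100, function(s)
    lag1(sample_b0_perturbation(c(32, 32), 1, 1.5, seed = s))))
  expect_gt(ac_smooth, ac_rough)
})

test_that("corrupted-line marking follows the displacement threshold and timing", {
  sch <- acquisition_times(24, 1000)
  idc <- motion_curve(seq(0, sch$scan_duration_s, 0.5),
                      matrix(0, length(seq(0, sch$scan_duration_s, 0.5)), 6))
  rm0 <- mark_corrupted_lines(idc, sch)
  expect_equal(rm0$odd$line_weights, rep(1, 24))
  expect_equal(rm0$even$line_weights, rep(1, 24))

  # constant 5-mm translation covering odd-package lines 10..20 exactly
  times <- seq(0, sch$scan_duration_s, 0.25)
  par <- matrix(0, length(times), 6)
  ev <- times >= 9 & times <= 19.4 # line k acquired at (k-1)*1 s, odd package
  par[ev, 1] <- 5
  cv <- motion_curve(times, par)
  rm <- mark_corrupted_lines(cv, sch)
  expect_equal(which(rm$odd$line_weights == 0), 10:20)

  rmi <- mark_corrupted_lines(cv, sch, threshold_mm = Inf)
  expect_equal(sum(rmi$odd$line_weights == 0) +
                 sum(rmi$even$line_weights == 0), 0)
})

test_that("reference masks from timing intervals", {
  sch <- acquisition_times(30, 1000)
  r0 <- reference_mask_from_timings(list(), sch)
  expect_equal(r0$odd$line_weights, rep(1, 30))
  # one interval covering the times of 9 consecutive odd-package lines
  r9 <- reference_mask_from_timings(list(c(3.9, 12.1)), sch)
  expect_equal(sum(r9$odd$line_weights == 0), 9)
  rall <- reference_mask_from_timings(list(c(0, sch$scan_duration_s)), sch)
  expect_equal(sum(rall$odd$line_weights) + sum(rall$even$line_weights), 0)
})

test_that("synthetic motion curves: stillness, disjoint events, amplitude scaling", {
  c0 <- synthetic_motion_curve(100, 0, amplitude_mm = 3, seed = 1)
  expect_equal(max(abs(c0$params)), 0)

  cv <- synthetic_motion_curve(120, 4, c(5, 10), amplitude_mm = 3, seed = 2)
  ev <- attr(cv, "events")
  expect_equal(nrow(ev), 4)
  expect_true(all(ev >= 0 & ev <= 120))
  ord <- ev[order(ev[, 1]), , drop = FALSE]
  expect_true(all(ord[-1, 1] > ord[-nrow(ord), 2]))

  peaks <- sapply(c(1, 3, 6), function(a) {
    cc <- synthetic_motion_curve(120, 2, c(5, 10), amplitude_mm = a, seed = 9)
    max(t2moco:::curve_displacements(cc))
  })
  expect_true(all(diff(peaks) > 0))
  expect_equal(peaks, c(1, 3, 6), tolerance = 0.05)
  expect_error(synthetic_motion_curve(15, 4, c(5, 10), 3, seed = 1),
               "cannot fit")
})

test_that("simulated corruption: identity passthrough and row-wise locality", {
  ph <- tiny_phantom()
  sch <- acquisition_times(dim(ph$images)[1], ph$tr_ms)
  idc <- motion_curve(c(0, sch$scan_duration_s), matrix(0, 2, 6))
  sim0 <- simulate_corrupted_kspace(ph$images, ph$csm, idc, sch, ph$te_ms)
  expect_identical(sim0$kspace$data, ph$kspace$data)
  expect_equal(sum(sim0$ref_mask$odd$line_weights == 0), 0)

  sc <- simulate_event_scenario(ph, lines = 8:13, amplitude_mm = 5)
  sim <- sc$sim
  # mask returned by the simulation equals mark_corrupted_lines
  rm <- mark_corrupted_lines(sc$curve, sc$scheme)
  expect_identical(sim$ref_mask$odd$line_weights, rm$odd$line_weights)
  expect_identical(sim$ref_mask$even$line_weights, rm$even$line_weights)

  # corrupted fraction matches the above-threshold fraction of entries
  disp <- t2moco:::curve_displacements(sc$curve)
  frac_time <- mean(sapply(seq_len(nrow(sc$scheme$entries)), function(i) {
    ci <- which.min(abs(sc$curve$times_s - sc$scheme$entries$time_s[i]))
    disp[ci] > 2
  }))
  frac_mask <- mean(c(sim$ref_mask$odd$line_weights,
                      sim$ref_mask$even$line_weights) == 0)
  expect_equal(frac_mask, frac_time)

  # only rows flagged corrupted differ from the static k-space
  for (pkg in c("odd", "even")) {
    sl <- t2moco:::slices_of_package(dim(ph$images)[3], pkg)
    bad <- which(sim$ref_mask[[pkg]]$line_weights == 0)
    good <- setdiff(seq_len(dim(ph$images)[1]), bad)
    diffs <- Mod(sim$kspace$data[, , sl, , , drop = FALSE] -
                   ph$kspace$data[, , sl, , , drop = FALSE])
    expect_lt(max(diffs[good, , , , ]), 1e-10)
    expect_gt(max(diffs[bad, , , , ]), 1e-6)
  }
})
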