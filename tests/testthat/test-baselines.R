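test_that("bootstrap-aggregation reconstruction: degenerate case and determinism", {
  ph <- tiny_phantom()
  d <- dim(ph$images)
  nz <- normalize_volume(ph$kspace, ph$csm)
  # one mask at rate 0 is the plain full reconstruction
  x1 <- orba_reconstruct(nz$data, ph$csm, unrolled_config(), n_masks = 1,
                         exclusion_rate = 0, seed = 1)
  W <- matrix(1, d[1], d[2])
  xf <- unrolled_reconstruct(nz$data$data, W, ph$csm, unrolled_config())
  expect_lt(max(Mod(x1 - xf)), 1e-12)

  a <- orba_reconstruct(nz$data, ph$csm, unrolled_config(), n_masks = 3,
                        seed = 7)
  b <- orba_reconstruct(nz$data, ph$csm, unrolled_config(), n_masks = 3,
                        seed = 7)
  expect_identical(a, b)
  expect_error(orba_reconstruct(nz$data, ph$csm, n_masks = 0), "n_masks")

  # averaging undersampled reconstructions blurs: worse than the full recon
  xo <- orba_reconstruct(nz$data, ph$csm, unrolled_config(), n_masks = 5,
                         seed = 2)
  expect_gt(phantom_t2star_mae(xo, ph), phantom_t2star_mae(xf, ph))
})

test_that("bootstrap mask generator honours its exclusion rate", {
  means <- sapply(1:300, function(s)
    mean(variable_density_line_mask(92, 0.5, seed = s)$line_weights))
  expect_lt(abs(mean(means) - 0.5), 0.01)
})

test_that("HR/QR combination arithmetic per k-space region", {
  ph <- tiny_phantom()
  yf <- ph$kspace
  # identical acquisitions: combination returns the full acquisition
  out <- hrqr_combine(yf, yf, yf)
  expect_lt(max(Mod(out$data - yf$data)), 1e-12)

  Y <- dim(yf$data)[1]
  half <- t2moco:::central_band(Y, Y %/% 2)
  quarter <- t2moco:::central_band(Y, Y %/% 4)
  # uniform weights with y_q = 3 y_f, y_h = 2 y_f on a central-quarter line
  out2 <- hrqr_combine(yf, kspace_volume(yf$data * 2, yf$te_ms, yf$tr_ms),
                       kspace_volume(yf$data * 3, yf$te_ms, yf$tr_ms))
  q1 <- quarter[1]
  expect_lt(max(Mod(out2$data[q1, , , , ] - 2 * yf$data[q1, , , , ])), 1e-10)
  h1 <- setdiff(half, quarter)[1]
  expect_lt(max(Mod(out2$data[h1, , , , ] - 1.5 * yf$data[h1, , , , ])), 1e-10)
  # peripheral lines always copy the full acquisition
  per <- setdiff(seq_len(Y), half)
  expect_lt(max(Mod(out2$data[per, , , , ] - yf$data[per, , , , ])), 1e-12)
  expect_error(hrqr_combine(yf, yf, kspace_volume(yf$data[, , 1, , ,
                                                          drop = FALSE],
                                                  yf$te_ms, yf$tr_ms)),
               "coverage mismatch")
})

test_that("line-detection metrics match their definitions", {
  expect_equal(mask_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))$mae, 0)
  p0 <- mask_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(p0$accuracy, 1); expect_equal(p0$precision, 1)
  expect_equal(p0$recall, 1)
  expect_equal(mask_metrics(c(0, 0, 1, 1), c(1, 1, 0, 0))$accuracy, 0)

  m <- mask_metrics(c(0.9, 0.4, 0.2, 0.6), c(1, 1, 0, 0))
  expect_equal(m$mae, 0.375)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(nrow(m$pr_curve), 101)
  expect_true(all(m$pr_curve$precision >= 0 & m$pr_curve$precision <= 1))
  expect_error(mask_metrics(c(1, 0), c(1, 0, 1)), "length mismatch")
  expect_error(mask_metrics(c(1, 0), c(0.4, 1)), "binary")
})

test_that("SSIM map matches a brute-force windowed evaluation", {
  set.seed(14)
  a <- matrix(stats::runif(20 * 18, 0, 200), 20, 18)
  b <- a + matrix(stats::rnorm(20 * 18, sd = 10), 20, 18)
  L <- 200; c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  k <- stats::dnorm(-3:3, sd = 1.5); k <- k / sum(k)
  sm <- ssim_map(a, b, L)
  # brute force at interior pixels: explicit Gaussian-window moments
  for (ij in list(c(6, 7), c(10, 10), c(14, 5))) {
    i <- ij[1]; j <- ij[2]
    wa <- a[i + (-3:3), j + (-3:3)]; wb <- b[i + (-3:3), j + (-3:3)]
    W <- outer(k, k)
    mua <- sum(W * wa); mub <- sum(W * wb)
    va <- sum(W * wa^2) - mua^2; vb <- sum(W * wb^2) - mub^2
    cab <- sum(W * wa * wb) - mua * mub
    ref <- ((2 * mua * mub + c1) * (2 * cab + c2)) /
      ((mua^2 + mub^2 + c1) * (va + vb + c2))
    expect_equal(sm[i, j], ref, tolerance = 1e-10)
  }
})

test_that("map metrics: exact match, constant offset, threshold monotonicity", {
  ph <- tiny_phantom()
  t2 <- ph$t2star_map
  eq <- t2star_map_metrics(t2, t2, ph$brain_mask, ph$sg_map,
                           sg_threshold = 1e4)
  expect_true(all(eq$mae_ms == 0))
  expect_true(all(abs(eq$ssim - 1) < 1e-12))

  off <- t2star_map_metrics(t2 + 5, t2, ph$brain_mask, ph$sg_map,
                            sg_threshold = 1e4)
  expect_true(all(abs(off$mae_ms - 5) < 1e-9))

  n80 <- sum(ph$brain_mask & ph$sg_map < 80)
  n100 <- sum(ph$brain_mask & ph$sg_map < 100)
  expect_gte(n100, n80)
  ev100 <- suppressWarnings(
    t2star_map_metrics(t2, t2, ph$brain_mask, ph$sg_map,
                       sg_threshold = 100))
  expect_true(all(ev100$n_vox >= 0))
  expect_warning(
    t2star_map_metrics(t2[, , 1, drop = FALSE], t2[, , 1, drop = FALSE],
                       ph$brain_mask[, , 1, drop = FALSE] & FALSE,
                       ph$sg_map[, , 1, drop = FALSE]),
    "empty evaluation mask")
})
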