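test_that("phantom obeys its own signal model and forward model", {
  ph <- tiny_phantom()
  te <- ph$te_ms
  # within-compartment echo ratio equals exp(-dTE / T2*)
  mag <- Mod(ph$images)
  sel <- which(ph$brain_mask)
  r12 <- (matrix(mag[, , , 2], ncol = 1)[sel] /
            matrix(mag[, , , 1], ncol = 1)[sel])
  expected <- exp(-(te[2] - te[1]) / ph$t2star_map[sel])
  expect_lt(max(abs(r12 - expected)), 1e-6)

  # clean k-space is exactly the static forward model of the clean images
  expect_identical(ph$kspace$data, sense_forward(ph$images, ph$csm))

  # coil maps have unit RSS everywhere the coils see signal
  rss <- sqrt(apply(Mod(ph$csm$csm)^2, c(1, 2, 3), sum))
  expect_lt(max(abs(rss[ph$brain_mask] - 1)), 1e-6)

  # seeded determinism and protocol defaults
  p1 <- make_digital_phantom(pe = 24, ro = 16, n_slices = 2, n_echoes = 3,
                             n_coils = 2, seed = 4)
  p2 <- make_digital_phantom(pe = 24, ro = 16, n_slices = 2, n_echoes = 3,
                             n_coils = 2, seed = 4)
  expect_identical(p1$images, p2$images)
  big <- study_phantom()
  expect_equal(big$te_ms, seq(5, 60, 5))
  expect_equal(dim(big$kspace$data)[5], 12)
  bf <- slice_brain_fraction(big)
  mid <- seq(3, 6)
  expect_true(all(bf[mid] > 0.2 & bf[mid] < 0.9))
  expect_error(make_digital_phantom(pe = 23), "even")
})

test_that("k-space containers round trip and validate their schema", {
  ph <- tiny_phantom()
  dir <- file.path(tempdir(), "ct1")
  write_kspace_container(dir, ph$kspace, csm = ph$csm,
                         brain_mask = ph$brain_mask, sg_map = ph$sg_map)
  ct <- read_kspace_container(dir)
  # float32 storage: one quantization, then exact idempotence
  expect_equal(ct$kspace$data, ph$kspace$data,
               tolerance = 1e-6)
  expect_equal(ct$kspace$te_ms, ph$te_ms)
  expect_equal(ct$kspace$tr_ms, ph$tr_ms)
  expect_identical(ct$brain_mask, ph$brain_mask)
  dir2 <- file.path(tempdir(), "ct2")
  write_kspace_container(dir2, ct$kspace, csm = ct$csm,
                         brain_mask = ct$brain_mask, sg_map = ct$sg_map)
  ct2 <- read_kspace_container(dir2)
  expect_identical(ct2$kspace$data, ct$kspace$data)
  expect_identical(ct2$sg_map, ct$sg_map)

  # schema error names the missing field
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  meta$attrs$te_ms <- NULL
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_kspace_container(dir), "te_ms")
})

test_that("phantom container round trip", {
  ph <- make_digital_phantom(pe = 24, ro = 16, n_slices = 2, n_echoes = 3,
                             n_coils = 2, seed = 4)
  dir <- file.path(tempdir(), "ph1")
  write_phantom(dir, ph)
  ph2 <- read_phantom(dir)
  expect_equal(ph2$images, ph$images, tolerance = 1e-6)
  expect_equal(ph2$t2star_map, ph$t2star_map, tolerance = 1e-5)
  expect_identical(ph2$brain_mask, ph$brain_mask)
  expect_equal(ph2$te_ms, ph$te_ms)
})

test_that("mask and motion-curve CSV round trips", {
  w <- withr::with_seed(3, stats::runif(30))
  mo <- exclusion_mask(w, "odd")
  me <- exclusion_mask(rev(w), "even")
  path <- file.path(tempdir(), "masks.csv")
  write_mask_csv(path, mo, me)
  rt <- read_mask_csv(path)
  expect_equal(rt$odd$line_weights, w, tolerance = 1e-6)
  expect_equal(rt$even$line_weights, rev(w), tolerance = 1e-6)

  cv <- synthetic_motion_curve(60, 2, c(5, 8), amplitude_mm = 3, seed = 5)
  cpath <- file.path(tempdir(), "curve.csv")
  write_motion_curve_csv(cpath, cv)
  cv2 <- read_motion_curve_csv(cpath)
  expect_equal(cv2$times_s, cv$times_s)
  expect_equal(unname(cv2$params), unname(cv$params), tolerance = 1e-12)

  bad <- data.frame(a = 1)
  bpath <- file.path(tempdir(), "bad.csv")
  utils::write.csv(bad, bpath, row.names = FALSE)
  expect_error(read_mask_csv(bpath), "line_index")
})

test_that("NIfTI map round trip", {
  m <- withr::with_seed(8, array(stats::runif(24 * 16 * 2, 0, 200),
                                 c(24, 16, 2)))
  path <- file.path(tempdir(), "map.nii.gz")
  write_map_nifti(m, path)
  m2 <- read_map_nifti(path)
  expect_equal(dim(m2), dim(m))
  expect_equal(m2, m, tolerance = 1e-5)
})
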