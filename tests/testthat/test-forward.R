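test_that("motion operator: identity, integer shift, phase-only states", {
  p <- random_complex_plane(16, 16, seed = 2)
  expect_identical(apply_motion_operator(p, rigid_state(), 5), p)

  # 2-voxel in-plane shift along readout (spacing 2 mm -> 4 mm translation)
  out <- apply_motion_operator(p, rigid_state(t = c(4, 0, 0)), 5)
  shifted <- cbind(matrix(0i, 16, 2), p[, 1:14])
  expect_lt(max(Mod(out[, 3:16] - shifted[, 3:16])), 1e-12)

  ph_only <- apply_motion_operator(p, rigid_state(omega = 30), te_ms = 20)
  expect_lt(max(abs(Mod(ph_only) - Mod(p))), 1e-10)
  # phase as printed: exp(-2 i omega TE)
  expect_lt(max(Mod(ph_only - p * exp(-2i * 30 * 0.020))), 1e-12)
  conv <- apply_motion_operator(p, rigid_state(omega = 30), te_ms = 20,
                                phase_gain = 1)
  expect_lt(max(Mod(conv - p * exp(-1i * 30 * 0.020))), 1e-12)

  expect_error(apply_motion_operator(p, rigid_state(), 5, interp = "cubic"),
               "unsupported interpolation")
})

test_that("static forward model: collapse to multicoil FFT, adjoint, linearity", {
  ph <- tiny_phantom()
  d <- dim(ph$images)
  sch <- acquisition_times(d[1], ph$tr_ms)
  states <- rep(list(rigid_state()), nrow(sch$entries))
  ks <- forward_acquire(ph$images, ph$csm, sch, states, ph$te_ms)
  expect_lt(max(Mod(ks$data - sense_forward(ph$images, ph$csm))), 1e-12)
  expect_lt(max(Mod(ks$data - ph$kspace$data)), 1e-12)

  # adjoint: |<A x, y> - <x, A^H y>| / (|x||y|) on random 32x32, 2-coil
  csm <- coil_sensitivities(random_complex_array(c(32, 32, 1, 2), seed = 3))
  x <- random_complex_array(c(32, 32, 1, 2), seed = 4)
  y <- random_complex_array(c(32, 32, 1, 2, 2), seed = 5)
  lhs <- sum(Conj(y) * sense_forward(x, csm))
  rhs <- sum(Conj(sense_adjoint(y, csm)) * x)
  den <- sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(y)^2))
  expect_lt(Mod(lhs - rhs) / den, 1e-6)

  x2 <- random_complex_array(dim(ph$images), seed = 6)
  a <- sense_forward(2 * ph$images - 3i * x2, ph$csm)
  b <- 2 * sense_forward(ph$images, ph$csm) - 3i * sense_forward(x2, ph$csm)
  expect_lt(max(Mod(a - b)) / max(Mod(a)), 1e-8)
  expect_equal(max(Mod(sense_forward(ph$images * 0, ph$csm))), 0)
})

test_that("forward_acquire validates the state count", {
  ph <- tiny_phantom()
  sch <- acquisition_times(dim(ph$images)[1], ph$tr_ms)
  expect_error(forward_acquire(ph$images, ph$csm, sch,
                               rep(list(rigid_state()), 3), ph$te_ms),
               "one rigid state per scheme entry")
})

test_that("KeepCenter expansion forces exactly the central 2x2 block", {
  plane <- expand_mask_keepcenter(rep(0, 12), 8, keepcenter = TRUE)
  expect_equal(sum(plane), 4)
  expect_equal(plane[6:7, 4:5], matrix(1, 2, 2))

  ones <- expand_mask_keepcenter(rep(1, 12), 8, keepcenter = TRUE)
  expect_equal(ones, matrix(1, 12, 8))

  w <- seq(0, 1, length.out = 12)
  off <- expand_mask_keepcenter(w, 8, keepcenter = FALSE)
  expect_equal(off, matrix(w, 12, 8))
  expect_error(expand_mask_keepcenter(rep(1, 11), 8), "even")
})

test_that("masking commutes with broadcast", {
  y <- random_complex_array(c(12, 8, 2, 2, 3), seed = 9)
  w <- withr::with_seed(1, stats::runif(12))
  plane <- expand_mask_keepcenter(w, 8, keepcenter = FALSE)
  a <- weight_kspace(y, plane)
  b <- y
  for (pe in 1:12) b[pe, , , , ] <- w[pe] * y[pe, , , , ]
  expect_identical(a, b)
})

test_that("variable-density mask: counts, determinism, density law", {
  expect_equal(variable_density_line_mask(92, 0)$line_weights, rep(1, 92))
  m <- variable_density_line_mask(92, 0.5, seed = 3)
  expect_equal(sum(m$line_weights == 0), 46)
  m2 <- variable_density_line_mask(92, 0.5, seed = 3)
  expect_identical(m$line_weights, m2$line_weights)
  m3 <- variable_density_line_mask(92, 0.5, seed = 4)
  expect_gt(sum(m3$line_weights != m$line_weights), 0)
  expect_error(variable_density_line_mask(92, 1.0), "exclusion_rate")

  # periphery is excluded more often than the centre; DC is never excluded
  draws <- sapply(1:300, function(s)
    variable_density_line_mask(92, 0.5, seed = s)$line_weights)
  excl <- 1 - rowMeans(draws)
  expect_equal(excl[47], 0) # DC line
  expect_gt(mean(excl[c(1:10, 83:92)]), mean(excl[38:56]))
})

test_that("acquisition timing of the interleaved packages", {
  sch <- acquisition_times(92, 2300)
  expect_equal(sch$scan_duration_s, 92 * 2.3)
  odd_times <- sch$entries$time_s[sch$entries$package == "odd"]
  even_times <- sch$entries$time_s[sch$entries$package == "even"]
  expect_equal(max(odd_times), 91 * 2.3) # last odd-package line
  expect_equal(sort(even_times) - sort(odd_times),
               rep(0.5 * 2.3, 92)) # half-TR package offset
  expect_true(all(diff(sort(odd_times)) > 0))
  expect_true(all(diff(sort(even_times)) > 0))
  expect_true(all(sch$entries$time_s >= 0 &
                    sch$entries$time_s <= sch$scan_duration_s))
  # each (pe, package) pair appears exactly once
  expect_equal(nrow(unique(sch$entries[, c("pe_index", "package")])),
               2 * 92)
  expect_error(acquisition_times(92, 2300, ordering = "spiral"),
               "unknown PE ordering")
})
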