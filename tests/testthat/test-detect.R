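test_that("exclusion regularizer values and central window", {
  expect_equal(exclusion_regularizer(rep(1, 92), 0.005, 2), 0)
  expect_equal(exclusion_regularizer(rep(0, 92), 0.005, 2), 0.015)
  m <- rep(1, 92)
  m[t2moco:::central_window_10(92)] <- 0
  expect_equal(exclusion_regularizer(m, 0.005, 2),
               0.005 * (10 / 92 + 2), tolerance = 1e-12)
  expect_length(t2moco:::central_window_10(92), 10)
  expect_true((92 / 2 + 1) %in% t2moco:::central_window_10(92)) # DC inside
  expect_error(exclusion_regularizer(rep(1, 8)), "at least 10")

  # analytic gradient against finite differences
  w <- withr::with_seed(2, stats::runif(20))
  g <- t2moco:::exclusion_regularizer_grad(w, 0.005, 2)
  h <- 1e-7
  for (i in c(1, 6, 11, 20)) {
    wp <- w; wm <- w; wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
    num <- (exclusion_regularizer(wp, 0.005, 2) -
              exclusion_regularizer(wm, 0.005, 2)) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-6)
  }
})

test_that("slice selection filters by brain fraction and susceptibility", {
  cfg <- detect_config()
  expect_equal(select_optimization_slices(rep(0, 12), rep(0.5, 12), cfg),
               1:8)
  expect_error(select_optimization_slices(rep(120, 6), rep(0.5, 6), cfg),
               "no slice passes")
  sg <- c(90, 70, 85, 60, 50, 40, 30, 20, 10, 5)
  sel <- select_optimization_slices(sg, rep(0.5, 10), cfg)
  expect_equal(sel, c(2, 4, 5, 6, 7, 8, 9, 10))
  # low-brain slices are rejected too
  bf <- rep(0.5, 10); bf[2] <- 0.1
  expect_false(2 %in% select_optimization_slices(sg, bf, cfg))
})

test_that("per-slice mask assignment follows 0-based parity", {
  me <- exclusion_mask(rep(1, 8), "even")
  mo <- exclusion_mask(rep(0.5, 8), "odd")
  out <- masks_for_all_slices(me, mo, 4)
  expect_identical(out[[1]], me); expect_identical(out[[2]], mo)
  expect_identical(out[[3]], me); expect_identical(out[[4]], mo)
  flip <- masks_for_all_slices(me, mo, 4, parity_flip = TRUE)
  expect_identical(flip[[1]], mo); expect_identical(flip[[2]], me)
  same <- masks_for_all_slices(me, me, 3)
  expect_true(all(vapply(same, identical, logical(1), me)))
  expect_error(masks_for_all_slices(me, mo, 0), "n_slices")
})

test_that("mask optimization decreases its objective and is deterministic", {
  ph <- tiny_phantom()
  sc <- simulate_event_scenario(ph, lines = 8:13, amplitude_mm = 6)
  cfgs <- lapply(0:2, function(s)
    detect_config(epochs = 30, batch_slices = 8, sg_threshold = 250,
                  seed = s))
  Y <- dim(ph$images)[1]
  for (cfg in cfgs) {
    opt <- optimize_exclusion_masks(sc$sim$kspace, ph$csm, unrolled_config(),
                                    ph$brain_mask, ph$sg_map, cfg)
    # full-batch objective at the final masks beats the keep-all init
    obj_init <- detect_objective(rep(cfg$init_mask, Y), rep(cfg$init_mask, Y),
                                 sc$sim$kspace, ph, cfg)
    obj_final <- detect_objective(opt$mask_even$line_weights,
                                  opt$mask_odd$line_weights,
                                  sc$sim$kspace, ph, cfg)
    expect_lte(obj_final, obj_init)
    expect_true(all(opt$mask_even$line_weights > 0 &
                      opt$mask_even$line_weights < 1))
    expect_true(all(opt$mask_odd$line_weights > 0 &
                      opt$mask_odd$line_weights < 1))
  }

  o1 <- optimize_exclusion_masks(sc$sim$kspace, ph$csm, unrolled_config(),
                                 ph$brain_mask, ph$sg_map, cfgs[[2]])
  o2 <- optimize_exclusion_masks(sc$sim$kspace, ph$csm, unrolled_config(),
                                 ph$brain_mask, ph$sg_map, cfgs[[2]])
  expect_identical(o1$mask_even$line_weights, o2$mask_even$line_weights)
  expect_identical(o1$mask_odd$line_weights, o2$mask_odd$line_weights)
  expect_identical(o1$loss_history, o2$loss_history)
})

test_that("masks adapt to the motion level and down-weighting helps", {
  ph <- tiny_phantom()
  d <- dim(ph$images)
  amps <- c(1, 3, 6)
  event_lines <- 8:13
  mean_event <- numeric(3)
  opts <- vector("list", 3)
  sims <- vector("list", 3)
  for (i in seq_along(amps)) {
    sc <- simulate_event_scenario(ph, lines = event_lines,
                                  amplitude_mm = amps[i])
    opt <- optimize_exclusion_masks(sc$sim$kspace, ph$csm, unrolled_config(),
                                    ph$brain_mask, ph$sg_map,
                                    detect_config(epochs = 40,
                                                  batch_slices = 8,
                                                  sg_threshold = 250,
                                                  seed = 0))
    # mask weight over the known event lines, both packages
    mean_event[i] <- mean(c(opt$mask_even$line_weights[event_lines],
                            opt$mask_odd$line_weights[event_lines]))
    opts[[i]] <- opt; sims[[i]] <- sc$sim
  }
  # weights on the event lines shrink as the amplitude grows
  expect_true(all(diff(mean_event) <= 1e-9))

  # on the 6-mm corrupted phantom the optimized mask beats keep-all
  nz <- normalize_volume(sims[[3]]$kspace, ph$csm)
  xopt <- reconstruct_with_masks(nz$data, opts[[3]]$mask_even,
                                 opts[[3]]$mask_odd, ph$csm)
  xnaive <- unrolled_reconstruct(nz$data$data, matrix(1, d[1], d[2]),
                                 ph$csm, unrolled_config())
  expect_lte(phantom_t2star_mae(xopt, ph), phantom_t2star_mae(xnaive, ph))
})
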