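# Shared fixtures, built once per test run.

# Desk-scale phantom used by the module tests: small enough that every
# reconstruction runs in seconds.
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_digital_phantom(pe = 48, ro = 32, n_slices = 4,
                                     n_echoes = 6, n_coils = 2, seed = 11)
    cache
  }
})

# Full-scale phantom at the default acquisition geometry, shared by the
# acceptance tests.
study_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_digital_phantom(seed = 0)
    cache
  }
})

random_complex_plane <- function(n, m, seed = 1) {
  withr::with_seed(seed, matrix(complex(real = stats::rnorm(n * m),
                                        imaginary = stats::rnorm(n * m)),
                                n, m))
}

random_complex_array <- function(dims, seed = 1) {
  n <- prod(dims)
  withr::with_seed(seed, array(complex(real = stats::rnorm(n),
                                       imaginary = stats::rnorm(n)), dims))
}

# A motion-free/corrupted pair with a single event of known timing.
# Returns the simulation plus the scheme and curve.
simulate_event_scenario <- function(ph, lines = 10:21, amplitude_mm = 6,
                                    pose_seed = 7, b0_seed = 0,
                                    b0_amplitude = 5) {
  sch <- acquisition_times(dim(ph$images)[1], ph$tr_ms)
  tr_s <- ph$tr_ms / 1000
  iv <- c((min(lines) - 1) * tr_s - 0.1,
          (max(lines) - 1) * tr_s + 0.6 * tr_s)
  cv <- event_motion_curve(list(iv), amplitude_mm = amplitude_mm,
                           scan_duration_s = sch$scan_duration_s,
                           seed = pose_seed)
  sim <- simulate_corrupted_kspace(ph$images, ph$csm, cv, sch, ph$te_ms,
                                   b0_cfg = list(amplitude_rad_s = b0_amplitude,
                                                 smoothness_vox = 6,
                                                 seed = b0_seed))
  list(sim = sim, scheme = sch, curve = cv, interval = iv)
}

# Deterministic full-batch detection objective (physics loss over all
# selected slices + regularizers) for a given pair of Even/Odd mask weight
# vectors. Used to verify optimization progress without batch noise.
detect_objective <- function(m_even, m_odd, kspace, ph, cfg,
                             recon_cfg = unrolled_config()) {
  y <- normalize_volume(kspace, ph$csm)$data$data
  n_slices <- dim(y)[3]
  bfrac <- apply(ph$brain_mask, 3, mean)
  msg <- sapply(seq_len(n_slices), function(s) {
    b <- ph$brain_mask[, , s]
    if (!any(b)) return(Inf)
    mean(ph$sg_map[, , s][b])
  })
  selected <- select_optimization_slices(msg, bfrac, cfg)
  num <- 0; den <- 0; reg <- 0
  for (pkg in c("even", "odd")) {
    m <- if (pkg == "even") m_even else m_odd
    sl <- selected[vapply(selected, t2moco:::slice_parity,
                          character(1)) == pkg]
    if (length(sl)) {
      res <- t2moco:::package_loss_and_grad(y, ph$csm$csm, sl,
                                            rep(1, length(sl)), m,
                                            kspace$te_ms, recon_cfg,
                                            cfg$keepcenter, NULL,
                                            ph$brain_mask)
      num <- num + res$loss * res$sw; den <- den + res$sw
    }
    reg <- reg + exclusion_regularizer(m, cfg$lambda_reg, cfg$lambda_center)
  }
  num / den + reg
}

# Mean T2* error (ms) of a reconstruction against the phantom truth over
# the standard evaluation mask.
phantom_t2star_mae <- function(images, ph, sg_threshold = 100) {
  fit <- t2star_from_images(images, ph$te_ms, mask = ph$brain_mask)
  tm <- t2star_map_metrics(fit$t2star_ms, ph$t2star_map, ph$brain_mask,
                           ph$sg_map, sg_threshold = sg_threshold)
  mean(tm$mae_ms)
}
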