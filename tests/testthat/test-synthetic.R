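test_that("presets carry the published regime parameters", {
  cgm <- make_preset("cGM")
  slow <- cgm$model$compartments[[1]]
  expect_equal(slow$fraction, 0.097)
  expect_equal(slow$D_par, 0.12)
  expect_equal(slow$T2, 61)
  expect_equal(cgm$snr_b0, 452)

  s2 <- make_preset("fig_scenario2")
  fdot <- sum(vapply(s2$model$compartments,
                     function(c) if (c$kind == "dot") c$fraction else 0, 1))
  expect_equal(fdot, 0.02)
  expect_equal(s2$model$compartments[[1]]$OD, 0.5)

  s1 <- make_preset("fig_scenario1")
  expect_false(any(vapply(s1$model$compartments,
                          function(c) c$kind == "dot", TRUE)))
  expect_equal(s1$model$compartments[[1]]$OD, 0.7)
  # stick 2.1, zeppelin 1.9/0.8 in both scenarios
  expect_equal(s1$model$compartments[[1]]$D_par, 2.1)
  expect_equal(s1$model$compartments[[2]]$D_par, 1.9)
  expect_equal(s1$model$compartments[[2]]$D_perp, 0.8)

  expect_error(make_preset("nope"), "Unknown preset")
})

test_that("all preset models have normalised fractions", {
  for (nm in c("mWM", "dGM", "oWM", "cWM", "cGM", "fig_scenario1",
               "fig_scenario2")) {
    fr <- vapply(make_preset(nm)$model$compartments,
                 function(c) c$fraction, 1)
    expect_equal(sum(fr), 1, tolerance = 1e-9)
  }
})

test_that("noiseless generation equals the forward model exactly", {
  p <- paper_protocol()
  pre <- make_preset("cGM", snr_b0 = Inf, voxelwise_jitter = 0)
  ds <- generate_dataset(pre, p, n_voxels = 1, seed = 1, temporal_jitter = 0)
  expect_equal(ds$signals$signal, noiseless_signals(pre$model, p),
               tolerance = 1e-12)
  expect_equal(ds$sigma, 0)
})

test_that("generation is bit-identical for the same seed", {
  p <- paper_protocol()
  pre <- make_preset("cGM")
  d1 <- generate_dataset(pre, p, n_voxels = 5, seed = 42)
  d2 <- generate_dataset(pre, p, n_voxels = 5, seed = 42)
  expect_identical(d1$signals, d2$signals)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(pre, p, n_voxels = 5, seed = 43)
  expect_false(identical(d1$signals, d3$signals))
})

test_that("truth table records every sampled parameter", {
  p <- paper_protocol()
  ds <- generate_dataset(make_preset("cGM"), p, n_voxels = 20, seed = 3)
  tr <- ds$truth
  expect_equal(nrow(tr), 20)
  expect_true(all(c("f_slow", "D_slow", "T2_slow", "f_dot", "s0",
                    "f1_apparent") %in% names(tr)))
  # 5% jitter: parameters vary around the preset values
  expect_gt(sd(tr$D_slow), 0)
  expect_equal(median(tr$D_slow), 0.12, tolerance = 0.05)
  expect_equal(median(tr$f_slow), 0.097, tolerance = 0.05)
})

test_that("the two dispersed-fibre scenarios separate under STE, not LTE", {
  m1 <- make_preset("fig_scenario1")$model
  m2 <- make_preset("fig_scenario2")$model
  # LTE along the mean axis: the higher dispersion of scenario 1 nearly
  # cancels the dot plateau of scenario 2, so the curves stay within a few
  # percent of each other (the exact gap depends on the stick/zeppelin
  # split, which is a free parameter of the presets)
  for (b in c(1, 2.5, 4)) {
    s1 <- signal_lte_mixture(b, m1, angle = 0)
    s2 <- signal_lte_mixture(b, m2, angle = 0)
    expect_lt(abs(s1 - s2) / s1, 0.06)
    expect_lt(abs(s1 - s2), 0.02)
  }
  # STE at b = 15: the scenarios separate by orders of magnitude because
  # the dot fraction survives while everything else is suppressed
  s1 <- signal_ste_mixture(15, m1)
  s2 <- signal_ste_mixture(15, m2)
  expect_equal(s2 - s1, 0.02, tolerance = 1e-3)
  expect_gt(s2 / s1, 100)
})

test_that("mean noisy signal sits above/at the floor as SNR varies", {
  m2 <- make_preset("fig_scenario2")$model
  s_true <- signal_ste_mixture(15, m2)
  withr::with_seed(9, {
    for (snr in c(100, 20)) {
      sigma <- 1 / snr
      m <- add_rician(rep(s_true, 3000), sigma)
      ratio <- mean(m) / noise_floor(sigma)
      if (snr == 100) expect_gt(ratio, 1.4) else expect_lt(ratio, 1.1)
    }
  })
})

test_that("tissue model configuration files round-trip", {
  m <- tissue_model(
    compartment("dot", 0.02),
    compartment("watson_stick", 0.98, D_par = 2.1, OD = 0.5, T2 = 70)
  )
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_tissue_model(m, tf)
  m2 <- read_tissue_model(tf)
  expect_equal(m2$compartments[[1]]$fraction, 0.02)
  expect_equal(m2$compartments[[2]]$OD, 0.5)
  expect_equal(m2$compartments[[2]]$T2, 70)

  mex <- tissue_model(
    compartment("dot", 0.02), compartment("ball", 0.98, D_par = 1),
    exchange = karger_spec(0.02, 0, 1, t_ex = 500, diffusion_time = 30)
  )
  tf2 <- withr::local_tempfile(fileext = ".yaml")
  write_tissue_model(mex, tf2)
  mex2 <- read_tissue_model(tf2)
  expect_equal(mex2$exchange$t_ex, 500)
})
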