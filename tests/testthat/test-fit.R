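test_that("shell averaging groups by (b, TE) and keeps b0 separate", {
  p <- paper_protocol()
  s <- rep(1, nrow(p))
  sm <- shell_average(s, p)
  expect_equal(unique(sm$mean), 1)
  expect_equal(unique(sm$sd), 0)
  expect_equal(sum(sm$is_b0), 1)
  expect_equal(sm$n[sm$is_b0], ceiling(231 / 14))
  expect_equal(sm$n[!sm$is_b0], c(6, 9, 12, 15, 18, 21, 24, 27, 30, 33, 36))

  # signals that do not cover every shell -> error
  expect_error(
    shell_average(tibble::tibble(voxel = 1L, volume = 1:10, signal = 1), p),
    "shell"
  )
})

test_that("the shell-mean standard error follows the sqrt(n) law", {
  p <- paper_protocol()
  sigma <- 0.01
  withr::with_seed(21, {
    means <- replicate(300, {
      s <- add_rician(rep(0.5, nrow(p)), sigma)
      sm <- shell_average(s, p)
      sm$mean[sm$b == 15]
    })
  })
  # 36 repeats at b = 15: SE of the shell mean = sigma_eff / 6
  expect_equal(sd(means), sigma / 6, tolerance = 0.15)
})

test_that("S(0) extrapolation from the two lowest shells", {
  p <- paper_protocol()
  # mono-exponential input: exact S(0) recovery by log-linearity
  s <- exp(-p$b * 0.7)
  sm <- shell_average(s, p)
  s0 <- estimate_s0_lowb(sm)
  expect_equal(s0$s0_tilde, 1, tolerance = 1e-12)

  # worked example frozen from direct evaluation of the formula
  sm2 <- tibble::tibble(
    voxel = 1L, shell = 1:2, b = c(0.25, 1.5), te = 88,
    is_b0 = FALSE, mean = c(0.8, 0.3), sd = 0, n = 1L
  )
  expect_equal(estimate_s0_lowb(sm2)$s0_tilde,
               exp(log(0.8) + 0.25 * (log(0.8) - log(0.3)) / 1.25),
               tolerance = 1e-12)
  expect_equal(estimate_s0_lowb(sm2)$s0_tilde, 0.9733829, tolerance = 1e-6)

  # CSF-heavy voxel: the extrapolation deliberately undershoots true S(0)
  csf <- tissue_model(compartment("ball", 0.3, D_par = 3),
                      compartment("ball", 0.7, D_par = 0.8))
  s_csf <- noiseless_signals(csf, p)
  s0_csf <- estimate_s0_lowb(shell_average(s_csf, p))
  expect_lt(s0_csf$s0_tilde, 1)

  # non-positive low-shell mean falls back with a warning
  sm_bad <- sm2
  sm_bad$mean[2] <- -0.1
  expect_warning(s0b <- estimate_s0_lowb(sm_bad), "fall")
  expect_equal(s0b$s0_tilde, 0.8)
})

test_that("the upper-limit dot fraction is S(b_max)/S0", {
  p <- paper_protocol()
  md <- tissue_model(compartment("dot", 0.02),
                     compartment("ball", 0.98, D_par = 1.0))
  sm <- shell_average(noiseless_signals(md, p), p)
  expect_equal(fdot_upper_limit(sm, 1), 0.02 + 0.98 * exp(-15),
               tolerance = 1e-9)
  # two-pool value at b_max = 15 equals the mixture evaluation
  sm2 <- shell_average(noiseless_signals(two_pool_cgm(), p), p)
  expect_equal(fdot_upper_limit(sm2, 1),
               signal_ste_mixture(15, two_pool_cgm()), tolerance = 1e-12)
  expect_error(fdot_upper_limit(sm, 0), "positive")
})

test_that("high-b mono-exponential fit recovers exact inputs", {
  p <- paper_protocol()
  s <- 0.097 * exp(-p$b * 0.12)
  sm <- shell_average(s, p)
  fit <- fit_highb_monoexp(sm, s0_tilde = 1, seed = 1)
  expect_equal(fit$estimates$amplitude, 0.097, tolerance = 1e-6)
  expect_equal(fit$estimates$D1_tilde, 0.12, tolerance = 1e-6)
  expect_equal(glance(fit)$n_starts_converged, 10L)
  expect_false(glance(fit)$flagged)
})

test_that("fast-pool contamination biases the slow-pool fit by < 5%", {
  p <- paper_protocol()
  sm <- shell_average(noiseless_signals(two_pool_cgm(), p), p)
  s0 <- estimate_s0_lowb(sm)$s0_tilde
  fit <- fit_highb_monoexp(sm, s0_tilde = 1, seed = 2)
  expect_equal(fit$estimates$D1_tilde, 0.12, tolerance = 0.05)
  expect_equal(fit$estimates$amplitude, 0.097, tolerance = 0.05)
})

test_that("the mono-exponential fit is scale equivariant", {
  p <- paper_protocol()
  s <- noiseless_signals(two_pool_cgm(), p)
  sm1 <- shell_average(s, p)
  sm2 <- shell_average(1000 * s, p)
  f1 <- fit_highb_monoexp(sm1, s0_tilde = 1, seed = 3)
  f2 <- fit_highb_monoexp(sm2, s0_tilde = 1000, seed = 3)
  expect_equal(f2$estimates$amplitude / 1000, f1$estimates$amplitude,
               tolerance = 1e-9)
  expect_equal(f2$estimates$D1_tilde, f1$estimates$D1_tilde,
               tolerance = 1e-9)
  expect_equal(f2$estimates$f1_tilde, f1$estimates$f1_tilde,
               tolerance = 1e-9)
})

test_that("multi-start fitting is reproducible given a seed", {
  p <- paper_protocol()
  withr::with_seed(10, {
    s <- add_rician(noiseless_signals(two_pool_cgm(), p), 0.002)
  })
  sm <- shell_average(s, p)
  f1 <- fit_highb_monoexp(sm, s0_tilde = 1, seed = 11)
  f2 <- fit_highb_monoexp(sm, s0_tilde = 1, seed = 11)
  expect_identical(f1$estimates, f2$estimates)
})

test_that("degenerate inputs give a flagged fit, not a crash", {
  p <- paper_protocol()
  sm <- shell_average(rep(0, nrow(p)), p)
  fit <- suppressWarnings(fit_highb_monoexp(sm, s0_tilde = 1, seed = 4))
  expect_true(glance(fit)$flagged)
  expect_lt(abs(fit$estimates$amplitude), 1e-8)
  expect_error(fit_highb_monoexp(sm, s0_tilde = 1, bs = 20), ">= 2 shells")
})

test_that("joint T2-D fit recovers exact multi-TE input", {
  p <- paper_protocol(TEs = c(88, 115, 140, 165))
  s <- 0.1 * exp(-p$te / 61) * exp(-p$b * 0.12)
  sm <- shell_average(s, p)
  fit <- fit_highb_t2(sm, seed = 5)
  expect_equal(fit$estimates$amplitude, 0.1, tolerance = 1e-6)
  expect_equal(fit$estimates$T2_1, 61, tolerance = 1e-5)
  expect_equal(fit$estimates$D1_tilde, 0.12, tolerance = 1e-6)
  expect_false(glance(fit)$flagged)
})

test_that("TE-independent data drives T2 to the bound and is flagged", {
  p <- paper_protocol(TEs = c(88, 115, 140, 165))
  s <- 0.1 * exp(-p$b * 0.12)  # no TE dependence
  sm <- shell_average(s, p)
  fit <- fit_highb_t2(sm, seed = 6)
  expect_equal(fit$estimates$T2_1, 300)
  expect_true(glance(fit)$flagged)
  # single TE -> directed to the mono-exponential path
  p1 <- paper_protocol()
  sm1 <- shell_average(rep(1, nrow(p1)), p1)
  expect_error(fit_highb_t2(sm1), "fit_highb_monoexp")
})

test_that("apparent slow fraction decreases with TE for distinct-T2 pools", {
  m <- tissue_model(
    compartment("ball", 0.097, D_par = 0.12, T2 = 61),
    compartment("ball", 0.903, D_par = 1.0, T2 = 120)
  )
  tes <- c(88, 115, 140, 165)
  f1_te <- vapply(tes, function(te) {
    p <- paper_protocol(TEs = te)
    s <- noiseless_signals(m, p)
    sm <- shell_average(s, p)
    s0 <- estimate_s0_lowb(sm)$s0_tilde
    fit_highb_monoexp(sm, s0_tilde = s0, seed = 7)$estimates$f1_tilde
  }, 1)
  expect_true(all(diff(f1_te) < 0))
})

test_that("sphere-radius fit recovers a noiseless synthetic sphere", {
  w <- ste_waveform(15, dt = 0.05)
  p <- paper_protocol()
  shells <- protocol_shells(p)
  highb <- shells$b[shells$b > 10]
  truth_r <- 4.5
  sm <- tibble::tibble(
    voxel = 1L, shell = seq_along(highb) + 7L, b = highb, te = 88,
    is_b0 = FALSE,
    mean = 0.1 * vapply(highb, function(bb) {
      signal_sphere_waveform(scale_waveform(w, bb), truth_r, 3)
    }, 1),
    sd = 0, n = 27L
  )
  fit <- fit_sphere_radius(sm, waveform = w, s0_tilde = 1, seed = 8)
  expect_equal(fit$estimates$r_s, truth_r, tolerance = 0.02)
  expect_equal(fit$estimates$amplitude, 0.1, tolerance = 0.02)

  # dot-like data (no b-dependence at high b) drives the radius to zero
  sm0 <- sm
  sm0$mean <- 0.05
  fit0 <- fit_sphere_radius(sm0, waveform = w, s0_tilde = 1, seed = 9)
  expect_lt(fit0$estimates$r_s, 0.5)

  expect_error(fit_sphere_radius(sm, waveform = NULL, s0_tilde = 1),
               "waveform")
})

test_that("ROI summaries report median and 10-90 percentiles", {
  fits <- tibble::tibble(
    voxel = 1:30,
    roi = rep(c("a", "b", "tiny"), c(15, 12, 3)),
    D1_tilde = c(rep(0.12, 15), seq(0.1, 0.32, length.out = 12), rep(0.2, 3))
  )
  out <- roi_summary(fits)
  a <- out[out$roi == "a", ]
  expect_equal(a$median, 0.12)
  expect_equal(a$p10, a$p90)  # identical voxels
  b <- out[out$roi == "b", ]
  expect_equal(b$median, median(seq(0.1, 0.32, length.out = 12)))
  expect_equal(b$p10, quantile(seq(0.1, 0.32, length.out = 12), 0.1,
                               names = FALSE))
  # small ROI: percentiles suppressed
  tiny <- out[out$roi == "tiny", ]
  expect_true(is.na(tiny$p10) && is.na(tiny$p90))
  # missing labels dropped with a warning
  fits$roi[1] <- NA
  expect_warning(roi_summary(fits), "missing ROI")
  # formatted table has one row per ROI
  tab <- format_roi_table(out)
  expect_equal(nrow(tab), 3)
  expect_true("D1_tilde" %in% names(tab))
})
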