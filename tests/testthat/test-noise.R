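test_that("Rician noise has the Rayleigh floor and high-SNR limits", {
  expect_equal(add_rician(c(0.5, 1), sigma = 0), c(0.5, 1))

  withr::with_seed(1, {
    # zero signal: mean magnitude = sigma * sqrt(pi/2)
    m <- add_rician(rep(0, 1e6), sigma = 1)
    se <- sd(m) / sqrt(length(m))
    expect_lt(abs(mean(m) - sqrt(pi / 2)), 3 * se)

    # SNR 250: mean magnitude within 0.01% of S
    s <- 250
    m <- add_rician(rep(s, 1e5), sigma = 1)
    expect_equal(mean(m), s, tolerance = 1e-4)
  })
})

test_that("Rician draws are reproducible given a seed", {
  a <- add_rician(rep(1, 100), sigma = 0.1, seed = 99)
  b <- add_rician(rep(1, 100), sigma = 0.1, seed = 99)
  expect_identical(a, b)
  # and the ambient RNG state is untouched
  withr::with_seed(5, {
    x1 <- rnorm(1)
  })
  withr::with_seed(5, {
    invisible(add_rician(rep(1, 10), 0.1, seed = 3))
    x2 <- rnorm(1)
  })
  expect_identical(x1, x2)
})

test_that("the rectified noise floor is sigma * sqrt(pi/2)", {
  expect_equal(noise_floor(0), 0)
  expect_equal(noise_floor(1), sqrt(pi / 2))
  expect_equal(noise_floor(1), 1.25331, tolerance = 1e-5)
  expect_equal(noise_floor(2) / 2, sqrt(pi / 2))
  # relative floor 0.5% of S(0) corresponds to SNR ~ 250
  expect_equal(sqrt(pi / 2) / 0.005, 250, tolerance = 0.01)
})

test_that("background sigma estimation recovers the Rayleigh moment", {
  withr::with_seed(2, {
    m <- add_rician(rep(0, 1e4), sigma = 1)
    expect_equal(estimate_sigma_background(m), 1, tolerance = 0.02)
  })
  expect_equal(estimate_sigma_background(rep(0, 200)), 0)
  expect_error(estimate_sigma_background(rep(0.1, 10)), "100")
  # mask form
  vals <- matrix(1, 20, 20)
  mask <- matrix(TRUE, 20, 20)
  expect_equal(estimate_sigma_background(vals, mask), sqrt(1 / 2))
})

test_that("signed debiasing inverts the second-moment identity", {
  expect_equal(debias_rician(sqrt(2) * 0.3, 0.3), 0)
  expect_equal(debias_rician(c(0.5, 2), 0), c(0.5, 2))
  # order preserved, negatives allowed
  m <- c(0.1, 0.3, 0.5, 1)
  expect_true(all(diff(debias_rician(m, 0.3)) > 0))
  expect_lt(debias_rician(0.1, 0.3), 0)
})

test_that("debiasing removes most of the noise-floor bias near the floor", {
  withr::with_seed(3, {
    s <- 0.02; sigma <- 0.004  # S/sigma = 5, close to the floor regime
    m <- add_rician(rep(s, 1e5), sigma)
    raw_bias <- mean(m) - s
    deb_bias <- mean(debias_rician(m, sigma)) - s
    expect_gt(raw_bias, 0)  # magnitude averaging overestimates
    expect_lt(abs(deb_bias) / s, 0.1)
    expect_lt(deb_bias, 0)  # per-sample debiasing slightly under-reads
  })
})

test_that("per-sample debiasing trades the floor for a bounded negative bias", {
  withr::with_seed(4, {
    sigma <- 1
    # deep in the floor the raw mean is dominated by sigma*sqrt(pi/2);
    # debiased means are far closer to the truth
    for (snr in c(0, 0.25, 0.5)) {
      s <- snr * sigma
      m <- add_rician(rep(s, 4e4), sigma)
      expect_lt(abs(mean(debias_rician(m, sigma)) - s), abs(mean(m) - s))
    }
    # at moderate SNR the residual bias is negative and bounded by
    # ~ sigma^2 / (2 S), mirroring the raw positive bias
    for (snr in c(3, 5)) {
      s <- snr * sigma
      m <- add_rician(rep(s, 4e4), sigma)
      deb_bias <- mean(debias_rician(m, sigma)) - s
      expect_lt(deb_bias, 0)
      expect_lt(abs(deb_bias), 1.5 * sigma^2 / (2 * s))
    }
  })
})

test_that("moment-combined shell means are debiased across S/sigma in [1,5]", {
  withr::with_seed(14, {
    sigma <- 1
    n_rep <- 36
    for (snr in 1:5) {
      s <- snr * sigma
      raw_bias <- deb_bias <- numeric(400)
      for (r in seq_len(400)) {
        m <- add_rician(rep(s, n_rep), sigma)
        raw_bias[r] <- mean(m) - s
        deb_bias[r] <- debias_mean_moments(m, sigma) - s
      }
      expect_lt(abs(mean(deb_bias)), abs(mean(raw_bias)))
    }
  })
})

test_that("SNR and tSNR metrics behave as constructed", {
  expect_error(snr_tsnr(matrix(1, 2, 2), sigma = 1), "3 b0")
  # constant series: tSNR capped
  out <- snr_tsnr(matrix(1, 1, 5), sigma = 0.1)
  expect_equal(out$tsnr, 1e6)
  withr::with_seed(6, {
    # pure Rician noise at SNR 250
    b0 <- matrix(add_rician(rep(1, 50 * 20), sigma = 1 / 250), 50, 20)
    out <- snr_tsnr(b0, sigma = 1 / 250)
    expect_equal(median(out$snr), 250, tolerance = 0.05)
    # 1% temporal amplitude jitter dominates: tSNR ~ 100
    sig <- outer(rep(1, 50), 1 + rnorm(20, sd = 0.01))
    out <- snr_tsnr(sig, sigma = 1 / 250)
    expect_equal(median(out$tsnr), 100, tolerance = 0.25)
  })
})
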