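test_that("Gaussian compartment attenuation matches the worked example", {
  B <- make_axisymmetric_btensor(8.5, 0)
  # at b = 8500 s/mm^2 a D = 0.8 pool is down to ~0.1%, a D = 0.1 pool to ~42%
  expect_equal(signal_gaussian(B, diag(rep(0.8, 3))), exp(-8.5 * 0.8))
  expect_equal(exp(-8.5 * 0.8), 0.0011, tolerance = 0.01)
  expect_equal(signal_gaussian(B, diag(rep(0.1, 3))), exp(-8.5 * 0.1))
  expect_equal(exp(-8.5 * 0.1), 0.427, tolerance = 0.001)
  expect_equal(signal_gaussian(make_axisymmetric_btensor(0, 0), diag(rep(2, 3))), 1)
  expect_error(signal_gaussian(B, diag(c(-0.1, 1, 1))), "semi-definite")
})

test_that("STE Gaussian signals are rotation invariant", {
  B <- make_axisymmetric_btensor(8.5, 0)
  D0 <- diag(c(2.1, 0.2, 0.05))
  withr::with_seed(11, {
    base <- signal_gaussian(B, D0)
    for (i in 1:20) {
      R <- random_rotation()
      expect_equal(signal_gaussian(B, R %*% D0 %*% t(R)), base,
                   tolerance = 1e-12)
    }
  })
})

test_that("STE mixture sums compartment exponentials (Eq-2 behaviour)", {
  m1 <- tissue_model(compartment("ball", 1, D_par = 0.8))
  expect_equal(signal_ste_mixture(1, m1), exp(-0.8))

  expect_equal(signal_ste_mixture(15, two_pool_cgm()),
               0.097 * exp(-15 * 0.12) + 0.903 * exp(-15), # = 0.016034
               tolerance = 1e-12)

  # any model containing a dot plateaus at f_dot
  md <- tissue_model(compartment("dot", 0.02),
                     compartment("ball", 0.98, D_par = 1.0))
  expect_equal(signal_ste_mixture(1e4, md), 0.02, tolerance = 1e-12)

  # attenuations in [0, 1], monotone non-increasing in b
  b <- seq(0, 15, by = 0.5)
  s <- signal_ste_mixture(b, two_pool_cgm())
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diff(s) <= 0))
})

test_that("Watson dispersion mapping round-trips", {
  od <- c(0.1, 0.3, 0.5, 0.7, 1)
  expect_equal(watson_od(watson_kappa(od)), od, tolerance = 1e-12)
  expect_equal(watson_kappa(0.5), 1)  # atan(1) = pi/4
  expect_equal(watson_kappa(1), 0)    # uniform limit
})

test_that("uniform-limit Watson stick equals the powder-average closed form", {
  for (bD in c(0.5, 2, 10.5, 20)) {
    powder <- sqrt(pi) * pracma::erf(sqrt(bD)) / (2 * sqrt(bD))
    expect_equal(signal_lte_watson_stick(bD, 1, OD = 1), powder,
                 tolerance = 1e-6)
  }
  expect_equal(signal_lte_watson_stick(0, 2.1, OD = 0.5), 1)
})

test_that("Watson quadrature agrees with Monte-Carlo orientation sampling", {
  withr::with_seed(101, {
    n <- 2e5
    kappa <- watson_kappa(0.5)
    dirs <- rwatson_z(n, kappa)

    # stick, encoding along the mean axis
    b <- 3; dpar <- 2.1
    vals <- exp(-b * dpar * dirs[, 3]^2)
    mc <- mean(vals); se <- sd(vals) / sqrt(n)
    quad <- signal_lte_watson_stick(b, dpar, OD = 0.5, angle = 0)
    expect_lt(abs(quad - mc), 3 * se)

    # zeppelin, encoding perpendicular to the mean axis
    g <- c(1, 0, 0)
    c2 <- (dirs %*% g)^2
    vals <- exp(-b * (0.8 + (1.9 - 0.8) * c2))
    mc <- mean(vals); se <- sd(vals) / sqrt(n)
    quad <- signal_lte_watson_zeppelin(b, 1.9, 0.8, OD = 0.5, angle = pi / 2)
    expect_lt(abs(quad - mc), 3 * se)
  })
})

test_that("Watson zeppelin reduces to a ball when D_par = D_perp", {
  for (od in c(0.2, 0.5, 1)) {
    expect_equal(signal_lte_watson_zeppelin(3, 0.9, 0.9, OD = od, angle = 1),
                 exp(-3 * 0.9), tolerance = 1e-9)
  }
  expect_equal(signal_lte_watson_zeppelin(0, 1.9, 0.8, OD = 0.5), 1)
})

test_that("T2 weighting multiplies compartment terms by exp(-TE/T2)", {
  m <- tissue_model(compartment("ball", 1, D_par = 0.12, T2 = 61))
  # TE = 0 reduces to the plain mixture
  expect_equal(signal_with_t2(m, 2, TE = 0), signal_ste_mixture(2, m))
  # a single pool scales by exp(-dTE/T2) between echo times
  expect_equal(signal_with_t2(m, 2, TE = 165) / signal_with_t2(m, 2, TE = 88),
               exp(-77 / 61), tolerance = 1e-12)
  expect_error(compartment("ball", 1, D_par = 1, T2 = -5), "T2")
})
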