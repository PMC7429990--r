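#' Eigenmode roots for restricted diffusion in a sphere
#'
#' Roots alpha_k of the derivative of the spherical Bessel function j1,
#' i.e. of `(x^2 - 2) sin x + 2 x cos x`; one root per interval
#' `((k-1) pi, k pi)`. These set the relaxation rates
#' `lambda_k = alpha_k^2 / r^2` of the position autocorrelation in an
#' impermeable sphere.
#'
#' @param n Number of roots.
#' @return Numeric vector of length `n` (alpha_1 ~ 2.0816).
#' @export
sphere_bessel_roots <- function(n) {
  f <- function(x) (x^2 - 2) * sin(x) + 2 * x * cos(x)
  vapply(seq_len(n), function(k) {
    lo <- (k - 1) * pi + 1e-6
    hi <- k * pi - 1e-6
    uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, 1)
}

# cached roots and geometry weights B_k / r^2 = 2 / (alpha^2 (alpha^2 - 2))
sphere_modes_env <- new.env(parent = emptyenv())
sphere_modes <- function(n) {
  if (is.null(sphere_modes_env$alpha) || length(sphere_modes_env$alpha) < n) {
    sphere_modes_env$alpha <- sphere_bessel_roots(max(n, 50L))
  }
  a <- sphere_modes_env$alpha[seq_len(n)]
  list(alpha = a, weight = 2 / (a^2 * (a^2 - 2)))
}

#' Restricted-sphere signal under an arbitrary gradient waveform
#'
#' Gaussian-phase-distribution attenuation for diffusion restricted in an
#' impermeable sphere of radius `r_s` with intra-sphere diffusivity `D_s`:
#' the position autocorrelation along each axis is
#' `<x(t1) x(t2)> = sum_k B_k exp(-lambda_k D_s |t1 - t2|)` with
#' `B_k = 2 r_s^2 / (alpha_k^2 (alpha_k^2 - 2))` and
#' `lambda_k = alpha_k^2 / r_s^2`, so
#' `ln S = -(1/2) sum_axes sum_k B_k double-integral
#' q'_a(t1) q'_a(t2) exp(-lambda_k D_s |t1 - t2|) dt1 dt2` where
#' `q' = gamma g_eff`. The mode series is truncated adaptively. As
#' `r_s -> 0` the signal tends to 1 (the dot limit).
#'
#' @param w A [gradient_waveform()].
#' @param r_s Sphere radius, um, in \[0, 20\].
#' @param D_s Intra-sphere diffusivity, um^2/ms.
#' @param tol Relative contribution below which the series is truncated.
#' @param max_modes Mode cap; non-convergence at the cap is an error.
#' @param max_dt Waveform is linearly resampled to at most this sample
#'   interval (ms) before integration.
#' @return Attenuation in \[0, 1\].
#' @examples
#' w <- pgse_waveform(G = 100, delta = 1, Delta = 30, dt = 0.02)
#' signal_sphere_waveform(w, r_s = 5, D_s = 3)
#' @export
signal_sphere_waveform <- function(w, r_s, D_s, tol = 1e-8,
                                   max_modes = 100L, max_dt = 0.02) {
  stopifnot(inherits(w, "gradient_waveform"))
  grid <- sphere_gradient_grid(w, max_dt)
  sphere_signal_grid(grid, r_s, D_s, tol = tol, max_modes = max_modes)
}

# waveform preparation factored out so that fits evaluating many radii
# against a fixed waveform pay it only once: resample, convert units, and
# precompute the weighted gradient autocorrelation
#   c_m = sum_axes sum_i (w_i g_i)(w_{i+m} g_{i+m})
# (trapezoid weights w), via FFT.  The mode double integral then collapses
# to dbl(lambda D) = c_0 + 2 sum_{m>=1} c_m exp(-lambda D m dt).
sphere_gradient_grid <- function(w, max_dt = 0.02) {
  eg <- effective_gradient(w)
  t <- eg$t
  g <- eg$g
  if (eg$dt > max_dt) {
    tf <- seq(0, t[length(t)], by = max_dt)
    g <- apply(g, 2L, function(col) approx(t, col, xout = tf)$y)
    t <- tf
  }
  dt <- t[2L] - t[1L]
  gs <- g * (GAMMA_PROTON * 1e-6)  # rad / (ms um)
  n <- length(t)
  wt <- rep(dt, n)
  wt[c(1L, n)] <- dt / 2
  nfft <- stats::nextn(2L * n, 2)
  corr <- numeric(n)
  active <- FALSE
  for (a in 1:3) {
    wg <- wt * gs[, a]
    if (all(wg == 0)) next
    active <- TRUE
    f <- stats::fft(c(wg, numeric(nfft - n)))
    corr <- corr + Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nfft
  }
  list(dt = dt, n = n, corr = corr, lag_t = (seq_len(n) - 1L) * dt,
       active = active)
}

sphere_signal_grid <- function(grid, r_s, D_s, tol = 1e-8, max_modes = 100L) {
  if (r_s < 0 || r_s > 20) abort("`r_s` must lie in [0, 20] um.")
  if (D_s <= 0) abort("`D_s` must be positive.")
  if (r_s == 0 || !grid$active) return(1)
  modes <- sphere_modes(max_modes)
  ln_s <- 0
  for (k in seq_len(max_modes)) {
    lam_d <- modes$alpha[k]^2 / r_s^2 * D_s
    Bk <- modes$weight[k] * r_s^2
    kern <- exp(-lam_d * grid$lag_t)
    dbl <- grid$corr[1L] + 2 * sum(grid$corr[-1L] * kern[-1L])
    term <- -0.5 * Bk * dbl
    ln_s <- ln_s + term
    # relative truncation, with an absolute floor for near-unity signals
    if (abs(term) <= max(tol * abs(ln_s), 1e-13)) {
      return(exp(ln_s))
    }
  }
  abort(sprintf(
    "Sphere eigenmode series not converged after %d modes (last relative term %.3g).",
    max_modes, abs(term) / max(abs(ln_s), 1e-14)
  ))
}
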