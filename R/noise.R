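#' Add Rician noise to magnitude signals
#'
#' Adds independent Gaussian noise of standard deviation `sigma` to the
#' real and imaginary channels and takes the magnitude:
#' `M = |S + n_re + i n_im|`. At zero signal the magnitude is Rayleigh with
#' mean `sigma * sqrt(pi / 2)` (the rectified noise floor); at high SNR
#' `E[M] ~ S + sigma^2 / (2 S)`.
#'
#' @param S Noiseless signal(s), >= 0.
#' @param sigma Per-channel Gaussian standard deviation (same units as `S`).
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Magnitude signal(s), same shape as `S`.
#' @examples
#' add_rician(rep(0, 5), sigma = 1, seed = 1)
#' @export
add_rician <- function(S, sigma, seed = NULL) {
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (any(S < 0)) abort("`S` must be non-negative (magnitude model).")
  if (sigma == 0) return(S)
  draw <- function() {
    n <- length(S)
    sqrt((S + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (!is.null(dim(S))) dim(out) <- dim(S)
  out
}

#' Rectified noise floor
#'
#' Expected magnitude of pure complex Gaussian noise,
#' `sigma * sqrt(pi / 2)`: the level magnitude signals level off at once the
#' true signal is fully attenuated. A relative floor of 0.5% of S(0)
#' corresponds to SNR = S(0) / sigma of about 250.
#'
#' @param sigma Per-channel Gaussian standard deviation.
#' @return Noise-floor level, same units as the signal.
#' @export
noise_floor <- function(sigma) {
  if (any(sigma < 0)) abort("`sigma` must be non-negative.")
  sigma * sqrt(pi / 2)
}

#' Estimate sigma from background voxels
#'
#' In signal-free background the magnitude is Rayleigh, so
#' `E[M^2] = 2 sigma^2` and `sigma_hat = sqrt(mean(M^2) / 2)`. This is a
#' deliberately simple stand-in for dedicated background-identification
#' methods: the caller supplies the background values (or a mask).
#'
#' @param values Magnitude values in background voxels (vector or array),
#'   or a full array when `mask` is given.
#' @param mask Optional logical mask selecting background entries of
#'   `values`.
#' @param min_voxels Minimum number of background voxels required.
#' @return Estimated per-channel sigma.
#' @export
estimate_sigma_background <- function(values, mask = NULL, min_voxels = 100L) {
  if (!is.null(mask)) values <- values[mask]
  values <- as.numeric(values)
  if (length(values) < min_voxels) {
    abort(sprintf(
      "Background mask has %d voxels; at least %d are required for a stable sigma estimate.",
      length(values), min_voxels
    ))
  }
  sqrt(mean(values^2) / 2)
}

#' Rician debiasing of magnitude signals
#'
#' Signed method-of-moments correction: since `E[M^2] = S^2 + 2 sigma^2`,
#' `S_hat = sign(M^2 - 2 sigma^2) * sqrt(|M^2 - 2 sigma^2|)`. Values below
#' the noise floor map to negative estimates rather than being clipped, so
#' that means of debiased signals are (asymptotically) unbiased - exactly
#' what the high-b fit needs.
#'
#' @param M Magnitude signal(s).
#' @param sigma Per-channel Gaussian standard deviation.
#' @return Debiased signal(s); may be negative.
#' @export
debias_rician <- function(M, sigma) {
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (sigma == 0) return(M)
  d <- M^2 - 2 * sigma^2
  sign(d) * sqrt(abs(d))
}

#' Moment-combined mean of repeated magnitude measurements
#'
#' The noise-floored mean of `n` repeated magnitudes, debiased at the
#' moment level: `sign(u) sqrt(|u|)` with `u = mean(M^2) - 2 sigma^2`.
#' Because `mean(M^2)` is an unbiased estimate of `S^2 + 2 sigma^2`, the
#' residual bias shrinks with the number of repeats, unlike the arithmetic
#' mean of per-sample debiased values which retains a `-sigma^2 / (2 S)`
#' term (and unlike the raw magnitude mean, which is floored). Note the
#' identity `d |d| = M^2 - 2 sigma^2` for `d = debias_rician(M, sigma)`:
#' this estimator is the signed-square-domain average of the per-sample
#' debiased values.
#'
#' @param M Magnitude repeats of the same underlying signal.
#' @param sigma Per-channel Gaussian standard deviation.
#' @return Debiased mean signal estimate (may be negative).
#' @export
debias_mean_moments <- function(M, sigma) {
  if (sigma < 0) abort("`sigma` must be non-negative.")
  u <- mean(M^2) - 2 * sigma^2
  sign(u) * sqrt(abs(u))
}

#' SNR and temporal SNR from a b = 0 series
#'
#' SNR is the temporal mean of the b0 signal divided by the (given or
#' estimated) noise sigma; tSNR is the per-voxel temporal mean divided by
#' the temporal standard deviation, which additionally picks up
#' physiological and system fluctuations.
#'
#' @param b0 Matrix of b0 signals, voxels x volumes (a vector is treated as
#'   one voxel).
#' @param sigma Noise standard deviation; required for SNR.
#' @param tsnr_cap Cap reported for constant series (infinite tSNR).
#' @return A tibble with one row per voxel: `snr`, `tsnr`.
#' @export
snr_tsnr <- function(b0, sigma, tsnr_cap = 1e6) {
  if (is.vector(b0)) b0 <- matrix(b0, nrow = 1L)
  if (ncol(b0) < 3L) abort("At least 3 b0 volumes are required.")
  if (sigma < 0) abort("`sigma` must be non-negative.")
  mu <- rowMeans(b0)
  s <- apply(b0, 1L, sd)
  tsnr <- ifelse(s > 0, mu / s, tsnr_cap)
  tibble(
    snr = if (sigma > 0) mu / sigma else rep(Inf, length(mu)),
    tsnr = pmin(tsnr, tsnr_cap)
  )
}
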