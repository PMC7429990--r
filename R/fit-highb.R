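#' Per-shell averages of voxel signals
#'
#' Arithmetic mean and standard deviation of the signal in every unique
#' (b, TE) shell, per voxel. The b = 0 volumes form their own shell
#' (`is_b0`), kept separate from the diffusion shells.
#'
#' @param signals Either a numeric vector aligned to `protocol` (one voxel)
#'   or a tibble with columns `voxel`, `volume`, `signal`.
#' @param protocol An [ste_protocol()].
#' @return A tibble with columns `voxel`, `shell`, `b`, `te`, `is_b0`,
#'   `mean`, `sd`, `n`, ordered by b then TE.
#' @export
shell_average <- function(signals, protocol) {
  stopifnot(inherits(protocol, "ste_protocol"))
  signals <- as_voxel_signals(signals, protocol)
  out <- signals |>
    dplyr::inner_join(
      dplyr::select(protocol, "volume", "shell", "b", "te", "is_b0"),
      by = "volume"
    ) |>
    dplyr::group_by(.data$voxel, .data$shell, .data$b, .data$te, .data$is_b0) |>
    dplyr::summarise(
      mean = mean(.data$signal),
      sd = sd(.data$signal),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$voxel, .data$b, .data$te)
  expected <- nrow(protocol_shells(protocol))
  got <- out |> dplyr::distinct(.data$shell, .data$te) |> nrow()
  if (got < expected) {
    abort("Signals do not cover every shell of the protocol.")
  }
  out
}

as_voxel_signals <- function(signals, protocol) {
  if (is.numeric(signals)) {
    if (length(signals) != nrow(protocol)) {
      abort("Signal vector length must equal the number of protocol volumes.")
    }
    return(tibble(voxel = 1L, volume = seq_along(signals),
                  signal = as.numeric(signals)))
  }
  if (!all(c("voxel", "volume", "signal") %in% names(signals))) {
    abort("`signals` needs columns voxel, volume, signal.")
  }
  signals
}

#' Extrapolated S(0) from the two lowest diffusion shells
#'
#' Rather than using the measured b = 0 signal (which contains CSF), S(0)
#' is log-linearly extrapolated from the two lowest non-zero shells:
#' `ln S(0) = ln S(b_a) + b_a (ln S(b_a) - ln S(b_b)) / (b_b - b_a)`. For a
#' CSF-contaminated voxel this deliberately under-shoots the measured b0
#' signal. Non-positive shell means trigger a fallback to the lowest shell
#' mean, with a warning.
#'
#' @param shell_means Output of [shell_average()] (any number of voxels;
#'   for multi-TE data the extrapolation is done per TE).
#' @return A tibble with columns `voxel`, `te`, `s0_tilde`.
#' @export
estimate_s0_lowb <- function(shell_means) {
  shell_means |>
    dplyr::filter(!.data$is_b0) |>
    dplyr::group_by(.data$voxel, .data$te) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$b)
      if (nrow(df) < 2L) abort("Need at least two non-zero shells for S(0).")
      ba <- df$b[1L]; bb <- df$b[2L]
      sa <- df$mean[1L]; sb <- df$mean[2L]
      if (sa <= 0 || sb <= 0) {
        warn("Non-positive low-shell mean; falling back to the lowest-shell value.")
        return(tibble(s0_tilde = sa))
      }
      tibble(s0_tilde = exp(log(sa) + ba * (log(sa) - log(sb)) / (bb - ba)))
    }) |>
    dplyr::ungroup()
}

#' Upper-limit dot fraction
#'
#' `f_dot <= S(b_max) / S(0)`: the mean (debiased) signal at the highest
#' shell divided by the extrapolated S(0). Negative values are possible
#' (and informative) after debiasing.
#'
#' @param shell_means Output of [shell_average()] for one voxel (single TE).
#' @param s0_tilde Extrapolated S(0) for that voxel (positive).
#' @return The upper-limit dot signal fraction (scalar).
#' @export
fdot_upper_limit <- function(shell_means, s0_tilde) {
  if (s0_tilde <= 0) abort("`s0_tilde` must be positive.")
  dwi <- dplyr::filter(shell_means, !.data$is_b0)
  dwi$mean[which.max(dwi$b)] / s0_tilde
}

# ---- multi-start bounded least squares ------------------------------------

# Levenberg-Marquardt with box bounds; returns best-of-n_starts solution.
# start_fun(i) draws a start; ties broken by residual norm then by the
# parameter named in tie_par.
multistart_lm <- function(residual_fun, start_fun, lower, upper,
                          n_starts, seed, tie_par = NULL) {
  run <- function() {
    fits <- vector("list", n_starts)
    for (i in seq_len(n_starts)) {
      st <- start_fun()
      fits[[i]] <- tryCatch(
        minpack.lm::nls.lm(
          par = st, fn = residual_fun, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(
            ftol = 1e-10, ptol = 1e-10, maxiter = 400
          )
        ),
        error = function(e) NULL
      )
    }
    fits
  }
  fits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) {
    return(list(par = NULL, residual_norm = NA_real_, n_converged = 0L))
  }
  fits <- fits[ok]
  rn <- vapply(fits, function(f) sqrt(sum(f$fvec^2)), 1)
  best <- order(rn, vapply(fits, function(f) {
    if (is.null(tie_par)) 0 else f$par[[tie_par]]
  }, 1))[1L]
  list(
    par = fits[[best]]$par,
    residual_norm = rn[best],
    n_converged = sum(ok)
  )
}

new_highb_fit <- function(estimates, data, fit_type, diagnostics) {
  structure(
    list(estimates = estimates, data = data, fit_type = fit_type,
         diagnostics = diagnostics),
    class = "highb_fit"
  )
}

#' @export
print.highb_fit <- function(x, ...) {
  cat(sprintf("<highb_fit: %s>%s\n", x$fit_type,
              if (x$diagnostics$flagged) " [flagged]" else ""))
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.highb_fit <- function(x, ...) x$estimates

#' @export
glance.highb_fit <- function(x, ...) {
  tibble(
    fit_type = x$fit_type,
    residual_norm = x$diagnostics$residual_norm,
    n_starts_converged = x$diagnostics$n_starts_converged,
    n_shells = nrow(x$data),
    flagged = x$diagnostics$flagged
  )
}

#' High-b mono-exponential fit
#'
#' Fits `A exp(-b D1)` to the shell means with `b > bs` by multi-start
#' bounded least squares (Levenberg-Marquardt; starts drawn uniformly from
#' the boxes S(0) in \[0, s0_max\] and f1 in \[0, 0.3\] with `A` their
#' product, D1 in \[0, 1\]; bounds `A >= 0`, `D1 >= 0`; best residual norm
#' kept, ties broken by lower D1). `A = S(0) f1` is the only identifiable
#' amplitude from high-b data alone, so the tissue fraction is reported as
#' `f1_tilde = A / s0_tilde` afterwards.
#'
#' @param shell_means [shell_average()] output for one voxel (single TE).
#' @param s0_tilde Extrapolated S(0) (used for `f1_tilde` and the start
#'   box; see [estimate_s0_lowb()]).
#' @param bs Shell threshold, ms/um^2; shells with `b > bs` strictly are
#'   fitted (default 10, i.e. 10000 s/mm^2).
#' @param n_starts Number of random starts.
#' @param seed Optional integer seed making the multi-start reproducible.
#' @return A `highb_fit` object; [tidy()] gives the estimates
#'   (`amplitude`, `D1_tilde`, `f1_tilde`, `s0_tilde`), [glance()] the fit
#'   diagnostics.
#' @export
fit_highb_monoexp <- function(shell_means, s0_tilde, bs = 10,
                              n_starts = 10L, seed = NULL) {
  dwi <- shell_means |>
    dplyr::filter(!.data$is_b0, .data$b > bs) |>
    dplyr::arrange(.data$b)
  if (nrow(dwi) < 2L) {
    abort(sprintf("Need >= 2 shells with b > %g ms/um^2.", bs))
  }
  y <- dwi$mean
  b <- dwi$b
  s0_max <- max(s0_tilde, max(y), .Machine$double.eps)
  res <- multistart_lm(
    residual_fun = function(p) p[["A"]] * exp(-b * p[["D1"]]) - y,
    start_fun = function() c(A = runif(1, 0, s0_max) * runif(1, 0, 0.3),
                             D1 = runif(1, 0, 1)),
    lower = c(A = 0, D1 = 0), upper = c(A = Inf, D1 = Inf),
    n_starts = n_starts, seed = seed, tie_par = "D1"
  )
  if (is.null(res$par)) {
    est <- tibble(amplitude = NA_real_, D1_tilde = NA_real_,
                  f1_tilde = NA_real_, s0_tilde = s0_tilde)
    return(new_highb_fit(est, dwi, "monoexp", list(
      residual_norm = NA_real_, n_starts_converged = 0L, flagged = TRUE)))
  }
  A <- unname(res$par[["A"]])
  D1 <- unname(res$par[["D1"]])
  flagged <- A <= 1e-12 * s0_max || A / s0_tilde > 1
  est <- tibble(amplitude = A, D1_tilde = D1,
                f1_tilde = A / s0_tilde, s0_tilde = s0_tilde)
  new_highb_fit(est, dwi, "monoexp", list(
    residual_norm = res$residual_norm,
    n_starts_converged = res$n_converged, flagged = flagged))
}

#' Joint T2-diffusivity fit at high b
#'
#' Fits `C exp(-TE / T2) exp(-b D1)` to multi-TE high-b shell means, same
#' multi-start scheme as [fit_highb_monoexp()] with T2 initialised and
#' constrained in \[0, 300\] ms. Requires at least 3 distinct TEs; a T2
#' estimate at the upper bound is flagged (TE-independent data).
#'
#' @inheritParams fit_highb_monoexp
#' @return A `highb_fit` with estimates `amplitude` (C), `T2_1`,
#'   `D1_tilde`.
#' @export
fit_highb_t2 <- function(shell_means, bs = 10, n_starts = 10L, seed = NULL) {
  dwi <- shell_means |>
    dplyr::filter(!.data$is_b0, .data$b > bs) |>
    dplyr::arrange(.data$b, .data$te)
  n_te <- dplyr::n_distinct(dwi$te)
  if (n_te < 3L) {
    abort("Joint T2 fit needs >= 3 distinct TEs; use fit_highb_monoexp() for single-TE data.")
  }
  y <- dwi$mean
  b <- dwi$b
  te <- dwi$te
  s_max <- max(y, .Machine$double.eps)
  t2_lower <- 1e-3  # exp(-TE/T2) underflows to 0 smoothly as T2 -> 0
  res <- multistart_lm(
    residual_fun = function(p) {
      p[["C"]] * exp(-te / p[["T2"]]) * exp(-b * p[["D1"]]) - y
    },
    start_fun = function() c(
      C = runif(1, 0, s_max * 4) * runif(1, 0, 0.3),
      T2 = runif(1, 0, 300), D1 = runif(1, 0, 1)
    ),
    lower = c(C = 0, T2 = t2_lower, D1 = 0),
    upper = c(C = Inf, T2 = 300, D1 = Inf),
    n_starts = n_starts, seed = seed, tie_par = "D1"
  )
  if (is.null(res$par)) {
    est <- tibble(amplitude = NA_real_, T2_1 = NA_real_, D1_tilde = NA_real_)
    return(new_highb_fit(est, dwi, "t2_joint", list(
      residual_norm = NA_real_, n_starts_converged = 0L, flagged = TRUE)))
  }
  T2 <- unname(res$par[["T2"]])
  est <- tibble(amplitude = unname(res$par[["C"]]), T2_1 = T2,
                D1_tilde = unname(res$par[["D1"]]))
  new_highb_fit(est, dwi, "t2_joint", list(
    residual_norm = res$residual_norm,
    n_starts_converged = res$n_converged,
    flagged = T2 >= 300 - 1e-6))
}

#' Sphere-radius fit at high b
#'
#' Fits `A * S_sphere(w scaled to b; r_s, D_s)` to high-b shell means with
#' the intra-sphere diffusivity fixed (default 3 um^2/ms) and
#' `r_s` constrained to \[0, 20\] um; multi-start as in
#' [fit_highb_monoexp()].
#'
#' @inheritParams fit_highb_monoexp
#' @param waveform The [gradient_waveform()] the data were acquired with;
#'   it is amplitude-rescaled to each shell's b.
#' @param D_s_fixed Intra-sphere diffusivity, um^2/ms.
#' @return A `highb_fit` with estimates `amplitude`, `r_s`.
#' @export
fit_sphere_radius <- function(shell_means, waveform, s0_tilde, bs = 10,
                              D_s_fixed = 3, n_starts = 10L, seed = NULL) {
  if (missing(waveform) || !inherits(waveform, "gradient_waveform")) {
    abort("The sphere signal is waveform-dependent: supply `waveform`.")
  }
  dwi <- shell_means |>
    dplyr::filter(!.data$is_b0, .data$b > bs) |>
    dplyr::arrange(.data$b)
  if (nrow(dwi) < 2L) abort(sprintf("Need >= 2 shells with b > %g ms/um^2.", bs))
  y <- dwi$mean
  shell_grids <- lapply(dwi$b, function(bb) {
    sphere_gradient_grid(scale_waveform(waveform, bb))
  })
  sphere_decay <- function(r) {
    vapply(shell_grids, sphere_signal_grid, 1, r_s = r, D_s = D_s_fixed)
  }
  s0_max <- max(s0_tilde, max(y), .Machine$double.eps)
  res <- multistart_lm(
    residual_fun = function(p) p[["A"]] * sphere_decay(p[["r_s"]]) - y,
    start_fun = function() c(A = runif(1, 0, s0_max), r_s = runif(1, 0, 20)),
    lower = c(A = 0, r_s = 0), upper = c(A = Inf, r_s = 20),
    n_starts = n_starts, seed = seed, tie_par = "r_s"
  )
  if (is.null(res$par)) {
    est <- tibble(amplitude = NA_real_, r_s = NA_real_, s0_tilde = s0_tilde)
    return(new_highb_fit(est, dwi, "sphere", list(
      residual_norm = NA_real_, n_starts_converged = 0L, flagged = TRUE)))
  }
  r_s <- unname(res$par[["r_s"]])
  est <- tibble(amplitude = unname(res$par[["A"]]), r_s = r_s,
                s0_tilde = s0_tilde)
  new_highb_fit(est, dwi, "sphere", list(
    residual_norm = res$residual_norm,
    n_starts_converged = res$n_converged,
    flagged = r_s >= 20 - 1e-6))
}

#' ROI summary table
#'
#' Median and 10-90 percentiles (linear interpolation) of per-voxel
#' parameter estimates within each ROI. Percentiles are suppressed for
#' ROIs with fewer than `min_voxels` voxels; empty ROIs are dropped with a
#' warning.
#'
#' @param fits Tibble of per-voxel estimates with a `roi` column; every
#'   other numeric column is summarised.
#' @param min_voxels Minimum ROI size for percentiles.
#' @return A long tibble: `roi`, `parameter`, `n`, `median`, `p10`, `p90`.
#' @export
roi_summary <- function(fits, min_voxels = 10L) {
  if (!"roi" %in% names(fits)) abort("`fits` needs a `roi` column.")
  if (any(is.na(fits$roi))) {
    warn("Dropping voxels with missing ROI label.")
    fits <- dplyr::filter(fits, !is.na(.data$roi))
  }
  params <- setdiff(names(fits)[vapply(fits, is.numeric, TRUE)],
                    c("voxel", "roi"))
  fits |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$roi, .data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$value),
      p10 = if (dplyr::n() >= min_voxels) {
        quantile(.data$value, 0.1, type = 7, names = FALSE)
      } else NA_real_,
      p90 = if (dplyr::n() >= min_voxels) {
        quantile(.data$value, 0.9, type = 7, names = FALSE)
      } else NA_real_,
      .groups = "drop"
    )
}

#' Format an ROI summary the way results tables are usually printed
#'
#' One row per ROI, one column per parameter, entries
#' `median (p10-p90)`.
#'
#' @param summary Output of [roi_summary()].
#' @param digits Significant digits.
#' @return A tibble of formatted strings.
#' @export
format_roi_table <- function(summary, digits = 3L) {
  summary |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$p10),
      sprintf("%.*g", digits, .data$median),
      sprintf("%.*g (%.*g-%.*g)", digits, .data$median, digits, .data$p10,
              digits, .data$p90)
    )) |>
    dplyr::select("roi", "parameter", "cell") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "cell")
}
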