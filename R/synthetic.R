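#' Tissue presets
#'
#' Ready-made tissue models matching the signal regimes of the in-vivo
#' ROIs (medial / occipital / cerebellar white matter, deep / cerebellar
#' grey matter) and the two illustrative dispersed-fibre scenarios:
#' `fig_scenario1` (Watson sticks + Watson zeppelins, OD = 0.7, no dot)
#' and `fig_scenario2` (the same split plus a 2% dot compartment,
#' OD = 0.5). Where a regime parameter is published (slow-pool fraction
#' and diffusivity, b0 SNR) the preset uses it; the remaining defaults
#' (fast-pool diffusivity 1.0 um^2/ms, T2 90 ms in cGM; WM/dGM pools) are
#' declared package choices and can be overridden.
#'
#' @param name One of `"mWM"`, `"dGM"`, `"oWM"`, `"cWM"`, `"cGM"`,
#'   `"fig_scenario1"`, `"fig_scenario2"`.
#' @param snr_b0 b0 signal-to-noise ratio; default per preset.
#' @param voxelwise_jitter Fractional lognormal standard deviation applied
#'   to each voxel's parameters (0 = exact).
#' @param f_dot Dot fraction override (fig scenarios).
#' @param OD Orientation dispersion override (fig scenarios).
#' @return An object of class `tissue_preset`: list with `name`, `model`,
#'   `snr_b0`, `voxelwise_jitter`.
#' @examples
#' make_preset("cGM")
#' @export
make_preset <- function(name, snr_b0 = NULL, voxelwise_jitter = 0.05,
                        f_dot = NULL, OD = NULL) {
  specs <- list(
    # slow isotropic pool per published ROI medians + declared fast pool
    cGM = list(snr = 452, cmps = list(
      list(kind = "ball", fraction = 0.097, D_par = 0.12, T2 = 61),
      list(kind = "ball", fraction = 0.903, D_par = 1.0, T2 = 90)
    )),
    oWM = list(snr = 415, cmps = list(
      list(kind = "ball", fraction = 0.026, D_par = 0.16, T2 = 60),
      list(kind = "ball", fraction = 0.974, D_par = 0.85, T2 = 70)
    )),
    cWM = list(snr = 242, cmps = list(
      list(kind = "ball", fraction = 0.054, D_par = 0.23, T2 = 60),
      list(kind = "ball", fraction = 0.946, D_par = 0.9, T2 = 70)
    )),
    mWM = list(snr = 251, cmps = list(
      list(kind = "ball", fraction = 1, D_par = 0.8, T2 = 70)
    )),
    dGM = list(snr = 143, cmps = list(
      list(kind = "ball", fraction = 1, D_par = 0.75, T2 = 70)
    ))
  )
  if (name %in% names(specs)) {
    sp <- specs[[name]]
    cmps <- lapply(sp$cmps, function(x) do.call(compartment, x))
    model <- tissue_model(cmps)
    snr <- snr_b0 %||% sp$snr
  } else if (name %in% c("fig_scenario1", "fig_scenario2")) {
    fd <- f_dot %||% if (name == "fig_scenario2") 0.02 else 0
    od <- OD %||% if (name == "fig_scenario2") 0.5 else 0.7
    rest <- 1 - fd
    cmps <- list(
      compartment("watson_stick", rest / 2, D_par = 2.1, OD = od),
      compartment("watson_zeppelin", rest / 2, D_par = 1.9, D_perp = 0.8,
                  OD = od)
    )
    if (fd > 0) cmps <- c(cmps, list(compartment("dot", fd)))
    model <- tissue_model(cmps)
    snr <- snr_b0 %||% 100
  } else {
    abort(sprintf("Unknown preset '%s'.", name))
  }
  structure(
    list(name = name, model = model, snr_b0 = snr,
         voxelwise_jitter = voxelwise_jitter),
    class = "tissue_preset"
  )
}

#' @export
print.tissue_preset <- function(x, ...) {
  cat(sprintf("<tissue_preset '%s'> SNR(b0) = %g, jitter = %g\n",
              x$name, x$snr_b0, x$voxelwise_jitter))
  print(x$model)
  invisible(x)
}

# lognormal multiplicative jitter with fractional sd `cv`
jitter_lnorm <- function(x, cv) {
  if (cv <= 0) return(x)
  x * exp(rnorm(length(x), mean = -0.5 * log(1 + cv^2),
                sd = sqrt(log(1 + cv^2))))
}

jitter_model <- function(model, cv) {
  if (cv <= 0) return(model)
  cmps <- lapply(model$compartments, function(cmp) {
    for (fld in c("D_par", "D_perp", "T2")) {
      if (!is.null(cmp[[fld]]) && cmp[[fld]] > 0) {
        cmp[[fld]] <- jitter_lnorm(cmp[[fld]], cv)
      }
    }
    if (!is.null(cmp$D_perp) && !is.null(cmp$D_par) &&
        cmp$D_perp > cmp$D_par) {
      cmp$D_perp <- cmp$D_par
    }
    cmp$fraction <- jitter_lnorm(cmp$fraction, cv)
    cmp
  })
  fsum <- sum(vapply(cmps, function(c) c$fraction, 1))
  cmps <- lapply(cmps, function(c) { c$fraction <- c$fraction / fsum; c })
  mdl <- model
  mdl$compartments <- cmps
  mdl
}

# slow pool = lowest-mean-diffusivity compartment (the Eq-3 target)
slow_pool_index <- function(model) {
  md <- vapply(model$compartments, compartment_mean_d, 1)
  which.min(md)
}

#' Generate a protocol-faithful synthetic dataset
#'
#' Per voxel: the preset's parameters are jittered (lognormal,
#' `voxelwise_jitter`), the noiseless signal is evaluated for every
#' protocol volume (with per-compartment T2 weighting), temporal b0
#' fluctuation is applied, and Rician noise is added at
#' `sigma = S(b=0, TE_min) / snr_b0`. Regeneration from the same
#' `(preset, protocol, seed)` is bit-identical, and every sampled
#' parameter is stored in the `truth` table.
#'
#' @param preset A [make_preset()] result.
#' @param protocol An [ste_protocol()].
#' @param n_voxels Number of voxels.
#' @param seed Integer seed.
#' @param roi ROI label attached to all voxels (default the preset name).
#' @param temporal_jitter Fractional sd of a slow multiplicative amplitude
#'   fluctuation applied per volume (emulates physiological b0 variation;
#'   this is what separates tSNR from SNR).
#' @return An object of class `ste_dataset`: list with `signals` (tibble
#'   voxel/volume/signal), `noiseless` (same shape), `voxels`
#'   (voxel/roi), `truth` (per-voxel generating parameters), `protocol`,
#'   `sigma`, `preset`, `seed`.
#' @export
generate_dataset <- function(preset, protocol, n_voxels = 100L, seed = 1L,
                             roi = preset$name, temporal_jitter = 0.015) {
  stopifnot(inherits(preset, "tissue_preset"), inherits(protocol, "ste_protocol"))
  te_min <- min(protocol$te)
  s0_ref <- signal_with_t2(preset$model, 0, te_min)
  sigma <- s0_ref / preset$snr_b0
  combos <- protocol |>
    dplyr::distinct(.data$b, .data$te) |>
    dplyr::arrange(.data$b, .data$te)
  out <- withr::with_seed(seed, {
    voxels <- vector("list", n_voxels)
    for (v in seq_len(n_voxels)) {
      mdl <- jitter_model(preset$model, preset$voxelwise_jitter)
      s_combo <- vapply(seq_len(nrow(combos)), function(i) {
        signal_with_t2(mdl, combos$b[i], combos$te[i])
      }, 1)
      s_vol <- s_combo[match(
        paste(protocol$b, protocol$te),
        paste(combos$b, combos$te)
      )]
      drift <- if (temporal_jitter > 0) {
        1 + rnorm(nrow(protocol), sd = temporal_jitter)
      } else rep(1, nrow(protocol))
      noisy <- add_rician(pmax(0, s_vol * drift), sigma)
      isl <- slow_pool_index(mdl)
      slow <- mdl$compartments[[isl]]
      f_dot <- sum(vapply(mdl$compartments, function(c) {
        if (c$kind == "dot") c$fraction else 0
      }, 1))
      s0_vox <- signal_with_t2(mdl, 0, te_min)
      w_slow <- if (is.null(slow$T2)) 1 else exp(-te_min / slow$T2)
      voxels[[v]] <- list(
        noiseless = s_vol, noisy = noisy,
        truth = tibble(
          voxel = v, roi = roi,
          f_slow = slow$fraction,
          D_slow = compartment_mean_d(slow),
          T2_slow = slow$T2 %||% NA_real_,
          f_dot = f_dot,
          s0 = s0_vox,
          f1_apparent = slow$fraction * w_slow / s0_vox
        )
      )
    }
    voxels
  })
  nvol <- nrow(protocol)
  signals <- tibble(
    voxel = rep(seq_len(n_voxels), each = nvol),
    volume = rep(seq_len(nvol), n_voxels),
    signal = unlist(lapply(out, `[[`, "noisy"))
  )
  noiseless <- tibble(
    voxel = signals$voxel, volume = signals$volume,
    signal = unlist(lapply(out, `[[`, "noiseless"))
  )
  structure(
    list(
      signals = signals,
      noiseless = noiseless,
      voxels = tibble(voxel = seq_len(n_voxels), roi = roi),
      truth = dplyr::bind_rows(lapply(out, `[[`, "truth")),
      protocol = protocol,
      sigma = sigma,
      preset = preset,
      seed = seed,
      temporal_jitter = temporal_jitter
    ),
    class = "ste_dataset"
  )
}

#' @export
print.ste_dataset <- function(x, ...) {
  cat(sprintf(
    "<ste_dataset '%s'> %d voxels x %d volumes, sigma = %.4g (SNR %g), seed %d\n",
    x$preset$name, nrow(x$voxels), nrow(x$protocol), x$sigma,
    x$preset$snr_b0, x$seed
  ))
  invisible(x)
}
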