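#' Pipeline configuration
#'
#' All knobs of the analysis stage in one record; every value is stamped
#' verbatim into the run manifest.
#'
#' @param bs High-b threshold, ms/um^2; shells with `b > bs` strictly are
#'   fitted (default 10 = 10000 s/mm^2).
#' @param n_starts Random starts of the bounded least-squares fits.
#' @param seed Integer seed; each voxel's multi-start draws from
#'   `seed + voxel`, so results do not depend on voxel order.
#' @param debias Apply Rician debiasing before shell averaging.
#' @param s0_method S(0) estimator id (currently `"lowb_extrapolation"`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bs = 10, n_starts = 10L, seed = 1L,
                            debias = TRUE, s0_method = "lowb_extrapolation") {
  if (!identical(s0_method, "lowb_extrapolation")) {
    abort("The only implemented S(0) method is 'lowb_extrapolation'.")
  }
  structure(
    list(bs = bs, n_starts = as.integer(n_starts), seed = as.integer(seed),
         debias = isTRUE(debias), s0_method = s0_method),
    class = "pipeline_config"
  )
}

#' Run the high-b analysis pipeline
#'
#' Executes, per voxel: Rician debiasing (if enabled) -> shell averaging ->
#' S(0) extrapolation from the two lowest shells -> upper-limit dot
#' fraction -> high-b mono-exponential fit (-> joint T2 fit when the
#' protocol has >= 3 TEs) -> ROI summary. Deterministic given
#' `config$seed`.
#'
#' @param data An `ste_dataset` from [generate_dataset()] /
#'   [run_simulation()], or a signals tibble (`voxel`, `volume`,
#'   `signal`).
#' @param protocol An [ste_protocol()]; taken from `data` when it is a
#'   dataset.
#' @param sigma Noise standard deviation; taken from the dataset if
#'   omitted, or estimated from `background` values.
#' @param rois Tibble `voxel`, `roi`; taken from the dataset if omitted.
#' @param config A [pipeline_config()].
#' @param background Optional magnitude values from signal-free voxels,
#'   used to estimate `sigma` when it is not supplied.
#' @return An object of class `ste_analysis`: `voxel_fits` (one row per
#'   voxel), `roi_table` ([roi_summary()] output), `shell_means`,
#'   `config`, `manifest`. [tidy()] returns the per-voxel fits,
#'   [glance()] a one-row overview.
#' @examples
#' \donttest{
#' ds <- run_simulation("cGM", n_voxels = 20, seed = 1)
#' fit <- run_analysis(ds)
#' tidy(fit)
#' }
#' @export
run_analysis <- function(data, protocol = NULL, sigma = NULL, rois = NULL,
                         config = pipeline_config(), background = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(data, "ste_dataset")) {
    protocol <- protocol %||% data$protocol
    sigma <- sigma %||% data$sigma
    rois <- rois %||% data$voxels
    signals <- data$signals
  } else {
    signals <- as_voxel_signals(data, protocol)
  }
  if (is.null(protocol)) abort("A protocol is required.")
  if (is.null(sigma)) {
    if (is.null(background)) {
      abort("Supply `sigma` or `background` values to estimate it from.")
    }
    sigma <- estimate_sigma_background(background)
  }
  n_high <- protocol |>
    dplyr::filter(!.data$is_b0, .data$b > config$bs) |>
    dplyr::distinct(.data$b) |>
    nrow()
  if (n_high < 2L) {
    abort(sprintf(
      "Protocol has %d shell(s) with b > %g ms/um^2; the high-b fit needs >= 2.",
      n_high, config$bs
    ))
  }
  # SNR/tSNR from the raw (pre-debias) interleaved b0 series
  b0_vols <- protocol$volume[protocol$is_b0 & protocol$te == min(protocol$te)]
  snr_tbl <- NULL
  if (length(b0_vols) >= 3L && sigma > 0) {
    b0_wide <- signals |>
      dplyr::filter(.data$volume %in% b0_vols) |>
      dplyr::arrange(.data$voxel, .data$volume)
    vox_ids <- unique(b0_wide$voxel)
    b0_mat <- matrix(b0_wide$signal, nrow = length(vox_ids), byrow = TRUE)
    snr_tbl <- dplyr::bind_cols(tibble(voxel = vox_ids),
                                snr_tsnr(b0_mat, sigma))
  }
  if (config$debias) {
    signals <- dplyr::mutate(signals, signal = debias_rician(.data$signal, sigma))
  }
  sm_all <- shell_average(signals, protocol)
  te_ref <- min(protocol$te)
  multi_te <- dplyr::n_distinct(protocol$te) >= 3L
  s0_tbl <- estimate_s0_lowb(dplyr::filter(sm_all, .data$te == te_ref))
  fit_one <- function(v) {
    sm_v <- dplyr::filter(sm_all, .data$voxel == v, .data$te == te_ref)
    s0 <- s0_tbl$s0_tilde[s0_tbl$voxel == v][1L]
    fdot <- if (s0 > 0) fdot_upper_limit(sm_v, s0) else NA_real_
    seed_v <- (config$seed + v) %% .Machine$integer.max
    fit <- fit_highb_monoexp(sm_v, s0_tilde = s0, bs = config$bs,
                             n_starts = config$n_starts, seed = seed_v)
    row <- dplyr::bind_cols(
      tibble(voxel = v, fdot_tilde = fdot),
      fit$estimates,
      tibble(
        residual_norm = fit$diagnostics$residual_norm,
        n_starts_converged = fit$diagnostics$n_starts_converged,
        flagged = fit$diagnostics$flagged
      )
    )
    if (multi_te) {
      ft2 <- fit_highb_t2(dplyr::filter(sm_all, .data$voxel == v),
                          bs = config$bs, n_starts = config$n_starts,
                          seed = seed_v)
      row$T2_1 <- ft2$estimates$T2_1
      row$flagged <- row$flagged | ft2$diagnostics$flagged
    }
    row
  }
  voxel_fits <- dplyr::bind_rows(lapply(unique(signals$voxel), fit_one))
  voxel_fits <- voxel_fits |>
    dplyr::mutate(noise_floor_rel = noise_floor(sigma) / .data$s0_tilde)
  if (!is.null(snr_tbl)) {
    voxel_fits <- dplyr::left_join(voxel_fits, snr_tbl, by = "voxel")
  }
  if (!is.null(rois)) {
    voxel_fits <- dplyr::left_join(voxel_fits, rois, by = "voxel")
  } else {
    voxel_fits$roi <- "all"
  }
  summary_cols <- intersect(
    c("voxel", "roi", "noise_floor_rel", "snr", "tsnr", "fdot_tilde",
      "f1_tilde", "D1_tilde", "T2_1"),
    names(voxel_fits)
  )
  roi_table <- roi_summary(voxel_fits[summary_cols])
  manifest <- list(
    package_version = as.character(utils::packageVersion("stedot")),
    config = unclass(config),
    sigma = sigma,
    n_voxels = dplyr::n_distinct(signals$voxel),
    n_volumes = nrow(protocol),
    te_ref = te_ref,
    multi_te = multi_te,
    n_flagged = sum(voxel_fits$flagged, na.rm = TRUE)
  )
  structure(
    list(voxel_fits = voxel_fits, roi_table = roi_table,
         shell_means = sm_all, sigma = sigma, config = config,
         manifest = manifest),
    class = "ste_analysis"
  )
}

#' @export
print.ste_analysis <- function(x, ...) {
  cat(sprintf("<ste_analysis> %d voxels, sigma = %.4g, %d flagged\n",
              x$manifest$n_voxels, x$sigma, x$manifest$n_flagged))
  print(format_roi_table(x$roi_table))
  invisible(x)
}

#' @export
tidy.ste_analysis <- function(x, ...) x$voxel_fits

#' @export
glance.ste_analysis <- function(x, ...) {
  tibble(
    n_voxels = x$manifest$n_voxels,
    n_volumes = x$manifest$n_volumes,
    sigma = x$sigma,
    multi_te = x$manifest$multi_te,
    n_flagged = x$manifest$n_flagged,
    median_fdot = median(x$voxel_fits$fdot_tilde, na.rm = TRUE),
    median_f1 = median(x$voxel_fits$f1_tilde, na.rm = TRUE),
    median_D1 = median(x$voxel_fits$D1_tilde, na.rm = TRUE)
  )
}

#' Simulate a dataset from a named preset
#'
#' Thin wrapper over [make_preset()], [paper_protocol()] and
#' [generate_dataset()]; optionally writes the dataset to disk (protocol
#' table, truth/signals TSV, manifest YAML, and NIfTI volumes when the
#' RNifti package is available).
#'
#' @param preset Preset name (see [make_preset()]) or a `tissue_preset`.
#' @param TEs Echo times, ms.
#' @param n_voxels Number of voxels.
#' @param seed Integer seed.
#' @param dir Optional output directory.
#' @param ... Passed to [make_preset()] when `preset` is a name.
#' @return An `ste_dataset` (invisibly when writing to `dir`).
#' @export
run_simulation <- function(preset, TEs = 88, n_voxels = 100L, seed = 1L,
                           dir = NULL, ...) {
  if (is.character(preset)) preset <- make_preset(preset, ...)
  protocol <- paper_protocol(TEs = TEs)
  ds <- generate_dataset(preset, protocol, n_voxels = n_voxels, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_protocol(protocol, file.path(dir, "protocol.txt"))
    write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(ds$signals, file.path(dir, "signals.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(
      preset = preset$name, snr_b0 = preset$snr_b0,
      voxelwise_jitter = preset$voxelwise_jitter, seed = seed,
      n_voxels = n_voxels, TEs = TEs, sigma = ds$sigma,
      temporal_jitter = ds$temporal_jitter,
      package_version = as.character(utils::packageVersion("stedot"))
    ), file.path(dir, "manifest.yaml"))
    if (requireNamespace("RNifti", quietly = TRUE)) {
      write_dataset_nifti(ds, file.path(dir, "volumes.nii"))
    }
    return(invisible(ds))
  }
  ds
}

#' Write / read dataset volumes as NIfTI
#'
#' The voxel table is laid out on a near-cubic grid; volumes become the 4th
#' dimension. Requires the RNifti package.
#'
#' @param ds An `ste_dataset`.
#' @param path NIfTI file path (`.nii`).
#' @return `write_dataset_nifti()` returns `path` invisibly;
#'   `read_volumes_nifti()` returns a signals tibble (`voxel`, `volume`,
#'   `signal`).
#' @export
write_dataset_nifti <- function(ds, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("Writing NIfTI requires the RNifti package.")
  }
  n_vox <- nrow(ds$voxels)
  n_vol <- nrow(ds$protocol)
  nx <- ceiling(sqrt(n_vox))
  ny <- ceiling(n_vox / nx)
  arr <- array(0, dim = c(nx, ny, 1L, n_vol))
  sig <- matrix(ds$signals$signal, nrow = n_vol)  # volumes x voxels
  for (v in seq_len(n_vox)) {
    ix <- (v - 1L) %% nx + 1L
    iy <- (v - 1L) %/% nx + 1L
    arr[ix, iy, 1L, ] <- sig[, v]
  }
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(4, 4, 4, 1)), path)
  invisible(path)
}

#' @rdname write_dataset_nifti
#' @param n_voxels Number of real voxels in the grid (trailing grid
#'   positions are padding).
#' @export
read_volumes_nifti <- function(path, n_voxels = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("Reading NIfTI requires the RNifti package.")
  }
  arr <- RNifti::readNifti(path)
  d <- dim(arr)
  if (length(d) != 4L) abort("Expected a 4-D NIfTI volume series.")
  n_grid <- prod(d[1:3])
  n_voxels <- n_voxels %||% n_grid
  flat <- matrix(arr, nrow = n_grid, ncol = d[4L])
  tibble(
    voxel = rep(seq_len(n_voxels), d[4L]),
    volume = rep(seq_len(d[4L]), each = n_voxels),
    signal = as.numeric(flat[seq_len(n_voxels), ])
  )
}
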