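#' Tissue compartments
#'
#' A compartment is one water pool with a signal kind and its parameters.
#' Supported kinds: `dot` (zero apparent diffusivity in all directions),
#' `ball` (isotropic Gaussian), `stick` (`D_perp = 0`), `zeppelin`
#' (axisymmetric Gaussian), `watson_stick` / `watson_zeppelin` (the same
#' kernels orientation-dispersed by a Watson distribution), and `sphere`
#' (restricted diffusion in an impermeable sphere, waveform-dependent).
#'
#' @param kind Compartment kind (see Details).
#' @param fraction Signal fraction at TE = 0, in \[0, 1\].
#' @param D_par,D_perp Parallel / perpendicular diffusivity, um^2/ms. For
#'   `ball`, `D_par` is the isotropic diffusivity.
#' @param OD Watson orientation dispersion in (0, 1\] (1 = uniform).
#' @param axis Mean orientation, unit 3-vector.
#' @param radius Sphere radius, um (sphere only, in \[0, 20\]).
#' @param D_s Intra-sphere diffusivity, um^2/ms (sphere only).
#' @param T2 Transverse relaxation time, ms, or `NULL` for no TE dependence.
#' @return An object of class `compartment`.
#' @examples
#' compartment("ball", 1, D_par = 0.8)
#' compartment("watson_stick", 0.5, D_par = 2.1, OD = 0.5)
#' @export
compartment <- function(kind, fraction, D_par = NULL, D_perp = NULL,
                        OD = NULL, axis = c(0, 0, 1), radius = NULL,
                        D_s = NULL, T2 = NULL) {
  kinds <- c("dot", "ball", "stick", "zeppelin", "watson_stick",
             "watson_zeppelin", "sphere")
  kind <- match.arg(kind, kinds)
  if (fraction < 0 || fraction > 1) abort("`fraction` must lie in [0, 1].")
  if (kind == "dot") {
    D_par <- D_perp <- 0
  }
  if (kind %in% c("ball", "stick", "watson_stick")) {
    if (is.null(D_par)) abort(sprintf("`%s` needs `D_par`.", kind))
    D_perp <- if (kind == "ball") D_par else 0
  }
  if (kind %in% c("zeppelin", "watson_zeppelin")) {
    if (is.null(D_par) || is.null(D_perp)) {
      abort(sprintf("`%s` needs `D_par` and `D_perp`.", kind))
    }
  }
  if (!is.null(D_par) && !is.null(D_perp) &&
      (D_perp < 0 || D_par < D_perp)) {
    abort("Diffusivities must satisfy D_par >= D_perp >= 0.")
  }
  if (kind %in% c("watson_stick", "watson_zeppelin")) {
    if (is.null(OD) || OD <= 0 || OD > 1) {
      abort("Watson compartments need `OD` in (0, 1].")
    }
  }
  if (kind == "sphere") {
    if (is.null(radius) || is.null(D_s)) abort("`sphere` needs `radius` and `D_s`.")
    if (radius < 0 || radius > 20) abort("`radius` must lie in [0, 20] um.")
    if (D_s <= 0) abort("`D_s` must be positive.")
  }
  if (!is.null(T2) && T2 <= 0) abort("`T2` must be positive (ms) or NULL.")
  axis <- axis / sqrt(sum(axis^2))
  structure(
    list(kind = kind, fraction = fraction, D_par = D_par, D_perp = D_perp,
         OD = OD, axis = axis, radius = radius, D_s = D_s, T2 = T2),
    class = "compartment"
  )
}

# Mean apparent diffusivity Tr(D)/3; what STE attenuates by (Gaussian kinds)
compartment_mean_d <- function(cmp) {
  switch(cmp$kind,
    dot = 0,
    ball = cmp$D_par,
    stick = cmp$D_par / 3,
    watson_stick = cmp$D_par / 3,
    zeppelin = (cmp$D_par + 2 * cmp$D_perp) / 3,
    watson_zeppelin = (cmp$D_par + 2 * cmp$D_perp) / 3,
    sphere = abort("A sphere compartment has no Gaussian mean diffusivity; its signal is waveform-dependent.")
  )
}

#' Tissue models
#'
#' A set of compartments whose fractions sum to one, with an optional
#' two-pool exchange specification (exchange requires exactly two
#' compartments; all other operations assume no exchange).
#'
#' @param ... [compartment()] objects.
#' @param exchange `NULL` or a [karger_spec()].
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(..., exchange = NULL) {
  cmps <- list(...)
  if (length(cmps) == 1L && is.list(cmps[[1L]]) &&
      !inherits(cmps[[1L]], "compartment")) {
    cmps <- cmps[[1L]]
  }
  if (!length(cmps) || !all(vapply(cmps, inherits, TRUE, "compartment"))) {
    abort("A tissue model is built from `compartment()` objects.")
  }
  fsum <- sum(vapply(cmps, function(c) c$fraction, 1))
  if (abs(fsum - 1) > 1e-9) {
    abort(sprintf("Compartment fractions must sum to 1 (got %.12g).", fsum))
  }
  if (!is.null(exchange)) {
    if (!inherits(exchange, "karger_spec")) abort("`exchange` must be a karger_spec().")
    if (length(cmps) != 2L) abort("Exchange is defined for exactly two compartments.")
  }
  structure(list(compartments = cmps, exchange = exchange),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> %d compartment(s)%s\n", length(x$compartments),
              if (is.null(x$exchange)) "" else " with two-pool exchange"))
  for (cmp in x$compartments) {
    cat(sprintf(
      "  %-16s f = %-6.4g D_par = %-5.4g D_perp = %-5.4g %s%s\n",
      cmp$kind, cmp$fraction, cmp$D_par %||% NA, cmp$D_perp %||% NA,
      if (!is.null(cmp$OD)) sprintf("OD = %.3g ", cmp$OD) else "",
      if (!is.null(cmp$T2)) sprintf("T2 = %.4g ms", cmp$T2) else ""
    ))
  }
  invisible(x)
}

#' Two-pool exchange specification
#'
#' First-order magnetisation exchange between two pools with equilibrium
#' fractions `f1`, `f2 = 1 - f1` and mean diffusivities `D1`, `D2`. The
#' exchange time is `t_ex = 1 / (k12 + k21)` with rates satisfying
#' equilibrium `f1 k12 = f2 k21`; the encoding is idealised as narrow-pulse
#' with one effective diffusion time.
#'
#' @param f1 Fraction of pool 1.
#' @param D1,D2 Mean diffusivities, um^2/ms.
#' @param t_ex Exchange time, ms (`Inf` = no exchange).
#' @param diffusion_time Effective diffusion time, ms.
#' @return An object of class `karger_spec`.
#' @export
karger_spec <- function(f1, D1, D2, t_ex, diffusion_time) {
  if (f1 < 0 || f1 > 1) abort("`f1` must lie in [0, 1].")
  if (t_ex <= 0) abort("`t_ex` must be positive (use Inf for no exchange).")
  if (diffusion_time <= 0) abort("`diffusion_time` must be positive.")
  if (D1 < 0 || D2 < 0) abort("Diffusivities must be non-negative.")
  structure(
    list(f1 = f1, f2 = 1 - f1, D1 = D1, D2 = D2, t_ex = t_ex,
         diffusion_time = diffusion_time),
    class = "karger_spec"
  )
}

#' Read / write a tissue model configuration
#'
#' Human-readable YAML: one block per compartment plus an optional
#' `exchange` block.
#'
#' @param model A [tissue_model()].
#' @param path File path.
#' @return `read_tissue_model()` returns a [tissue_model()];
#'   `write_tissue_model()` returns `path` invisibly.
#' @export
write_tissue_model <- function(model, path) {
  stopifnot(inherits(model, "tissue_model"))
  cmp_list <- lapply(model$compartments, function(cmp) {
    Filter(Negate(is.null), list(
      kind = cmp$kind, fraction = cmp$fraction, D_par = cmp$D_par,
      D_perp = cmp$D_perp, OD = cmp$OD, axis = as.numeric(cmp$axis),
      radius = cmp$radius, D_s = cmp$D_s, T2 = cmp$T2
    ))
  })
  out <- list(compartments = cmp_list)
  if (!is.null(model$exchange)) {
    ex <- model$exchange
    out$exchange <- list(f1 = ex$f1, D1 = ex$D1, D2 = ex$D2, t_ex = ex$t_ex,
                         diffusion_time = ex$diffusion_time)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_tissue_model
#' @export
read_tissue_model <- function(path) {
  raw <- yaml::read_yaml(path)
  cmps <- lapply(raw$compartments, function(x) {
    do.call(compartment, c(
      list(kind = x$kind, fraction = x$fraction),
      x[intersect(names(x), c("D_par", "D_perp", "OD", "axis", "radius",
                              "D_s", "T2"))]
    ))
  })
  exchange <- NULL
  if (!is.null(raw$exchange)) exchange <- do.call(karger_spec, raw$exchange[
    c("f1", "D1", "D2", "t_ex", "diffusion_time")])
  tissue_model(cmps, exchange = exchange)
}
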