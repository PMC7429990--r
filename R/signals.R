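#' Gaussian compartment signal under a general B-tensor
#'
#' Attenuation `exp(-Tr(B D))` of a Gaussian pool with diffusion tensor `D`
#' probed by encoding tensor `B`. For isotropic `B` (STE) this depends on
#' `D` only through its mean diffusivity `Tr(D)/3`, which is what makes STE
#' insensitive to orientation and anisotropy.
#'
#' @param B A [btensor()], ms/um^2.
#' @param D 3x3 symmetric PSD diffusion tensor, um^2/ms.
#' @return Attenuation in \[0, 1\].
#' @examples
#' B <- make_axisymmetric_btensor(8.5, 0)
#' signal_gaussian(B, diag(rep(0.8, 3))) # ~0.001
#' @export
signal_gaussian <- function(B, D) {
  stopifnot(inherits(B, "btensor"))
  D <- as.matrix(D)
  if (!all(dim(D) == c(3L, 3L))) abort("`D` must be a 3x3 matrix.")
  if (max(abs(D - t(D))) > 1e-9 * max(1, max(abs(D)))) {
    abort("`D` must be symmetric.")
  }
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1e-12)) {
    abort("`D` must be positive semi-definite.")
  }
  exp(-sum(B$matrix * D))
}

#' STE signal of a non-exchanging compartment mixture
#'
#' For spherical tensor encoding every Gaussian compartment attenuates by
#' its mean diffusivity: `S(b)/S(0) = sum_i f_i exp(-b D_i)`. A dot
#' compartment contributes `f_i` at every b (the high-b plateau); a sphere
#' compartment is waveform-dependent and requires `waveform`.
#'
#' @param b b-value(s), ms/um^2 (vectorised).
#' @param model A [tissue_model()] with `exchange = NULL`.
#' @param waveform Optional [gradient_waveform()], needed only when the
#'   model contains sphere compartments; it is amplitude-rescaled to each
#'   requested b.
#' @return Attenuation(s) in \[0, 1\].
#' @examples
#' m <- tissue_model(
#'   compartment("ball", 0.097, D_par = 0.12),
#'   compartment("ball", 0.903, D_par = 1.0)
#' )
#' signal_ste_mixture(15, m) # ~0.016
#' @export
signal_ste_mixture <- function(b, model, waveform = NULL) {
  stopifnot(inherits(model, "tissue_model"))
  if (!is.null(model$exchange)) {
    abort("Use signal_karger() for a model with exchange.")
  }
  vapply(b, function(bb) {
    sum(vapply(model$compartments, function(cmp) {
      if (cmp$kind == "sphere") {
        if (is.null(waveform)) {
          abort("A sphere compartment needs a `waveform` to evaluate its STE signal.")
        }
        cmp$fraction * signal_sphere_waveform(
          scale_waveform(waveform, bb), cmp$radius, cmp$D_s
        )
      } else {
        cmp$fraction * exp(-bb * compartment_mean_d(cmp))
      }
    }, 1))
  }, 1)
}

#' Watson concentration / orientation dispersion mapping
#'
#' `OD = (2 / pi) * atan(1 / kappa)`: OD 1 is the uniform distribution
#' (kappa = 0), OD -> 0 is perfectly aligned (kappa -> Inf).
#'
#' @param OD Orientation dispersion in (0, 1].
#' @param kappa Watson concentration, >= 0.
#' @return The corresponding concentration / dispersion.
#' @export
watson_kappa <- function(OD) {
  stopifnot(all(OD > 0), all(OD <= 1))
  ifelse(OD == 1, 0, 1 / tan(pi * OD / 2))
}

#' @rdname watson_kappa
#' @export
watson_od <- function(kappa) {
  stopifnot(all(kappa >= 0))
  (2 / pi) * atan(1 / kappa)
}

# Orientation average of kernel(cos2) over a Watson distribution with the
# mean axis at `angle` from the encoding axis; cos2 is (g.n)^2.
# Gauss-Legendre in cos(theta), periodic trapezoid in phi, order doubled
# until the result is 1e-6 stable.
watson_average <- function(kernel, kappa, angle, tol = 1e-6, max_order = 512L) {
  g <- c(sin(angle), 0, cos(angle))
  prev <- NULL
  m <- 16L
  while (m <= max_order) {
    gl <- pracma::gaussLegendre(m, -1, 1)
    u <- gl$x                       # cos(theta) in the mean-axis frame
    su <- sqrt(pmax(0, 1 - u^2))
    phi <- (seq_len(2L * m) - 1L) * pi / m
    w_watson <- exp(kappa * u^2)    # un-normalised Watson density
    # cos2[i, j] for node (u_i, phi_j)
    cos_gn <- outer(su, cos(phi)) * g[1L] + matrix(u * g[3L], m, 2L * m)
    vals <- kernel(cos_gn^2)
    num <- sum(gl$w * w_watson * rowMeans(vals))
    den <- sum(gl$w * w_watson)
    est <- num / den
    if (!is.null(prev) && abs(est - prev) <= tol * max(abs(est), 1e-12)) {
      return(est)
    }
    prev <- est
    m <- m * 2L
  }
  abort("Watson quadrature did not converge; increase `max_order`.")
}

#' LTE signal of Watson-dispersed sticks
#'
#' `integral W(n; kappa(OD)) exp(-b D_par (g.n)^2) dn` over the sphere. In
#' the uniform limit (OD = 1) this is the powder average of a stick,
#' `sqrt(pi) erf(sqrt(b D_par)) / (2 sqrt(b D_par))`.
#'
#' @param b b-value, ms/um^2 (vectorised).
#' @param D_par Stick parallel diffusivity, um^2/ms.
#' @param OD Watson orientation dispersion in (0, 1].
#' @param angle Angle between encoding axis and mean orientation, rad.
#' @return Attenuation(s) in \[0, 1\].
#' @export
signal_lte_watson_stick <- function(b, D_par, OD, angle = 0) {
  stopifnot(D_par >= 0)
  kappa <- watson_kappa(OD)
  vapply(b, function(bb) {
    if (bb == 0) return(1)
    watson_average(function(c2) exp(-bb * D_par * c2), kappa, angle)
  }, 1)
}

#' LTE signal of Watson-dispersed zeppelins
#'
#' As [signal_lte_watson_stick()] with kernel
#' `exp(-b D_perp - b (D_par - D_perp) (g.n)^2)`. With `D_par = D_perp` it
#' reduces to a ball, `exp(-b D)`, for any OD.
#'
#' @inheritParams signal_lte_watson_stick
#' @param D_perp Perpendicular diffusivity, um^2/ms.
#' @return Attenuation(s) in \[0, 1\].
#' @export
signal_lte_watson_zeppelin <- function(b, D_par, D_perp, OD, angle = 0) {
  stopifnot(D_par >= D_perp, D_perp >= 0)
  kappa <- watson_kappa(OD)
  vapply(b, function(bb) {
    if (bb == 0) return(1)
    exp(-bb * D_perp) *
      watson_average(function(c2) exp(-bb * (D_par - D_perp) * c2), kappa, angle)
  }, 1)
}

#' LTE signal of a compartment mixture
#'
#' Linear tensor encoding along a single axis at `angle` from the model's
#' mean orientation; Watson compartments are orientation-averaged by
#' quadrature, `stick` / `zeppelin` use their own axis, `dot` contributes
#' its fraction and `ball` its exponential.
#'
#' @inheritParams signal_ste_mixture
#' @param angle Angle between the encoding axis and each compartment's mean
#'   axis, rad.
#' @return Attenuation(s) in \[0, 1\].
#' @export
signal_lte_mixture <- function(b, model, angle = 0) {
  stopifnot(inherits(model, "tissue_model"))
  if (!is.null(model$exchange)) {
    abort("Use signal_karger() for a model with exchange.")
  }
  vapply(b, function(bb) {
    sum(vapply(model$compartments, function(cmp) {
      cmp$fraction * switch(cmp$kind,
        dot = 1,
        ball = exp(-bb * cmp$D_par),
        stick = exp(-bb * cmp$D_par * cos(angle)^2),
        zeppelin = exp(-bb * (cmp$D_perp +
          (cmp$D_par - cmp$D_perp) * cos(angle)^2)),
        watson_stick = signal_lte_watson_stick(bb, cmp$D_par, cmp$OD, angle),
        watson_zeppelin = signal_lte_watson_zeppelin(
          bb, cmp$D_par, cmp$D_perp, cmp$OD, angle),
        sphere = abort("LTE mixture does not support sphere compartments.")
      )
    }, 1))
  }, 1)
}

#' Two-pool Kärger exchange signal
#'
#' Narrow-pulse idealisation: magnetisation in two exchanging pools
#' dephases at rates `q^2 D_i = b D_i / Delta` while exchanging at
#' first-order rates `k12 = f2 / t_ex`, `k21 = f1 / t_ex`. The attenuation
#' is `1' expm(-(Q + K) Delta) f` with `Q = diag(b D_i / Delta)` and `K`
#' the exchange matrix, evaluated by eigendecomposition of the 2x2 system.
#' Limits: `t_ex -> Inf` gives the non-exchanging bi-exponential,
#' `t_ex -> 0` the mono-exponential at the mean diffusivity.
#'
#' @param b b-value(s), ms/um^2 (vectorised).
#' @param spec A [karger_spec()].
#' @return Attenuation(s) in \[0, 1\].
#' @examples
#' ks <- karger_spec(f1 = 0.02, D1 = 0, D2 = 1, t_ex = 500, diffusion_time = 30)
#' signal_karger(15, ks)
#' @export
signal_karger <- function(b, spec) {
  stopifnot(inherits(spec, "karger_spec"))
  Delta <- spec$diffusion_time
  k12 <- if (is.finite(spec$t_ex)) spec$f2 / spec$t_ex else 0
  k21 <- if (is.finite(spec$t_ex)) spec$f1 / spec$t_ex else 0
  f <- c(spec$f1, spec$f2)
  vapply(b, function(bb) {
    R <- matrix(c(bb * spec$D1 / Delta + k12, -k12,
                  -k21, bb * spec$D2 / Delta + k21), 2L, 2L)
    e <- eigen(R)
    m <- Re(e$vectors %*% diag(exp(-e$values * Delta)) %*% solve(e$vectors) %*% f)
    sum(m)
  }, 1)
}

#' Compartment mixture signal with T2 weighting
#'
#' Each compartment term is additionally weighted by `exp(-TE / T2_i)`;
#' compartments with `T2 = NULL` have no TE dependence. Fractions are
#' defined at TE = 0, so the apparent fraction of a pool at finite TE
#' differs from its `fraction` whenever T2s differ between pools.
#'
#' @inheritParams signal_ste_mixture
#' @param TE Echo time, ms.
#' @return Signal (not normalised by the TE-dependent b = 0 signal).
#' @export
signal_with_t2 <- function(model, b, TE, waveform = NULL) {
  stopifnot(inherits(model, "tissue_model"), TE >= 0)
  w_t2 <- vapply(model$compartments, function(cmp) {
    if (is.null(cmp$T2)) 1 else exp(-TE / cmp$T2)
  }, 1)
  vapply(b, function(bb) {
    terms <- vapply(model$compartments, function(cmp) {
      if (cmp$kind == "sphere") {
        if (is.null(waveform)) {
          abort("A sphere compartment needs a `waveform`.")
        }
        if (bb == 0) 1 else signal_sphere_waveform(
          scale_waveform(waveform, bb), cmp$radius, cmp$D_s)
      } else {
        exp(-bb * compartment_mean_d(cmp))
      }
    }, 1)
    sum(vapply(model$compartments, function(cmp) cmp$fraction, 1) *
          w_t2 * terms)
  }, 1)
}
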