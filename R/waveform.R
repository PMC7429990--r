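#' Gradient waveforms
#'
#' A sampled 3-axis diffusion-encoding gradient waveform for a spin-echo
#' sequence: a segment played before the refocusing pulse, a gap (the 180
#' pulse, gradient off) and a segment after it. The effective gradient seen
#' by the magnetisation has the post-pulse segment sign-inverted; a valid
#' diffusion waveform refocuses, i.e. the net dephasing vector
#' `q(TE) = gamma * integral(g_eff dt)` is zero.
#'
#' @param pre,post Numeric matrices (n x 3), gradient samples in mT/m,
#'   uniformly sampled at `dt`, as played out (lab frame).
#' @param dt Sample interval, ms.
#' @param gap Refocusing-pulse duration, ms (gradient off).
#' @return An object of class `gradient_waveform`.
#' @examples
#' w <- pgse_waveform(G = 300, delta = 10, Delta = 20)
#' btensor_from_waveform(w)
#' @export
gradient_waveform <- function(pre, post, dt, gap) {
  pre <- as_gradient_matrix(pre, "pre")
  post <- as_gradient_matrix(post, "post")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    abort("`dt` must be a single positive number (ms).")
  }
  if (!is.numeric(gap) || length(gap) != 1L || gap <= 0) {
    abort("`gap` must be a single positive number (ms).")
  }
  w <- structure(
    list(pre = pre, post = post, dt = dt, gap = gap),
    class = "gradient_waveform"
  )
  q <- dephasing_vector(w)
  qn <- sqrt(rowSums(q$q^2))
  if (max(qn) > 0 && qn[length(qn)] > 1e-6 * max(qn)) {
    abort(sprintf(
      "Waveform does not refocus: residual |q| = %.3g of peak %.3g rad/um.",
      qn[length(qn)], max(qn)
    ))
  }
  w
}

as_gradient_matrix <- function(g, what) {
  g <- as.matrix(g)
  if (ncol(g) == 1L) g <- cbind(g, 0, 0)
  if (ncol(g) != 3L || !is.numeric(g) || nrow(g) < 2L) {
    abort(sprintf("`%s` must be an n x 3 numeric matrix with n >= 2.", what))
  }
  unname(g)
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf(
    "<gradient_waveform> pre %.3g ms | gap %.3g ms | post %.3g ms, dt = %.4g ms, max |g| = %.3g mT/m\n",
    (nrow(x$pre) - 1L) * x$dt, x$gap, (nrow(x$post) - 1L) * x$dt, x$dt,
    max(abs(c(x$pre, x$post)))
  ))
  invisible(x)
}

# Uniform time grid of the effective gradient (post segment negated, zeros
# during the refocusing gap), and the dephasing vector q in rad/um
# accumulated by trapezoidal integration.
effective_gradient <- function(w) {
  n_gap <- max(1L, round(w$gap / w$dt))
  g <- rbind(w$pre, matrix(0, n_gap, 3L), -w$post)
  list(t = (seq_len(nrow(g)) - 1L) * w$dt, g = g, dt = w$dt)
}

dephasing_vector <- function(w) {
  eg <- effective_gradient(w)
  q <- apply(eg$g, 2L, pracma::cumtrapz, x = eg$t)
  list(t = eg$t, q = q * GAMMA_PROTON * 1e-6)
}

#' Compute the B-tensor of a gradient waveform
#'
#' `B = integral(q(t) q(t)' dt)` with `q(t)` the dephasing vector of the
#' effective gradient; trapezoidal quadrature on the waveform's own grid.
#' Converges to the Stejskal-Tanner closed form
#' `b = (gamma G delta)^2 (Delta - delta / 3)` for rectangular PGSE as
#' `dt -> 0`.
#'
#' @param w A [gradient_waveform()].
#' @return A [btensor()] in ms/um^2.
#' @export
btensor_from_waveform <- function(w) {
  stopifnot(inherits(w, "gradient_waveform"))
  qq <- dephasing_vector(w)
  m <- matrix(0, 3L, 3L)
  for (i in 1:3) {
    for (j in i:3) {
      m[i, j] <- m[j, i] <- pracma::trapz(qq$t, qq$q[, i] * qq$q[, j])
    }
  }
  btensor(m)
}

#' Idealised pulsed-gradient (Stejskal-Tanner) waveform
#'
#' Two rectangular lobes of amplitude `G` and duration `delta` whose onsets
#' are `Delta` apart, with the refocusing pulse centred between them.
#'
#' @param G Gradient amplitude, mT/m.
#' @param delta Pulse duration, ms.
#' @param Delta Pulse onset separation (diffusion time), ms.
#' @param dt Sample interval, ms.
#' @param gap Refocusing-pulse duration, ms; must fit between the lobes.
#' @param axis Unit 3-vector gradient direction.
#' @return A [gradient_waveform()].
#' @export
pgse_waveform <- function(G, delta, Delta, dt = 0.01,
                          gap = (Delta - delta) / 2, axis = c(0, 0, 1)) {
  stopifnot(G >= 0, delta > 0, Delta > delta, dt > 0)
  if (gap <= 0 || gap > Delta - delta) {
    abort("`gap` must be positive and fit between the two lobes.")
  }
  axis <- axis / sqrt(sum(axis^2))
  n_d <- max(2L, round(delta / dt))
  n_gap <- max(1L, round(gap / dt))
  n_Delta <- round(Delta / dt)
  tot_pad <- n_Delta - n_d - n_gap - 2L
  if (tot_pad < 0L) abort("`gap` must fit between the two lobes at this `dt`.")
  n_pad1 <- ceiling(tot_pad / 2)
  n_pad2 <- tot_pad - n_pad1
  # lobe onsets (mid-ramp) exactly n_Delta * dt apart on the effective grid;
  # both lobes positive in the lab frame, the constructor negates `post`.
  pre <- c(0, rep(G, n_d), rep(0, n_pad1 + 1L))
  post <- c(rep(0, n_pad2 + 1L), rep(G, n_d), 0)
  gradient_waveform(
    pre = outer(pre, axis), post = outer(post, axis),
    dt = dt, gap = gap
  )
}

#' Spherical tensor encoding waveform
#'
#' A smooth sweep of the dephasing vector on the magic-angle cone with a
#' squared-sine envelope, held constant during the refocusing gap and
#' linearly symmetrised so that the resulting B-tensor is exactly isotropic
#' with trace `b`. This is an idealised stand-in for numerically optimised
#' STE waveforms: it has the defining property (isotropic B, refocused q)
#' without claiming efficiency optimality.
#'
#' @param b Target b-value, ms/um^2.
#' @param dur_pre,dur_post Durations of the two encoding segments, ms.
#' @param gap Refocusing-pulse duration, ms.
#' @param dt Sample interval, ms.
#' @param n_turns Number of cone revolutions of q over the active time.
#' @return A [gradient_waveform()] whose [btensor_from_waveform()] has
#'   `b_delta` ~ 0 and trace `b`.
#' @export
ste_waveform <- function(b, dur_pre = 35.5, dur_post = 25.6, gap = 6.9,
                         dt = 0.02, n_turns = 3) {
  stopifnot(b > 0, dur_pre > 0, dur_post > 0, gap > 0, dt > 0)
  n1 <- round(dur_pre / dt)
  n2 <- round(dur_post / dt)
  n_gap <- max(1L, round(gap / dt))
  # active (gradient-on) time parameter; q frozen during the gap
  active <- c(rep(TRUE, n1), rep(FALSE, n_gap), rep(TRUE, n2))
  tau <- c(seq_len(n1) - 1L, rep(n1 - 1L, n_gap), n1 - 1L + seq_len(n2)) * dt
  t_act <- (n1 + n2 - 1L) * dt
  # q(tau) = s(tau) u(psi(tau)) on the magic-angle cone; gradient is the
  # analytic derivative dq/dtau (zero during the gap)
  s <- sin(pi * tau / t_act)^2
  ds <- 2 * sin(pi * tau / t_act) * cos(pi * tau / t_act) * pi / t_act
  psi <- 2 * pi * n_turns * tau / t_act
  dpsi <- 2 * pi * n_turns / t_act
  theta_m <- acos(1 / sqrt(3))
  st <- sin(theta_m)
  g <- cbind(
    ds * st * cos(psi) - s * st * sin(psi) * dpsi,
    ds * st * sin(psi) + s * st * cos(psi) * dpsi,
    ds * cos(theta_m)
  )
  g[!active, ] <- 0
  g <- g / (GAMMA_PROTON * 1e-6)
  # remove the O(dt^2) quadrature residual so q refocuses exactly on the
  # trapezoidal grid; the correction is spread over the active samples
  t_grid <- (seq_along(tau) - 1L) * dt
  wgt <- s * active
  wgt <- wgt / pracma::trapz(t_grid, wgt)
  q_end <- apply(g, 2L, function(col) pracma::trapz(t_grid, col))
  g <- g - outer(wgt, q_end)
  # symmetrise: g -> L g makes B exactly (b/3) I
  B <- btensor_from_unit_geff(g, dt)
  e <- eigen(B, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(b / 3 / e$values)) %*% t(e$vectors)
  g <- g %*% t(L)
  idx_pre <- seq_len(n1)
  idx_post <- n1 + n_gap + seq_len(n2)
  gradient_waveform(
    pre = g[idx_pre, , drop = FALSE],
    post = -g[idx_post, , drop = FALSE],
    dt = dt, gap = gap
  )
}

btensor_from_unit_geff <- function(g, dt) {
  t <- (seq_len(nrow(g)) - 1L) * dt
  q <- apply(g, 2L, pracma::cumtrapz, x = t) * GAMMA_PROTON * 1e-6
  m <- matrix(0, 3L, 3L)
  for (i in 1:3) {
    for (j in i:3) m[i, j] <- m[j, i] <- pracma::trapz(t, q[, i] * q[, j])
  }
  m
}

#' Rescale a waveform to a target b-value
#'
#' Gradient amplitudes scale by `sqrt(b_target / b)` (b is quadratic in
#' amplitude), which is how a scanner plays one optimised waveform shape
#' across shells.
#'
#' @param w A [gradient_waveform()].
#' @param b_target Target b-value, ms/um^2.
#' @return A [gradient_waveform()].
#' @export
scale_waveform <- function(w, b_target) {
  stopifnot(inherits(w, "gradient_waveform"), b_target >= 0)
  b0 <- btensor_from_waveform(w)$b
  if (b0 <= 0) abort("Cannot scale a zero-amplitude waveform.")
  s <- sqrt(b_target / b0)
  gradient_waveform(w$pre * s, w$post * s, dt = w$dt, gap = w$gap)
}

#' Read / write a gradient waveform file
#'
#' Plain-text format: header lines `#dt_ms=` and `#gap_ms=`, then rows
#' `gx gy gz` in mT/m; the pre- and post-pulse segments are separated by a
#' blank line.
#'
#' @param path File path.
#' @param w A [gradient_waveform()].
#' @return `read_waveform()` returns a [gradient_waveform()];
#'   `write_waveform()` returns `path` invisibly.
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  dt <- header_value(hdr, "dt_ms")
  gap <- header_value(hdr, "gap_ms")
  body <- lines[!grepl("^#", lines)]
  blank <- which(!nzchar(trimws(body)))
  if (length(blank) == 0L) {
    abort("Waveform file must separate pre/post segments with a blank line.")
  }
  split_at <- blank[1L]
  parse_seg <- function(seg_lines, offset) {
    seg_lines <- seg_lines[nzchar(trimws(seg_lines))]
    vals <- lapply(seq_along(seg_lines), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(seg_lines[i]), "\\s+")[[1L]]))
      if (length(v) != 3L || anyNA(v)) {
        abort(sprintf("Malformed waveform row at line %d.", offset + i))
      }
      v
    })
    do.call(rbind, vals)
  }
  gradient_waveform(
    pre = parse_seg(body[seq_len(split_at - 1L)], 0L),
    post = parse_seg(body[-seq_len(split_at)], split_at),
    dt = dt, gap = gap
  )
}

header_value <- function(hdr, key) {
  ln <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
  if (length(ln) != 1L) abort(sprintf("Waveform file needs one '#%s=' header.", key))
  as.numeric(sub(paste0("^#\\s*", key, "\\s*="), "", ln))
}

#' @rdname read_waveform
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "gradient_waveform"))
  fmt <- function(m) apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(
    sprintf("#dt_ms=%.17g", w$dt),
    sprintf("#gap_ms=%.17g", w$gap),
    fmt(w$pre),
    "",
    fmt(w$post)
  ), path)
  invisible(path)
}
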