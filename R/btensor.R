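#' B-tensors
#'
#' A `btensor` is a 3x3 symmetric positive semi-definite diffusion-encoding
#' tensor (units ms/um^2) together with its two rotation invariants: the
#' b-value `b = Tr(B)` and the normalised anisotropy `b_delta` in
#' \[-0.5, 1\]. Spherical tensor encoding (STE) has `b_delta = 0`, linear
#' tensor encoding (LTE) `b_delta = 1`.
#'
#' @param matrix 3x3 symmetric PSD matrix, ms/um^2.
#' @return An object of class `btensor`: a list with `matrix`, `b`,
#'   `b_delta`.
#' @seealso [make_axisymmetric_btensor()], [btensor_from_waveform()],
#'   [effective_btensor()]
#' @export
btensor <- function(matrix) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(3L, 3L)) || !is.numeric(m)) {
    abort("`matrix` must be a numeric 3x3 matrix.")
  }
  if (max(abs(m - t(m))) > 1e-9 * max(1, max(abs(m)))) {
    abort("`matrix` must be symmetric.")
  }
  m <- (m + t(m)) / 2
  b <- sum(diag(m))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(b, 1e-12)) {
    abort("`matrix` must be positive semi-definite.")
  }
  structure(
    list(matrix = m, b = b, b_delta = btensor_anisotropy(ev)),
    class = "btensor"
  )
}

# Normalised anisotropy from eigenvalues; for an axially symmetric tensor
# this equals (b_par - b_perp) / (b_par + 2 b_perp).  General tensors are
# summarised by the same invariant of the axially symmetric part, i.e. the
# largest-deviation eigenvalue convention used for encoding tensors.
btensor_anisotropy <- function(ev) {
  b <- sum(ev)
  if (b <= 0) return(0)
  iso <- b / 3
  dev <- ev - iso
  # eigenvalue furthest from the isotropic value defines the symmetry axis
  k <- which.max(abs(dev))
  b_par <- ev[k]
  b_perp <- (b - b_par) / 2
  (b_par - b_perp) / b
}

#' @export
print.btensor <- function(x, ...) {
  cat(sprintf(
    "<btensor> b = %.6g ms/um^2 (%.6g s/mm^2), b_delta = %.4g\n",
    x$b, b_internal_to_si(x$b), x$b_delta
  ))
  print(x$matrix)
  invisible(x)
}

#' Construct an axially symmetric B-tensor
#'
#' Eigenvalues are `b_par = b (1 + 2 b_delta) / 3` along `axis` and
#' `b_perp = b (1 - b_delta) / 3` (twice) perpendicular to it, so the trace
#' is `b` and the anisotropy invariant is `b_delta`.
#'
#' @param b b-value (trace), ms/um^2, non-negative.
#' @param b_delta Anisotropy in \[-0.5, 1\]: 0 gives STE (isotropic), 1 LTE
#'   (rank-1), -0.5 planar encoding.
#' @param axis Unit 3-vector, symmetry axis; ignored when `b_delta = 0`.
#' @return A [btensor()].
#' @examples
#' make_axisymmetric_btensor(15, 0)               # STE, 5 * I
#' make_axisymmetric_btensor(1, 1, c(0, 0, 1))    # LTE along z
#' @export
make_axisymmetric_btensor <- function(b, b_delta, axis = c(0, 0, 1)) {
  stopifnot(is.numeric(b), length(b) == 1L, is.numeric(b_delta),
            length(b_delta) == 1L)
  if (b < 0) abort("`b` must be non-negative.")
  if (b_delta < -0.5 || b_delta > 1) {
    abort("`b_delta` must lie in [-0.5, 1] (outside this the tensor is not PSD).")
  }
  if (b_delta != 0) {
    nrm <- sqrt(sum(axis^2))
    if (abs(nrm - 1) > 1e-6) {
      abort(sprintf("`axis` must be a unit vector (|axis| = %.8g).", nrm))
    }
    axis <- axis / nrm
  } else {
    axis <- c(0, 0, 1)
  }
  b_par <- b * (1 + 2 * b_delta) / 3
  b_perp <- b * (1 - b_delta) / 3
  m <- b_perp * diag(3) + (b_par - b_perp) * tcrossprod(axis)
  out <- btensor(m)
  # exact invariants for the canonical constructions
  out$b <- b
  out$b_delta <- b_delta
  out
}

#' Voxel-wise effective B-tensor under gradient nonlinearity
#'
#' Gradient-coil nonlinearity makes the played-out gradient `L g(t)` rather
#' than `g(t)`, where `L` is the local (voxel-wise) coil tensor. The
#' dephasing vector is transformed the same way, so the effective encoding
#' tensor is `L B L'`. With `L = I` the tensor is returned unchanged.
#'
#' @param B A [btensor()].
#' @param L 3x3 real coil tensor (identity means no nonlinearity).
#' @return A [btensor()].
#' @examples
#' B <- make_axisymmetric_btensor(1, 0)
#' effective_btensor(B, diag(c(1.05, 1, 0.95)))
#' @export
effective_btensor <- function(B, L) {
  stopifnot(inherits(B, "btensor"))
  L <- as.matrix(L)
  if (!all(dim(L) == c(3L, 3L))) abort("`L` must be a 3x3 matrix.")
  btensor(L %*% B$matrix %*% t(L))
}
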