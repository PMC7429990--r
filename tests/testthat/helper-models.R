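# shared fixtures, built in code

# the two-pool model with the cerebellar-GM slow-pool medians (no T2)
two_pool_cgm <- function() {
  tissue_model(
    compartment("ball", 0.097, D_par = 0.12),
    compartment("ball", 0.903, D_par = 1.0)
  )
}

# single-voxel signal vector aligned to a protocol, noiseless
noiseless_signals <- function(model, protocol) {
  vapply(seq_len(nrow(protocol)), function(i) {
    signal_with_t2(model, protocol$b[i], protocol$te[i])
  }, 1)
}

# draw n unit vectors from a Watson distribution about +z (rejection
# sampling on cos(theta)); independent oracle for the quadrature
rwatson_z <- function(n, kappa) {
  u <- numeric(0)
  while (length(u) < n) {
    cand <- runif(2 * n, -1, 1)
    keep <- runif(2 * n) < exp(kappa * (cand^2 - 1))
    u <- c(u, cand[keep])
  }
  u <- u[seq_len(n)]
  phi <- runif(n, 0, 2 * pi)
  su <- sqrt(pmax(0, 1 - u^2))
  cbind(su * cos(phi), su * sin(phi), u)
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}
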