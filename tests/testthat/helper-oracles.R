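# Independent oracles used against the package's engines. Everything here is
# deliberately naive: direct quadrature and closed forms, no recursions.

HARTREE_CM1 <- 219474.6313632
KB_CM1 <- 0.695034800

# Gauss-Hermite nodes/weights (weight exp(-x^2)) via Golub-Welsch.
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  Jm <- matrix(0, n, n)
  Jm[cbind(seq_len(n - 1), 2:n)] <- off
  Jm[cbind(2:n, seq_len(n - 1))] <- off
  es <- eigen(Jm, symmetric = TRUE)
  list(nodes = es$values, weights = sqrt(pi) * es$vectors[1, ]^2)
}

# Harmonic-oscillator eigenfunction, mass-weighted a.u. (hbar = m = 1):
# psi_v(x) = (w/pi)^(1/4) / sqrt(2^v v!) H_v(sqrt(w) x) exp(-w x^2 / 2)
ho_psi <- function(v, w, x) {
  z <- sqrt(w) * x
  h0 <- rep(1, length(z)); h1 <- 2 * z
  H <- if (v == 0) h0 else if (v == 1) h1 else {
    for (k in 2:v) { h2 <- 2 * z * h1 - 2 * (k - 1) * h0; h0 <- h1; h1 <- h2 }
    h1
  }
  (w / pi)^0.25 / sqrt(2^v * factorial(v)) * H * exp(-w * x^2 / 2)
}

# Brute-force FC overlap by tensor-product Gauss-Hermite quadrature of the
# explicit wavefunction product, independent of the recursion engine.
fc_overlap_quadrature <- function(map, v, vp, nq = 48) {
  n <- map$nmodes
  w <- map$freqs_initial / HARTREE_CM1
  wp <- map$freqs_final / HARTREE_CM1
  J <- map$J; K <- map$K
  U <- t(J) %*% (wp * J)
  C0 <- diag(w, n) + U
  es <- eigen(C0, symmetric = TRUE)
  Tm <- sqrt(2) * es$vectors %*% diag(1 / sqrt(es$values), n) %*% t(es$vectors)
  mu <- solve(C0, U %*% K)
  gh <- gauss_hermite(nq)
  grids <- as.matrix(expand.grid(rep(list(seq_len(nq)), n)))
  Y <- matrix(gh$nodes[grids], ncol = n)
  Wt <- matrix(gh$weights[grids], ncol = n)
  logw <- rowSums(log(Wt)) + rowSums(Y^2)
  Q <- sweep(Y %*% t(Tm), 2, as.numeric(mu), "+")
  Qp <- sweep(Q, 2, K) %*% t(J)
  f <- rep(1, nrow(Q))
  for (i in seq_len(n)) f <- f * ho_psi(v[i], w[i], Q[, i])
  for (k in seq_len(n)) f <- f * ho_psi(vp[k], wp[k], Qp[, k])
  sum(exp(logw) * f) * abs(det(Tm))
}

poisson_fc <- function(S, nvals) exp(-S) * S^nvals / factorial(nvals)
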