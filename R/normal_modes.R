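# Normal-mode analysis: mass-weighting, Eckart translation/rotation
# projection, diagonalization, and gradient projection onto normal modes.

# Orthonormal translation/rotation vectors in mass-weighted Cartesian space,
# built at the centre of mass of the reference geometry. Returns the 3N x k
# basis (k = 6, or 5 for linear molecules) and the linearity flag.
# Linearity: smallest principal moment of inertia < 1e-10 amu*Angstrom^2.
tr_vectors <- function(geometry_ang, masses_amu) {
  n <- nrow(geometry_ang)
  m <- masses_amu
  com <- colSums(geometry_ang * m) / sum(m)
  r <- sweep(geometry_ang, 2, com)
  # principal moments in amu*Angstrom^2
  inertia <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    ri <- r[i, ]
    inertia <- inertia + m[i] * (sum(ri^2) * diag(3) - tcrossprod(ri))
  }
  mom <- eigen(inertia, symmetric = TRUE)$values
  linear <- min(mom) < 1e-10
  sm <- sqrt(m)
  trans <- matrix(0, 3 * n, 3)
  for (a in 1:3) trans[seq(a, 3 * n, by = 3), a] <- sm
  rot <- matrix(0, 3 * n, 3)
  for (a in 1:3) {
    e <- numeric(3); e[a] <- 1
    cr <- t(apply(r, 1, function(ri) c(ri[2] * e[3] - ri[3] * e[2],
                                       ri[3] * e[1] - ri[1] * e[3],
                                       ri[1] * e[2] - ri[2] * e[1])))
    rot[, a] <- as.vector(t(cr * sm))
  }
  basis <- cbind(trans, rot)
  # orthonormalize; drop the null rotation for linear molecules (and for
  # single atoms all rotations)
  qrd <- qr(basis)
  k <- qrd$rank
  qr.Q(qrd)[, seq_len(k), drop = FALSE] -> out
  list(basis = out, linear = linear, k = k)
}

# Fix mode-vector phases: largest-|component| entry made positive
# (ties broken by the first such index). Applied to columns.
fix_phases <- function(modes) {
  for (j in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  modes
}

#' Normal-mode analysis of a state bundle
#'
#' Builds the mass-weighted Hessian, projects out the six (five if linear)
#' translation/rotation directions with an explicit Eckart-frame projector,
#' diagonalizes, and converts eigenvalues to wavenumbers. Imaginary
#' frequencies are encoded as negative cm^-1 and never dropped.
#'
#' @param bundle an [electronic_state_bundle()] carrying a Hessian.
#' @return object of class `NormalModeBasis`: `frequencies` (cm^-1,
#'   ascending), `modes` (3N x Nvib mass-weighted orthonormal columns),
#'   `reference_geometry` (Angstrom), `masses` (amu), `nvib`, `linear`.
#' @export
normal_modes <- function(bundle) {
  stopifnot(inherits(bundle, "ElectronicStateBundle"))
  if (is.null(bundle$hessian)) stop("bundle has no hessian")
  if (sum(bundle$masses) < 1e-10) stop("near-zero total mass")
  n <- bundle$natoms
  m_me <- amu_to_me(bundle$masses)
  sm <- rep(sqrt(m_me), each = 3)
  hmw <- bundle$hessian / tcrossprod(sm)
  tr <- tr_vectors(bundle$geometry, bundle$masses)
  nvib <- 3 * n - tr$k
  # orthonormal complement of the TR space
  qfull <- qr.Q(qr(tr$basis), complete = TRUE)
  B <- qfull[, (tr$k + 1):(3 * n), drop = FALSE]
  hred <- crossprod(B, hmw %*% B)
  hred <- (hred + t(hred)) / 2
  es <- eigen(hred, symmetric = TRUE)
  ord <- order(es$values)
  lam <- es$values[ord]
  vec <- es$vectors[, ord, drop = FALSE]
  freqs <- au_to_cm1(sign(lam) * sqrt(abs(lam)))
  # sort by signed frequency (negative = imaginary first)
  ord2 <- order(freqs)
  freqs <- freqs[ord2]
  modes <- fix_phases(B %*% vec[, ord2, drop = FALSE])
  structure(list(frequencies = freqs, modes = modes,
                 reference_geometry = bundle$geometry,
                 masses = bundle$masses, nvib = nvib, linear = tr$linear),
            class = "NormalModeBasis")
}

#' @export
print.NormalModeBasis <- function(x, ...) {
  cat("NormalModeBasis:", x$nvib, "modes,",
      sprintf("%.1f..%.1f cm^-1", min(x$frequencies), max(x$frequencies)),
      if (x$linear) "(linear)" else "", "\n")
  invisible(x)
}

#' Project a Cartesian gradient onto normal modes
#'
#' Computes `g_Q = t(L) %*% M^(-1/2) %*% g_cart` in atomic units
#' (mass-weighted normal coordinates). The translation/rotation content of
#' the gradient is removed implicitly because the mode vectors span only the
#' vibrational space.
#'
#' @param bundle bundle carrying a Cartesian gradient (hartree/bohr).
#' @param basis a [normal_modes()] basis from a compatible geometry.
#' @return numeric vector of per-mode gradients, a.u., length Nvib.
#' @export
project_gradient <- function(bundle, basis) {
  stopifnot(inherits(basis, "NormalModeBasis"))
  if (!length(bundle$gradient)) stop("bundle has no gradient")
  if (length(bundle$gradient) != nrow(basis$modes)) {
    stop("gradient dimension does not match the mode basis")
  }
  sm <- rep(sqrt(amu_to_me(basis$masses)), each = 3)
  as.numeric(crossprod(basis$modes, bundle$gradient / sm))
}
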