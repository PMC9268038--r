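# Analytic model chromophores: displaced/rotated harmonic surface pairs and
# a cyanine-like 6-mode model, so every engine is testable without any
# electronic-structure run.

#' Displaced harmonic oscillators (J = I)
#'
#' Canonical oracle system: per-mode displacements set from Huang-Rhys
#' factors, `K_i = sqrt(2 S_i / w_i)` (a.u.), no Duschinsky mixing, so the
#' 0 K intensity of mode i follows the Poisson progression
#' `exp(-S_i) S_i^n / n!`.
#'
#' @param freqs mode wavenumbers, cm^-1 (used for both states unless
#'   `freqs_final` is given).
#' @param S Huang-Rhys factors (>= 0), or give `K` directly (a.u.).
#' @param K displacements in mass-weighted a.u. (alternative to `S`).
#' @param E00 adiabatic electronic gap, cm^-1 (without ZPE).
#' @param freqs_final optional distinct final-state wavenumbers.
#' @param transition_dipole 3-vector, a.u.
#' @return a `DuschinskyMap`.
#' @export
make_displaced_oscillators <- function(freqs, S = NULL, K = NULL,
                                       E00 = 18200, freqs_final = freqs,
                                       transition_dipole = c(1, 0, 0)) {
  n <- length(freqs)
  if (is.null(K)) {
    if (is.null(S)) stop("provide S or K")
    if (any(S < 0)) stop("Huang-Rhys factors must be >= 0")
    K <- sqrt(2 * S / cm1_to_au(freqs_final))
  }
  new_duschinsky_map("AS", diag(n), K, freqs, freqs_final, E00,
                     transition_dipole)
}

# Givens rotation product over mode pairs (i, i+1) with the given angles.
rotation_matrix <- function(n, angles_deg) {
  R <- diag(n)
  k <- 1
  for (i in seq_len(n - 1)) {
    if (k > length(angles_deg)) break
    th <- angles_deg[k] * pi / 180
    G <- diag(n)
    G[i, i] <- cos(th); G[i + 1, i + 1] <- cos(th)
    G[i, i + 1] <- sin(th); G[i + 1, i] <- -sin(th)
    R <- G %*% R
    k <- k + 1
  }
  R
}

#' Duschinsky-rotated model pair
#'
#' Builds a map whose final modes are the initial modes rotated by the given
#' angles (Givens rotations over successive mode pairs), together with the
#' generating bundle pair: two synthetic Cartesian state bundles whose
#' [build_map()] `"AH"` reconstruction reproduces the emitted (J, K) within
#' 1e-9. The final minimum is displaced along the breathing direction
#' (uniform scaling about the centre of mass), the one family of
#' displacements that leaves the translation/rotation subspace untouched so
#' the synthetic pair is free of Eckart-frame contamination and J stays
#' exactly orthogonal. Exercises adiabatic-vs-shift distinctions.
#'
#' @param freqs_initial,freqs_final mode wavenumbers, cm^-1 (>= 2 modes,
#'   ascending).
#' @param angles_deg rotation angles in (-90, 90), one per successive mode
#'   pair.
#' @param displacement norm of the displacement K of the final minimum,
#'   mass-weighted a.u. (0 for an undisplaced pair).
#' @param E00 adiabatic electronic gap, cm^-1.
#' @param natoms number of atoms of the synthetic bundles (needs
#'   `3 * natoms - 6 >= length(freqs_initial)`).
#' @param seed seed for the synthetic Cartesian embedding.
#' @param transition_dipole 3-vector, a.u.
#' @return list: `map`, `initial`, `final` (bundles).
#' @export
make_duschinsky_rotated <- function(freqs_initial, freqs_final = freqs_initial,
                                    angles_deg, displacement = 10, E00 = 18200,
                                    natoms = NULL, seed = 1,
                                    transition_dipole = c(1, 0, 0)) {
  n <- length(freqs_initial)
  if (n < 2) stop("need at least 2 modes")
  if (is.unsorted(freqs_initial) || is.unsorted(freqs_final)) {
    stop("frequencies must be ascending (mode ordering convention)")
  }
  if (any(abs(angles_deg) >= 90)) stop("angles must lie in (-90, 90)")
  if (is.null(natoms)) natoms <- ceiling((n + 6) / 3)
  scaffold <- random_cartesian_scaffold(natoms, seed)
  # center at the COM so that scaling preserves it
  com <- colSums(scaffold$geometry * scaffold$masses) / sum(scaffold$masses)
  scaffold$geometry <- sweep(scaffold$geometry, 2, com)
  tr <- tr_vectors(scaffold$geometry, scaffold$masses)
  qfull <- qr.Q(qr(tr$basis), complete = TRUE)
  scaffold$B <- qfull[, (tr$k + 1):(3 * natoms), drop = FALSE]
  nvib <- ncol(scaffold$B)
  if (nvib < n) stop("natoms too small for the requested mode count")
  if (nvib > n) {
    # park surplus modes far above the active ones so they stay spectators
    pad <- max(freqs_initial, freqs_final) * 2 + 1000 * seq_len(nvib - n)
    freqs_initial <- c(freqs_initial, pad)
    freqs_final <- c(freqs_final, pad)
  }
  R <- diag(nvib)
  R[seq_len(n), seq_len(n)] <- rotation_matrix(n, angles_deg)
  w_i <- cm1_to_au(freqs_initial)
  w_f <- cm1_to_au(freqs_final)
  Li <- fix_phases(scaffold$B)
  Lf <- fix_phases(Li %*% t(R))
  J <- crossprod(Lf, Li)                 # equals R up to phase fixing
  sm <- scaffold$sm
  # breathing displacement: x_f = (1 + c) x_i, purely vibrational for a
  # COM-centered geometry
  r_mw <- sm * angstrom_to_bohr(as.vector(t(scaffold$geometry)))
  Kdir <- as.numeric(crossprod(Li, r_mw))
  cfac <- if (displacement > 0) displacement / sqrt(sum(Kdir^2)) else 0
  K <- cfac * Kdir
  hess_i <- tcrossprod(sm) * (Li %*% (w_i^2 * t(Li)))
  hess_f <- tcrossprod(sm) * (Lf %*% (w_f^2 * t(Lf)))
  geom_f <- (1 + cfac) * scaffold$geometry
  E00_h <- convert_energy(E00, "cm-1", "hartree")
  initial <- electronic_state_bundle(
    "model-initial", scaffold$elements, scaffold$geometry, scaffold$masses,
    energy = -100, hessian = (hess_i + t(hess_i)) / 2)
  final <- electronic_state_bundle(
    "model-final", scaffold$elements, geom_f, scaffold$masses,
    energy = -100 + E00_h, hessian = (hess_f + t(hess_f)) / 2,
    transition_dipole = transition_dipole)
  map <- new_duschinsky_map("AH", J, K, freqs_initial, freqs_final, E00,
                            transition_dipole)
  list(map = map, initial = initial, final = final)
}

#' Cyanine-like six-mode model
#'
#' A model chromophore with the six excited-state wavenumbers typical of a
#' trimethine cyanine: a global backbone-bending mode at 34.9 cm^-1, a
#' dimethyl-twisting mode at 354 cm^-1, and a cluster of polymethine C-C
#' stretching modes at 1136, 1378, 1415 and 1525 cm^-1. The default
#' Huang-Rhys profile is illustrative (displacements of the real dye are not
#' established data): the ~1300 cm^-1 cluster carries a combined S of 0.6,
#' matching the effective one-mode strength implied by the dye family's
#' 0-1/0-0 band ratio, and the low-frequency bending mode carries the
#' largest single S. Ground-state frequencies default to the excited-state
#' values.
#'
#' @param S six Huang-Rhys factors.
#' @param E00 adiabatic electronic gap, cm^-1.
#' @param freqs_initial optional distinct ground-state wavenumbers.
#' @param transition_dipole 3-vector, a.u.
#' @return a `DuschinskyMap` (J = I).
#' @export
make_cy3_like <- function(S = c(0.7, 0.05, 0.15, 0.15, 0.15, 0.15),
                          E00 = 18200, freqs_initial = NULL,
                          transition_dipole = c(1, 0, 0)) {
  freqs_final <- c(34.9, 354, 1136, 1378, 1415, 1525)
  if (length(S) != 6) stop("need 6 Huang-Rhys factors")
  if (is.null(freqs_initial)) freqs_initial <- freqs_final
  make_displaced_oscillators(freqs_initial, S = S, E00 = E00,
                             freqs_final = freqs_final,
                             transition_dipole = transition_dipole)
}

# Random geometry/masses plus the orthonormal vibrational complement of the
# translation/rotation space; shared by the synthetic-bundle generators.
random_cartesian_scaffold <- function(natoms, seed) {
  set.seed(as.integer(seed))
  geometry <- matrix(stats::runif(natoms * 3, -2, 2), natoms, 3)
  masses <- stats::runif(natoms, 1, 30)
  elements <- rep("X", natoms)
  tr <- tr_vectors(geometry, masses)
  qfull <- qr.Q(qr(tr$basis), complete = TRUE)
  B <- qfull[, (tr$k + 1):(3 * natoms), drop = FALSE]
  sm <- rep(sqrt(amu_to_me(masses)), each = 3)
  list(geometry = geometry, masses = masses, elements = elements,
       B = B, sm = sm, k = tr$k)
}

#' Random positive-definite state bundle
#'
#' Property-test input for the normal-mode machinery: a random geometry and
#' masses with a random positive-definite mass-weighted Hessian lifted to
#' Cartesian coordinates with an exact translation/rotation null space, so
#' [normal_modes()] returns exactly `3 * natoms - 6` positive frequencies.
#'
#' @param natoms number of atoms (>= 2).
#' @param seed integer seed (bit-reproducible output).
#' @return an [electronic_state_bundle()] with a Hessian.
#' @export
make_random_bundle <- function(natoms, seed = 1) {
  if (natoms < 2) stop("natoms must be >= 2")
  scaffold <- random_cartesian_scaffold(natoms, seed)
  nvib <- ncol(scaffold$B)
  A <- matrix(stats::rnorm(nvib^2), nvib)
  spd <- crossprod(A) / nvib + diag(nvib) * 0.1
  # scale to chemically plausible frequencies (hundreds to thousands cm^-1)
  spd <- spd * cm1_to_au(1000)^2
  hmw <- scaffold$B %*% spd %*% t(scaffold$B)
  hess <- tcrossprod(scaffold$sm) * hmw
  electronic_state_bundle("random-model", scaffold$elements,
                          scaffold$geometry, scaffold$masses, energy = -50,
                          hessian = (hess + t(hess)) / 2)
}
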