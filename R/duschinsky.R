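# Harmonic final-state surfaces as Duschinsky maps.
#
# Convention used throughout the package: the final-state normal coordinates
# are Q' = J (Q - K), where Q are the initial-state mass-weighted normal
# coordinates (a.u.), J is the Duschinsky rotation and K is the position of
# the final-state minimum expressed in the initial-state normal coordinates.
# With this convention the vertical-gradient displacement is K = -g_Q/omega^2
# and Franck-Condon intensities are invariant under the (phase) sign choices
# of the mode vectors.

new_duschinsky_map <- function(model, J, K, freqs_initial, freqs_final,
                               E00, transition_dipole = c(1, 0, 0)) {
  n <- length(freqs_initial)
  stopifnot(length(freqs_final) == n, length(K) == n,
            all(dim(J) == c(n, n)))
  wF <- cm1_to_au(freqs_final)
  lam <- 0.5 * sum(wF^2 * as.numeric(J %*% K)^2)  # reorganization, a.u.
  Evert <- E00 + au_to_cm1(lam)
  structure(list(
    model = model, J = J, K = as.numeric(K),
    freqs_initial = as.numeric(freqs_initial),
    freqs_final = as.numeric(freqs_final),
    E00 = E00, Evert = Evert,
    E00_zpe = E00 + 0.5 * (sum(freqs_final) - sum(freqs_initial)),
    transition_dipole = transition_dipole, nmodes = n
  ), class = "DuschinskyMap")
}

#' @export
print.DuschinskyMap <- function(x, ...) {
  cat(sprintf("DuschinskyMap [%s]: %d modes, E00 = %.1f cm^-1, Evert = %.1f cm^-1\n",
              x$model, x$nmodes, x$E00, x$Evert))
  mix <- max(abs(x$J - diag(x$nmodes)))
  cat(sprintf("  max |J - I| = %.3g, |K| = %.4g a.u.\n", mix,
              sqrt(sum(x$K^2))))
  invisible(x)
}

map_is_diagonal <- function(map, tol = 1e-12) {
  max(abs(map$J - diag(map$nmodes))) < tol
}

mu2 <- function(map) {
  if (is.null(map$transition_dipole)) 1 else sum(map$transition_dipole^2)
}

#' Build a Duschinsky map under the AH, AS, VH or VG harmonic model
#'
#' Constructs the final-state harmonic surface relative to the initial state:
#' \describe{
#'   \item{AH (adiabatic Hessian)}{final-state minimum geometry and Hessian;
#'     J from the two mode bases, K from the geometry difference.}
#'   \item{AS (adiabatic shift)}{final-state minimum geometry only; J = I and
#'     the final frequencies are copied from the initial state.}
#'   \item{VH (vertical Hessian)}{final-state Hessian and gradient evaluated
#'     at the initial minimum; the effective minimum is extrapolated from the
#'     gradient. Imaginary extrapolated frequencies are a hard error unless
#'     `drop_imaginary = TRUE` (approximate mode removal, see Details).}
#'   \item{VG (vertical gradient)}{final-state gradient at the initial
#'     minimum; J = I, K = -g_Q/omega^2, frequencies copied.}
#' }
#' For AH/AS the final bundle's `energy` is the final-state minimum energy,
#' so `E00` comes from the energy difference; for VH/VG the final bundle is
#' evaluated at the initial geometry, so its energy is the vertical energy
#' and `E00` is back-extrapolated. Both geometries are assumed to be
#' expressed in the same Cartesian frame (no axis switching correction).
#'
#' @param initial bundle of the initial state (must carry a Hessian).
#' @param final bundle of the final state; required fields depend on `model`.
#' @param model `"AH"`, `"AS"`, `"VH"` or `"VG"`.
#' @param drop_imaginary VH only: drop imaginary extrapolated modes (and the
#'   maximally overlapping initial modes) instead of erroring.
#' @return a `DuschinskyMap`.
#' @export
build_map <- function(initial, final, model = c("AH", "AS", "VH", "VG"),
                      drop_imaginary = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(initial, "ElectronicStateBundle"),
            inherits(final, "ElectronicStateBundle"))
  basis_i <- normal_modes(initial)
  if (any(basis_i$frequencies <= 0)) {
    stop("initial state has non-positive frequencies")
  }
  n <- basis_i$nvib
  sm <- rep(sqrt(amu_to_me(initial$masses)), each = 3)
  w_i <- cm1_to_au(basis_i$frequencies)
  tdip <- final$transition_dipole
  if (is.null(tdip) && !is.null(final$oscillator_strength)) {
    # magnitude only; direction is irrelevant under the Condon approximation
    tdip <- c(1, 0, 0)  # placeholder replaced below once Evert is known
  }

  if (model %in% c("AH", "AS")) {
    dx <- angstrom_to_bohr(as.vector(t(final$geometry - initial$geometry)))
    K <- as.numeric(crossprod(basis_i$modes, sm * dx))
    E00 <- convert_energy(final$energy - initial$energy, "hartree", "cm-1")
    if (model == "AH") {
      if (is.null(final$hessian)) stop("AH requires the final-state hessian")
      basis_f <- normal_modes(final)
      if (basis_f$nvib != n) stop("nvib mismatch between states")
      if (any(basis_f$frequencies <= 0)) {
        stop("final state has imaginary frequencies at its minimum")
      }
      J <- crossprod(basis_f$modes, basis_i$modes)
      map <- new_duschinsky_map("AH", J, K, basis_i$frequencies,
                                basis_f$frequencies, E00)
    } else {
      map <- new_duschinsky_map("AS", diag(n), K, basis_i$frequencies,
                                basis_i$frequencies, E00)
    }
  } else {
    if (!length(final$gradient)) stop(model, " requires the final-state gradient")
    if (max(abs(final$geometry - initial$geometry)) > 1e-8) {
      stop(model, " requires the final state evaluated at the initial geometry")
    }
    gQ <- project_gradient(final, basis_i)
    Evert <- convert_energy(final$energy - initial$energy, "hartree", "cm-1")
    if (model == "VG") {
      K <- -gQ / w_i^2
      E00 <- Evert - au_to_cm1(0.5 * sum(w_i^2 * K^2))
      map <- new_duschinsky_map("VG", diag(n), K, basis_i$frequencies,
                                basis_i$frequencies, E00)
    } else {
      if (is.null(final$hessian)) stop("VH requires the final-state hessian")
      hQ <- crossprod(basis_i$modes,
                      (final$hessian / tcrossprod(sm)) %*% basis_i$modes)
      hQ <- (hQ + t(hQ)) / 2
      es <- eigen(hQ, symmetric = TRUE)
      ord <- order(es$values)
      lam <- es$values[ord]
      W <- es$vectors[, ord, drop = FALSE]
      if (any(lam <= 0)) {
        if (!drop_imaginary) {
          stop("VH extrapolation yields imaginary final frequencies; ",
               "use drop_imaginary = TRUE to remove those modes")
        }
        keep <- which(lam > 0)
        message("VH: dropping ", n - length(keep),
                " imaginary extrapolated mode(s)")
        Wk <- W[, keep, drop = FALSE]
        # pair each dropped final mode with its dominant initial mode and
        # remove that initial column too, then re-orthogonalize (approximate)
        drop_init <- integer(0)
        for (j in setdiff(seq_len(n), keep)) {
          cand <- setdiff(order(abs(W[, j]), decreasing = TRUE), drop_init)
          drop_init <- c(drop_init, cand[1])
        }
        keep_init <- setdiff(seq_len(n), drop_init)
        Jr <- t(Wk)[, keep_init, drop = FALSE]
        sv <- svd(Jr)
        J <- sv$u %*% t(sv$v)
        gk <- gQ[keep_init]
        wk2 <- lam[keep]
        K <- -as.numeric(t(J) %*% ((J %*% gk) / wk2))
        E00 <- Evert - au_to_cm1(0.5 * sum(wk2 * as.numeric(J %*% K)^2))
        map <- new_duschinsky_map("VH", J, K,
                                  basis_i$frequencies[keep_init],
                                  au_to_cm1(sqrt(wk2)), E00)
        map$transition_dipole <- if (is.null(tdip)) c(1, 0, 0) else tdip
        return(map)
      }
      J <- fix_phases(W)  # columns; rows of t(W) are final modes
      J <- t(J)
      Kv <- -solve(hQ, gQ)
      E00 <- Evert - au_to_cm1(0.5 * sum(lam * as.numeric(J %*% Kv)^2))
      map <- new_duschinsky_map("VH", J, Kv, basis_i$frequencies,
                                au_to_cm1(sqrt(lam)), E00)
    }
  }
  if (!is.null(final$transition_dipole)) {
    map$transition_dipole <- final$transition_dipole
  } else if (!is.null(final$oscillator_strength)) {
    # |mu|^2 = 3 f / (2 dE), dE = vertical gap in a.u.
    dE <- cm1_to_au(map$Evert)
    map$transition_dipole <- c(sqrt(3 * final$oscillator_strength / (2 * dE)), 0, 0)
  }
  # orthogonality sanity for rotated models
  if (model %in% c("AH", "VH")) {
    dev <- max(abs(crossprod(map$J) - diag(nrow(map$J))))
    if (dev > 1e-8) {
      warning(sprintf("Duschinsky J deviates from orthogonality by %.2g ", dev),
              "(translation/rotation contamination between frames?)")
    }
  }
  map
}

#' Per-mode activity of a Duschinsky map
#'
#' Huang-Rhys factors and the reorganization energy. For J = I the
#' Huang-Rhys factor of mode i is `S_i = omega'_i K_i^2 / 2` (a.u.) and the
#' reorganization energy is `lambda = sum(S_i * omega'_i)`; for general J,
#' `lambda` is the final-surface energy at the initial minimum minus at the
#' final minimum (= Evert - E00) and the per-mode S are reported in the
#' final-state mode basis using the rotated displacement `J K`.
#'
#' @param map a `DuschinskyMap`.
#' @return list with `S` (dimensionless, per final mode) and `lambda_cm1`.
#' @export
mode_activity <- function(map) {
  stopifnot(inherits(map, "DuschinskyMap"))
  wF <- cm1_to_au(map$freqs_final)
  d <- as.numeric(map$J %*% map$K)
  S <- wF * d^2 / 2
  list(S = S, lambda_cm1 = map$Evert - map$E00)
}
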