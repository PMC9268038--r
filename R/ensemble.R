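# Nuclear-ensemble spectra: Wigner (quantum) and classical-Boltzmann
# harmonic sampling of the initial state, vertical excitations against the
# analytic harmonic final surface, Gaussian convolution, and convergence
# analysis. The classical sampler is an explicit harmonic surrogate for
# MD-ensemble statistics; real excitation tables can be injected through the
# transition-records CSV instead.

sampling_freqs <- function(x) {
  if (inherits(x, "NormalModeBasis")) x$frequencies
  else if (inherits(x, "DuschinskyMap")) x$freqs_initial
  else as.numeric(x)
}

new_ensemble <- function(displacements, momenta, basis, method, T) {
  geometries <- NULL
  if (inherits(basis, "NormalModeBasis")) {
    sm <- rep(sqrt(amu_to_me(basis$masses)), each = 3)
    x0 <- angstrom_to_bohr(as.vector(t(basis$reference_geometry)))
    cart <- basis$modes %*% t(displacements)   # 3N x n, mass-weighted
    geometries <- t(bohr_to_angstrom(x0 + cart / sm))
  }
  structure(list(displacements = displacements, momenta = momenta,
                 geometries = geometries, method = method, temperature = T),
            class = "EnsembleSample")
}

#' @export
print.EnsembleSample <- function(x, ...) {
  cat(sprintf("EnsembleSample [%s]: %d samples x %d modes, T = %g K\n",
              x$method, nrow(x$displacements), ncol(x$displacements),
              x$temperature))
  invisible(x)
}

#' Wigner sampling of harmonic normal coordinates
#'
#' Draws normal-coordinate displacements from the Wigner distribution of the
#' vibrational ground (T = 0) or thermal state: per-mode Gaussians with
#' coordinate variance `(1/(2 w)) coth(w/(2 kB T))` and momentum variance
#' `(w/2) coth(w/(2 kB T))` (a.u.). Modes are independent.
#'
#' @param basis a [normal_modes()] basis, a `DuschinskyMap` (its initial
#'   frequencies are used), or a numeric vector of wavenumbers (cm^-1).
#' @param T temperature, K (default 0: zero-point sampling).
#' @param n number of samples.
#' @param seed integer seed; identical seeds give identical samples.
#' @param momenta also draw conjugate momenta.
#' @return an `EnsembleSample`; Cartesian geometries (Angstrom) are filled in
#'   when a full `NormalModeBasis` is supplied.
#' @export
wigner_sample <- function(basis, T = 0, n, seed, momenta = FALSE) {
  freqs <- sampling_freqs(basis)
  if (any(freqs <= 0)) stop("imaginary/zero frequency present; cannot sample")
  if (n < 1) stop("n must be >= 1")
  if (T < 0) stop("temperature must be >= 0")
  w <- cm1_to_au(freqs)
  cothf <- if (T == 0) rep(1, length(w)) else {
    x <- freqs / (2 * .const$kB_cm1 * T)
    1 / tanh(x)
  }
  sd_q <- sqrt(cothf / (2 * w))
  set.seed(as.integer(seed))
  disp <- matrix(stats::rnorm(n * length(w)), n) %*% diag(sd_q, length(w))
  mom <- NULL
  if (momenta) {
    sd_p <- sqrt(w * cothf / 2)
    mom <- matrix(stats::rnorm(n * length(w)), n) %*% diag(sd_p, length(w))
  }
  new_ensemble(disp, mom, basis, "wigner", T)
}

#' Classical-Boltzmann sampling of harmonic normal coordinates
#'
#' Per-mode Gaussians with the classical coordinate variance `kB T / w^2`
#' (a.u.), the harmonic surrogate for sampling geometries from classical MD.
#' Narrower than the Wigner distribution for every mode with `w > kB T`.
#'
#' @inheritParams wigner_sample
#' @export
classical_sample <- function(basis, T, n, seed, momenta = FALSE) {
  freqs <- sampling_freqs(basis)
  if (any(freqs <= 0)) stop("imaginary/zero frequency present; cannot sample")
  if (T <= 0) stop("classical sampling requires T > 0")
  if (n < 1) stop("n must be >= 1")
  w <- cm1_to_au(freqs)
  kT <- cm1_to_au(.const$kB_cm1 * T)
  sd_q <- sqrt(kT) / w
  set.seed(as.integer(seed))
  disp <- matrix(stats::rnorm(n * length(w)), n) %*% diag(sd_q, length(w))
  mom <- NULL
  if (momenta) {
    mom <- matrix(stats::rnorm(n * length(w)), n) * sqrt(kT)
  }
  new_ensemble(disp, mom, basis, "classical", T)
}

#' Vertical excitations of an ensemble on a harmonic final surface
#'
#' Evaluates `dE(Q) = E00 + V'(Q) - V(Q)` with both potentials harmonic
#' (`V` from the map's initial frequencies, `V'` from `Q' = J(Q - K)`).
#' Under the Condon approximation the transition dipole is constant and the
#' oscillator strength is `f = (2/3) dE |mu|^2` (a.u.).
#'
#' @param samples an `EnsembleSample` drawn in the map's initial mode space.
#' @param map a `DuschinskyMap`.
#' @return a [transition_records()] table.
#' @export
vertical_excitations <- function(samples, map) {
  stopifnot(inherits(samples, "EnsembleSample"),
            inherits(map, "DuschinskyMap"))
  Q <- samples$displacements
  if (ncol(Q) != map$nmodes) stop("sample/map mode-count mismatch")
  w <- cm1_to_au(map$freqs_initial)
  wp <- cm1_to_au(map$freqs_final)
  Qp <- sweep(Q, 2, map$K) %*% t(map$J)
  V <- 0.5 * (Q^2 %*% w^2)
  Vp <- 0.5 * (Qp^2 %*% wp^2)
  dE_au <- cm1_to_au(map$E00) + as.numeric(Vp - V)
  f <- (2 / 3) * dE_au * mu2(map)
  transition_records(au_to_cm1(dE_au), pmax(f, 0))
}

# Gaussian line accumulation shared by the ensemble and stick convolutions.
# Exact windowed evaluation for moderate line counts; linear-split binning
# plus kernel convolution for large ensembles (error O((step/2 sigma)^2)).
gaussian_lines <- function(positions, weights, sigma, grid,
                           exact_limit = 20000) {
  ng <- length(grid)
  step <- grid[2] - grid[1]
  vals <- numeric(ng)
  if (length(positions) <= exact_limit) {
    for (i in seq_along(positions)) {
      lo <- max(1L, floor((positions[i] - 10 * sigma - grid[1]) / step) + 1L)
      hi <- min(ng, ceiling((positions[i] + 10 * sigma - grid[1]) / step) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      vals[idx] <- vals[idx] +
        weights[i] * exp(-((grid[idx] - positions[i])^2) / (2 * sigma^2))
    }
  } else {
    # linear-split binning on a grid extended by the kernel radius, so lines
    # just outside the requested window still contribute their tails and
    # lines far outside are dropped rather than clamped to the edge
    half <- ceiling(8 * sigma / step)
    pos <- (positions - grid[1]) / step + half
    nb <- ng + 2 * half
    inside <- pos >= 0 & pos <= nb - 1
    pos <- pos[inside]
    wts <- weights[inside]
    i0 <- pmin(pmax(floor(pos), 0), nb - 2)
    frac <- pos - i0
    binned <- numeric(nb)
    add <- function(idx, wt) {
      s <- tapply(wt, idx, sum)
      ii <- as.integer(names(s))
      binned[ii] <<- binned[ii] + as.numeric(s)
    }
    add(i0 + 1L, wts * (1 - frac))
    add(i0 + 2L, wts * frac)
    kx <- (-half:half) * step
    kernel <- exp(-kx^2 / (2 * sigma^2))
    conv <- stats::convolve(binned, rev(kernel), type = "open")
    vals <- conv[(2 * half + 1):(2 * half + ng)]
  }
  vals
}

#' Nuclear-ensemble spectrum from transition records
#'
#' Gaussian summation over vertical excitations:
#' `eps(nu) = sum_i f_i exp(-(nu - nu_i)^2 / (2 sigma^2))`. Conventional
#' widths: `sigma = 250` cm^-1 for MD-style (classical) input and
#' `sigma = 500` cm^-1 for Wigner-style input give smooth spectra.
#'
#' @param records a [transition_records()] table.
#' @param sigma Gaussian standard deviation, cm^-1 (> 0).
#' @param grid output wavenumber grid (uniform, cm^-1).
#' @return a [spectrum()].
#' @export
nuclear_ensemble_spectrum <- function(records, sigma = 500,
                                      grid = seq(10000, 30000, by = 1)) {
  if (!nrow(records)) stop("empty transition records")
  if (sigma <= 0) stop("sigma must be positive")
  e <- records$excitation_cm1
  if (min(e) - 4 * sigma < min(grid) || max(e) + 4 * sigma > max(grid)) {
    warning("grid does not cover the record range +/- 4 sigma")
  }
  vals <- gaussian_lines(e, records$oscillator_strength, sigma, grid)
  spectrum(grid, vals, meta = list(scheme = "nuclear-ensemble",
                                   broadening = sigma,
                                   broadening_convention = "sigma"))
}

#' Spectral convergence versus ensemble size
#'
#' For each size, builds the ensemble spectrum from a seeded random subset of
#' the records (nested: prefixes of one permutation, as frames accumulating
#' along a trajectory) and reports successive peak-normalized relative L1
#' distances between consecutive sizes.
#'
#' @param records a [transition_records()] table.
#' @param sizes increasing subset sizes; `max(sizes) <= nrow(records)`.
#' @param sigma Gaussian width (standard deviation), cm^-1.
#' @param grid wavenumber grid.
#' @param seed subset-selection seed.
#' @return list: `spectra` (one per size), `l1_distances`
#'   (length `length(sizes) - 1`), `sizes`.
#' @export
convergence_series <- function(records, sizes, sigma = 500,
                               grid = seq(10000, 30000, by = 1), seed = 1) {
  if (max(sizes) > nrow(records)) stop("max(sizes) exceeds the record count")
  set.seed(as.integer(seed))
  perm <- sample.int(nrow(records))
  spectra <- lapply(sizes, function(k) {
    nuclear_ensemble_spectrum(records[perm[seq_len(k)], , drop = FALSE],
                              sigma = sigma, grid = grid)
  })
  dists <- if (length(sizes) > 1) {
    vapply(seq_len(length(sizes) - 1), function(i) {
      spectral_distance(spectra[[i]], spectra[[i + 1]])$l1
    }, 0)
  } else numeric(0)
  list(spectra = spectra, l1_distances = dists, sizes = sizes)
}
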