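# Time-dependent Franck-Condon engine.
#
# The thermal dipole autocorrelation function of two harmonic surfaces
# related by Q' = J(Q - K) is, under the Condon approximation,
#
#   chi(t) = e^{-i E00 t} Tr[ e^{-(beta - it) H} e^{-it H'} ] / Tr e^{-beta H}
#
# Both propagators have Gaussian (Mehler) position kernels, so the trace is
# a 2n-dimensional complex Gaussian integral. Exploiting its symmetric block
# structure it reduces to n x n algebra (all frequencies in a.u.):
#
#   u = e^{-iwt}, q = e^{-beta w}, p = e^{-iw't}
#   a1 = w (u^2 + q^2)/(u^2 - q^2)   b1 = 2 w q u /(u^2 - q^2)
#   a2 = w'(1 + p^2)/(1 - p^2)       b2 = 2 w' p  /(1 - p^2)
#   P = J^T a2 J,  R = J^T b2 J,  M+- = diag(a1) + P -+ (diag(b1) + R)
#   chi^2 = prod F_i prod G_k / (det M+ det M-)
#           * exp(2 c0^T M+^{-1} c0 - 2 K^T(P-R)K - 2i E00 t),  c0 = (P-R)K
#   F_i = 2 w (1-q)^2 u/(u^2 - q^2)  (initial modes, thermal-normalized)
#   G_k = 2 w' p/(1 - p^2)           (final modes)
#
# Everything is accumulated as a complex logarithm of chi^2; the physical
# chi is recovered by unwrapping the accumulated phase along the (uniform)
# time grid after stripping the fast mid-spectrum phase e^{-i Ebar t}, so
# only the slow residual (of order the spectral width) must stay below pi
# per step. Writing the hyperbolic ratios in q, u, p keeps everything finite
# at arbitrarily low temperature.

td_factors <- function(map, T) {
  n <- map$nmodes
  w <- cm1_to_au(map$freqs_initial)
  wp <- cm1_to_au(map$freqs_final)
  if (any(w <= 0) || any(wp <= 0)) {
    stop("TD engine requires positive frequencies")
  }
  q <- if (T == 0) rep(0, n) else exp(-map$freqs_initial / (.const$kB_cm1 * T))
  list(n = n, w = w, wp = wp, q = q, J = map$J, K = map$K,
       E00 = cm1_to_au(map$E00),
       Ebar = cm1_to_au((map$Evert + map$E00_zpe) / 2))
}

# log(chi(t)^2) at a single positive time (a.u.)
log_chi2 <- function(f, t) {
  u <- exp(-1i * f$w * t)
  p <- exp(-1i * f$wp * t)
  du <- u^2 - f$q^2
  dp <- 1 - p^2
  a1 <- f$w * (u^2 + f$q^2) / du
  b1 <- 2 * f$w * f$q * u / du
  a2 <- f$wp * (1 + p^2) / dp
  b2 <- 2 * f$wp * p / dp
  P <- t(f$J) %*% (a2 * f$J)
  R <- t(f$J) %*% (b2 * f$J)
  Mp <- diag(a1, f$n) + P - diag(b1, f$n) - R
  Mm <- diag(a1, f$n) + P + diag(b1, f$n) + R
  c0 <- (P - R) %*% f$K
  quad <- sum(c0 * solve(Mp, c0)) - sum(f$K * ((P - R) %*% f$K))
  ldet <- sum(log(eigen(Mp, only.values = TRUE)$values)) +
    sum(log(eigen(Mm, only.values = TRUE)$values))
  lF <- log(2 * f$w) + 2 * log(1 - f$q) + log(u) - log(du)
  lG <- log(2 * f$wp) + log(p) - log(dp)
  sum(lF) + sum(lG) - ldet + 2 * quad - 2i * f$E00 * t
}

#' Thermal dipole correlation function of a Duschinsky map
#'
#' Closed-form harmonic correlation function at temperature `T`, normalized
#' so that `chi(0) = 1`. Valid at any temperature at fixed cost; the
#' spectrum is its Fourier transform (see [td_spectrum()]).
#'
#' @param map a `DuschinskyMap` with positive frequencies.
#' @param T temperature, K.
#' @param times uniform, increasing time grid starting at 0 (a.u.). The step
#'   must resolve the spectral span (phase change per step below pi), which
#'   [td_spectrum()] guarantees by construction.
#' @return object of class `CorrelationSeries`: `times`, complex `values`,
#'   `damping` descriptor (filled in by [td_spectrum()]).
#' @export
correlation_function <- function(map, T = 0, times) {
  stopifnot(inherits(map, "DuschinskyMap"))
  if (T < 0) stop("temperature must be >= 0")
  times <- as.numeric(times)
  nt <- length(times)
  if (nt < 2 || times[1] != 0 ||
      max(abs(diff(times) - (times[2] - times[1]))) > 1e-9 * times[2]) {
    stop("times must be a uniform grid starting at 0")
  }
  f <- td_factors(map, T)
  vals <- complex(nt)
  vals[1] <- 1 + 0i
  phase_prev <- 0   # unwrapped slow phase of chi^2 (Ebar stripped)
  raw_prev <- 0
  for (j in 2:nt) {
    lc <- log_chi2(f, times[j])
    if (!is.finite(Re(lc)) || !is.finite(Im(lc))) {
      stop("singular determinant at t = ", times[j],
           " (resonance artifact); use a different time step")
    }
    raw <- Im(lc) + 2 * f$Ebar * times[j]
    dph <- (raw - raw_prev) %% (2 * pi)
    if (dph > pi) dph <- dph - 2 * pi
    phase <- phase_prev + dph
    vals[j] <- exp(0.5 * Re(lc)) *
      exp(1i * (0.5 * phase - f$Ebar * times[j]))
    phase_prev <- phase
    raw_prev <- raw
  }
  structure(list(times = times, values = vals, damping = NULL,
                 temperature = T),
            class = "CorrelationSeries")
}

#' @export
print.CorrelationSeries <- function(x, ...) {
  cat(sprintf("CorrelationSeries: %d points, t <= %.1f a.u., T = %g K\n",
              length(x$times), max(x$times), x$temperature))
  invisible(x)
}

#' Time-dependent Franck-Condon spectrum
#'
#' Fourier transform of the damped correlation function. A Gaussian
#' time-domain window `exp(-sigma_au^2 t^2 / 2)` is applied so the
#' frequency-domain broadening is Gaussian with standard deviation `sigma`
#' (specify either `sigma` or `hwhm`; `HWHM = sigma * sqrt(2 ln 2)`). The
#' correlation function is evaluated at a Nyquist-oversampled time step up to
#' the time where the window has decayed below 1e-8, then zero-padded to at
#' least 2^15 transform points for frequency resolution and spline
#' interpolated onto the requested grid.
#'
#' @param map a `DuschinskyMap`.
#' @param T temperature, K.
#' @param sigma,hwhm Gaussian broadening, cm^-1 (exactly one).
#' @param grid output wavenumber grid, cm^-1; must cover the active window.
#' @param prefactor multiply by the transition wavenumber and `|mu|^2`.
#' @param oversample Nyquist oversampling factor for the time step.
#' @return a [spectrum()].
#' @export
td_spectrum <- function(map, T = 0, sigma = NULL, hwhm = NULL,
                        grid = seq(10000, 30000, by = 1), prefactor = TRUE,
                        oversample = 2) {
  stopifnot(inherits(map, "DuschinskyMap"))
  br <- resolve_sigma(sigma, hwhm)
  sig_au <- cm1_to_au(br$sigma)
  # the irrational factor keeps dt incommensurate with mode periods, so a
  # round-number grid cannot land a time point exactly on a lineshape
  # resonance (sin(w t) = 0)
  numax <- (cm1_to_au(max(grid) * 1.05) + 6 * sig_au) * (1 + pi * 1e-4)
  dt <- pi / (oversample * numax)
  t_end <- sqrt(2 * log(1e8)) / sig_au
  nt <- ceiling(t_end / dt) + 1
  if (nt > 2^18) stop("time grid too large; increase the broadening width")
  times <- (seq_len(nt) - 1) * dt
  chi <- correlation_function(map, T, times)
  window <- exp(-0.5 * (sig_au * times)^2)
  x <- chi$values * window
  if (Mod(x[nt]) > 1e-6) {
    stop("correlation function not decayed at the final time (aliasing); ",
         "increase the broadening or the window span")
  }
  npad <- 2^max(15, ceiling(log2(4 * nt)))
  xp <- c(x, complex(npad - nt))
  X <- stats::fft(xp, inverse = TRUE)       # sum x_j exp(+2pi i jm/N)
  half <- seq_len(npad %/% 2 + 1)
  nu_au <- 2 * pi * (half - 1) / (npad * dt)
  I <- (dt / pi) * (Re(X[half]) - 0.5 * Re(x[1]))
  nu_cm <- au_to_cm1(nu_au)
  vals <- stats::spline(nu_cm, I, xout = grid, method = "natural")$y
  if (prefactor) vals <- vals * grid * mu2(map)
  neg <- vals < 0
  if (any(vals < -1e-4 * max(vals))) {
    warning("TD spectrum has negative values beyond the numerical floor")
  }
  vals[neg] <- 0
  spectrum(grid, vals,
           meta = list(scheme = paste0("FC-TD/", map$model), temperature = T,
                       broadening = br$given,
                       broadening_convention = br$convention,
                       prefactor = prefactor))
}
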