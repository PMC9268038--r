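# Spectrum post-processing: stick convolution, normalization, shifting,
# peak finding, band spacings, lambda_max and spectral distances.

#' Convolve a stick spectrum with Gaussians
#'
#' When the sticks carry the frequency prefactor (their default intensity is
#' `nu_stick * |mu|^2 * population * FC`), the convolution re-weights it to
#' the observation frequency: `eps(nu) = nu * sum FC_i G(nu - nu_i)`. This is
#' the standard absorption convention and makes the broadened TI spectrum
#' identical to the TD spectrum rather than agreeing only to O(sigma/nu).
#'
#' @param sticks a `StickSpectrum`.
#' @param sigma,hwhm Gaussian broadening, cm^-1 (exactly one of the two;
#'   `HWHM = sigma * sqrt(2 ln 2)`).
#' @param grid uniform wavenumber grid, cm^-1.
#' @return a [spectrum()].
#' @export
convolve_sticks <- function(sticks, sigma = NULL, hwhm = NULL,
                            grid = seq(10000, 30000, by = 1)) {
  stopifnot(inherits(sticks, "StickSpectrum"))
  if (!length(sticks$energies)) stop("empty stick spectrum")
  br <- resolve_sigma(sigma, hwhm)
  pref <- isTRUE(sticks$meta$prefactor)
  wts <- if (pref) sticks$intensities / sticks$energies else sticks$intensities
  vals <- gaussian_lines(sticks$energies, wts, br$sigma, grid)
  if (pref) vals <- vals * grid
  spectrum(grid, vals,
           meta = list(scheme = paste0("FC-TI/",
                                       sticks$meta$model %||% "sticks"),
                       temperature = sticks$meta$temperature %||% NA_real_,
                       broadening = br$given,
                       broadening_convention = br$convention,
                       prefactor = sticks$meta$prefactor %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wavenumber of maximum absorbance
#'
#' Grid point of the global maximum; ties are broken toward lower wavenumber.
#'
#' @param spec a [spectrum()].
#' @return wavenumber, cm^-1.
#' @export
lambda_max <- function(spec) {
  stopifnot(inherits(spec, "Spectrum"))
  spec$grid[which.max(spec$values)]
}

#' Rigidly shift a spectrum
#'
#' Translates the wavenumber grid so a chosen feature matches a reference:
#' `mode = "match_max"` aligns the global maximum, `"match_first_peak"` the
#' lowest-wavenumber detected peak, `"fixed"` applies `reference` directly as
#' the shift. The applied shift (`reference - feature`) is recorded in the
#' metadata and accumulates over repeated shifts.
#'
#' @param spec a [spectrum()].
#' @param mode shift mode.
#' @param reference reference wavenumber (or the shift itself for `"fixed"`).
#' @return list: `spectrum` (shifted), `shift` (cm^-1).
#' @export
shift_spectrum <- function(spec, mode = c("match_max", "match_first_peak",
                                          "fixed"), reference) {
  stopifnot(inherits(spec, "Spectrum"))
  mode <- match.arg(mode)
  shift <- switch(mode,
    match_max = reference - lambda_max(spec),
    match_first_peak = {
      pk <- find_peaks(spec)
      if (!nrow(pk)) stop("no peak detected for match_first_peak")
      reference - pk$wavenumber[1]
    },
    fixed = reference
  )
  meta <- spec$meta
  meta$shift_applied <- (meta$shift_applied %||% 0) + shift
  out <- spectrum(spec$grid + shift, spec$values, meta = meta)
  list(spectrum = out, shift = shift)
}

#' Peak detection and band spacings
#'
#' Local maxima exceeding `prominence_fraction` of the global maximum.
#' Plateaus report their lowest-wavenumber point. `band_spacing` returns the
#' successive differences of the peak positions.
#'
#' @param spec a [spectrum()].
#' @param prominence_fraction minimum height relative to the global max.
#' @return `find_peaks`: data.frame `wavenumber`, `value`;
#'   `band_spacing`: numeric vector of successive spacings (cm^-1).
#' @export
find_peaks <- function(spec, prominence_fraction = 0.05) {
  stopifnot(inherits(spec, "Spectrum"))
  v <- spec$values
  n <- length(v)
  if (n < 3) return(data.frame(wavenumber = numeric(0), value = numeric(0)))
  is_pk <- v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]
  idx <- which(is_pk) + 1L
  idx <- idx[v[idx] >= prominence_fraction * max(v)]
  data.frame(wavenumber = spec$grid[idx], value = v[idx])
}

#' @rdname find_peaks
#' @param peaks result of `find_peaks`.
#' @export
band_spacing <- function(peaks) {
  diff(peaks$wavenumber)
}

#' Normalize a spectrum
#'
#' `"peak"` scales the maximum to 1 (idempotent); `"area"` scales the
#' trapezoid integral to 1.
#'
#' @param spec a [spectrum()].
#' @param mode `"peak"` or `"area"`.
#' @export
normalize_spectrum <- function(spec, mode = c("peak", "area")) {
  mode <- match.arg(mode)
  s <- switch(mode,
    peak = max(spec$values),
    area = sum((spec$values[-1] + spec$values[-length(spec$values)]) / 2 *
                 diff(spec$grid))
  )
  if (s <= 0) stop("cannot normalize a zero spectrum")
  spectrum(spec$grid, spec$values / s, meta = spec$meta)
}

#' Distances between two spectra
#'
#' Both spectra are linearly resampled onto the overlap of their grids and
#' peak-normalized; reported metrics are the peak-normalized L1 distance
#' (grid average of `|a - b|` for curves scaled to unit maximum), the
#' L-infinity distance (max absolute difference of the peak-normalized
#' curves) and the lambda_max difference.
#'
#' @param a,b [spectrum()] objects with overlapping grids.
#' @return list: `l1`, `linf`, `dlambda_max`.
#' @export
spectral_distance <- function(a, b) {
  stopifnot(inherits(a, "Spectrum"), inherits(b, "Spectrum"))
  lo <- max(min(a$grid), min(b$grid))
  hi <- min(max(a$grid), max(b$grid))
  if (lo >= hi) stop("spectra have disjoint grids")
  grid <- seq(lo, hi, length.out = max(512, min(length(a$grid),
                                                length(b$grid))))
  va <- stats::approx(a$grid, a$values, grid)$y
  vb <- stats::approx(b$grid, b$values, grid)$y
  va <- va / max(va); vb <- vb / max(vb)
  list(
    l1 = mean(abs(va - vb)),
    linf = max(abs(va - vb)),
    dlambda_max = abs(grid[which.max(va)] - grid[which.max(vb)])
  )
}
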