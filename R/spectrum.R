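#' Spectrum objects
#'
#' A `Spectrum` is broadened intensity on a strictly increasing wavenumber
#' grid (cm^-1) with nonnegative values and a metadata list recording the
#' scheme that produced it, the temperature, the broadening width and
#' convention, and any rigid shift applied.
#'
#' @param grid strictly increasing wavenumbers, cm^-1.
#' @param values nonnegative intensities, same length as `grid`.
#' @param meta named list of metadata.
#' @return object of class `Spectrum`.
#' @export
spectrum <- function(grid, values, meta = list()) {
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) == 0) stop("empty grid")
  if (length(grid) != length(values)) {
    stop("grid and values must have the same length")
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (any(!is.finite(values)) || any(values < -1e-12 * max(abs(values), 1))) {
    stop("values must be finite and nonnegative")
  }
  values[values < 0] <- 0
  defaults <- list(scheme = NA_character_, temperature = NA_real_,
                   broadening = NA_real_, broadening_convention = NA_character_,
                   shift_applied = 0)
  meta <- utils::modifyList(defaults, meta)
  structure(list(grid = grid, values = values, meta = meta),
            class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d points, %.1f..%.1f cm^-1, max %.4g",
              length(x$grid), min(x$grid), max(x$grid), max(x$values)))
  if (!is.na(x$meta$scheme)) cat(" [", x$meta$scheme, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read / write spectra as CSV
#'
#' Two-column CSV `wavenumber_cm1,epsilon` preceded by `#`-prefixed metadata
#' lines. Round-trips preserve grid and values to full printed precision.
#'
#' @param spec a [spectrum()].
#' @param path file path.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "Spectrum"))
  m <- spec$meta
  hdr <- c(
    sprintf("# scheme: %s", m$scheme),
    sprintf("# temperature_K: %s", m$temperature),
    sprintf("# broadening_cm1: %s", m$broadening),
    sprintf("# broadening_convention: %s", m$broadening_convention),
    sprintf("# shift_applied_cm1: %s", m$shift_applied),
    "wavenumber_cm1,epsilon"
  )
  body <- sprintf("%.10g,%.12g", spec$grid, spec$values)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    key <- switch(key,
      "temperature_K" = "temperature",
      "broadening_cm1" = "broadening",
      "shift_applied_cm1" = "shift_applied",
      key)
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else if (val == "NA") NA else val
  }
  dat <- utils::read.csv(text = lines[!is_meta], header = TRUE)
  spectrum(dat$wavenumber_cm1, dat$epsilon, meta = meta)
}

#' Transition records
#'
#' A transition-record table holds one vertical excitation per ensemble
#' member: `excitation_cm1`, `oscillator_strength`, `source_index`. This is
#' the exchange format between the sampling step (or an external QM/MM run)
#' and the ensemble convolution.
#'
#' @param excitation_cm1 excitation energies, cm^-1, finite.
#' @param oscillator_strength nonnegative oscillator strengths f.
#' @param source_index sample identifiers (default 1..n).
#' @return data.frame of class `transition_records`.
#' @export
transition_records <- function(excitation_cm1, oscillator_strength,
                               source_index = seq_along(excitation_cm1)) {
  if (any(!is.finite(excitation_cm1))) stop("excitation energies must be finite")
  if (any(oscillator_strength < 0)) stop("oscillator strengths must be >= 0")
  out <- data.frame(excitation_cm1 = as.numeric(excitation_cm1),
                    oscillator_strength = as.numeric(oscillator_strength),
                    source_index = source_index)
  class(out) <- c("transition_records", "data.frame")
  out
}

#' @rdname transition_records
#' @param path file path of a CSV `excitation_cm1,oscillator_strength`.
#' @export
read_records <- function(path) {
  dat <- utils::read.csv(path, comment.char = "#")
  transition_records(dat$excitation_cm1, dat$oscillator_strength,
                     if ("source_index" %in% names(dat)) dat$source_index
                     else seq_len(nrow(dat)))
}

#' @rdname transition_records
#' @param records a `transition_records` table.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
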