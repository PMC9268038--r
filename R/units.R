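# Physical constants (CODATA). The internal unit system is atomic units
# (hbar = 1, m_e = 1, bohr, hartree); external interfaces use Angstrom, amu,
# cm^-1 and eV. Fixing the constants here eliminates unit drift between the
# recursion engines and the correlation-function code.
.const <- list(
  hartree_cm1 = 219474.6313632,   # 1 hartree in cm^-1
  hartree_eV  = 27.211386245988,  # 1 hartree in eV
  bohr_angstrom = 0.529177210903, # 1 bohr in Angstrom
  amu_me      = 1822.888486,      # 1 amu in electron masses
  kB_cm1      = 0.695034800       # Boltzmann constant in cm^-1 / K
)

cm1_to_au <- function(x) x / .const$hartree_cm1
au_to_cm1 <- function(x) x * .const$hartree_cm1
angstrom_to_bohr <- function(x) x / .const$bohr_angstrom
bohr_to_angstrom <- function(x) x * .const$bohr_angstrom
amu_to_me <- function(x) x * .const$amu_me

#' Convert energies between spectroscopic units
#'
#' Converts between hartree, electron-volt, wavenumber (`"cm-1"`) and
#' wavelength in nanometres (`"nm"`). Wavelength is related to energy by
#' \eqn{\tilde\nu = 10^7 / \lambda}, so conversions involving `"nm"` require
#' strictly positive values.
#'
#' @param value numeric vector of energies (or wavelengths for `from = "nm"`).
#' @param from,to one of `"hartree"`, `"eV"`, `"cm-1"`, `"nm"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(1, "hartree", "cm-1")   # 219474.6313632
#' convert_energy(0.23, "eV", "cm-1")     # ~1855 cm^-1
#' @export
convert_energy <- function(value, from, to) {
  units <- c("hartree", "eV", "cm-1", "nm")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) return(value)
  if ((from == "nm" || to == "nm") && any(value <= 0)) {
    stop("wavelength/energy must be strictly positive for nm conversions")
  }
  # route through cm^-1
  x <- switch(from,
    "hartree" = value * .const$hartree_cm1,
    "eV"      = value / .const$hartree_eV * .const$hartree_cm1,
    "cm-1"    = value,
    "nm"      = 1e7 / value
  )
  switch(to,
    "hartree" = x / .const$hartree_cm1,
    "eV"      = x / .const$hartree_cm1 * .const$hartree_eV,
    "cm-1"    = x,
    "nm"      = 1e7 / x
  )
}

# Gaussian width conventions: HWHM = sigma * sqrt(2 ln 2).
hwhm_to_sigma <- function(hwhm) hwhm / sqrt(2 * log(2))

# Resolve a broadening specification; exactly one of sigma/hwhm must be given.
resolve_sigma <- function(sigma = NULL, hwhm = NULL) {
  if (is.null(sigma) && is.null(hwhm)) stop("provide sigma or hwhm")
  if (!is.null(sigma) && !is.null(hwhm)) stop("provide only one of sigma/hwhm")
  conv <- if (is.null(sigma)) "hwhm" else "sigma"
  s <- if (is.null(sigma)) hwhm_to_sigma(hwhm) else sigma
  if (s <= 0) stop("broadening width must be positive")
  list(sigma = s, convention = conv,
       given = if (is.null(sigma)) hwhm else sigma)
}
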