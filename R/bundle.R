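#' Electronic state bundles
#'
#' An `ElectronicStateBundle` collects the harmonic electronic-structure data
#' of one electronic state: Cartesian geometry (Angstrom), atomic masses
#' (amu), electronic energy (hartree) and, optionally, the Cartesian Hessian
#' (hartree/bohr^2), the Cartesian gradient (hartree/bohr), the electronic
#' transition dipole (a.u.) and the oscillator strength. It is the neutral,
#' QM-package-agnostic contract between electronic-structure output and the
#' spectral engines.
#'
#' @param label short text label for the state.
#' @param elements character vector of element symbols (length natoms).
#' @param geometry natoms x 3 numeric matrix, Angstrom.
#' @param masses numeric vector of atomic masses, amu; strictly positive.
#' @param energy electronic energy, hartree.
#' @param hessian optional 3N x 3N symmetric matrix, hartree/bohr^2.
#' @param gradient optional length-3N numeric vector, hartree/bohr.
#' @param transition_dipole optional length-3 numeric vector, a.u.
#' @param oscillator_strength optional nonnegative scalar.
#' @return an object of class `ElectronicStateBundle`.
#' @export
electronic_state_bundle <- function(label, elements, geometry, masses, energy,
                                    hessian = NULL, gradient = NULL,
                                    transition_dipole = NULL,
                                    oscillator_strength = NULL) {
  geometry <- as.matrix(geometry)
  if (ncol(geometry) != 3) stop("geometry must be an natoms x 3 matrix")
  natoms <- nrow(geometry)
  if (length(elements) != natoms) stop("elements length must equal natoms")
  if (length(masses) != natoms) stop("masses length must equal natoms")
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("masses must be strictly positive")
  }
  if (!is.null(hessian)) {
    hessian <- as.matrix(hessian)
    if (!all(dim(hessian) == c(3 * natoms, 3 * natoms))) {
      stop("hessian must be 3N x 3N")
    }
    asym <- max(abs(hessian - t(hessian)))
    scale <- max(abs(hessian), 1e-300)
    if (asym > 1e-8 * scale) {
      stop("hessian is asymmetric beyond 1e-8 relative tolerance")
    }
    hessian <- (hessian + t(hessian)) / 2
  }
  if (!is.null(gradient) && length(gradient) != 3 * natoms) {
    stop("gradient must have length 3N")
  }
  if (!is.null(transition_dipole) && length(transition_dipole) != 3) {
    stop("transition_dipole must have length 3")
  }
  if (!is.null(oscillator_strength) &&
      (length(oscillator_strength) != 1 || oscillator_strength < 0)) {
    stop("oscillator_strength must be a nonnegative scalar")
  }
  structure(list(
    label = as.character(label), natoms = natoms,
    elements = as.character(elements), geometry = geometry,
    masses = as.numeric(masses), energy = as.numeric(energy),
    hessian = hessian, gradient = as.numeric(gradient),
    transition_dipole = if (is.null(transition_dipole)) NULL
                        else as.numeric(transition_dipole),
    oscillator_strength = if (is.null(oscillator_strength)) NULL
                          else as.numeric(oscillator_strength)
  ), class = "ElectronicStateBundle")
}

#' @export
print.ElectronicStateBundle <- function(x, ...) {
  cat("ElectronicStateBundle '", x$label, "': ", x$natoms, " atoms",
      if (!is.null(x$hessian)) ", hessian" else "",
      if (length(x$gradient)) ", gradient" else "",
      if (!is.null(x$transition_dipole)) ", transition dipole" else "",
      "\n", sep = "")
  invisible(x)
}

#' Read / write electronic state bundles
#'
#' Bundles are stored as structured text (JSON) with self-describing keys:
#' `label`, `elements`, `geometry_angstrom`, `masses_amu`, `energy_hartree`,
#' `hessian_hartree_bohr2`, `gradient_hartree_bohr`, `transition_dipole_au`,
#' `oscillator_strength`. Units are declared in the key names so any
#' electronic-structure code (or a hand editor) can produce the format.
#'
#' @param path file path.
#' @return `read_bundle` returns a validated [electronic_state_bundle()];
#'   `write_bundle` returns `path` invisibly.
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("label", "elements", "geometry_angstrom", "masses_amu",
            "energy_hartree")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("malformed bundle: missing field(s) ", paste(missing, collapse = ", "))
  }
  as_mat <- function(x, ncol) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
    if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = ncol, byrow = TRUE)
    storage.mode(x) <- "double"
    x
  }
  geom <- as_mat(raw$geometry_angstrom, 3)
  if (is.null(geom) || ncol(geom) != 3) {
    stop("malformed bundle: geometry_angstrom must be natoms x 3")
  }
  hess <- as_mat(raw$hessian_hartree_bohr2, 3 * nrow(geom))
  electronic_state_bundle(
    label = raw$label, elements = raw$elements, geometry = geom,
    masses = raw$masses_amu, energy = raw$energy_hartree,
    hessian = hess, gradient = raw$gradient_hartree_bohr,
    transition_dipole = raw$transition_dipole_au,
    oscillator_strength = raw$oscillator_strength
  )
}

#' @rdname read_bundle
#' @param bundle an `ElectronicStateBundle`.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "ElectronicStateBundle"))
  out <- list(
    label = bundle$label,
    elements = bundle$elements,
    geometry_angstrom = bundle$geometry,
    masses_amu = bundle$masses,
    energy_hartree = bundle$energy
  )
  if (!is.null(bundle$hessian)) out$hessian_hartree_bohr2 <- bundle$hessian
  if (length(bundle$gradient)) out$gradient_hartree_bohr <- bundle$gradient
  if (!is.null(bundle$transition_dipole)) {
    out$transition_dipole_au <- bundle$transition_dipole
  }
  if (!is.null(bundle$oscillator_strength)) {
    out$oscillator_strength <- bundle$oscillator_strength
  }
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read / write XYZ geometries
#'
#' Standard XYZ format: atom count, comment line, then one
#' `element x y z` row per atom, coordinates in Angstrom.
#'
#' @param path file path.
#' @return `read_xyz`: list with `elements`, `geometry` (Angstrom), `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2) stop("malformed XYZ file")
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  elements <- vapply(rows, `[`, "", 1)
  geometry <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  list(elements = elements, geometry = geometry, comment = lines[2])
}

#' @rdname read_xyz
#' @param elements element symbols.
#' @param geometry natoms x 3 matrix, Angstrom.
#' @param comment comment line.
#' @export
write_xyz <- function(elements, geometry, path, comment = "") {
  geometry <- as.matrix(geometry)
  lines <- c(nrow(geometry), comment,
             sprintf("%-3s %18.12f %18.12f %18.12f", elements,
                     geometry[, 1], geometry[, 2], geometry[, 3]))
  writeLines(lines, path)
  invisible(path)
}
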