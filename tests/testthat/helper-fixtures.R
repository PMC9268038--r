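# Shared fixtures, all generated in code.

fixture_diatomic <- function(k = 1.8923e-2, masses = c(1, 1), d = 1.0) {
  g <- rbind(c(0, 0, 0), c(0, 0, d))
  h <- matrix(0, 6, 6)
  h[3, 3] <- k; h[6, 6] <- k; h[3, 6] <- -k; h[6, 3] <- -k
  electronic_state_bundle("diatomic", c("H", "H"), g, masses, -1, hessian = h)
}

fixture_rotated_2mode <- function(displacement = 15, seed = 3) {
  make_duschinsky_rotated(c(1000, 1400), angles_deg = 30,
                          displacement = displacement, E00 = 18200,
                          seed = seed)
}

fixture_vg_pair <- function(seed = 9, gQ = c(1e-4, -5e-5, 2e-5),
                            evert_h = 0.086) {
  ini <- make_random_bundle(3, seed = seed)
  basis <- normal_modes(ini)
  sm <- rep(sqrt(ini$masses * 1822.888486), each = 3)
  gcart <- sm * (basis$modes %*% gQ)
  fin <- electronic_state_bundle(
    "S1", ini$elements, ini$geometry, ini$masses,
    energy = ini$energy + evert_h, gradient = as.numeric(gcart),
    transition_dipole = c(1.2, 0, 0))
  list(initial = ini, final = fin, basis = basis, gQ = gQ)
}
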