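test_that("identical states give the trivial map under every model", {
  fix <- fixture_rotated_2mode(displacement = 0)
  ini <- fix$initial
  # AH / AS with final == initial
  same <- electronic_state_bundle("same", ini$elements, ini$geometry,
                                  ini$masses, ini$energy,
                                  hessian = ini$hessian,
                                  transition_dipole = c(1, 0, 0))
  for (model in c("AH", "AS")) {
    m <- build_map(ini, same, model)
    expect_equal(m$J, diag(m$nmodes), tolerance = 1e-10)
    expect_equal(m$K, rep(0, m$nmodes), tolerance = 1e-10)
    expect_equal(m$Evert, m$E00, tolerance = 1e-9)
  }
  # VG / VH with zero gradient at the initial geometry
  flat <- electronic_state_bundle("flat", ini$elements, ini$geometry,
                                  ini$masses, ini$energy + 0.08,
                                  hessian = ini$hessian,
                                  gradient = rep(0, 3 * ini$natoms),
                                  transition_dipole = c(1, 0, 0))
  for (model in c("VG", "VH")) {
    m <- build_map(ini, flat, model)
    expect_equal(m$K, rep(0, m$nmodes), tolerance = 1e-12)
    expect_equal(m$Evert, m$E00, tolerance = 1e-9)
  }
})

test_that("AH reconstruction reproduces the generating rotation", {
  # K = 0: the mode spaces coincide exactly, so J is the rotation itself
  fix0 <- fixture_rotated_2mode(displacement = 0)
  R30 <- rbind(c(cos(pi / 6), sin(pi / 6)), c(-sin(pi / 6), cos(pi / 6)))
  expect_lt(max(abs(abs(fix0$map$J[1:2, 1:2]) - abs(R30))), 1e-10)
  m0 <- build_map(fix0$initial, fix0$final, "AH")
  expect_lt(max(abs(m0$J - fix0$map$J)), 1e-9)
  expect_lt(max(abs(m0$K)), 1e-9)
  # displaced pair: emitted (J, K) round-trips through build_map
  fix <- fixture_rotated_2mode(displacement = 15)
  m <- build_map(fix$initial, fix$final, "AH")
  expect_lt(max(abs(m$J - fix$map$J)), 1e-9)
  expect_lt(max(abs(m$K - fix$map$K)), 1e-9)
  expect_lt(max(abs(crossprod(m$J) - diag(m$nmodes))), 1e-8)
  expect_equal(m$E00, 18200, tolerance = 1e-6)
  expect_equal(m$freqs_final[1:2], c(1000, 1400), tolerance = 1e-6)
})

test_that("VG displacement follows K = -g/omega^2", {
  # 1 mode at 1000 cm^-1 with g_Q = 1e-4 a.u. -> K = -4.8169 a.u.
  b <- fixture_diatomic()
  basis <- normal_modes(b)
  sm <- rep(sqrt(b$masses * 1822.888486), each = 3)
  gcart <- sm * (basis$modes %*% 1e-4)
  fin <- electronic_state_bundle("S1", b$elements, b$geometry, b$masses,
                                 b$energy + 0.086,
                                 gradient = as.numeric(gcart),
                                 transition_dipole = c(1, 0, 0))
  m <- build_map(b, fin, "VG")
  w1 <- normal_modes(b)$frequencies / 219474.6313632
  expect_equal(m$K, -1e-4 / w1^2, tolerance = 1e-8)
  expect_equal(m$K, -4.8169, tolerance = 1e-3)
  expect_equal(mode_activity(m)$S, 0.05286, tolerance = 1e-3)
  # multimode arithmetic
  fix <- fixture_vg_pair(seed = 9)
  mv <- build_map(fix$initial, fix$final, "VG")
  w <- normal_modes(fix$initial)$frequencies / 219474.6313632
  expect_equal(mv$K, -fix$gQ / w^2, tolerance = 1e-8)
  expect_equal(mv$Evert, 0.086 * 219474.6313632, tolerance = 1e-6)
})

test_that("gradient route and geometry route agree for a shifted surface", {
  # final surface exactly harmonic with the initial frequencies, no rotation:
  # AS (geometry difference) and VG (gradient) must give identical K
  fix <- make_duschinsky_rotated(c(900, 1300), angles_deg = 0,
                                 displacement = 12, seed = 6)
  mAS <- build_map(fix$initial, fix$final, "AS")
  ini <- fix$initial
  sm <- rep(sqrt(ini$masses * 1822.888486), each = 3)
  basis <- normal_modes(ini)
  w <- basis$frequencies / 219474.6313632
  gQ <- -w^2 * mAS$K    # gradient of the shifted surface at the initial min
  lam_h <- 0.5 * sum(w^2 * mAS$K^2)
  finVG <- electronic_state_bundle(
    "S1v", ini$elements, ini$geometry, ini$masses,
    energy = fix$final$energy + lam_h,
    gradient = as.numeric(sm * (basis$modes %*% gQ)),
    transition_dipole = c(1, 0, 0))
  mVG <- build_map(ini, finVG, "VG")
  expect_equal(mVG$K, mAS$K, tolerance = 1e-10)
  expect_equal(mVG$E00, mAS$E00, tolerance = 1e-6)
  # AH with zero Duschinsky mixing reduces to AS
  mAH <- build_map(fix$initial, fix$final, "AH")
  expect_lt(max(abs(mAH$J - mAS$J)), 1e-10)
  expect_lt(max(abs(mAH$K - mAS$K)), 1e-10)
})

test_that("VH recovers extrapolated frequencies and flags imaginary ones", {
  fix <- make_duschinsky_rotated(c(800, 1200, 1500), c(900, 1100, 1600),
                                 angles_deg = c(20, -15), displacement = 8,
                                 seed = 5)
  ini <- fix$initial
  finVH <- electronic_state_bundle(
    "S1", ini$elements, ini$geometry, ini$masses, ini$energy + 0.09,
    gradient = rep(0, 3 * ini$natoms), hessian = fix$final$hessian,
    transition_dipole = c(1, 0, 0))
  m <- build_map(ini, finVH, "VH")
  expect_equal(m$freqs_final[1:3], c(900, 1100, 1600), tolerance = 1e-6)
  expect_lt(max(abs(abs(m$J) - abs(fix$map$J))), 1e-8)
  # negative-curvature direction -> hard error by default
  sm <- rep(sqrt(ini$masses * 1822.888486), each = 3)
  Li <- normal_modes(ini)$modes
  wbad <- (c(-400, 1100, 1600) / 219474.6313632)
  hbad <- tcrossprod(sm) * (Li %*% (sign(wbad) * wbad^2 * t(Li)))
  finBad <- electronic_state_bundle(
    "S1b", ini$elements, ini$geometry, ini$masses, ini$energy + 0.09,
    gradient = rep(0, 3 * ini$natoms), hessian = (hbad + t(hbad)) / 2)
  expect_error(build_map(ini, finBad, "VH"), "imaginary")
})

test_that("missing ingredients raise usage errors", {
  fix <- fixture_rotated_2mode()
  nograd <- electronic_state_bundle("x", fix$initial$elements,
                                    fix$initial$geometry, fix$initial$masses,
                                    -1)
  expect_error(build_map(fix$initial, nograd, "VG"), "gradient")
  expect_error(build_map(fix$initial, nograd, "AH"), "hessian")
})

test_that("mode activity and the reorganization-energy identity hold", {
  m0 <- make_displaced_oscillators(c(700, 1300), S = c(0, 0))
  act0 <- mode_activity(m0)
  expect_equal(act0$S, c(0, 0))
  expect_equal(act0$lambda_cm1, 0)
  # single mode, S = 0.6 at 1150 cm^-1 -> lambda = 690 cm^-1
  m1 <- make_displaced_oscillators(1150, S = 0.6)
  expect_equal(mode_activity(m1)$lambda_cm1, 690, tolerance = 1e-9)
  # Evert - E00 = lambda for J = I maps (mechanism behind lambda_max != VEE)
  for (S in list(c(0.3, 0.8), c(1.2, 0.1))) {
    m <- make_displaced_oscillators(c(500, 1400), S = S, E00 = 18200)
    expect_equal(m$Evert - m$E00, sum(S * c(500, 1400)),
                 tolerance = 1e-6 * m$Evert)
    expect_equal(sum(mode_activity(m)$S * m$freqs_final),
                 mode_activity(m)$lambda_cm1, tolerance = 1e-9 * 1000)
  }
})
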