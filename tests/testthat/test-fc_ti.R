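test_that("overlaps are orthonormal for the identity map", {
  m <- make_displaced_oscillators(c(800, 1200), S = c(0, 0))
  for (v in list(c(0, 0), c(1, 0), c(2, 3))) {
    expect_equal(fc_overlap(m, v, v), 1, tolerance = 1e-12)
    expect_equal(fc_overlap(m, v, rev(v) + c(0, 1)), 0, tolerance = 1e-12)
  }
})

test_that("displaced-mode factors follow the Poisson law, and the 0-0 the
           frequency-change closed form", {
  m <- make_displaced_oscillators(1150, S = 1)
  fc2 <- sapply(0:6, function(n) fc_overlap(m, 0, n)^2)
  expect_equal(fc2, poisson_fc(1, 0:6), tolerance = 1e-10)
  expect_equal(fc2[1], 0.367879, tolerance = 1e-5)
  expect_equal(fc2[3], 0.183940, tolerance = 1e-5)
  # K = 0, omega' = 2 omega: |<0|0>|^2 = 2 sqrt(w w')/(w + w')
  m2 <- make_displaced_oscillators(1000, K = 0, freqs_final = 2000)
  expect_equal(fc_overlap(m2, 0, 0)^2, 2 * sqrt(2) / 3, tolerance = 1e-10)
  expect_equal(fc_overlap(m2, 0, 0)^2, 0.942809, tolerance = 1e-5)
})

test_that("recursion matches Gauss-Hermite quadrature on rotated maps", {
  fix <- fixture_rotated_2mode()
  map2 <- fix$map
  # restrict to the two active modes by building an explicit 2-mode map
  # with the same rotation block (spectator modes are exact zeros anyway)
  cases <- list(c(0, 0, 0, 0, 0, 0), c(0, 0, 0, 2, 1, 0),
                c(1, 0, 0, 0, 3, 1), c(2, 2, 0, 1, 1, 2))
  for (cs in cases) {
    v <- cs[1:3]; vp <- cs[4:6]
    expect_equal(fc_overlap(map2, v, vp),
                 fc_overlap_quadrature(map2, v, vp, nq = 40),
                 tolerance = 1e-8)
  }
})

test_that("zero-temperature enumeration is complete and assigned", {
  # K = 0 -> exactly one stick, the 0-0, FC factor 1
  m0 <- make_displaced_oscillators(c(900, 1500), S = c(0, 0), E00 = 18200)
  st0 <- sticks_zero_T(m0, prefactor = FALSE)
  expect_length(st0$energies, 1)
  expect_equal(st0$intensities, 1, tolerance = 1e-12)
  expect_equal(st0$energies, 18200)
  # 2 modes, S = (1, 0.5), max 2 quanta/mode -> 9 sticks; combination (1,1)
  m <- make_displaced_oscillators(c(1000, 1400), S = c(1, 0.5))
  st <- suppressWarnings(
    sticks_zero_T(m, max_quanta = 2, max_simultaneous = 2, floor = 0,
                  prefactor = FALSE))
  expect_length(st$energies, 9)
  i11 <- which(st$final_quanta[, 1] == 1 & st$final_quanta[, 2] == 1)
  expect_equal(st$intensities[i11], exp(-1.5) * 1 * 0.5, tolerance = 1e-10)
  expect_equal(st$intensities[i11], 0.111565, tolerance = 1e-5)
  # stick energies follow E(0-0) + sum v' w' - sum v w
  expect_equal(st$energies,
               m$E00_zpe + as.numeric(st$final_quanta %*% m$freqs_final),
               tolerance = 1e-6)
  # Poisson tail: S = 0.6 captured to 0.9999 within 10 quanta
  m6 <- make_displaced_oscillators(1150, S = 0.6)
  st6 <- sticks_zero_T(m6, max_quanta = 10, prefactor = FALSE)
  expect_gte(st6$meta$captured_fraction, 0.9999)
})

test_that("FC sum rule holds at default truncation for small maps", {
  maps <- list(
    make_displaced_oscillators(1150, S = 1),
    make_displaced_oscillators(c(500, 1300), S = c(0.8, 0.4)),
    make_displaced_oscillators(c(300, 900, 1500), S = c(1, 0.5, 0.25))
  )
  for (m in maps) {
    st <- sticks_zero_T(m, floor = 0, prefactor = FALSE)
    expect_lte(st$meta$captured_fraction, 1 + 1e-10)
    expect_gte(st$meta$captured_fraction, 0.999)
  }
})

test_that("stick intensities are invariant under mode phase flips", {
  fix <- fixture_rotated_2mode()
  m <- fix$map
  flip_final <- m; flip_final$J <- diag(c(-1, 1, -1)) %*% m$J
  flip_init <- m
  flip_init$J <- m$J %*% diag(c(1, -1, 1))
  flip_init$K <- c(1, -1, 1) * m$K
  st <- sticks_zero_T(m, max_quanta = 4, prefactor = FALSE)
  for (mm in list(flip_final, flip_init)) {
    st2 <- sticks_zero_T(mm, max_quanta = 4, prefactor = FALSE)
    expect_equal(st2$energies, st$energies, tolerance = 1e-9)
    expect_equal(st2$intensities, st$intensities, tolerance = 1e-10)
  }
})

test_that("Boltzmann populations follow the geometric law", {
  p0 <- boltzmann_populations(c(500, 1200), 0)
  expect_equal(p0$populations, 1)
  expect_equal(p0$vectors, matrix(0L, 1, 2))
  # 34.9 cm^-1 at 298 K: p0 = 1 - exp(-34.9/207.12) = 0.15507
  p <- boltzmann_populations(34.9, 298, floor = 1e-7)
  i0 <- which(p$vectors[, 1] == 0)
  expect_equal(p$populations[i0], 0.15507, tolerance = 1e-4)
  # stiff mode is entirely cold at room temperature
  p2 <- boltzmann_populations(1525, 298)
  expect_gt(p2$populations[which(p2$vectors[, 1] == 0)], 0.999)
  expect_error(boltzmann_populations(1000, -5), ">= 0")
})

test_that("thermal sticks reduce to 0 K and obey the classical first moment", {
  m <- make_displaced_oscillators(c(700, 1400), S = c(0.5, 0.3), E00 = 18200)
  st0 <- sticks_zero_T(m, prefactor = FALSE)
  stT <- sticks_thermal(m, 0, prefactor = FALSE)
  expect_equal(stT$energies, st0$energies, tolerance = 1e-12)
  expect_equal(stT$intensities, st0$intensities, tolerance = 1e-12)
  # kT >> omega: the intensity-weighted mean approaches Evert (here it is
  # exactly Evert for a displaced mode at any T, truncation aside)
  mh <- make_displaced_oscillators(140, S = 0.4, E00 = 18200)
  sth <- sticks_thermal(mh, 600, max_quanta = 45, population_floor = 1e-6,
                        prefactor = FALSE)
  mean_e <- sum(sth$energies * sth$intensities) / sum(sth$intensities)
  expect_equal(mean_e, mh$Evert, tolerance = 5 / mh$Evert)
  # hot bands dominate a soft mode at room temperature
  m349 <- make_displaced_oscillators(34.9, S = 0.6, E00 = 18200)
  st <- sticks_thermal(m349, 298, max_quanta = 30, population_floor = 1e-5,
                       prefactor = FALSE)
  hot <- rowSums(st$init_quanta) >= 1
  expect_gt(sum(st$intensities[hot]) / sum(st$intensities), 0.5)
})

test_that("fundamental fractions count singly-excited cold bands", {
  m0 <- make_displaced_oscillators(c(900, 1500), S = c(0, 0))
  st0 <- sticks_zero_T(m0, prefactor = FALSE)
  ff0 <- fundamental_fraction(st0)
  expect_equal(ff0$count_fraction, 0)
  expect_equal(ff0$intensity_fraction, 0)
  # 1-mode Poisson S = 1 truncated at 3 quanta
  m1 <- make_displaced_oscillators(1150, S = 1)
  st1 <- suppressWarnings(sticks_zero_T(m1, max_quanta = 3, floor = 0,
                                        prefactor = FALSE))
  ff1 <- fundamental_fraction(st1)
  tot <- sum(poisson_fc(1, 0:3))
  expect_equal(ff1$intensity_fraction, poisson_fc(1, 1) / tot,
               tolerance = 1e-9)
  expect_equal(ff1$count_fraction, 1 / 3)
  # 2-mode enumeration: 2 fundamentals among the 8 non-0-0 sticks
  m2 <- make_displaced_oscillators(c(1000, 1400), S = c(1, 0.5))
  st2 <- suppressWarnings(sticks_zero_T(m2, max_quanta = 2,
                                        max_simultaneous = 2, floor = 0,
                                        prefactor = FALSE))
  ff2 <- fundamental_fraction(st2)
  expect_equal(ff2$count_fraction, 2 / 8)
})

test_that("assignment reports rank, label and break ties as documented", {
  # Poisson S = 1: 0-0 and 0-1 tie; lower energy (the 0-0) wins
  m1 <- make_displaced_oscillators(1150, S = 1)
  rep1 <- assignment_report(sticks_zero_T(m1, prefactor = FALSE), top_n = 3)
  expect_equal(rep1$label[1], "0-0")
  expect_equal(rep1$label[2], "1^1")
  expect_equal(rep1$relative_energy_cm1[2], 1150)
  # K = 0 map: only the 0-0 appears
  m0 <- make_displaced_oscillators(c(900, 1500), S = c(0, 0))
  rep0 <- assignment_report(sticks_zero_T(m0), top_n = 5)
  expect_equal(nrow(rep0), 1)
  expect_equal(rep0$label, "0-0")
  # hot-band labels carry the initial side
  m349 <- make_displaced_oscillators(34.9, S = 0.6)
  st <- sticks_thermal(m349, 298, max_quanta = 20, population_floor = 1e-4,
                       prefactor = FALSE)
  reph <- assignment_report(st, top_n = 10)
  expect_true(any(grepl("<-", reph$label)))
})
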