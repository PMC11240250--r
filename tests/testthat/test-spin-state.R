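test_that("the singlet state has the defining expectation values", {
  rho <- singlet_state(fum)
  expect_valid_density(rho)
  expect_equal(singlet_population(rho, fum), 1, tolerance = 1e-12)
  expect_equal(scalar_order(rho, fum), -0.75, tolerance = 1e-12)
  expect_error(singlet_state(fum, pair = c(1, 3)), "1H")
})

test_that("the singlet is invariant under any hard nonselective proton pulse", {
  rho <- singlet_state(fum)
  for (angle in c(pi / 7, pi / 2, 1.1, pi, 2 * pi)) {
    for (phase in c(0, pi / 3, pi / 2)) {
      out <- pulse(rho, fum, "1H", angle, phase)
      expect_valid_density(out)
      expect_equal(singlet_population(out, fum), 1, tolerance = 1e-12)
    }
  }
})

test_that("free evolution is unitary: trace, Hermiticity and spectrum preserved", {
  rho <- pulse(singlet_state(fum), fum, "1H", 0.4, 0.2) # something non-trivial
  spec0 <- eigen_spectrum(rho)
  for (t in c(0, 1e-3, 17e-3, 0.3)) {
    out <- evolve(rho, fum, t)
    expect_valid_density(out)
    expect_equal(eigen_spectrum(out), spec0, tolerance = 1e-12)
  }
  expect_identical(evolve(rho, fum, 0)$op, rho$op)
})

test_that("evolution agrees with an independent matrix-exponential propagator", {
  rho <- pulse(singlet_state(fum), fum, "1H", pi / 2, pi / 5)
  t <- 8.31e-3
  H <- phipchip:::spin_hamiltonian(fum)
  U <- expm_taylor(-1i * H * t)
  want <- U %*% rho$op %*% Conj(t(U))
  got <- evolve(rho, fum, t)$op
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("a magnetically equivalent pair keeps its singlet under evolution", {
  sys <- pair_system(j_hh = 23.4, with_carbon = TRUE, j_ch = c(5, 5))
  rho <- singlet_state(sys)
  for (t in c(1e-3, 0.05, 0.4)) {
    expect_equal(singlet_population(evolve(rho, sys, t), sys), 1,
                 tolerance = 1e-10)
  }
})

test_that("pulses behave as rotations: identity cases and purge action", {
  rho <- singlet_state(fum)
  expect_lt(max(abs(pulse(rho, fum, "1H", 0)$op - rho$op)), 1e-14)
  # 2*pi rotation acts as identity on all observables
  out <- pulse(rho, fum, "1H", 2 * pi)
  expect_lt(max(abs(out$op - rho$op)), 1e-12)
  expect_error(pulse(rho, fum, "19F", pi / 2), "no spin")

  # purge: a pi/2 proton pulse empties T0 into the outer triplet states
  # while the singlet population stays put
  n <- 3
  t0_op <- phipchip:::.pair_projector(n, c(1, 2), "T0") / 2
  mixed <- density_state(0.6 * singlet_state(fum)$op + 0.4 * t0_op, fum)
  purged <- pulse(mixed, fum, "1H", pi / 2)
  expect_equal(singlet_population(purged, fum), 0.6, tolerance = 1e-12)
  pops <- triplet_populations(purged, fum)
  expect_equal(unname(pops["T0"]), 0, tolerance = 1e-12)
  expect_equal(unname(pops["Tp"] + pops["Tm"]), 0.4, tolerance = 1e-12)
})

test_that("singlet-triplet mixing follows the two-level Rabi formula", {
  sys <- pair_system(j_hh = 0)
  rho <- singlet_state(sys)
  delta <- 7.3 # Hz

  expect_identical(st_mixing(rho, sys, 0, 0.1)$op, rho$op)

  # full transfer to T0 at t = 1/(2 delta)
  full <- st_mixing(rho, sys, delta, 1 / (2 * delta))
  expect_equal(singlet_population(full, sys), 0, tolerance = 1e-10)
  expect_equal(unname(triplet_populations(full, sys)["T0"]), 1,
               tolerance = 1e-10)

  # analytic S0 population at arbitrary times, outer triplets untouched
  rho_mix <- density_state(0.5 * rho$op +
                           0.25 * phipchip:::.pair_projector(2, 1:2, "Tp") +
                           0.25 * phipchip:::.pair_projector(2, 1:2, "Tm"),
                           sys)
  for (t in c(0.013, 0.071, 0.2)) {
    out <- st_mixing(rho_mix, sys, delta, t)
    expect_equal(singlet_population(out, sys),
                 0.5 * cos(pi * delta * t)^2, tolerance = 1e-10)
    pops <- triplet_populations(out, sys)
    expect_equal(unname(pops["Tp"]), 0.25, tolerance = 1e-10)
    expect_equal(unname(pops["Tm"]), 0.25, tolerance = 1e-10)
    expect_valid_density(out)
  }
})

test_that("density-state validation rejects unphysical operators", {
  bad_trace <- diag(8) / 4
  expect_error(density_state(bad_trace, fum), "trace")
  nh <- matrix(0, 8, 8); nh[1, 2] <- 1; nh[1, 1] <- 1
  expect_error(density_state(nh, fum), "Hermitian")
})
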