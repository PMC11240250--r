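test_that("S2hM needs a transferable asymmetry and a supported topology", {
  # both heteronuclear couplings zero: nothing breaks the singlet symmetry
  sys0 <- pair_system(j_hh = 15.7, with_carbon = TRUE, j_ch = c(0, 0))
  eff <- transfer_efficiency(sys0, sequence_params(tau = 15.7e-3))
  expect_equal(eff, 0, tolerance = 1e-10)

  # thermal identity input gives no carbon signal
  rho_id <- density_state(diag(8) / 8, fum)
  out <- s2hm(rho_id, fum, sequence_params(tau = 15.7e-3))
  expect_equal(magnetization_z(out, fum, "13C"), 0, tolerance = 1e-12)

  expect_error(transfer_efficiency(pair_system(10)), "topology")
  expect_error(
    transfer_efficiency(spin_system(c("1H", "13C"),
                                    matrix(c(0, 5, 5, 0), 2, 2))),
    "topology")
})

test_that("transfer efficiency respects its unitary bound and relaxation limits", {
  # independent bound: optimal eigenvalue pairing of the initial state
  # against 2*Sz (von Neumann / rearrangement argument)
  rho0 <- singlet_state(fum)$op
  iz <- phipchip:::spin_operators(fum)$z[[3]]
  bound <- sum(sort(Re(eigen(rho0, symmetric = TRUE,
                             only.values = TRUE)$values),
                    decreasing = TRUE) *
               sort(Re(eigen(2 * iz, symmetric = TRUE,
                             only.values = TRUE)$values),
                    decreasing = TRUE))
  for (tau in c(5e-3, 12e-3, 15.7e-3, 22e-3)) {
    eff <- transfer_efficiency(fum, sequence_params(tau = tau))
    expect_lte(eff, bound + 1e-10)
    expect_lte(abs(eff), 1 + 1e-10)
  }
  # vanishing singlet lifetime kills the transfer
  eff0 <- transfer_efficiency(fum, sequence_params(tau = 15.7e-3),
                              relaxation = relaxation_params(
                                t_singlet = 1e-4, t1_carbon = 50))
  expect_lt(abs(eff0), 1e-10)
  # finite lifetimes damp but do not flip the transfer
  effr <- transfer_efficiency(fum, sequence_params(tau = 15.7e-3),
                              relaxation = relaxation_params(30, 50))
  expect_gt(effr, 0)
  expect_lt(effr, transfer_efficiency(fum, sequence_params(tau = 15.7e-3)))
})

test_that("the sequence agrees with an independent expm-based simulation", {
  params <- sequence_params(tau = 15.7e-3, n1 = 7, n2 = 7)
  got <- transfer_efficiency(fum, params)

  # independent path: build every propagator with a series expansion
  ops <- phipchip:::spin_operators(fum)
  H <- phipchip:::spin_hamiltonian(fum)
  U <- function(t) expm_taylor(-1i * H * t)
  P <- function(idx, angle, phase) {
    G <- Reduce(`+`, lapply(idx, function(i) {
      cos(phase) * ops$x[[i]] + sin(phase) * ops$y[[i]]
    }))
    expm_taylor(-1i * angle * G)
  }
  conj_by <- function(rho, u) u %*% rho %*% Conj(t(u))
  rho <- singlet_state(fum)$op
  rho <- conj_by(rho, P(1:2, pi / 2, 0))
  echo <- U(params$tau) %*% P(1:2, pi, 0) %*% U(params$tau)
  for (k in 1:params$n1) rho <- conj_by(rho, echo)
  rho <- conj_by(rho, P(3, pi / 2, 0))
  rho <- conj_by(rho, U(1.25 * params$tau))
  for (k in 1:params$n2) rho <- conj_by(rho, echo)
  rho <- conj_by(rho, P(3, pi / 2, pi / 2))
  want <- 2 * Re(sum(diag(rho %*% ops$z[[3]])))

  expect_equal(got, want, tolerance = 1e-6)
})

test_that("every sequence stage returns a physical density operator", {
  rho <- singlet_state(fum)
  out <- s2hm(rho, fum, sequence_params(tau = 12e-3, n1 = 3, n2 = 5))
  expect_valid_density(out)
  expect_equal(eigen_spectrum(out), eigen_spectrum(rho), tolerance = 1e-12)
})

test_that("the purge pulse rescues signal from T0 contamination", {
  n <- 3
  s0 <- phipchip:::.pair_projector(n, c(1, 2), "S0") / 2
  t0 <- phipchip:::.pair_projector(n, c(1, 2), "T0") / 2
  mixed <- density_state(0.7 * s0 + 0.3 * t0, fum)
  run <- function(purge) {
    p <- sequence_params(tau = 15.7e-3, purge = purge)
    magnetization_z(s2hm(mixed, fum, p), fum, "13C")
  }
  with_purge <- run(TRUE)
  without <- run(FALSE)
  expect_gt(with_purge, without)
  expect_gt(with_purge, 0)
})

test_that("grid optimization finds the published operating point", {
  # coarse scan (the acceptance suite runs the full 0.1 ms grid)
  opt <- optimize_sequence(fum, tau_grid = seq(5e-3, 30e-3, by = 5e-4))
  expect_lt(abs(opt$best$tau - 15.7e-3), 1e-3)
  expect_gt(opt$best_efficiency, 0.9)

  # the printed parameters sit within 2% of the grid maximum
  eff_printed <- transfer_efficiency(fum, sequence_params(15.7e-3, 7, 7))
  expect_gt(eff_printed, 0.98 * max(opt$map$efficiency))
})

test_that("optimization is deterministic: singleton grids and tie-breaks", {
  single <- optimize_sequence(fum, tau_grid = 11e-3, n1_grid = 4,
                              n2_grid = 6)
  expect_equal(single$best$tau, 11e-3)
  expect_equal(single$best$n1, 4L)
  expect_equal(single$best$n2, 6L)

  # a system with no heteronuclear coupling scores zero everywhere:
  # ties resolve to the smallest tau, then the smallest n1 + n2
  sys0 <- pair_system(j_hh = 15, with_carbon = TRUE)
  tied <- optimize_sequence(sys0, tau_grid = c(20e-3, 10e-3),
                            n1_grid = c(3, 2), n2_grid = 2)
  expect_equal(tied$best$tau, 10e-3)
  expect_equal(tied$best$n1 + tied$best$n2, 4L)
})

test_that("the efficiency map is symmetric under relabelling the protons", {
  swapped <- spin_system(c("1H", "1H", "13C"),
                         matrix(c(0, 15.7, 6.6,
                                  15.7, 0, 3.2,
                                  6.6, 3.2, 0), 3, 3, byrow = TRUE))
  taus <- c(8e-3, 15.7e-3, 24e-3)
  for (tau in taus) {
    expect_equal(transfer_efficiency(fum, sequence_params(tau)),
                 transfer_efficiency(swapped, sequence_params(tau)),
                 tolerance = 1e-10)
  }
})
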