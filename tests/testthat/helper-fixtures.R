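# Shared fixtures, built once per test run.

# transport parameters calibrated on the beta-chip anchor point
calibrated_tp <- calibrate_film_depth()

fum <- fumarate_13c1()

# a chip with a single uniform membrane-contact segment (closed-form
# uptake solution available)
uniform_chip <- function(length_mm = 30, n_gas_sides = 2,
                         chamber = 0) {
  chip_geometry(
    channel_segment(length_mm, 0.3, 0.5, n_gas_sides = n_gas_sides),
    chamber_volume = chamber, label = "uniform"
  )
}

# closed-form chamber concentration for a uniform chip
closed_form_uptake <- function(geometry, flow, pressure, params) {
  seg <- geometry$segments[[1]]
  kla <- mass_transfer_coefficient(seg, params)
  t_res <- seg$length * seg$width * seg$depth / flow * 60
  c_sat <- saturation_concentration(pressure, params)
  c_sat * (1 - exp(-kla * t_res))
}

# an isolated proton pair (optionally J-coupled, optionally with a 13C
# whose couplings are zero)
pair_system <- function(j_hh = 10, with_carbon = FALSE,
                        j_ch = c(0, 0)) {
  if (with_carbon) {
    j <- matrix(0, 3, 3)
    j[1, 2] <- j[2, 1] <- j_hh
    j[1, 3] <- j[3, 1] <- j_ch[1]
    j[2, 3] <- j[3, 2] <- j_ch[2]
    spin_system(c("1H", "1H", "13C"), j)
  } else {
    spin_system(c("1H", "1H"), matrix(c(0, j_hh, j_hh, 0), 2, 2))
  }
}

# density-matrix health checks
expect_valid_density <- function(state) {
  op <- state$op
  expect_lt(max(abs(op - Conj(t(op)))), 1e-12)
  expect_lt(abs(Re(sum(diag(op))) - 1), 1e-12)
  ev <- eigen(op, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-12)
}

eigen_spectrum <- function(state) {
  sort(eigen(state$op, symmetric = TRUE, only.values = TRUE)$values)
}

# independent matrix exponential (Taylor series with scaling and
# squaring); used as an oracle against the eigendecomposition propagator
expm_taylor <- function(A) {
  nrm <- max(abs(A)) * nrow(A)
  s <- max(0, ceiling(log2(max(nrm, 1))) + 1)
  A2 <- A / 2^s
  X <- diag(nrow(A)) + 0i
  term <- diag(nrow(A)) + 0i
  for (k in 1:30) {
    term <- term %*% A2 / k
    X <- X + term
  }
  for (k in seq_len(s)) X <- X %*% X
  X
}
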