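# Density operators over the spin product basis: construction, unitary
# propagation, ideal pulses, singlet-triplet mixing, observables.

#' Construct a density state
#'
#' Wraps a Hermitian, unit-trace, positive-semidefinite operator over the
#' `2^N` product basis of a spin system. Validation tolerances: trace and
#' Hermiticity to 1e-12, eigenvalues >= -1e-12.
#'
#' @param operator Complex matrix of dimension `2^N`.
#' @param system The [spin_system()] the operator refers to.
#' @return An object of class `density_state`.
#' @export
density_state <- function(operator, system) {
  stopifnot(inherits(system, "spin_system"))
  dim <- 2^n_spins(system)
  operator <- as.matrix(operator)
  if (!all(dim(operator) == c(dim, dim))) {
    stop("operator dimension does not match the spin system", call. = FALSE)
  }
  if (max(abs(operator - Conj(t(operator)))) > 1e-12) {
    stop("operator is not Hermitian (tolerance 1e-12)", call. = FALSE)
  }
  if (abs(Re(sum(diag(operator))) - 1) > 1e-12) {
    stop("operator trace must equal 1 (tolerance 1e-12)", call. = FALSE)
  }
  ev <- eigen(operator, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) {
    stop("operator has negative eigenvalues (tolerance 1e-12)",
         call. = FALSE)
  }
  structure(list(op = operator, basis = "Zeeman product, spins as listed"),
            class = "density_state")
}

#' @export
print.density_state <- function(x, ...) {
  cat(sprintf("<density_state: %d x %d, trace %.6f>\n",
              nrow(x$op), ncol(x$op), Re(sum(diag(x$op)))))
  invisible(x)
}

.conj_by <- function(rho, U) U %*% rho %*% Conj(t(U))

#' Proton-pair singlet state
#'
#' Returns the density operator with the chosen proton pair in the nuclear
#' singlet state `|S0><S0|` and every other spin maximally mixed — the
#' spin order delivered by pairwise addition of parahydrogen.
#'
#' @param system A [spin_system()].
#' @param pair Indices of the two 1H spins forming the pair.
#' @return A [density_state()].
#' @examples
#' sys <- fumarate_13c1()
#' rho <- singlet_state(sys)
#' singlet_population(rho, sys) # 1
#' @export
singlet_state <- function(system, pair = c(1, 2)) {
  stopifnot(inherits(system, "spin_system"), length(pair) == 2)
  if (!all(system$isotopes[pair] == "1H")) {
    stop("both `pair` indices must be 1H spins", call. = FALSE)
  }
  n <- n_spins(system)
  P <- .pair_projector(n, pair, "S0")
  rho <- P / (2^(n - 2))
  density_state(rho, system)
}

# projector onto a two-spin state of the pair (S0, T0, Tp, Tm), identity on
# the remaining spins
.pair_projector <- function(n, pair, which = c("S0", "T0", "Tp", "Tm")) {
  which <- match.arg(which)
  up <- c(1, 0); dn <- c(0, 1)
  v12 <- switch(which,
    S0 = (kronecker(up, dn) - kronecker(dn, up)) / sqrt(2),
    T0 = (kronecker(up, dn) + kronecker(dn, up)) / sqrt(2),
    Tp = kronecker(up, up),
    Tm = kronecker(dn, dn)
  )
  P12 <- v12 %*% t(v12)
  # embed: pair spins at positions pair[1] < pair[2]
  i <- min(pair); k <- max(pair)
  # basis vector of the full space built spin by spin
  mats <- vector("list", n)
  # use the two-spin projector via permutation-free kron when the pair is
  # adjacent in order; general case handled by index bookkeeping
  if (k == i + 1) {
    left <- if (i > 1) diag(2^(i - 1)) else NULL
    right <- if (k < n) diag(2^(n - k)) else NULL
    out <- P12
    if (!is.null(left)) out <- kronecker(left, out)
    if (!is.null(right)) out <- kronecker(out, right)
    return(out)
  }
  # non-adjacent pair: build from ladder operators (rare path, small n)
  dim <- 2^n
  out <- matrix(0 + 0i, dim, dim)
  idx <- seq_len(dim) - 1L
  bit <- function(v, pos) bitwAnd(bitwShiftR(v, n - pos), 1L)
  amp <- function(b1, b2) {
    # amplitude of |b1 b2> in the pair state
    if (which == "S0") {
      if (b1 == 0 && b2 == 1) return(1 / sqrt(2))
      if (b1 == 1 && b2 == 0) return(-1 / sqrt(2))
      return(0)
    }
    if (which == "T0") {
      if (b1 != b2) return(1 / sqrt(2))
      return(0)
    }
    if (which == "Tp") return(as.numeric(b1 == 0 && b2 == 0))
    as.numeric(b1 == 1 && b2 == 1)
  }
  for (a in idx) for (b in idx) {
    rest_a <- bitwAnd(a, bitwNot(bitwOr(bitwShiftL(1L, n - i),
                                        bitwShiftL(1L, n - k))))
    rest_b <- bitwAnd(b, bitwNot(bitwOr(bitwShiftL(1L, n - i),
                                        bitwShiftL(1L, n - k))))
    if (rest_a != rest_b) next
    out[a + 1, b + 1] <- amp(bit(a, i), bit(a, k)) *
      amp(bit(b, i), bit(b, k))
  }
  out
}

#' Free evolution under the system Hamiltonian
#'
#' Exact unitary propagation `rho -> U rho U*` with
#' `U = exp(-i H t)` computed by eigendecomposition of the
#' time-independent rotating-frame Hamiltonian.
#'
#' @param state A [density_state()].
#' @param system The matching [spin_system()].
#' @param duration Evolution time in seconds (>= 0).
#' @return The evolved [density_state()].
#' @export
evolve <- function(state, system, duration) {
  stopifnot(inherits(state, "density_state"), duration >= 0)
  if (duration == 0) return(state)
  ctx <- spin_context(system)
  U <- context_propagator(ctx, duration)
  state$op <- .conj_by(state$op, U)
  state
}

#' Ideal hard pulse on one isotope channel
#'
#' Applies an instantaneous rotation by `angle` about the axis
#' `cos(phase) x + sin(phase) y` to every spin of the given isotope.
#'
#' @param state A [density_state()].
#' @param system The matching [spin_system()].
#' @param channel Isotope label (`"1H"` or `"13C"`).
#' @param angle Flip angle in radians.
#' @param phase Pulse phase in radians (0 = x, pi/2 = y).
#' @return The rotated [density_state()].
#' @export
pulse <- function(state, system, channel, angle, phase = 0) {
  stopifnot(inherits(state, "density_state"))
  idx <- which(system$isotopes == channel)
  if (length(idx) == 0) {
    stop("channel `", channel, "` matches no spin in the system",
         call. = FALSE)
  }
  ops <- spin_operators(system)
  U <- .pulse_operator(ops, idx, angle, phase)
  state$op <- .conj_by(state$op, U)
  state
}

.pulse_operator <- function(ops, idx, angle, phase) {
  dim <- nrow(ops$x[[1]])
  G <- matrix(0 + 0i, dim, dim)
  for (i in idx) G <- G + cos(phase) * ops$x[[i]] + sin(phase) * ops$y[[i]]
  eg <- eigen(G, symmetric = TRUE)
  eg$vectors %*% (exp(-1i * angle * eg$values) * Conj(t(eg$vectors)))
}

#' Coherent singlet-triplet mixing at a hydride intermediate
#'
#' Models the chemical-shift difference experienced by the proton pair in
#' a transient metal-hydride species: the pair evolves under a difference
#' term `pi * delta_hydride (I1z - I2z)` plus an optional hydride J
#' coupling `2 pi j_hydride I1.I2`. The difference term interconverts the
#' singlet `|S0>` and central triplet `|T0>` states; for `j_hydride = 0`
#' the S0 population follows the two-level Rabi formula and transfer to T0
#' is complete at `t = 1/(2 delta_hydride)`. The outer triplet states are
#' untouched.
#'
#' @param state A [density_state()].
#' @param system The matching [spin_system()].
#' @param delta_hydride Chemical-shift difference in Hz.
#' @param duration Contact time in seconds (>= 0).
#' @param pair Indices of the proton pair.
#' @param j_hydride Proton-proton J coupling in the hydride, Hz.
#' @return The mixed [density_state()].
#' @export
st_mixing <- function(state, system, delta_hydride, duration,
                      pair = c(1, 2), j_hydride = 0) {
  stopifnot(inherits(state, "density_state"), duration >= 0)
  if (duration == 0 || (delta_hydride == 0 && j_hydride == 0)) {
    return(state)
  }
  ops <- spin_operators(system)
  i <- pair[1]; k <- pair[2]
  H <- pi * delta_hydride * (ops$z[[i]] - ops$z[[k]]) +
    2 * pi * j_hydride * (ops$x[[i]] %*% ops$x[[k]] +
                          ops$y[[i]] %*% ops$y[[k]] +
                          ops$z[[i]] %*% ops$z[[k]])
  eig <- eigen(H, symmetric = TRUE)
  U <- eig$vectors %*% (exp(-1i * eig$values * duration) *
                        Conj(t(eig$vectors)))
  state$op <- .conj_by(state$op, U)
  state
}

#' Expectation value of total Iz on one channel
#'
#' @param state A [density_state()].
#' @param system The matching [spin_system()].
#' @param channel Isotope label.
#' @return `<sum Iz>` over the spins of that isotope (dimensionless; a
#'   single fully polarized spin-1/2 gives 0.5).
#' @export
magnetization_z <- function(state, system, channel) {
  idx <- which(system$isotopes == channel)
  if (length(idx) == 0) stop("unknown channel", call. = FALSE)
  ops <- spin_operators(system)
  tot <- Reduce(`+`, ops$z[idx])
  Re(sum(diag(state$op %*% tot)))
}

#' Populations of the pair singlet/triplet manifold
#'
#' @param state A [density_state()].
#' @param system The matching [spin_system()].
#' @param pair Proton pair indices.
#' @return For `singlet_population`, the population of `|S0>`; for
#'   `triplet_populations`, a named vector over `T+`, `T0`, `T-`.
#' @export
singlet_population <- function(state, system, pair = c(1, 2)) {
  P <- .pair_projector(n_spins(system), pair, "S0")
  Re(sum(diag(state$op %*% P)))
}

#' @rdname singlet_population
#' @export
triplet_populations <- function(state, system, pair = c(1, 2)) {
  n <- n_spins(system)
  c(Tp = Re(sum(diag(state$op %*% .pair_projector(n, pair, "Tp")))),
    T0 = Re(sum(diag(state$op %*% .pair_projector(n, pair, "T0")))),
    Tm = Re(sum(diag(state$op %*% .pair_projector(n, pair, "Tm")))))
}

#' Scalar order of a spin pair
#'
#' `<I1.I2>`: -3/4 for a pure singlet, +1/4 for any pure triplet state.
#'
#' @inheritParams singlet_population
#' @return Numeric scalar.
#' @export
scalar_order <- function(state, system, pair = c(1, 2)) {
  ops <- spin_operators(system)
  i <- pair[1]; k <- pair[2]
  dot <- ops$x[[i]] %*% ops$x[[k]] + ops$y[[i]] %*% ops$y[[k]] +
    ops$z[[i]] %*% ops$z[[k]]
  Re(sum(diag(state$op %*% dot)))
}
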