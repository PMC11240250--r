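# The purge + S2hM pulse sequence: echo-train conversion of proton singlet
# order into 13C z-magnetization, its transfer efficiency, and a grid
# optimizer for the sequence parameters.
#
# Layout (fixed by the sequence builder below):
#   [90(H)x purge] - [tau - 180(H)x - tau]^n1 - 90(C)x - 5*tau/4
#                  - [tau - 180(H)x - tau]^n2 - 90(C)y
# The echo spacing 2*tau is resonant with the singlet-triplet gap of the
# proton pair when tau ~= 1/(4 J_HH); each train then drives a pi/2
# rotation in the {S0, T0} subspace conditioned on the 13C state, and the
# inter-train interval sets the relative phase of the two conditioned
# rotations so that they compose into net 13C magnetization rather than a
# spin-correlated term.

#' S2hM sequence parameters
#'
#' @param tau Echo delay in seconds (> 0); each echo element is
#'   `tau - 180(1H) - tau`.
#' @param n1,n2 Repetition counts of the two echo trains (>= 1).
#' @param purge Apply the initial 1H pi/2 purge pulse? The purge moves
#'   contaminating `|T0>` population into the outer `|T+->` states, where
#'   it cannot cancel the singlet-derived signal.
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(tau = 15.7e-3, n1 = 7, n2 = 7, purge = TRUE) {
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (n1 < 1 || n2 < 1) stop("`n1` and `n2` must be >= 1", call. = FALSE)
  structure(list(tau = tau, n1 = as.integer(n1), n2 = as.integer(n2),
                 purge = isTRUE(purge)),
            class = "sequence_params")
}

# total 1H-evolution duration of the sequence (s); pulses are ideal
sequence_duration <- function(params) {
  (params$n1 + params$n2) * 2 * params$tau + 1.25 * params$tau
}

# check the supported topology: >= 2 protons, exactly one 13C
.check_s2hm_system <- function(system) {
  nH <- sum(system$isotopes == "1H")
  nC <- sum(system$isotopes == "13C")
  if (nH < 2 || nC != 1) {
    stop("unsupported spin topology for S2hM: need >= 2 1H spins and ",
         "exactly one 13C (got ", nH, " 1H, ", nC, " 13C)", call. = FALSE)
  }
  invisible(TRUE)
}

# run the sequence on a density operator given a precomputed spin context;
# returns the final operator matrix
.s2hm_operator <- function(rho, ctx, params) {
  ops <- ctx$ops
  iH <- which(ctx$system$isotopes == "1H")
  iC <- which(ctx$system$isotopes == "13C")
  Ud <- context_propagator(ctx, params$tau)
  piH <- .pulse_operator(ops, iH, pi, 0)
  Uecho <- Ud %*% piH %*% Ud
  if (params$purge) {
    rho <- .conj_by(rho, .pulse_operator(ops, iH, pi / 2, 0))
  }
  for (k in seq_len(params$n1)) rho <- .conj_by(rho, Uecho)
  rho <- .conj_by(rho, .pulse_operator(ops, iC, pi / 2, 0))
  rho <- .conj_by(rho, context_propagator(ctx, 1.25 * params$tau))
  for (k in seq_len(params$n2)) rho <- .conj_by(rho, Uecho)
  .conj_by(rho, .pulse_operator(ops, iC, pi / 2, pi / 2))
}

#' Apply the purge + S2hM sequence
#'
#' Applies the optional 1H purge pulse followed by the two S2hM echo
#' trains and the inter-train and terminal pulses (see the package
#' vignette for the layout and its derivation). Pulses are ideal
#' (instantaneous); all evolution is exact unitary propagation.
#'
#' @param state A [density_state()].
#' @param system The matching [spin_system()]; must contain at least two
#'   1H spins and exactly one 13C.
#' @param params A [sequence_params()].
#' @return The final [density_state()].
#' @seealso [transfer_efficiency()]
#' @export
s2hm <- function(state, system, params = sequence_params()) {
  stopifnot(inherits(state, "density_state"),
            inherits(params, "sequence_params"))
  .check_s2hm_system(system)
  ctx <- spin_context(system)
  state$op <- .s2hm_operator(state$op, ctx, params)
  state
}

#' Relaxation lifetimes
#'
#' @param t_singlet 1H singlet-order lifetime T_S in seconds. The default
#'   is a field-typical lifetime for the fumarate proton pair in D2O in
#'   the presence of the dissolved catalyst.
#' @param t1_carbon 13C longitudinal lifetime T1 in seconds.
#' @return An object of class `relaxation_params`.
#' @export
relaxation_params <- function(t_singlet = 18, t1_carbon = 50) {
  if (t_singlet <= 0 || t1_carbon <= 0) {
    stop("lifetimes must be > 0", call. = FALSE)
  }
  structure(list(t_singlet = t_singlet, t1_carbon = t1_carbon),
            class = "relaxation_params")
}

#' Singlet-to-13C transfer efficiency of the S2hM sequence
#'
#' Runs the sequence from the pure proton-singlet state and returns the
#' final 13C z-magnetization normalized so that 1 means complete
#' conversion of the singlet order into 13C polarization (for the singlet
#' initial state this normalization coincides with the unitary bound).
#'
#' Relaxation, if supplied, is applied as phenomenological exponential
#' damping: the transferred order decays with the 1H singlet lifetime
#' `T_S` over the sequence duration, and with the 13C `T1` over
#' `post_delay` after the transfer.
#'
#' @param system A [spin_system()] with >= 2 1H and exactly one 13C.
#' @param params A [sequence_params()].
#' @param relaxation Optional [relaxation_params()].
#' @param post_delay Delay after the sequence in seconds (used only with
#'   `relaxation`).
#' @return Efficiency in `[-1, 1]`.
#' @examples
#' transfer_efficiency(fumarate_13c1(), sequence_params(tau = 15.7e-3))
#' @export
transfer_efficiency <- function(system, params = sequence_params(),
                                relaxation = NULL, post_delay = 0) {
  .check_s2hm_system(system)
  ctx <- spin_context(system)
  eff <- .transfer_efficiency_ctx(ctx, params)
  if (!is.null(relaxation)) {
    stopifnot(inherits(relaxation, "relaxation_params"))
    eff <- eff * exp(-sequence_duration(params) / relaxation$t_singlet) *
      exp(-post_delay / relaxation$t1_carbon)
  }
  eff
}

.transfer_efficiency_ctx <- function(ctx, params) {
  system <- ctx$system
  n <- n_spins(system)
  pair <- which(system$isotopes == "1H")[1:2]
  rho0 <- .pair_projector(n, pair, "S0") / (2^(n - 2))
  rho <- .s2hm_operator(rho0, ctx, params)
  iC <- which(system$isotopes == "13C")
  2 * Re(sum(diag(rho %*% ctx$ops$z[[iC]])))
}

#' Grid optimization of the S2hM parameters
#'
#' Exhaustive evaluation of [transfer_efficiency()] over a grid of echo
#' delays and train lengths. Ties are broken deterministically: smallest
#' `tau`, then smallest `n1 + n2`.
#'
#' @param system A [spin_system()].
#' @param tau_grid Vector of echo delays in seconds.
#' @param n1_grid,n2_grid Vectors of train repetition counts.
#' @param relaxation Optional [relaxation_params()] passed through.
#' @return A list with `best` (a [sequence_params()]), `best_efficiency`,
#'   and `map` (data frame `tau`, `n1`, `n2`, `efficiency`).
#' @examples
#' \donttest{
#' opt <- optimize_sequence(fumarate_13c1(),
#'                          tau_grid = seq(5e-3, 30e-3, by = 1e-4))
#' opt$best$tau * 1000 # ~ 15.7 ms
#' }
#' @export
optimize_sequence <- function(system, tau_grid, n1_grid = 7, n2_grid = 7,
                              relaxation = NULL) {
  if (length(tau_grid) == 0 || length(n1_grid) == 0 ||
      length(n2_grid) == 0) {
    stop("grids must be non-empty", call. = FALSE)
  }
  .check_s2hm_system(system)
  ctx <- spin_context(system)
  grid <- expand.grid(tau = tau_grid, n1 = n1_grid, n2 = n2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  eff <- vapply(seq_len(nrow(grid)), function(i) {
    p <- sequence_params(grid$tau[i], grid$n1[i], grid$n2[i])
    e <- .transfer_efficiency_ctx(ctx, p)
    if (!is.null(relaxation)) {
      e <- e * exp(-sequence_duration(p) / relaxation$t_singlet)
    }
    e
  }, 0)
  grid$efficiency <- eff
  # deterministic tie-break: efficiencies equal to within 1e-12 count as
  # tied; then smallest tau, then smallest n1 + n2
  ord <- order(-round(grid$efficiency, 12), grid$tau, grid$n1 + grid$n2)
  best <- grid[ord[1], ]
  list(best = sequence_params(best$tau, best$n1, best$n2),
       best_efficiency = best$efficiency,
       map = grid)
}
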