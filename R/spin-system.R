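# Spin systems: isotopes, offsets, J-coupling network; product-basis
# operators and the rotating-frame Hamiltonian.

#' Define a spin system
#'
#' Spins are listed in a fixed order (the tensor-product basis order); each
#' has an isotope label and a rotating-frame offset. Couplings between
#' same-isotope spins enter the Hamiltonian as full scalar couplings
#' `2 pi J Ii.Ij` (strong coupling); couplings between different isotopes
#' are truncated to their secular part `2 pi J Iiz Ijz`, as appropriate for
#' a doubly rotating frame at high field.
#'
#' @param isotopes Character vector of isotope labels (`"1H"`, `"13C"`).
#' @param j_couplings Symmetric matrix of J couplings in Hz with zero
#'   diagonal; dimension equal to the number of spins.
#' @param offsets Rotating-frame offsets in Hz (default all zero).
#' @return An object of class `spin_system`.
#' @seealso [fumarate_13c1()]
#' @export
spin_system <- function(isotopes, j_couplings,
                        offsets = rep(0, length(isotopes))) {
  n <- length(isotopes)
  if (!all(isotopes %in% names(.gyromagnetic))) {
    stop("unknown isotope label(s): ",
         paste(setdiff(isotopes, names(.gyromagnetic)), collapse = ", "),
         call. = FALSE)
  }
  j_couplings <- as.matrix(j_couplings)
  if (!all(dim(j_couplings) == c(n, n))) {
    stop("`j_couplings` must be an n x n matrix", call. = FALSE)
  }
  if (max(abs(j_couplings - t(j_couplings))) > 1e-9) {
    stop("`j_couplings` must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(j_couplings)) > 0)) {
    stop("`j_couplings` must have a zero diagonal", call. = FALSE)
  }
  if (length(offsets) != n) {
    stop("`offsets` must match the number of spins", call. = FALSE)
  }
  structure(list(isotopes = isotopes, j = j_couplings,
                 offsets = as.numeric(offsets)),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system: %s>\n", paste(x$isotopes, collapse = "-")))
  cat("J couplings (Hz):\n")
  print(round(x$j, 3))
  invisible(x)
}

n_spins <- function(system) length(system$isotopes)

#' The three-spin system of (1-13C)fumarate
#'
#' Spins ordered (Ha, Hb, C1). The J-coupling network is read from the
#' fixture file `inst/extdata/fumarate_13c1.yaml`, which records the value
#' provenance.
#'
#' @return A [spin_system()].
#' @examples
#' fumarate_13c1()
#' @export
fumarate_13c1 <- function() {
  path <- system.file("extdata", "fumarate_13c1.yaml",
                      package = "phipchip", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  n <- length(cfg$isotopes)
  j <- matrix(0, n, n)
  for (cp in cfg$j_couplings) {
    i <- cp$pair[1]; k <- cp$pair[2]
    j[i, k] <- j[k, i] <- cp$value_hz
  }
  spin_system(unlist(cfg$isotopes), j)
}

# single-spin Pauli operators (spin-1/2)
.sigma <- list(
  x = matrix(c(0, 0.5, 0.5, 0), 2, 2),
  y = matrix(c(0, 0.5i, -0.5i, 0), 2, 2),
  z = matrix(c(0.5, 0, 0, -0.5), 2, 2)
)

# operator acting as `m` on spin i, identity elsewhere
.op1 <- function(n, i, m) {
  out <- if (i == 1) m else diag(2)
  for (k in 2:n) out <- kronecker(out, if (k == i) m else diag(2))
  if (n == 1) m else out
}

# full operator set for a system: lists Ix, Iy, Iz indexed by spin
spin_operators <- function(system) {
  n <- n_spins(system)
  list(
    x = lapply(seq_len(n), function(i) .op1(n, i, .sigma$x)),
    y = lapply(seq_len(n), function(i) .op1(n, i, .sigma$y)),
    z = lapply(seq_len(n), function(i) .op1(n, i, .sigma$z))
  )
}

# rotating-frame Hamiltonian in rad/s
spin_hamiltonian <- function(system, ops = spin_operators(system)) {
  n <- n_spins(system)
  dim <- 2^n
  H <- matrix(0 + 0i, dim, dim)
  for (i in seq_len(n)) {
    if (system$offsets[i] != 0) {
      H <- H + 2 * pi * system$offsets[i] * ops$z[[i]]
    }
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (k in (i + 1):n) {
      Jik <- system$j[i, k]
      if (Jik == 0) next
      if (system$isotopes[i] == system$isotopes[k]) {
        H <- H + 2 * pi * Jik * (ops$x[[i]] %*% ops$x[[k]] +
                                 ops$y[[i]] %*% ops$y[[k]] +
                                 ops$z[[i]] %*% ops$z[[k]])
      } else {
        H <- H + 2 * pi * Jik * (ops$z[[i]] %*% ops$z[[k]])
      }
    }
  }
  H
}

# cached context (operators + Hamiltonian eigendecomposition) so repeated
# propagation over a tau grid stays cheap
spin_context <- function(system) {
  ops <- spin_operators(system)
  H <- spin_hamiltonian(system, ops)
  eig <- eigen(H, symmetric = TRUE)
  list(system = system, ops = ops, H = H,
       evals = eig$values, evecs = eig$vectors)
}

# unitary propagator for free evolution of duration t (s)
context_propagator <- function(ctx, t) {
  ctx$evecs %*% (exp(-1i * ctx$evals * t) * Conj(t(ctx$evecs)))
}
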