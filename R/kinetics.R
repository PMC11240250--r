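# Hydrogenation kinetics coupled to membrane H2 supply, integrated along
# the fluid path in residence-time coordinates; the detection chamber is a
# well-mixed tank solved to steady state.

#' Kinetic parameters for on-chip hydrogenation
#'
#' Rate law: first-order catalyst activation
#' `d[cat*]/dt = k_act ([cat]_tot - [cat*])`, bilinear hydrogenation
#' `substrate + H2 -> product` at rate `k_hyd [cat*] [A] [H2]`, and
#' over-reduction `product + H2 -> over-reduced` at rate
#' `k_over [cat*] [P] [H2]`. One H2 is consumed per event.
#'
#' The default constants place the model in the mixed supply/reaction
#' regime of the original single-gas-channel device, where improving the
#' hydrogen supply is the most effective lever on yield.
#'
#' @param k_act Catalyst activation rate, 1/s.
#' @param k_hyd Effective bimolecular hydrogenation constant, 1/(mM s).
#' @param k_over Over-reduction constant, 1/(mM s).
#' @param catalyst_total Total catalyst concentration, mM (zero disables
#'   the reaction entirely).
#' @param substrate_inlet Substrate concentration at the inlet, mM.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_act = 0.05, k_hyd = 1e-4, k_over = 5e-6,
                           catalyst_total = 5, substrate_inlet = 20) {
  vals <- c(k_act = k_act, k_hyd = k_hyd, k_over = k_over,
            catalyst_total = catalyst_total,
            substrate_inlet = substrate_inlet)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("kinetic parameters must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(vals), class = "kinetic_params")
}

#' Kinetic defaults for the fumarate trans-hydrogenation
#'
#' The conditions of the hyperpolarized-fumarate runs: 100 mM
#' acetylenedicarboxylate precursor, 6 mM ruthenium catalyst, and a slow
#' effective trans-hydrogenation constant sized so the chamber yields a
#' few mM of fumarate at the working flow rates.
#'
#' @param ... Overrides passed to [kinetic_params()].
#' @return A [kinetic_params()].
#' @export
fumarate_kinetics <- function(...) {
  defaults <- list(k_act = 0.05, k_hyd = 5e-6, k_over = 2.5e-7,
                   catalyst_total = 6, substrate_inlet = 100)
  do.call(kinetic_params, utils::modifyList(defaults, list(...)))
}

# reaction right-hand side shared by the plug-flow and chamber solvers;
# y = (cat_act, substrate, product, overred, h2), mM
.reaction_rates <- function(y, kin) {
  r_hyd <- kin$k_hyd * y[1] * y[2] * y[5]
  r_over <- kin$k_over * y[1] * y[3] * y[5]
  c(kin$k_act * (kin$catalyst_total - y[1]),
    -r_hyd,
    r_hyd - r_over,
    r_over,
    -r_hyd - r_over)
}

#' Coupled H2 uptake and hydrogenation along the fluid path
#'
#' Integrates catalyst activation, substrate hydrogenation, over-reduction
#' and the H2 balance (membrane source minus reactive consumption) along
#' the path in residence-time coordinates with an adaptive stiff solver
#' (lsoda, atol 1e-9 mM, rtol 1e-8), then solves the well-mixed detection
#' chamber to steady state.
#'
#' @param geometry A [chip_geometry()].
#' @param flow_rate Liquid flow rate in uL/min.
#' @param pressure H2 pressure in bar.
#' @param transport A calibrated [transport_params()].
#' @param kinetics A [kinetic_params()].
#' @param points_per_segment Profile resolution per segment.
#' @return A list of class `hydrogenation_profile` with elements `profile`
#'   (data frame: `time_s`, `segment`, `cat_act_mM`, `substrate_mM`,
#'   `product_mM`, `overred_mM`, `c_h2_mM`) and `chamber` (named numeric,
#'   steady-state chamber concentrations in mM).
#' @export
hydrogenation_profile <- function(geometry, flow_rate, pressure,
                                  transport, kinetics,
                                  points_per_segment = 50) {
  stopifnot(inherits(geometry, "chip_geometry"),
            inherits(kinetics, "kinetic_params"))
  if (!is.numeric(flow_rate) || flow_rate <= 0) {
    stop("`flow_rate` must be positive", call. = FALSE)
  }
  c_sat <- saturation_concentration(pressure, transport)
  y <- c(cat_act = 0, substrate = kinetics$substrate_inlet,
         product = 0, overred = 0, h2 = 0)
  t0 <- 0
  rows <- list()
  for (i in seq_along(geometry$segments)) {
    seg <- geometry$segments[[i]]
    kla <- mass_transfer_coefficient(seg, transport)
    t_seg <- segment_volume(seg) / flow_rate * 60
    rhs <- function(t, y, p) {
      dy <- .reaction_rates(y, kinetics)
      dy[5] <- dy[5] + kla * (c_sat - y[5])
      list(dy)
    }
    times <- seq(0, t_seg, length.out = max(points_per_segment, 2))
    sol <- deSolve::ode(y, times, rhs, NULL, method = "lsoda",
                        atol = 1e-9, rtol = 1e-8)
    if (attr(sol, "istate")[1] < 0) {
      stop("stiff integration failed in segment ", i,
           " (lsoda istate ", attr(sol, "istate")[1], ")", call. = FALSE)
    }
    rows[[i]] <- data.frame(
      time_s = t0 + sol[, "time"], segment = i,
      cat_act_mM = sol[, "cat_act"], substrate_mM = sol[, "substrate"],
      product_mM = sol[, "product"], overred_mM = sol[, "overred"],
      c_h2_mM = sol[, "h2"]
    )
    y <- sol[nrow(sol), -1]
    t0 <- t0 + t_seg
  }
  chamber <- .chamber_steady_state(y, geometry, flow_rate, kinetics)
  profile <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(profile = profile, chamber = chamber,
                 inlet = c(cat_act = 0,
                           substrate = kinetics$substrate_inlet,
                           product = 0, overred = 0, h2 = 0),
                 c_sat = c_sat, flow_rate = flow_rate,
                 pressure = pressure, label = geometry$label),
            class = "hydrogenation_profile")
}

# steady state of the well-mixed chamber fed by the last segment: integrate
# the transient tank balance until the state stops changing
.chamber_steady_state <- function(feed, geometry, flow_rate, kinetics) {
  if (geometry$chamber_volume <= 0) return(feed)
  tau_c <- geometry$chamber_volume / flow_rate * 60
  rhs <- function(t, y, p) {
    list((feed - y) / tau_c + .reaction_rates(y, kinetics))
  }
  t_end <- 60 * tau_c
  sol <- deSolve::ode(feed, c(0, t_end), rhs, NULL, method = "lsoda",
                      atol = 1e-9, rtol = 1e-8)
  if (attr(sol, "istate")[1] < 0) {
    stop("stiff integration failed in chamber steady-state solve",
         call. = FALSE)
  }
  y <- sol[nrow(sol), -1]
  names(y) <- names(feed)
  y
}

#' Compare hypothetical improvement scenarios
#'
#' Runs [hydrogenation_profile()] over a set of flow rates under base
#' parameters and under one modified scenario, and returns the ratio of the
#' maximum-over-flow-rates chamber product concentrations.
#'
#' Scenarios: `"rates_x2"` doubles all rate constants (approximating a
#' 10 degC temperature increase), `"pressure_x2"` doubles the H2 supply
#' pressure, `"activation_x10"` multiplies the catalyst activation rate by
#' ten (an easier-to-remove protecting group), `"none"` is the null
#' scenario.
#'
#' @param geometry A [chip_geometry()].
#' @param flow_rates Flow rates (uL/min) over which the maximum is taken.
#' @param pressure Base H2 pressure in bar.
#' @param transport A calibrated [transport_params()].
#' @param kinetics A [kinetic_params()].
#' @param scenario One of `"none"`, `"rates_x2"`, `"pressure_x2"`,
#'   `"activation_x10"`.
#' @return A list with `ratio` (scenario / base maximum product), and the
#'   two per-flow product vectors `base` and `scenario`.
#' @export
scenario_compare <- function(geometry, flow_rates = seq(2, 10, by = 2),
                             pressure = 5,
                             transport, kinetics = kinetic_params(),
                             scenario = c("none", "rates_x2",
                                          "pressure_x2",
                                          "activation_x10")) {
  scenario <- match.arg(scenario)
  prod_max <- function(kin, p) {
    vapply(flow_rates, function(q) {
      hydrogenation_profile(geometry, q, p, transport, kin)$chamber["product"]
    }, 0)
  }
  base <- prod_max(kinetics, pressure)
  kin2 <- kinetics
  p2 <- pressure
  if (scenario == "rates_x2") {
    kin2$k_act <- 2 * kin2$k_act
    kin2$k_hyd <- 2 * kin2$k_hyd
    kin2$k_over <- 2 * kin2$k_over
  } else if (scenario == "pressure_x2") {
    p2 <- 2 * pressure
  } else if (scenario == "activation_x10") {
    kin2$k_act <- 10 * kin2$k_act
  }
  scen <- if (scenario == "none") base else prod_max(kin2, p2)
  list(ratio = max(scen) / max(base), base = base, scenario = scen,
       which = scenario)
}
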