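# Synthetic-spectrum generators: Lorentzian lines plus i.i.d. Gaussian
# noise, deterministic under an explicit seed. Ground truth is always
# returned alongside the data so downstream stages can be tested by
# parameter recovery.

#' Peak specification for the spectrum generator
#'
#' Peak areas are proportional to `concentration * protons`, so spectra
#' generated from known concentrations round-trip through the
#' quantification chain.
#'
#' @param center Peak position in ppm.
#' @param concentration Species concentration in mM (>= 0).
#' @param protons Number of contributing nuclei (>= 1).
#' @param linewidth Full width at half maximum in Hz (> 0).
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, concentration, protons = 1, linewidth = 1) {
  if (linewidth <= 0) stop("`linewidth` must be > 0", call. = FALSE)
  if (concentration < 0) stop("`concentration` must be >= 0", call. = FALSE)
  if (protons < 1) stop("`protons` must be >= 1", call. = FALSE)
  structure(list(center = center, concentration = concentration,
                 protons = protons, linewidth = linewidth),
            class = "peak_spec")
}

#' Generator configuration
#'
#' @param seed Integer seed; every generator call is deterministic for a
#'   fixed seed and leaves the global RNG untouched.
#' @param noise_sigma Standard deviation of the i.i.d. Gaussian noise per
#'   point, in intensity units.
#' @param frequency Spectrometer frequency of the observed nucleus in MHz
#'   (converts linewidths from Hz to ppm).
#' @param points Number of axis points (>= 64).
#' @param sweep Length-2 ppm range `c(low, high)`; must be non-degenerate.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1, noise_sigma = 0, frequency = 500,
                             points = 8192, sweep = c(0, 10)) {
  if (points < 64) stop("`points` must be >= 64", call. = FALSE)
  if (length(sweep) != 2 || sweep[2] <= sweep[1]) {
    stop("`sweep` must be an increasing ppm range", call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (frequency <= 0) stop("`frequency` must be > 0", call. = FALSE)
  structure(list(seed = as.integer(seed), noise_sigma = noise_sigma,
                 frequency = frequency, points = as.integer(points),
                 sweep = as.numeric(sweep)),
            class = "generator_config")
}

# run `expr` under a private RNG stream, restoring the global state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic 1-D spectrum
#'
#' Sum of Lorentzian lines (area proportional to concentration x protons)
#' plus i.i.d. Gaussian noise. The ppm axis is descending, following NMR
#' display convention.
#'
#' @param peaks List of [peak_spec()]s (a single `peak_spec` is accepted).
#' @param config A [generator_config()].
#' @param nucleus Isotope label stored in the spectrum.
#' @param n_scans Scan count stored in the spectrum (the generator does
#'   not rescale noise with scans; set `noise_sigma` accordingly).
#' @return An [nmr_spectrum()] with the ground-truth peak list in
#'   `metadata$truth`.
#' @examples
#' sp <- synth_spectrum(peak_spec(4.55, 10, protons = 2),
#'                      generator_config(seed = 7, noise_sigma = 0.01))
#' @export
synth_spectrum <- function(peaks, config = generator_config(),
                           nucleus = "1H", n_scans = 1) {
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  stopifnot(all(vapply(peaks, inherits, TRUE, "peak_spec")),
            inherits(config, "generator_config"))
  ppm <- seq(config$sweep[2], config$sweep[1], length.out = config$points)
  y <- numeric(config$points)
  for (pk in peaks) {
    if (pk$center < config$sweep[1] || pk$center > config$sweep[2]) {
      stop("peak at ", pk$center, " ppm lies outside the sweep range",
           call. = FALSE)
    }
    hw <- pk$linewidth / config$frequency / 2 # HWHM in ppm
    area <- pk$concentration * pk$protons
    y <- y + area / pi * hw / ((ppm - pk$center)^2 + hw^2)
  }
  if (config$noise_sigma > 0) {
    y <- y + .with_seed(config$seed,
                        stats::rnorm(config$points, 0, config$noise_sigma))
  }
  truth <- lapply(peaks, unclass)
  nmr_spectrum(ppm, y, nucleus = nucleus, n_scans = n_scans,
               metadata = list(truth = truth,
                               noise_sigma = config$noise_sigma,
                               seed = config$seed))
}

#' Emulate the H2-uptake NMR measurement
#'
#' Runs the transport model at each flow rate and renders the chamber H2
#' concentration as a 1H spectrum containing the dissolved-H2 peak at
#' 4.55 ppm and a sodium-acetate concentration standard at 1.90 ppm.
#'
#' @param geometry A [chip_geometry()].
#' @param params A calibrated [transport_params()].
#' @param flow_rates Flow rates in uL/min.
#' @param pressure H2 pressure in bar.
#' @param noise_sigma Gaussian noise sigma per point.
#' @param seed Integer seed (each flow rate draws an independent
#'   sub-stream).
#' @param ref_concentration Acetate standard concentration in mM.
#' @return A list with `spectra` (list of [nmr_spectrum()]) and `truth`
#'   (data frame `flow_uL_min`, `c_h2_mM`).
#' @export
synth_uptake_experiment <- function(geometry, params, flow_rates,
                                    pressure = 5, noise_sigma = 0,
                                    seed = 1, ref_concentration = 20) {
  conc <- vapply(flow_rates, function(q) {
    h2_profile(geometry, q, pressure, params)$chamber_concentration
  }, 0)
  spectra <- lapply(seq_along(flow_rates), function(i) {
    cfg <- generator_config(seed = seed + 1000L * i,
                            noise_sigma = noise_sigma,
                            frequency = 500, points = 8192,
                            sweep = c(0, 10))
    synth_spectrum(list(
      peak_spec(4.55, conc[i], protons = .molecule_protons[["h2"]],
                linewidth = 5),
      peak_spec(1.90, ref_concentration,
                protons = .molecule_protons[["sodium_acetate"]],
                linewidth = 5)
    ), cfg, nucleus = "1H")
  })
  list(spectra = spectra,
       truth = data.frame(flow_uL_min = flow_rates, c_h2_mM = conc))
}

#' Quantify H2 from an uptake-emulation spectrum
#'
#' Convenience inverse of [synth_uptake_experiment()]: integrates the H2
#' and acetate peaks and applies [concentration_by_reference()].
#'
#' @param spectrum An [nmr_spectrum()] from [synth_uptake_experiment()].
#' @param ref_concentration Acetate standard concentration in mM.
#' @return Estimated H2 concentration in mM.
#' @export
quantify_h2 <- function(spectrum, ref_concentration = 20) {
  a_h2 <- integrate_peak(spectrum, peak_region(4.55, 0.35))
  a_ref <- integrate_peak(spectrum, peak_region(1.90, 0.35))
  concentration_by_reference(a_h2, a_ref, ref_concentration,
                             analyte_protons = .molecule_protons[["h2"]],
                             ref_protons =
                               .molecule_protons[["sodium_acetate"]])
}

#' Emulate the hyperpolarized 13C flow sweep
#'
#' Per flow rate: the hydrogenation model yields the chamber product
#' concentration; the spin model provides the S2hM transfer efficiency;
#' singlet relaxation during transit damps the available order by
#' `exp(-t_transit / T_S)`. The resulting signal amplitude is rendered as
#' a single-scan 13C spectrum of the fumarate carboxylate resonance with
#' Gaussian noise.
#'
#' @param geometry A [chip_geometry()].
#' @param transport A calibrated [transport_params()].
#' @param kinetics A [kinetic_params()].
#' @param system A [spin_system()] (default [fumarate_13c1()]).
#' @param seq_params A [sequence_params()].
#' @param relaxation A [relaxation_params()].
#' @param flow_rates Flow rates in uL/min.
#' @param pressure H2 pressure in bar.
#' @param noise_sigma Gaussian noise sigma per point.
#' @param seed Integer seed.
#' @param yield_override Optional fixed product concentration in mM
#'   (bypasses the hydrogenation model; used for limiting-case studies).
#' @return A list with `spectra` and `truth` (data frame `flow_uL_min`,
#'   `product_mM`, `transit_s`, `relax_factor`, `efficiency`,
#'   `amplitude_mM`).
#' @export
synth_flow_sweep_13c <- function(geometry, transport,
                                 kinetics = fumarate_kinetics(),
                                 system = fumarate_13c1(),
                                 seq_params = sequence_params(),
                                 relaxation = relaxation_params(),
                                 flow_rates = seq(2, 16, by = 2),
                                 pressure = 6, noise_sigma = 0.04,
                                 seed = 1, yield_override = NULL) {
  eff <- transfer_efficiency(system, seq_params)
  rows <- lapply(flow_rates, function(q) {
    prod_mM <- if (is.null(yield_override)) {
      hydrogenation_profile(geometry, q, pressure, transport,
                            kinetics)$chamber[["product"]]
    } else {
      yield_override
    }
    t_transit <- residence_time(geometry, q)
    relax <- exp(-t_transit / relaxation$t_singlet)
    data.frame(flow_uL_min = q, product_mM = prod_mM,
               transit_s = t_transit, relax_factor = relax,
               efficiency = eff,
               amplitude_mM = prod_mM * relax * abs(eff))
  })
  truth <- do.call(rbind, rows)
  spectra <- lapply(seq_along(flow_rates), function(i) {
    cfg <- generator_config(seed = seed + 1000L * i,
                            noise_sigma = noise_sigma,
                            frequency = 125.7, points = 8192,
                            sweep = c(100, 300))
    synth_spectrum(peak_spec(175.4, truth$amplitude_mM[i], protons = 1,
                             linewidth = 15),
                   cfg, nucleus = "13C")
  })
  list(spectra = spectra, truth = truth)
}

#' Emulate a multi-scan thermal 13C reference spectrum
#'
#' @param concentration Reference concentration in mM (e.g. 1 M glucose =
#'   1000).
#' @param n_scans Number of co-added scans.
#' @param peak_height_sigma Target peak height in units of the per-point
#'   noise sigma (i.e. the SNR the spectrum is built to have).
#' @param noise_sigma Noise sigma.
#' @param seed Integer seed.
#' @param center Peak position in ppm.
#' @param linewidth Line width in Hz.
#' @return An [nmr_spectrum()].
#' @export
synth_thermal_reference_13c <- function(concentration = 1000, n_scans = 32,
                                        peak_height_sigma = 2,
                                        noise_sigma = 0.01, seed = 1,
                                        center = 96.8, linewidth = 15) {
  cfg <- generator_config(seed = seed, noise_sigma = noise_sigma,
                          frequency = 125.7, points = 8192,
                          sweep = c(0, 200))
  # choose the concentration->intensity scale so the rendered peak height
  # equals peak_height_sigma * noise_sigma
  hw_ppm <- linewidth / cfg$frequency / 2
  scale <- peak_height_sigma * noise_sigma * pi * hw_ppm / concentration
  sp <- synth_spectrum(peak_spec(center, concentration * scale,
                                 protons = 1, linewidth = linewidth),
                       cfg, nucleus = "13C", n_scans = n_scans)
  sp$metadata$concentration_mM <- concentration
  sp
}
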