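# NMR quantification arithmetic: peak areas, concentration referencing,
# SNR, enhancement factor, thermal polarization, percent polarization and
# percent yield.

#' Integrate a peak over a spectral region
#'
#' Trapezoidal integral of the intensity over the region after subtracting
#' a linear baseline drawn through the region edges (each edge value is
#' the mean of the outermost three points, which de-weights noise on the
#' anchors).
#'
#' @param spectrum An [nmr_spectrum()].
#' @param region A [peak_region()].
#' @return Peak area in intensity x ppm units (positive for an upright
#'   peak on a flat baseline).
#' @export
integrate_peak <- function(spectrum, region) {
  stopifnot(inherits(spectrum, "nmr_spectrum"),
            inherits(region, "peak_region"))
  idx <- .region_indices(spectrum, region)
  if (length(idx) < 4) {
    stop("region does not overlap the spectrum axis (or too few points)",
         call. = FALSE)
  }
  x <- spectrum$ppm[idx]
  y <- spectrum$intensity[idx]
  m <- min(3L, floor(length(idx) / 2))
  x_lo <- mean(x[seq_len(m)]); y_lo <- mean(y[seq_len(m)])
  x_hi <- mean(x[seq(length(x) - m + 1, length(x))])
  y_hi <- mean(y[seq(length(y) - m + 1, length(y))])
  slope <- if (x_hi == x_lo) 0 else (y_hi - y_lo) / (x_hi - x_lo)
  base <- y_lo + slope * (x - x_lo)
  yc <- y - base
  # trapezoid; axis may be descending
  area <- sum(diff(x) * (yc[-1] + yc[-length(yc)]) / 2)
  abs_sign <- if (x[length(x)] < x[1]) -1 else 1
  area * abs_sign
}

#' Concentration from an internal reference
#'
#' `conc = ref_conc * (analyte_area / ref_area) * (ref_protons /
#' analyte_protons)` — area referencing that accounts for the different
#' numbers of contributing nuclei (e.g. the 15 Cp* protons of the
#' catalyst vs the 2 vinylic protons of fumarate).
#'
#' @param analyte_area,ref_area Peak areas (same units); `ref_area > 0`.
#' @param ref_concentration Reference concentration in mM.
#' @param analyte_protons,ref_protons Contributing nuclei counts (>= 1).
#' @return Analyte concentration in mM.
#' @examples
#' concentration_by_reference(1, 1, 6, 2, 2) # 6 mM
#' @export
concentration_by_reference <- function(analyte_area, ref_area,
                                       ref_concentration,
                                       analyte_protons, ref_protons) {
  if (ref_area <= 0) stop("`ref_area` must be > 0", call. = FALSE)
  if (analyte_protons < 1 || ref_protons < 1) {
    stop("proton counts must be >= 1", call. = FALSE)
  }
  ref_concentration * (analyte_area / ref_area) *
    (ref_protons / analyte_protons)
}

#' Signal-to-noise ratio of a peak
#'
#' Peak maximum in the signal region divided by the root-mean-square
#' residual in a signal-free noise region, both after subtracting the
#' linear baseline fitted to the noise region.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param signal_region,noise_region Disjoint [peak_region()]s.
#' @return SNR (dimensionless).
#' @export
snr <- function(spectrum, signal_region, noise_region) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (abs(signal_region$center - noise_region$center) <
      signal_region$half_width + noise_region$half_width) {
    stop("signal and noise regions must be disjoint", call. = FALSE)
  }
  i_sig <- .region_indices(spectrum, signal_region)
  i_noi <- .region_indices(spectrum, noise_region)
  if (length(i_sig) < 2 || length(i_noi) < 4) {
    stop("regions must overlap the spectrum axis", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, spectrum$ppm[i_noi]),
                       spectrum$intensity[i_noi])
  rms <- sqrt(mean(fit$residuals^2))
  if (rms == 0) stop("noise region has zero rms noise", call. = FALSE)
  baseline_at <- function(x) fit$coefficients[1] + fit$coefficients[2] * x
  peak <- max(spectrum$intensity[i_sig] - baseline_at(spectrum$ppm[i_sig]))
  peak / rms
}

#' Signal enhancement factor
#'
#' Hyperpolarized signal per scan and per spin relative to the thermal
#' reference: the reference SNR is reduced to a single scan by the
#' square-root-of-N averaging law, and the concentration difference is
#' divided out.
#'
#' @param snr_hyper Single-scan SNR of the hyperpolarized spectrum.
#' @param snr_ref SNR of the thermal reference spectrum.
#' @param n_scans_ref Number of scans averaged into the reference.
#' @param conc_hyper,conc_ref Sample concentrations in mM.
#' @return Dimensionless enhancement factor.
#' @examples
#' enhancement_factor(9, 2, 32, 3, 1000) # ~ 8.49e3
#' @export
enhancement_factor <- function(snr_hyper, snr_ref, n_scans_ref,
                               conc_hyper, conc_ref) {
  vals <- c(snr_hyper, snr_ref, n_scans_ref, conc_hyper, conc_ref)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all enhancement inputs must be > 0", call. = FALSE)
  }
  (snr_hyper / (snr_ref / sqrt(n_scans_ref))) * (conc_ref / conc_hyper)
}

#' Thermal equilibrium polarization
#'
#' `tanh(hbar gamma B0 / (2 kB T))` — the Boltzmann polarization of a
#' spin-1/2 isotope at field `B0` and temperature `T`.
#'
#' @param isotope Isotope label (see [gyromagnetic_ratio()]).
#' @param field Magnetic field in T.
#' @param temperature Temperature in K.
#' @return Polarization as a dimensionless fraction.
#' @examples
#' thermal_polarization("13C", 11.7, 298) # ~ 1.01e-5
#' @export
thermal_polarization <- function(isotope, field, temperature) {
  if (field <= 0 || temperature <= 0) {
    stop("`field` and `temperature` must be > 0", call. = FALSE)
  }
  g <- abs(gyromagnetic_ratio(isotope))
  tanh(.const$hbar * g * field / (2 * .const$kB * temperature))
}

#' Percent polarization from enhancement and thermal level
#'
#' @param enhancement Enhancement factor (> 0).
#' @param thermal Thermal polarization fraction (> 0).
#' @return Polarization in percent.
#' @examples
#' percent_polarization(8485, thermal_polarization("13C", 11.7, 298)) # ~8.5
#' @export
percent_polarization <- function(enhancement, thermal) {
  if (enhancement <= 0 || thermal <= 0) {
    stop("inputs must be > 0", call. = FALSE)
  }
  100 * enhancement * thermal
}

#' Percent reaction yield
#'
#' @param product Product concentration in mM (>= 0).
#' @param precursor Precursor concentration in mM (> 0).
#' @return Yield in percent.
#' @examples
#' percent_yield(4.9, 20) # 24.5
#' @export
percent_yield <- function(product, precursor) {
  if (precursor <= 0) stop("`precursor` must be > 0", call. = FALSE)
  if (product < 0) stop("`product` must be >= 0", call. = FALSE)
  100 * product / precursor
}
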