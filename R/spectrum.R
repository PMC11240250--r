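# 1-D NMR spectrum container and peak regions.

#' 1-D NMR spectrum
#'
#' @param ppm Chemical-shift axis in ppm (monotone; descending allowed, as
#'   customary for NMR display).
#' @param intensity Real intensities, same length as `ppm`.
#' @param nucleus Isotope label, e.g. `"1H"`.
#' @param n_scans Number of co-added scans (>= 1).
#' @param metadata Free-form named list (field strength, temperature,
#'   sample concentrations, ...).
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, nucleus = "1H", n_scans = 1,
                         metadata = list()) {
  if (length(ppm) != length(intensity)) {
    stop("`ppm` and `intensity` must have equal length", call. = FALSE)
  }
  if (length(ppm) < 2) stop("spectrum needs >= 2 points", call. = FALSE)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) {
    stop("`ppm` must be strictly monotone", call. = FALSE)
  }
  if (n_scans < 1) stop("`n_scans` must be >= 1", call. = FALSE)
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 nucleus = nucleus, n_scans = as.integer(n_scans),
                 metadata = metadata),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum: %s, %d points, %.2f..%.2f ppm, %d scan(s)>\n",
              x$nucleus, length(x$ppm), max(x$ppm), min(x$ppm), x$n_scans))
  invisible(x)
}

#' Spectral region around a peak
#'
#' @param center Region center in ppm.
#' @param half_width Half-width in ppm (> 0).
#' @return An object of class `peak_region`.
#' @export
peak_region <- function(center, half_width) {
  if (half_width <= 0) stop("`half_width` must be > 0", call. = FALSE)
  structure(list(center = center, half_width = half_width),
            class = "peak_region")
}

# indices of the spectrum inside a region, in axis order
.region_indices <- function(spectrum, region) {
  which(spectrum$ppm >= region$center - region$half_width &
        spectrum$ppm <= region$center + region$half_width)
}
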