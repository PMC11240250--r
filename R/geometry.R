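# Chip geometry: channel segments, derived volumes, residence times,
# membrane contact areas. Public units: mm, uL, uL/min; time in s.

#' Channel segment of a microfluidic chip
#'
#' A straight (or serpentine, taken at its unrolled length) channel segment
#' of rectangular cross-section. A segment may be in diffusive contact with
#' one or two gas channels through a gas-permeable membrane bridge.
#'
#' @param length Segment length in mm.
#' @param width Channel width in mm.
#' @param depth Channel depth in mm.
#' @param membrane_contact_width Width of the membrane strip in diffusive
#'   contact with the liquid, in mm; defaults to the channel width. May be
#'   zero for membrane-free segments.
#' @param membrane_thickness Effective membrane diffusion path in mm. For a
#'   bridge-type membrane lying across the wall separating the liquid and
#'   gas channels this is the lateral bridge distance, not the sheet
#'   thickness.
#' @param n_gas_sides Number of flanking gas channels (0, 1 or 2).
#' @return An object of class `channel_segment`.
#' @examples
#' channel_segment(30, 0.3, 0.5, n_gas_sides = 2)
#' @export
channel_segment <- function(length, width, depth,
                            membrane_contact_width = width,
                            membrane_thickness = 0.5,
                            n_gas_sides = 0) {
  for (nm in c("length", "width", "depth", "membrane_thickness")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid geometry: `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (!is.numeric(membrane_contact_width) || membrane_contact_width < 0) {
    stop("invalid geometry: `membrane_contact_width` must be >= 0",
         call. = FALSE)
  }
  if (membrane_contact_width > width + 1e-12) {
    stop("invalid geometry: membrane contact cannot exceed channel width",
         call. = FALSE)
  }
  if (!n_gas_sides %in% c(0L, 1L, 2L)) {
    stop("invalid geometry: `n_gas_sides` must be 0, 1 or 2", call. = FALSE)
  }
  structure(
    list(length = length, width = width, depth = depth,
         membrane_contact_width = membrane_contact_width,
         membrane_thickness = membrane_thickness,
         n_gas_sides = as.integer(n_gas_sides)),
    class = "channel_segment"
  )
}

#' Chip geometry: an ordered fluid path plus a detection chamber
#'
#' Segment order defines the fluid path from the inlet to the detection
#' chamber. The chamber is treated by the transport solver as a well-mixed
#' volume with no membrane contact of its own.
#'
#' @param segments List of [channel_segment()] objects (may be empty).
#' @param chamber_volume Detection-chamber volume in uL.
#' @param label Free-text label, e.g. `"beta"`.
#' @return An object of class `chip_geometry`.
#' @seealso [beta_chip()], [alpha_chip()], [total_volume()]
#' @export
chip_geometry <- function(segments, chamber_volume, label = "") {
  if (inherits(segments, "channel_segment")) segments <- list(segments)
  if (!is.list(segments) || !all(vapply(segments, inherits, TRUE,
                                        "channel_segment"))) {
    stop("`segments` must be a list of channel_segment objects",
         call. = FALSE)
  }
  if (!is.numeric(chamber_volume) || chamber_volume < 0) {
    stop("invalid geometry: `chamber_volume` must be >= 0", call. = FALSE)
  }
  geo <- structure(
    list(segments = segments, chamber_volume = chamber_volume,
         label = label),
    class = "chip_geometry"
  )
  if (total_volume(geo) <= 0) {
    stop("invalid geometry: total volume must be positive", call. = FALSE)
  }
  geo
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat(sprintf("<chip_geometry '%s'>\n", x$label))
  cat(sprintf("  segments: %d, path length %.2f mm\n",
              length(x$segments), path_length(x)))
  cat(sprintf("  total volume %.3f uL (chamber %.3f uL)\n",
              total_volume(x), x$chamber_volume))
  cat(sprintf("  membrane contact area %.2f mm^2\n",
              membrane_contact_area(x)))
  invisible(x)
}

segment_volume <- function(seg) seg$length * seg$width * seg$depth # mm^3 = uL

#' Total liquid volume of a chip
#'
#' Sum of segment volumes (length x width x depth) plus the chamber volume.
#'
#' @param geometry A [chip_geometry()].
#' @return Volume in uL.
#' @examples
#' total_volume(beta_chip()) # 7 uL
#' @export
total_volume <- function(geometry) {
  stopifnot(inherits(geometry, "chip_geometry"))
  sum(vapply(geometry$segments, segment_volume, 0)) + geometry$chamber_volume
}

#' Unrolled fluid-path length
#'
#' @param geometry A [chip_geometry()].
#' @return Path length in mm (segments only; the chamber is not a channel).
#' @export
path_length <- function(geometry) {
  stopifnot(inherits(geometry, "chip_geometry"))
  sum(vapply(geometry$segments, function(s) s$length, 0))
}

#' Membrane contact area of the fluid path
#'
#' @param geometry A [chip_geometry()].
#' @return Total membrane-liquid contact area in mm^2, counting each gas
#'   side separately.
#' @export
membrane_contact_area <- function(geometry) {
  stopifnot(inherits(geometry, "chip_geometry"))
  sum(vapply(geometry$segments,
             function(s) s$length * s$membrane_contact_width * s$n_gas_sides,
             0))
}

#' Plug-flow residence time up to a point on the fluid path
#'
#' Cumulative liquid volume up to the stated point divided by the
#' volumetric flow rate, assuming plug flow (flat velocity profile).
#'
#' @param geometry A [chip_geometry()].
#' @param flow_rate Volumetric flow rate in uL/min; must be positive.
#' @param up_to Either `"chamber"` (default; includes the chamber volume,
#'   i.e. the transit time to the chamber outlet) or a segment index, in
#'   which case the time to the outlet of that segment is returned.
#' @return Residence time in seconds.
#' @examples
#' residence_time(beta_chip(), 7)           # 60 s
#' residence_time(beta_chip(), 2) / 60      # 3.5 min
#' @export
residence_time <- function(geometry, flow_rate, up_to = "chamber") {
  stopifnot(inherits(geometry, "chip_geometry"))
  if (!is.numeric(flow_rate) || length(flow_rate) != 1L || flow_rate <= 0) {
    stop("`flow_rate` must be a single positive number (uL/min)",
         call. = FALSE)
  }
  seg_vols <- vapply(geometry$segments, segment_volume, 0)
  if (identical(up_to, "chamber")) {
    vol <- sum(seg_vols) + geometry$chamber_volume
  } else {
    i <- as.integer(up_to)
    if (is.na(i) || i < 1L || i > length(seg_vols)) {
      stop("`up_to` must be \"chamber\" or a valid segment index",
           call. = FALSE)
    }
    vol <- sum(seg_vols[seq_len(i)])
  }
  vol / flow_rate * 60
}

#' Reference chip fixtures
#'
#' Named geometry fixtures for the two chip designs studied in the package:
#' the original single-gas-channel design (`alpha_chip`) and the improved
#' design (`beta_chip`) in which the fluid path runs between two gas
#' channels and is extended by 30 % in length.
#'
#' The individual channel dimensions are documented plausible values
#' constrained to reproduce the published aggregates: the beta chip has a
#' 7 uL total volume with a 2.5 uL detection chamber, a fluid path 1.3x
#' the alpha path, and two gas-contact sides where the alpha chip has one.
#' Every dimension is an argument and may be overridden.
#'
#' @param channel_width,channel_depth Channel cross-section in mm.
#' @param path_length_mm Unrolled fluid-path length in mm.
#' @param membrane_thickness Effective membrane diffusion path in mm.
#' @param chamber_volume Detection-chamber volume in uL.
#' @return A [chip_geometry()].
#' @examples
#' total_volume(beta_chip())                      # 7
#' path_length(beta_chip()) / path_length(alpha_chip()) # 1.3
#' @export
beta_chip <- function(channel_width = 0.3, channel_depth = 0.5,
                      path_length_mm = 30, membrane_thickness = 0.5,
                      chamber_volume = 2.5) {
  chip_geometry(
    list(channel_segment(path_length_mm, channel_width, channel_depth,
                         membrane_contact_width = channel_width,
                         membrane_thickness = membrane_thickness,
                         n_gas_sides = 2)),
    chamber_volume = chamber_volume, label = "beta"
  )
}

#' @rdname beta_chip
#' @export
alpha_chip <- function(channel_width = 0.3, channel_depth = 0.5,
                       path_length_mm = 30 / 1.3, membrane_thickness = 0.5,
                       chamber_volume = 2.5) {
  chip_geometry(
    list(channel_segment(path_length_mm, channel_width, channel_depth,
                         membrane_contact_width = channel_width,
                         membrane_thickness = membrane_thickness,
                         n_gas_sides = 1)),
    chamber_volume = chamber_volume, label = "alpha"
  )
}
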