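# Plain-text spectrum IO: a minimal JCAMP-DX (XYPOINTS) dialect and
# two-column CSV with a JSON metadata sidecar.

#' Write a spectrum as JCAMP-DX
#'
#' Writes the uncompressed `##XYPOINTS=(XY..XY)` form, one `x, y` pair per
#' line — the simplest JCAMP-DX representation, readable by common NMR
#' software.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jcampdx <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  meta <- spectrum$metadata
  header <- c(
    "##TITLE=phipchip spectrum",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    sprintf("##.OBSERVE NUCLEUS=^%s", spectrum$nucleus),
    sprintf("##NSCANS=%d", spectrum$n_scans),
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    sprintf("##FIRSTX=%.10g", spectrum$ppm[1]),
    sprintf("##LASTX=%.10g", spectrum$ppm[length(spectrum$ppm)]),
    sprintf("##NPOINTS=%d", length(spectrum$ppm))
  )
  if (length(meta)) {
    header <- c(header, vapply(names(meta), function(k) {
      sprintf("##$%s=%s", toupper(k), format(meta[[k]]))
    }, ""))
  }
  body <- sprintf("%.10g, %.10g", spectrum$ppm, spectrum$intensity)
  writeLines(c(header, "##XYPOINTS=(XY..XY)", body, "##END="), path)
  invisible(path)
}

#' Read a JCAMP-DX spectrum
#'
#' Reads the `##XYPOINTS=(XY..XY)` dialect written by [write_jcampdx()].
#'
#' @param path File path.
#' @return An [nmr_spectrum()].
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path)
  get_field <- function(key, default = NA) {
    hit <- grep(paste0("^##\\$?", key, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^##\\$?", key, "="), "", hit[1])
  }
  nucleus <- sub("^\\^", "", get_field("\\.OBSERVE NUCLEUS", "1H"))
  n_scans <- as.integer(get_field("NSCANS", "1"))
  start <- grep("^##XYPOINTS=", lines)
  if (!length(start)) stop("no ##XYPOINTS block in ", path, call. = FALSE)
  end <- grep("^##END=", lines)
  end <- end[end > start[1]][1]
  body <- lines[(start[1] + 1):(end - 1)]
  parts <- do.call(rbind, strsplit(body, ",\\s*"))
  meta_lines <- grep("^##\\$", lines, value = TRUE)
  metadata <- list()
  for (ml in meta_lines) {
    kv <- sub("^##\\$", "", ml)
    k <- tolower(sub("=.*$", "", kv))
    v <- sub("^[^=]*=", "", kv)
    vn <- suppressWarnings(as.numeric(v))
    metadata[[k]] <- if (is.na(vn)) v else vn
  }
  nmr_spectrum(as.numeric(parts[, 1]), as.numeric(parts[, 2]),
               nucleus = nucleus,
               n_scans = if (is.na(n_scans)) 1L else n_scans,
               metadata = metadata)
}

#' Write/read a spectrum as CSV with a JSON sidecar
#'
#' The CSV has columns `ppm`, `intensity`; nucleus, scan count and
#' metadata go to `<path>.meta.json`.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param path CSV file path.
#' @return `path` (write) or an [nmr_spectrum()] (read).
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  utils::write.csv(data.frame(ppm = spectrum$ppm,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  side <- list(nucleus = spectrum$nucleus, n_scans = spectrum$n_scans,
               metadata = spectrum$metadata)
  jsonlite::write_json(side, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  tab <- utils::read.csv(path)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    side <- list(nucleus = "1H", n_scans = 1L, metadata = list())
  }
  nmr_spectrum(tab$ppm, tab$intensity, nucleus = side$nucleus,
               n_scans = side$n_scans,
               metadata = as.list(side$metadata))
}
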