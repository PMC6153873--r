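#' Construct an MR spectrum object
#'
#' An `mrs_spectrum` holds one processed single-voxel proton spectrum: a
#' chemical-shift axis in ppm and intensities in arbitrary units, plus the
#' acquisition metadata that matters for this tool (echo time, field
#' strength, a free-text source tag identifying centre/scanner). The ppm
#' axis is stored in descending order, the usual display convention.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `ppm`, all finite.
#' @param echo_time_ms Echo time in milliseconds (short TE is 28-35 ms).
#' @param field_strength_T Static field strength in tesla.
#' @param source_id Free-text centre/scanner tag.
#' @return An object of class `mrs_spectrum`: a list with elements `ppm`,
#'   `intensity`, `echo_time_ms`, `field_strength_T`, `source_id`.
#' @examples
#' s <- mrs_spectrum(seq(4.5, 0, length.out = 256), rnorm(256, sd = 0.01))
#' print(s)
#' @export
mrs_spectrum <- function(ppm, intensity, echo_time_ms = 30,
                         field_strength_T = 1.5, source_id = "synthetic") {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("`ppm` and `intensity` must have the same length")
  if (length(ppm) < 2L)
    stop("a spectrum needs at least two points")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("`ppm` must be strictly monotone")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensities must be finite")
  if (min(ppm) > 0.5 || max(ppm) < 4.0)
    warning("ppm axis does not cover [0.5, 4.0]; ",
            "some peak windows will be unavailable")
  if (d[1] > 0) {          # normalise to descending display order
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  }
  structure(
    list(ppm = ppm, intensity = intensity,
         echo_time_ms = as.numeric(echo_time_ms),
         field_strength_T = as.numeric(field_strength_T),
         source_id = as.character(source_id)),
    class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("MR spectrum: %d points, %.2f-%.2f ppm\n",
              length(x$ppm), min(x$ppm), max(x$ppm)))
  cat(sprintf("  TE %.0f ms, %.1f T, source '%s'\n",
              x$echo_time_ms, x$field_strength_T, x$source_id))
  invisible(x)
}

#' @export
plot.mrs_spectrum <- function(x, ...) {
  graphics::plot(x$ppm, x$intensity, type = "l",
                 xlim = rev(range(x$ppm)),
                 xlab = "chemical shift (ppm)",
                 ylab = "intensity (a.u.)", ...)
  invisible(x)
}

#' Read a spectrum from a two-column CSV file
#'
#' The expected format is the scanner-export surrogate used throughout the
#' package: a header line, then one `ppm,intensity` pair per line, comma
#' separated with dot decimals. The axis direction in the file does not
#' matter; the returned spectrum is normalised to descending ppm.
#'
#' @param path Path to a CSV file with header and two numeric columns.
#' @param echo_time_ms,field_strength_T,source_id Metadata attached to the
#'   returned spectrum (a plain CSV export carries none).
#' @return An [mrs_spectrum()] object.
#' @export
read_spectrum_csv <- function(path, echo_time_ms = 30, field_strength_T = 1.5,
                              source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expected two columns (ppm, intensity) in ", path)
  ppm <- suppressWarnings(as.numeric(raw[[1]]))
  intensity <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(ppm) | is.na(intensity))
  if (length(bad))
    stop(sprintf("non-numeric value in %s at data row %d", path, bad[1]))
  if (length(ppm) < 64L)
    stop("spectrum in ", path, " has fewer than 64 points")
  if (anyDuplicated(ppm))
    stop("duplicate ppm values in ", path)
  o <- order(ppm, decreasing = TRUE)
  mrs_spectrum(ppm[o], intensity[o], echo_time_ms = echo_time_ms,
               field_strength_T = field_strength_T, source_id = source_id)
}

#' Write a spectrum to CSV (and optionally JSON with metadata)
#'
#' @param s An [mrs_spectrum()] object.
#' @param path Output CSV path (header `ppm,intensity`).
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "mrs_spectrum"))
  utils::write.csv(data.frame(ppm = s$ppm, intensity = s$intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
write_spectrum_json <- function(s, path) {
  stopifnot(inherits(s, "mrs_spectrum"))
  jsonlite::write_json(
    list(metadata = list(echo_time_ms = s$echo_time_ms,
                         field_strength_T = s$field_strength_T,
                         source_id = s$source_id,
                         n_points = length(s$ppm)),
         ppm = s$ppm, intensity = s$intensity),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# intensity at an arbitrary ppm by linear interpolation
spectrum_at <- function(s, ppm) {
  stats::approx(s$ppm, s$intensity, xout = ppm, rule = 2)$y
}
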