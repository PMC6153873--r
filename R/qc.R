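#' Quality control: Cr/tCho separation check
#'
#' Operationalises "the creatine and total choline peaks must be visually
#' well separated": the minimum intensity (above baseline) between the two
#' apexes must dip below `(1 - valley_depth)` times the lower of the two
#' apex heights. The default 10% valley depth is a package choice; no
#' numeric criterion is standard.
#'
#' @param s An [mrs_spectrum()].
#' @param peaks An `mrs_peaks` object measured from `s`.
#' @param valley_depth Required fractional dip, default 0.10.
#' @return List `(name, passed, detail)`.
#' @export
check_peak_separation <- function(s, peaks, valley_depth = 0.10) {
  stopifnot(inherits(s, "mrs_spectrum"), inherits(peaks, "mrs_peaks"))
  h_cr <- peaks$heights[["cr"]]; h_cho <- peaks$heights[["tcho"]]
  if (h_cr <= 0 || h_cho <= 0 || any(is.na(peaks$apex_ppm[c("cr", "tcho")])))
    return(list(name = "peak_separation", passed = FALSE,
                detail = "apex not found for Cr and/or tCho"))
  lo <- min(peaks$apex_ppm[c("cr", "tcho")])
  hi <- max(peaks$apex_ppm[c("cr", "tcho")])
  between <- s$ppm > lo & s$ppm < hi
  valley <- if (any(between)) min(s$intensity[between]) - peaks$baseline_level
            else Inf
  ok <- is.finite(valley) && valley < (1 - valley_depth) * min(h_cr, h_cho)
  list(name = "peak_separation", passed = ok,
       detail = sprintf("valley %.3g vs limit %.3g",
                        valley, (1 - valley_depth) * min(h_cr, h_cho)))
}

#' Quality control: choline signal-to-noise check
#'
#' The total-choline peak height must be at least five times the noise
#' level (inclusive threshold).
#'
#' @param peaks An `mrs_peaks` object.
#' @param snr_min Minimum tCho height / noise ratio, default 5.
#' @return List `(name, passed, detail)`.
#' @export
check_choline_snr <- function(peaks, snr_min = 5) {
  stopifnot(inherits(peaks, "mrs_peaks"))
  if (peaks$noise_sd <= 0) stop("noise_sd must be > 0 for the SNR check")
  snr <- peaks$heights[["tcho"]] / peaks$noise_sd
  list(name = "choline_snr", passed = snr >= snr_min,
       detail = sprintf("tCho SNR %.2f (threshold %g)", snr, snr_min))
}

#' Apply both quality-control rules
#'
#' Aggregates the peak-separation and choline-SNR checks; a case passes QC
#' only if every individual check passes. Failing cases are meant to be
#' excluded from classification (and logged), mirroring how poor-quality
#' spectra are handled in practice.
#'
#' @inheritParams check_peak_separation
#' @param snr_min Passed to [check_choline_snr()].
#' @return An object of class `mrs_qc`: list with `passed` and `checks`.
#' @export
apply_qc <- function(s, peaks, valley_depth = 0.10, snr_min = 5) {
  checks <- list(check_peak_separation(s, peaks, valley_depth),
                 check_choline_snr(peaks, snr_min))
  structure(list(passed = all(vapply(checks, `[[`, TRUE, "passed")),
                 checks = checks),
            class = "mrs_qc")
}

#' @export
print.mrs_qc <- function(x, ...) {
  cat("QC:", if (x$passed) "PASS" else "FAIL", "\n")
  for (ch in x$checks)
    cat(sprintf("  %-16s %s  (%s)\n", ch$name,
                if (ch$passed) "pass" else "FAIL", ch$detail))
  invisible(x)
}
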