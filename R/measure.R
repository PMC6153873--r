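#' Default peak windows
#'
#' ppm windows used to locate the six measured peaks. Only the centre
#' positions are standard (NAA 2.02, Cr 3.03, tCho 3.20, mIns ~3.56, LMM
#' 0.9 and 1.3); the +/-0.1 ppm windows are a package default and can be
#' overridden. Cr and tCho windows are deliberately disjoint.
#'
#' @return A data.frame with columns `peak`, `centre`, `lo`, `hi`.
#' @export
default_windows <- function() {
  data.frame(
    peak   = MRS_PEAKS,
    centre = c(2.02, 3.03, 3.20, 3.56, 0.90, 1.30),
    lo     = c(1.90, 2.90, 3.10, 3.45, 0.80, 1.20),
    hi     = c(2.10, 3.10, 3.30, 3.65, 1.00, 1.40),
    stringsAsFactors = FALSE)
}

in_window <- function(ppm, lo, hi) ppm >= lo & ppm <= hi

#' Estimate the spectral noise level
#'
#' Standard deviation of linearly detrended intensities in a peak-free
#' region of the spectrum. The default region (4.05-4.45 ppm) contains no
#' configured peak on the default axis.
#'
#' @param s An [mrs_spectrum()].
#' @param region Length-2 ppm interval.
#' @param windows Peak windows that the region must not overlap.
#' @return Noise sd (a.u.). Exactly zero (a degenerate, noiseless trace)
#'   carries attribute `flag = "zero_noise"`.
#' @export
estimate_noise <- function(s, region = c(4.05, 4.45), windows = default_windows()) {
  stopifnot(inherits(s, "mrs_spectrum"))
  region <- sort(region)
  if (region[1] < min(s$ppm) || region[2] > max(s$ppm))
    stop("noise region outside the ppm axis")
  for (i in seq_len(nrow(windows)))
    if (region[1] < windows$hi[i] && region[2] > windows$lo[i])
      stop("noise region overlaps the ", windows$peak[i], " window")
  sel <- in_window(s$ppm, region[1], region[2])
  if (sum(sel) < 32L) stop("noise region contains fewer than 32 points")
  x <- s$ppm[sel]; y <- s$intensity[sel]
  res <- stats::lm.fit(cbind(1, x), y)$residuals
  out <- stats::sd(res)
  if (out == 0) attr(out, "flag") <- "zero_noise"
  out
}

# smooth baseline estimate through peak-free points, evaluated on the full
# axis; ppm above `hi_cut` (residual water territory) is excluded, and the
# peak windows are inflated by `margin` so Lorentzian tails do not pull the
# baseline
baseline_fit <- function(s, windows = default_windows(), hi_cut = 4.45,
                         margin = 0.25) {
  free <- s$ppm <= hi_cut
  for (i in seq_len(nrow(windows)))
    free <- free & !in_window(s$ppm, windows$lo[i] - margin,
                              windows$hi[i] + margin)
  if (sum(free) < 8L) stop("too few peak-free points for a baseline estimate")
  x <- s$ppm[free]; y <- s$intensity[free]
  sm <- stats::lowess(x, y, f = 0.35)
  stats::approx(sm$x, sm$y, xout = s$ppm, rule = 2)$y
}

#' Classify the baseline as flat or non-flat
#'
#' A smooth baseline is estimated through the peak-free regions; the
#' spectrum is called flat when the largest absolute deviation of that
#' estimate from its median stays within twice the noise level, i.e. a
#' visually flat baseline is one indistinguishable from noise.
#'
#' @param s An [mrs_spectrum()].
#' @param noise_sd Noise level from [estimate_noise()].
#' @param windows Peak windows to exclude from the fit.
#' @return `"flat"` or `"non_flat"`.
#' @export
assess_baseline <- function(s, noise_sd = estimate_noise(s),
                            windows = default_windows()) {
  b <- baseline_fit(s, windows)
  dev <- max(abs(b - stats::median(b)))
  if (dev <= 2 * noise_sd) "flat" else "non_flat"
}

# short running mean used only for extrema detection (never for height
# measurement, which stays on the raw trace)
smooth_trace <- function(y, k = 7L) {
  sm <- stats::filter(y, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- y[is.na(sm)]
  as.numeric(sm)
}

# nearest flanking local minima around index i0; returns the linearly
# interpolated "local base" intensity at the apex ppm. `y` defaults to the
# raw trace but extrema detection may pass a smoothed one.
local_base_at <- function(s, i0, y = s$intensity) {
  n <- length(y)
  il <- i0
  while (il > 1L && !(y[il] <= y[max(il - 1L, 1L)] && y[il] <= y[min(il + 1L, n)]))
    il <- il - 1L
  ir <- i0
  while (ir < n && !(y[ir] <= y[max(ir - 1L, 1L)] && y[ir] <= y[min(ir + 1L, n)]))
    ir <- ir + 1L
  if (il == ir) return(y[i0])
  x1 <- s$ppm[il]; x2 <- s$ppm[ir]
  if (x1 == x2) return(min(y[il], y[ir]))
  y[il] + (y[ir] - y[il]) * (s$ppm[i0] - x1) / (x2 - x1)
}

#' Measure one peak height
#'
#' The apex is the maximum intensity inside the window. With a flat
#' baseline the height is measured from the global baseline level to the
#' apex; with a non-flat baseline it is measured from the base of the
#' individual peak (linear interpolation between the nearest flanking
#' local minima) to the apex.
#'
#' @param s An [mrs_spectrum()].
#' @param window Length-2 ppm interval (or one row of [default_windows()]).
#' @param mode `"flat"` or `"local_base"`.
#' @param baseline_level Global baseline level used in flat mode.
#' @return Height (a.u.), with attributes `apex_ppm` and, if the apex sits
#'   on a window edge, `flag = "apex_on_edge"`.
#' @export
measure_peak_height <- function(s, window, mode = c("flat", "local_base"),
                                baseline_level = 0) {
  mode <- match.arg(mode)
  if (is.data.frame(window)) window <- c(window$lo[1], window$hi[1])
  window <- sort(as.numeric(window))
  idx <- which(in_window(s$ppm, window[1], window[2]))
  if (!length(idx)) stop("empty peak window [",
                         window[1], ", ", window[2], "]")
  i0 <- idx[which.max(s$intensity[idx])]
  apex <- s$intensity[i0]
  base <- if (mode == "flat") baseline_level else local_base_at(s, i0)
  h <- apex - base
  attr(h, "apex_ppm") <- s$ppm[i0]
  if (i0 == idx[1] || i0 == idx[length(idx)])
    attr(h, "flag") <- "apex_on_edge"
  h
}

#' Measure the NAA height, distinguishing narrow and broad modes
#'
#' If a local maximum in 1.95-2.10 ppm has prominence above twice the
#' noise level, NAA is measured as a narrow peak at that maximum.
#' Otherwise the broad 2.0-2.5 ppm signal (lipids, macromolecules,
#' glutamate/glutamine) is all that is present and the intensity of the
#' broad envelope at 2.0 ppm above the baseline is used instead.
#'
#' @param s An [mrs_spectrum()].
#' @param noise_sd Noise level.
#' @param mode Baseline mode for the narrow measurement.
#' @param baseline_level Global baseline level.
#' @return List with `height` and `naa_mode` (`"narrow"`/`"broad"`).
#' @export
measure_naa <- function(s, noise_sd = estimate_noise(s),
                        mode = c("flat", "local_base"), baseline_level = 0) {
  mode <- match.arg(mode)
  idx <- which(in_window(s$ppm, 1.95, 2.10))
  y <- s$intensity
  ys <- smooth_trace(y)  # extrema detection on a lightly smoothed trace
  n <- length(y)
  best_i <- NA_integer_; best_prom <- -Inf
  for (i in idx) {
    if (i <= 1L || i >= n) next
    if (ys[i] >= ys[i - 1L] && ys[i] >= ys[i + 1L]) {
      prom <- ys[i] - local_base_at(s, i, ys)
      if (prom > best_prom) { best_prom <- prom; best_i <- i }
    }
  }
  if (!is.na(best_i) && best_prom > 2 * noise_sd) {
    # narrow peak confirmed; measure its height from the raw trace
    i0 <- idx[which.max(y[idx])]
    h <- if (mode == "flat") y[i0] - baseline_level
         else y[i0] - local_base_at(s, i0)
    return(list(height = max(h, 0), naa_mode = "narrow"))
  }
  h <- spectrum_at(s, 2.0) - baseline_level
  list(height = max(h, 0), naa_mode = "broad")
}

#' Measure all six peak heights and the noise level
#'
#' Runs the full deterministic measurement chain: noise estimation,
#' baseline flatness assessment (which fixes the measurement mode for all
#' peaks), the narrow/broad NAA rule, and windowed apex measurement for
#' the remaining five peaks. Small negative baseline-corrected heights are
#' clipped to zero and flagged.
#'
#' @param s An [mrs_spectrum()].
#' @param windows Peak windows, see [default_windows()].
#' @param noise_region ppm interval for [estimate_noise()].
#' @return An object of class `mrs_peaks`: list with `heights` (named,
#'   a.u.), `noise_sd`, `baseline_mode`, `naa_mode`, `baseline_level`,
#'   `apex_ppm`, `flags`.
#' @examples
#' s <- synthesize_spectrum(c(naa = 8, cr = 4, tcho = 6, mins = 5))
#' measure_all(s)
#' @export
measure_all <- function(s, windows = default_windows(),
                        noise_region = c(4.05, 4.45)) {
  noise_sd <- estimate_noise(s, noise_region, windows)
  flags <- character(0)
  if (!is.null(attr(noise_sd, "flag"))) flags <- c(flags, attr(noise_sd, "flag"))
  b <- baseline_fit(s, windows)
  level <- stats::median(b)
  flatness <- if (max(abs(b - level)) <= 2 * as.numeric(noise_sd)) "flat"
              else "non_flat"
  mode <- if (flatness == "flat") "flat" else "local_base"

  heights <- stats::setNames(numeric(length(MRS_PEAKS)), MRS_PEAKS)
  apex <- stats::setNames(rep(NA_real_, length(MRS_PEAKS)), MRS_PEAKS)

  naa <- measure_naa(s, as.numeric(noise_sd), mode, level)
  heights["naa"] <- naa$height
  apex["naa"] <- 2.0

  for (pk in setdiff(MRS_PEAKS, "naa")) {
    w <- windows[windows$peak == pk, , drop = FALSE]
    h <- measure_peak_height(s, w, mode, level)
    if (!is.null(attr(h, "flag")))
      flags <- c(flags, paste0(pk, ":", attr(h, "flag")))
    apex[pk] <- attr(h, "apex_ppm")
    if (h < 0) { flags <- c(flags, paste0(pk, ":negative_height_clipped")); h <- 0 }
    heights[pk] <- as.numeric(h)
  }
  if (naa$height == 0) flags <- c(flags, "naa:zero_height")

  structure(list(heights = heights, noise_sd = as.numeric(noise_sd),
                 baseline_mode = stats::setNames(rep(mode, length(MRS_PEAKS)),
                                                 MRS_PEAKS),
                 naa_mode = naa$naa_mode, baseline_level = level,
                 apex_ppm = apex, flags = flags),
            class = "mrs_peaks")
}

#' Construct a peak-height set directly from known heights
#'
#' Convenience constructor used when heights come from an external
#' measurement (e.g. a per-case CSV row) rather than from a spectrum.
#'
#' @param heights Named non-negative vector over the six peaks.
#' @param noise_sd Noise level (a.u.), must be positive.
#' @param baseline_mode Measurement mode recorded per peak.
#' @param naa_mode `"narrow"` or `"broad"`.
#' @return An `mrs_peaks` object.
#' @export
peak_height_set <- function(heights, noise_sd = 0.05,
                            baseline_mode = "flat", naa_mode = "narrow") {
  h <- stats::setNames(numeric(length(MRS_PEAKS)), MRS_PEAKS)
  heights <- unlist(heights)
  h[names(heights)] <- heights
  if (any(h < 0)) stop("peak heights must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(list(heights = h, noise_sd = noise_sd,
                 baseline_mode = stats::setNames(rep(baseline_mode,
                                                     length(MRS_PEAKS)), MRS_PEAKS),
                 naa_mode = naa_mode, baseline_level = 0,
                 apex_ppm = stats::setNames(c(2.02, 3.03, 3.20, 3.56, 0.90, 1.30),
                                            MRS_PEAKS),
                 flags = character(0)),
            class = "mrs_peaks")
}

#' @export
print.mrs_peaks <- function(x, ...) {
  cat("Peak heights (a.u.):\n")
  print(round(x$heights, 4))
  cat(sprintf("noise sd %.4g | baseline %s | NAA mode %s\n",
              x$noise_sd, x$baseline_mode[1], x$naa_mode))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
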