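# Canonical peak and ratio naming used across the package.
MRS_PEAKS  <- c("naa", "cr", "tcho", "mins", "lmm09", "lmm13")
MRS_RATIOS <- c("cr_tcho", "naa_tcho", "mins_tcho", "naa_cr", "mins_cr",
                "mins_naa", "lmm09_tcho", "lmm13_tcho", "lmm09_lmm13")
MRS_CLASSES <- c("PA", "EP", "MB")

# run `expr` with a private, restored RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Default class-conditional ratio distribution parameters
#'
#' Latent peak heights are modelled per tumour class as independent
#' log-normals relative to total choline: each metabolite m has a median
#' height `med` (tCho itself has median 1) and a log-scale spread `sdlog`;
#' tCho carries its own spread so that all x/tCho ratios share a common
#' noise source while ratios between two metabolites (e.g. NAA/Cr) cancel
#' it, as height ratios do in practice. The nine ratios are derived from
#' the latent heights and are therefore mutually consistent by
#' construction.
#'
#' No per-class ratio means are published for the three tumour types; the
#' shipped values were calibrated once so that large simulated cohorts
#' reproduce the qualitative discrimination structure of the reference
#' study (NAA/Cr and mIns/NAA the only PA-vs-rest AUCs above 0.9,
#' mIns/tCho the dominant ependymoma/medulloblastoma discriminator) and an
#' updated-scheme accuracy of roughly 90%.
#'
#' @return A nested list: per class (`PA`, `EP`, `MB`), per latent peak,
#'   `med` (median height relative to tCho) and `sdlog`.
#' @export
default_ratio_params <- function() {
  list(
    PA = list(naa   = list(med = 1.05, sdlog = 0.18),
              cr    = list(med = 0.28, sdlog = 0.18),
              mins  = list(med = 0.42, sdlog = 0.25),
              lmm09 = list(med = 0.35, sdlog = 0.30),
              lmm13 = list(med = 0.40, sdlog = 0.30),
              tcho  = list(med = 1.00, sdlog = 0.35)),
    EP = list(naa   = list(med = 0.80, sdlog = 0.18),
              cr    = list(med = 0.62, sdlog = 0.18),
              mins  = list(med = 1.40, sdlog = 0.25),
              lmm09 = list(med = 0.40, sdlog = 0.30),
              lmm13 = list(med = 0.50, sdlog = 0.30),
              tcho  = list(med = 1.00, sdlog = 0.35)),
    MB = list(naa   = list(med = 0.50, sdlog = 0.18),
              cr    = list(med = 0.36, sdlog = 0.18),
              mins  = list(med = 0.48, sdlog = 0.25),
              lmm09 = list(med = 0.50, sdlog = 0.30),
              lmm13 = list(med = 0.75, sdlog = 0.30),
              tcho  = list(med = 1.00, sdlog = 0.35)))
}

#' Simulation configuration
#'
#' Bundles everything the synthetic-data generator needs: per-class case
#' counts, class-conditional log-normal ratio parameters, spectral line
#' shape and axis settings, baseline/noise/water-residual amplitudes, and
#' the RNG seed recorded in all outputs.
#'
#' @param class_counts Named integer vector of cases per class. The default
#'   mirrors the prospective cohort of the reference study (13 pilocytic
#'   astrocytomas, 4 ependymomas, 14 medulloblastomas).
#' @param ratio_params See [default_ratio_params()].
#' @param linewidth Lorentzian half-width at half-maximum of metabolite
#'   lines, ppm. Default 0.03 keeps Cr (3.03) and tCho (3.20) visually
#'   separated, as expected of acceptable 1.5-T spectra.
#' @param lmm_width Gaussian sd of the broad lipid/macromolecule humps, ppm.
#' @param mins_ppm Chemical shift used for myo-inositol (literature
#'   position, configurable).
#' @param baseline_amplitude Amplitude (a.u.) of a slowly varying synthetic
#'   baseline; 0 gives a flat zero baseline.
#' @param noise_sd Gaussian noise sd in a.u.
#' @param water_amplitude Amplitude of a residual-water tail centred at
#'   4.7 ppm.
#' @param ppm_range,n_points Axis specification; the axis is generated in
#'   descending ppm order.
#' @param seed Integer RNG seed; recorded in generated tables.
#' @return A list of class `mrs_sim_config`.
#' @export
sim_config <- function(class_counts = c(PA = 13, EP = 4, MB = 14),
                       ratio_params = default_ratio_params(),
                       linewidth = 0.03, lmm_width = 0.07, mins_ppm = 3.56,
                       baseline_amplitude = 0, noise_sd = 0,
                       water_amplitude = 0,
                       ppm_range = c(0, 4.5), n_points = 1024L,
                       seed = 1L) {
  class_counts <- class_counts[MRS_CLASSES[MRS_CLASSES %in% names(class_counts)]]
  if (any(class_counts < 0)) stop("class counts must be >= 0")
  if (linewidth <= 0 || lmm_width <= 0) stop("linewidths must be > 0")
  if (noise_sd < 0 || baseline_amplitude < 0 || water_amplitude < 0)
    stop("amplitudes must be >= 0")
  for (cl in names(ratio_params))
    for (pk in names(ratio_params[[cl]])) {
      p <- ratio_params[[cl]][[pk]]
      if (!is.finite(p$med) || p$med <= 0 || !is.finite(p$sdlog) || p$sdlog <= 0)
        stop(sprintf("invalid log-normal parameters for %s/%s (scale must be > 0)",
                     cl, pk))
    }
  structure(list(class_counts = class_counts, ratio_params = ratio_params,
                 linewidth = linewidth, lmm_width = lmm_width,
                 mins_ppm = mins_ppm,
                 baseline_amplitude = baseline_amplitude, noise_sd = noise_sd,
                 water_amplitude = water_amplitude, ppm_range = ppm_range,
                 n_points = as.integer(n_points), seed = seed),
            class = "mrs_sim_config")
}

#' Sample a cohort of class-labelled ratio profiles
#'
#' Draws, per case, latent log-normal heights for NAA, Cr, mIns, LMM0.9 and
#' LMM1.3 relative to tCho and derives the nine canonical peak-height
#' ratios from them, so that e.g. `mins_naa == mins_tcho / naa_tcho` holds
#' exactly for every row.
#'
#' @param config An [sim_config()] object.
#' @return A data.frame (the cohort table) with columns `case_id`,
#'   `true_class`, the nine ratio columns in canonical order, `source_id`
#'   and a `seed` attribute.
#' @examples
#' tab <- sample_ratio_profiles(sim_config(c(PA = 5, EP = 5, MB = 5), seed = 42))
#' table(tab$true_class)
#' @export
sample_ratio_profiles <- function(config = sim_config()) {
  stopifnot(inherits(config, "mrs_sim_config"))
  with_seed(config$seed, {
    rows <- list()
    idx <- 0L
    for (cl in names(config$class_counts)) {
      n <- config$class_counts[[cl]]
      if (n == 0) next
      pars <- config$ratio_params[[cl]]
      if (is.null(pars)) stop("no ratio parameters for class ", cl)
      draw <- function(pk) stats::rlnorm(n, log(pars[[pk]]$med), pars[[pk]]$sdlog)
      h <- list(naa = draw("naa"), cr = draw("cr"), mins = draw("mins"),
                lmm09 = draw("lmm09"), lmm13 = draw("lmm13"),
                tcho = draw("tcho"))
      rows[[cl]] <- data.frame(
        case_id = sprintf("%s_%03d", cl, seq_len(n) + idx),
        true_class = cl,
        cr_tcho = h$cr / h$tcho,
        naa_tcho = h$naa / h$tcho,
        mins_tcho = h$mins / h$tcho,
        naa_cr = h$naa / h$cr,
        mins_cr = h$mins / h$cr,
        mins_naa = h$mins / h$naa,
        lmm09_tcho = h$lmm09 / h$tcho,
        lmm13_tcho = h$lmm13 / h$tcho,
        lmm09_lmm13 = h$lmm09 / h$lmm13,
        source_id = "simulated",
        stringsAsFactors = FALSE)
      idx <- idx + n
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "seed") <- config$seed
    out
  })
}

#' Synthesize a processed spectrum from requested peak heights
#'
#' Builds a noise-free sum of Lorentzian metabolite lines (NAA 2.02, Cr
#' 3.03, tCho 3.20, mIns at `config$mins_ppm`) and broad Gaussian
#' lipid/macromolecule humps at 0.90 and 1.30 ppm, then optionally adds a
#' slowly varying baseline, a residual-water tail and Gaussian noise. Peak
#' centres are snapped to the nearest grid point so the noise-free apex of
#' an isolated line equals the requested height exactly.
#'
#' @param heights Named non-negative numeric vector with entries
#'   `naa`, `cr`, `tcho`, `mins`, `lmm09`, `lmm13` (missing entries are 0).
#' @param config An [sim_config()] object (line widths, axis, amplitudes).
#' @param seed Seed for baseline wobble and noise; defaults to
#'   `config$seed`.
#' @param source_id Source tag for the returned spectrum.
#' @return An [mrs_spectrum()] object.
#' @examples
#' s <- synthesize_spectrum(c(naa = 8, cr = 4, tcho = 6, mins = 5))
#' @export
synthesize_spectrum <- function(heights, config = sim_config(),
                                seed = config$seed, source_id = "synthetic") {
  stopifnot(inherits(config, "mrs_sim_config"))
  h <- stats::setNames(numeric(length(MRS_PEAKS)), MRS_PEAKS)
  heights <- unlist(heights)
  unknown <- setdiff(names(heights), MRS_PEAKS)
  if (length(unknown)) stop("unknown peak name(s): ",
                            paste(unknown, collapse = ", "))
  h[names(heights)] <- heights
  if (any(h < 0)) stop("peak heights must be >= 0")

  ppm <- seq(config$ppm_range[2], config$ppm_range[1],
             length.out = config$n_points)
  snap <- function(p0) ppm[which.min(abs(ppm - p0))]
  centres <- c(naa = 2.02, cr = 3.03, tcho = 3.20, mins = config$mins_ppm)
  g <- config$linewidth  # Lorentzian HWHM
  y <- numeric(length(ppm))
  for (pk in names(centres)) {
    if (h[[pk]] == 0) next
    c0 <- snap(centres[[pk]])
    y <- y + h[[pk]] * g^2 / ((ppm - c0)^2 + g^2)
  }
  lmm_centres <- c(lmm09 = 0.90, lmm13 = 1.30)
  for (pk in names(lmm_centres)) {
    if (h[[pk]] == 0) next
    c0 <- snap(lmm_centres[[pk]])
    y <- y + h[[pk]] * exp(-(ppm - c0)^2 / (2 * config$lmm_width^2))
  }
  with_seed(seed, {
    if (config$baseline_amplitude > 0) {
      period <- stats::runif(1, 3, 6)
      phase <- stats::runif(1, 0, period)
      y <- y + config$baseline_amplitude *
        (0.6 * sin(2 * pi * (ppm - phase) / period) +
           0.4 * sin(4 * pi * (ppm - phase) / period))
    }
    if (config$water_amplitude > 0)
      y <- y + config$water_amplitude * exp(-(ppm - 4.7)^2 / (2 * 0.2^2))
    if (config$noise_sd > 0)
      y <- y + stats::rnorm(length(ppm), 0, config$noise_sd)
    mrs_spectrum(ppm, y, source_id = source_id)
  })
}

#' Convert a ratio row back to absolute peak heights
#'
#' Given one cohort row (ratios relative to tCho), returns a height vector
#' with tCho scaled to `tcho_height` a.u., suitable for
#' [synthesize_spectrum()].
#'
#' @param row A one-row data.frame or named vector/list with the
#'   `*_tcho` ratio entries.
#' @param tcho_height Absolute tCho height in a.u.
#' @return Named numeric vector over the six peaks.
#' @export
heights_from_ratios <- function(row, tcho_height = 6) {
  row <- as.list(row)
  c(naa = as.numeric(row$naa_tcho) * tcho_height,
    cr = as.numeric(row$cr_tcho) * tcho_height,
    tcho = tcho_height,
    mins = as.numeric(row$mins_tcho) * tcho_height,
    lmm09 = as.numeric(row$lmm09_tcho) * tcho_height,
    lmm13 = as.numeric(row$lmm13_tcho) * tcho_height)
}

#' Read/write cohort tables
#'
#' Cohort tables are CSVs with the fixed columns `case_id`, `true_class`,
#' the nine ratio columns in canonical order, and `source_id`. Ratio
#' values must be finite and non-negative; `case_id` must be unique.
#'
#' @param path CSV path.
#' @return `read_cohort_csv` returns a validated data.frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(tab)
}

#' @rdname read_cohort_csv
#' @param cohort A cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_cohort <- function(tab) {
  need <- c("case_id", "true_class", MRS_RATIOS)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$case_id)) stop("duplicate case_id in cohort table")
  vals <- as.matrix(tab[, MRS_RATIOS])
  if (any(!is.finite(vals))) stop("non-finite ratio value in cohort table")
  if (any(vals < 0)) stop("negative ratio value in cohort table")
  tab
}
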