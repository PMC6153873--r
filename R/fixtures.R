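#' Reference ratio profiles for rare cerebellar tumours
#'
#' Mean peak-height ratio profiles for the rare tumour types seen in the
#' reference multicentre cohort: atypical teratoid rhabdoid tumour (ATRT,
#' mean of the cases with its standard error), one diffuse astrocytoma,
#' one ganglioglioma and one high-grade lesion of undetermined nature.
#' Values are reproduced exactly as published; note the diffuse-astrocytoma
#' zeros for the LMM1.3 ratios (no measurable 1.3-ppm signal), which is
#' why cohort validation accepts zero ratio values.
#'
#' @return A data.frame with one row per tumour type (`case_id` in
#'   `atrt`, `diffuse_astrocytoma`, `ganglioglioma`, `high_grade`),
#'   `true_class` of the form `OTHER:<subtype>`, the nine canonical ratio
#'   columns and `source_id = "reference"`. ATRT standard errors are
#'   attached as attribute `"atrt_sem"`.
#' @examples
#' rare_tumour_profiles()[, c("case_id", "naa_cr", "mins_naa", "mins_tcho")]
#' @export
rare_tumour_profiles <- function() {
  tab <- data.frame(
    case_id = c("atrt", "diffuse_astrocytoma", "ganglioglioma", "high_grade"),
    true_class = c("OTHER:ATRT", "OTHER:diffuse_astrocytoma",
                   "OTHER:ganglioglioma", "OTHER:high_grade"),
    cr_tcho     = c(0.123, 1.245, 0.651, 0.590),
    naa_tcho    = c(0.584, 1.129, 1.005, 0.967),
    mins_tcho   = c(0.386, 1.299, 0.499, 0.872),
    naa_cr      = c(4.502, 0.907, 1.543, 1.638),
    mins_cr     = c(2.593, 1.043, 0.766, 1.479),
    mins_naa    = c(0.547, 1.150, 0.496, 0.903),
    lmm09_tcho  = c(0.661, 0.152, 0.283, 0.521),
    lmm13_tcho  = c(0.838, 0.000, 0.448, 1.902),
    lmm09_lmm13 = c(1.799, 0.000, 0.632, 0.274),
    source_id = "reference",
    stringsAsFactors = FALSE)
  attr(tab, "atrt_sem") <- c(
    cr_tcho = 0.050, naa_tcho = 0.299, mins_tcho = 0.293, naa_cr = 0.580,
    mins_cr = 1.318, mins_naa = 0.222, lmm09_tcho = 0.451,
    lmm13_tcho = 0.515, lmm09_lmm13 = 1.644)
  tab
}

#' Reference confusion-matrix counts
#'
#' Confusion matrices (rows = histopathological truth, columns = MRS
#' classification) reported for the two evaluations of the peak-height
#' classifier: `"updated"` is the refined two-step scheme on the full
#' 53-case multicentre dataset; `"original_prospective"` is the original
#' scheme applied prospectively to the 26 new multicentre cases.
#'
#' @param which `"updated"` or `"original_prospective"`.
#' @return A 3x3 integer matrix with dimnames `PA`, `EP`, `MB`.
#' @export
reference_confusion <- function(which = c("updated", "original_prospective")) {
  which <- match.arg(which)
  m <- switch(which,
    updated = matrix(c(15L, 1L, 0L,
                       0L, 7L, 1L,
                       2L, 1L, 26L), nrow = 3, byrow = TRUE),
    original_prospective = matrix(c(5L, 1L, 3L,
                                    0L, 2L, 2L,
                                    3L, 0L, 10L), nrow = 3, byrow = TRUE))
  dimnames(m) <- list(truth = MRS_CLASSES, predicted = MRS_CLASSES)
  m
}

# archetype heights whose ratios land squarely in each predicted region of
# the updated scheme (PA: naa_cr 4.5, mins_naa 0.33; EP: mins_tcho 1.25;
# MB: naa_cr 1.2, mins_tcho 0.375)
archetype_heights <- function(label) {
  switch(label,
    PA = c(naa = 9, cr = 2, tcho = 6, mins = 3, lmm09 = 2, lmm13 = 2.4),
    EP = c(naa = 4, cr = 3.6, tcho = 4, mins = 5, lmm09 = 2, lmm13 = 2.5),
    MB = c(naa = 3, cr = 2.5, tcho = 8, mins = 3, lmm09 = 3, lmm13 = 4.5),
    stop("unknown label ", label))
}

#' Engineer a cohort realising a given confusion matrix
#'
#' Builds a cohort table that, when classified with the updated two-step
#' scheme, reproduces the supplied confusion counts exactly: for every
#' (truth, predicted) cell it emits that many copies of an archetype ratio
#' profile lying unambiguously in the predicted class's decision region.
#' Used to turn published confusion counts into a concrete evaluable
#' cohort.
#'
#' @param confusion 3x3 count matrix, rows = truth, columns = predicted,
#'   in `PA`, `EP`, `MB` order (e.g. from [reference_confusion()]).
#' @return A cohort data.frame as from [sample_ratio_profiles()].
#' @export
cohort_from_confusion <- function(confusion) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == c(3, 3)),
            all(confusion >= 0))
  rows <- list()
  k <- 0L
  for (i in seq_len(3)) for (j in seq_len(3)) {
    n <- confusion[i, j]
    if (n == 0) next
    r <- as.list(compute_ratios(peak_height_set(archetype_heights(MRS_CLASSES[j]))))
    for (m in seq_len(n)) {
      k <- k + 1L
      rows[[k]] <- data.frame(case_id = sprintf("case_%03d", k),
                              true_class = MRS_CLASSES[i],
                              as.data.frame(r),
                              source_id = "engineered",
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_cohort(out)
}

#' Packaged demonstration cohort
#'
#' A fixed cohort combining the four rare-tumour mean profiles of
#' [rare_tumour_profiles()] with simulated pilocytic astrocytoma,
#' ependymoma and medulloblastoma cases (16/8/29, the class sizes of the
#' multicentre dataset) drawn from the default generator at a fixed seed.
#'
#' @param seed Seed for the simulated portion.
#' @return A cohort data.frame; rare rows carry `OTHER:` truth labels.
#' @export
make_fixture_cohort <- function(seed = 20180730) {
  sim <- sample_ratio_profiles(sim_config(c(PA = 16, EP = 8, MB = 29),
                                          seed = seed))
  rbind(sim, rare_tumour_profiles())
}
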