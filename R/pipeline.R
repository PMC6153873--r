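pkg_version <- function() {
  as.character(utils::packageVersion("mrspeaks"))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

provenance <- function(config, seed) {
  list(package = "mrspeaks", version = pkg_version(),
       seed = seed, config_hash = config_hash(config))
}

#' Run the full simulate-measure-qc-classify-evaluate pipeline
#'
#' End-to-end orchestration: draws a labelled ratio cohort, renders one
#' synthetic spectrum per case, re-measures peak heights from each
#' spectrum, applies quality control, classifies the QC-passing cases with
#' the given scheme and evaluates the result against the generative
#' labels. All artifacts (CSV tables, JSON reports) are written to
#' `out_dir` and stamped with the package version, seed and a hash of the
#' simulation config; QC exclusions are logged in the QC report.
#'
#' @param config An [sim_config()]; needs `noise_sd > 0` so that the SNR
#'   check is meaningful.
#' @param scheme Rule scheme used for classification.
#' @param out_dir Output directory (created; must not already contain a
#'   run's `provenance.json` unless `overwrite = TRUE`).
#' @param overwrite Allow writing into a directory holding a previous run.
#' @param tcho_height Absolute tCho height (a.u.) used when rendering
#'   spectra from ratio profiles.
#' @return Invisibly, a list with `cohort`, `measured`, `qc`,
#'   `evaluation`, `files`.
#' @examples
#' \donttest{
#' cfg <- sim_config(c(PA = 5, EP = 4, MB = 5), noise_sd = 0.05, seed = 7)
#' res <- run_pipeline(cfg, out_dir = tempfile())
#' res$evaluation
#' }
#' @export
run_pipeline <- function(config = sim_config(noise_sd = 0.05),
                         scheme = scheme_updated(),
                         out_dir, overwrite = FALSE, tcho_height = 6) {
  stopifnot(inherits(config, "mrs_sim_config"), inherits(scheme, "mrs_scheme"))
  if (config$noise_sd <= 0)
    stop("pipeline needs config$noise_sd > 0 (the SNR check is undefined ",
         "for noiseless spectra)")
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "provenance.json")) &&
      !overwrite)
    stop("out_dir already holds a pipeline run; use overwrite = TRUE")

  stage <- tempfile("mrspeaks_run_")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  cohort <- sample_ratio_profiles(config)
  prov <- provenance(config, config$seed)

  measured <- vector("list", nrow(cohort))
  qc_list <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    s <- synthesize_spectrum(heights_from_ratios(cohort[i, ], tcho_height),
                             config, seed = config$seed + i,
                             source_id = cohort$case_id[i])
    pk <- measure_all(s)
    qc <- apply_qc(s, pk)
    measured[[i]] <- data.frame(case_id = cohort$case_id[i],
                                true_class = cohort$true_class[i],
                                t(pk$heights), noise_sd = pk$noise_sd,
                                naa_mode = pk$naa_mode,
                                qc_passed = qc$passed,
                                stringsAsFactors = FALSE)
    qc_list[[i]] <- list(
      case_id = cohort$case_id[i], passed = qc$passed,
      checks = lapply(qc$checks, function(ch)
        list(name = ch$name, passed = ch$passed, detail = ch$detail)))
  }
  measured <- do.call(rbind, measured)

  excluded <- measured$case_id[!measured$qc_passed]
  if (length(excluded))
    message("QC excluded ", length(excluded), " case(s): ",
            paste(excluded, collapse = ", "))

  keep <- measured$qc_passed
  ratios <- do.call(rbind, lapply(which(keep), function(i) {
    r <- compute_ratios(stats::setNames(
      as.numeric(measured[i, MRS_PEAKS]), MRS_PEAKS))
    data.frame(case_id = measured$case_id[i],
               true_class = measured$true_class[i], as.data.frame(t(r)),
               source_id = "pipeline", stringsAsFactors = FALSE)
  }))
  if (is.null(ratios) || !nrow(ratios)) stop("no case passed quality control")

  evaluation <- evaluate_scheme(ratios, scheme)

  files <- c(cohort = "cohort.csv", measured = "measured.csv",
             predictions = "predictions.csv", qc = "qc.json",
             evaluation = "evaluation.json", provenance = "provenance.json")
  write_cohort_csv(cohort, file.path(stage, files["cohort"]))
  utils::write.csv(measured, file.path(stage, files["measured"]),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(evaluation$predictions, file.path(stage, files["predictions"]),
                   row.names = FALSE)
  jsonlite::write_json(list(provenance = prov, cases = qc_list),
                       file.path(stage, files["qc"]), auto_unbox = TRUE)
  jsonlite::write_json(
    list(provenance = prov, scheme = scheme$name,
         confusion = as.data.frame.matrix(evaluation$confusion),
         per_class_pct = as.list(evaluation$per_class_pct),
         overall_pct = evaluation$overall_pct,
         pa_vs_rest_pct = evaluation$pa_vs_rest_pct,
         correct = evaluation$correct, n = evaluation$n,
         n_excluded_qc = length(excluded)),
    file.path(stage, files["evaluation"]), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(prov, file.path(stage, files["provenance"]),
                       auto_unbox = TRUE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.copy(file.path(stage, files), out_dir, overwrite = TRUE)
  if (!all(ok)) stop("failed to write artifacts to ", out_dir)

  invisible(list(cohort = cohort, measured = measured, qc = qc_list,
                 evaluation = evaluation,
                 files = file.path(out_dir, files)))
}

#' Worked example: classify the rare-tumour reference profiles
#'
#' Applies the updated two-step scheme to the packaged rare-tumour mean
#' profiles ([rare_tumour_profiles()]) and prints the assigned classes:
#' the ATRT mean lands in the pilocytic-astrocytoma region (driven by its
#' very small creatine peak), the diffuse astrocytoma is called
#' ependymoma (high myo-inositol) and the ganglioglioma medulloblastoma on
#' step 2.
#'
#' @param quiet Suppress printing.
#' @return Data.frame of predictions, invisibly.
#' @export
demo_rare_tumours <- function(quiet = FALSE) {
  rare <- rare_tumour_profiles()
  pred <- predict(scheme_updated(), rare)
  out <- data.frame(case_id = rare$case_id,
                    naa_cr = rare$naa_cr, mins_naa = rare$mins_naa,
                    mins_tcho = rare$mins_tcho,
                    predicted_class = pred$predicted_class,
                    step_fired = pred$step_fired,
                    stringsAsFactors = FALSE)
  if (!quiet) print(out, row.names = FALSE)
  invisible(out)
}
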