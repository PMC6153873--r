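#' Compute the nine canonical peak-height ratios
#'
#' Forms the ratio vector used throughout the tool from a set of measured
#' peak heights: Cr/tCho, NAA/tCho, mIns/tCho, NAA/Cr, mIns/Cr, mIns/NAA,
#' LMM0.9/tCho, LMM1.3/tCho and LMM0.9/LMM1.3. Ratios sharing one
#' peak-height set are internally consistent by construction
#' (`naa_cr * cr_tcho == naa_tcho` up to floating point).
#'
#' @param peaks An `mrs_peaks` object or a named height vector over
#'   `naa`, `cr`, `tcho`, `mins`, `lmm09`, `lmm13`.
#' @return Named numeric vector over the nine ratios.
#' @examples
#' compute_ratios(c(naa = 9, cr = 2, tcho = 4, mins = 3, lmm09 = 1, lmm13 = 2))
#' @export
compute_ratios <- function(peaks) {
  h <- if (inherits(peaks, "mrs_peaks")) peaks$heights else {
    v <- stats::setNames(numeric(length(MRS_PEAKS)), MRS_PEAKS)
    p <- unlist(peaks)
    v[names(p)] <- p
    v
  }
  for (pk in c("tcho", "cr", "naa", "lmm13")) {
    if (!is.finite(h[[pk]]) || h[[pk]] <= 0)
      stop("zero ", c(tcho = "total choline", cr = "creatine", naa = "NAA",
                      lmm13 = "LMM 1.3")[[pk]], " height: cannot form ratios")
  }
  c(cr_tcho = h[["cr"]] / h[["tcho"]],
    naa_tcho = h[["naa"]] / h[["tcho"]],
    mins_tcho = h[["mins"]] / h[["tcho"]],
    naa_cr = h[["naa"]] / h[["cr"]],
    mins_cr = h[["mins"]] / h[["cr"]],
    mins_naa = h[["mins"]] / h[["naa"]],
    lmm09_tcho = h[["lmm09"]] / h[["tcho"]],
    lmm13_tcho = h[["lmm13"]] / h[["tcho"]],
    lmm09_lmm13 = h[["lmm09"]] / h[["lmm13"]])
}

# ---- rule schemes -----------------------------------------------------------

new_step <- function(label, ...) {
  conds <- list(...)
  for (cn in conds)
    stopifnot(is.list(cn), cn$ratio %in% MRS_RATIOS, cn$op %in% c("<", ">"),
              is.finite(cn$cutoff))
  list(label = label, conditions = conds)
}

cond <- function(ratio, op, cutoff) list(ratio = ratio, op = op, cutoff = cutoff)

#' Construct a two-step rule scheme
#'
#' A rule scheme is an ordered list of steps. Each step is a conjunction
#' of strict inequality conditions on named ratios; the first step whose
#' conditions all hold assigns its class label, and a case satisfying no
#' step receives the else-class. Values exactly at a cutoff fail the
#' strict comparison and fall through. Optional checks are extra
#' conditions that never change the label; a violated check only raises a
#' flag on the result.
#'
#' @param steps List of steps; each step is a list with `label` and
#'   `conditions` (each condition a list with `ratio`, `op` in `<`/`>`,
#'   `cutoff`).
#' @param else_label Class assigned when no step fires.
#' @param checks Optional list of checks: each a list with `ratio`, `op`,
#'   `cutoff` and `label` (the class whose assignment it verifies).
#' @param name Scheme name used in printing and reports.
#' @return An object of class `mrs_scheme`.
#' @seealso [scheme_updated()], [scheme_original()], [scheme_reoptimized()]
#' @export
mrs_scheme <- function(steps, else_label, checks = list(), name = "custom") {
  stopifnot(is.list(steps), length(else_label) == 1L)
  for (st in steps) {
    stopifnot(!is.null(st$label), is.list(st$conditions))
    for (cn in st$conditions) {
      if (!cn$ratio %in% MRS_RATIOS)
        stop("scheme references unknown ratio: ", cn$ratio)
      if (!cn$op %in% c("<", ">")) stop("comparator must be '<' or '>'")
      if (!is.finite(cn$cutoff)) stop("cutoff must be finite")
    }
  }
  for (ch in checks)
    if (!ch$ratio %in% MRS_RATIOS)
      stop("check references unknown ratio: ", ch$ratio)
  structure(list(steps = steps, else_label = else_label, checks = checks,
                 name = name),
            class = "mrs_scheme")
}

#' The updated two-step classification scheme
#'
#' Step 1 assigns pilocytic astrocytoma when NAA/Cr > 2.22 and
#' mIns/NAA < 0.65. Step 2 assigns medulloblastoma when mIns/tCho < 0.85;
#' anything else is called ependymoma. Cr/tCho and NAA/tCho act as checks
#' on the step-2 assignment (flags only).
#'
#' @return An `mrs_scheme`.
#' @export
scheme_updated <- function() {
  mrs_scheme(
    steps = list(
      new_step("PA", cond("naa_cr", ">", 2.22), cond("mins_naa", "<", 0.65)),
      new_step("MB", cond("mins_tcho", "<", 0.85))),
    else_label = "EP",
    checks = list(list(ratio = "cr_tcho", op = "<", cutoff = 0.75, label = "MB"),
                  list(ratio = "naa_tcho", op = "<", cutoff = 1.0, label = "MB")),
    name = "updated")
}

#' Reconstruction of the original classification scheme
#'
#' The original scheme used NAA/Cr and mIns/NAA to separate pilocytic
#' astrocytoma (NAA/Cr cutoff 4) and Cr/tCho to split ependymoma from
#' medulloblastoma. Its exact published step structure is not restated in
#' the multicentre evaluation, so this constructor is a documented
#' reconstruction: step 1 PA by NAA/Cr > 4 and mIns/NAA < 1.35; step 2 MB
#' by Cr/tCho < 0.45; else EP.
#'
#' @return An `mrs_scheme` (name `"original_reconstruction"`).
#' @export
scheme_original <- function() {
  mrs_scheme(
    steps = list(
      new_step("PA", cond("naa_cr", ">", 4), cond("mins_naa", "<", 1.35)),
      new_step("MB", cond("cr_tcho", "<", 0.45))),
    else_label = "EP",
    name = "original_reconstruction")
}

#' The original scheme with re-optimised cutoffs
#'
#' Same structure as [scheme_original()] with the cutoffs re-optimised on
#' the combined multicentre dataset: NAA/Cr 2.22, mIns/NAA 1.35, Cr/tCho
#' 0.45.
#'
#' @return An `mrs_scheme` (name `"reoptimized_original"`).
#' @export
scheme_reoptimized <- function() {
  mrs_scheme(
    steps = list(
      new_step("PA", cond("naa_cr", ">", 2.22), cond("mins_naa", "<", 1.35)),
      new_step("MB", cond("cr_tcho", "<", 0.45))),
    else_label = "EP",
    name = "reoptimized_original")
}

#' @export
print.mrs_scheme <- function(x, ...) {
  cat(sprintf("Rule scheme '%s'\n", x$name))
  for (i in seq_along(x$steps)) {
    st <- x$steps[[i]]
    conds <- vapply(st$conditions, function(cn)
      sprintf("%s %s %g", cn$ratio, cn$op, cn$cutoff), "")
    cat(sprintf("  step %d: %s -> %s\n", i, paste(conds, collapse = " & "),
                st$label))
  }
  cat("  else ->", x$else_label, "\n")
  if (length(x$checks))
    for (ch in x$checks)
      cat(sprintf("  check (%s): %s %s %g\n", ch$label, ch$ratio, ch$op,
                  ch$cutoff))
  invisible(x)
}

cond_holds <- function(cn, ratios) {
  v <- ratios[[cn$ratio]]
  if (cn$op == "<") v < cn$cutoff else v > cn$cutoff
}

#' Classify one ratio vector with a rule scheme
#'
#' @param scheme An [mrs_scheme()].
#' @param ratios Named ratio vector (see [compute_ratios()]) or a one-row
#'   cohort data.frame.
#' @return List with `label`, `step_fired` (0 for the else-class) and
#'   `check_flags` (character vector of violated checks).
#' @export
classify_with_scheme <- function(scheme, ratios) {
  stopifnot(inherits(scheme, "mrs_scheme"))
  if (is.data.frame(ratios)) ratios <- as.list(ratios[1, , drop = FALSE])
  ratios <- as.list(ratios)
  for (rn in unique(unlist(lapply(scheme$steps, function(st)
    vapply(st$conditions, `[[`, "", "ratio")))))
    if (is.null(ratios[[rn]]) || !is.finite(ratios[[rn]]))
      stop("ratio vector lacks a finite value for ", rn)
  label <- scheme$else_label
  fired <- 0L
  for (i in seq_along(scheme$steps)) {
    st <- scheme$steps[[i]]
    if (all(vapply(st$conditions, cond_holds, TRUE, ratios = ratios))) {
      label <- st$label; fired <- i; break
    }
  }
  flags <- character(0)
  for (ch in scheme$checks)
    if (identical(label, ch$label) && !is.null(ratios[[ch$ratio]]) &&
        !cond_holds(ch, ratios))
      flags <- c(flags, sprintf("check failed: %s %s %g (%s)",
                                ch$ratio, ch$op, ch$cutoff, ch$label))
  list(label = label, step_fired = fired, check_flags = flags)
}

#' Classify with the updated scheme (hard-coded rules)
#'
#' Direct implementation of the updated two-step rules, independent of the
#' generic scheme engine (the two are cross-checked in the test suite):
#' PA iff NAA/Cr > 2.22 and mIns/NAA < 0.65; else MB iff mIns/tCho < 0.85;
#' else EP.
#'
#' @param ratios Named ratio vector or one-row cohort data.frame.
#' @return List with `label`, `step_fired`, `check_flags` (always empty).
#' @examples
#' classify_updated(c(naa_cr = 4.5, mins_naa = 0.55, mins_tcho = 0.39))
#' @export
classify_updated <- function(ratios) {
  if (is.data.frame(ratios)) ratios <- as.list(ratios[1, , drop = FALSE])
  ratios <- as.list(ratios)
  for (rn in c("naa_cr", "mins_naa", "mins_tcho"))
    if (is.null(ratios[[rn]]) || !is.finite(ratios[[rn]]))
      stop("ratio vector lacks a finite value for ", rn)
  if (ratios$naa_cr > 2.22 && ratios$mins_naa < 0.65)
    return(list(label = "PA", step_fired = 1L, check_flags = character(0)))
  if (ratios$mins_tcho < 0.85)
    return(list(label = "MB", step_fired = 2L, check_flags = character(0)))
  list(label = "EP", step_fired = 0L, check_flags = character(0))
}

#' @export
predict.mrs_scheme <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  res <- lapply(seq_len(nrow(newdata)), function(i)
    classify_with_scheme(object, newdata[i, , drop = FALSE]))
  data.frame(
    case_id = if ("case_id" %in% names(newdata)) newdata$case_id
              else sprintf("case_%03d", seq_len(nrow(newdata))),
    predicted_class = vapply(res, `[[`, "", "label"),
    step_fired = vapply(res, `[[`, 0L, "step_fired"),
    flags = vapply(res, function(r)
      paste(r$check_flags, collapse = "; "), ""),
    stringsAsFactors = FALSE)
}

# ---- evaluation -------------------------------------------------------------

#' Classification rates from a confusion matrix
#'
#' Per-class correct rates (rounded to the nearest integer percent), the
#' overall rate (one decimal percent) and the binary PA-vs-rest accuracy
#' (integer percent), the presentation used in the reference evaluations.
#'
#' @param confusion 3x3 count matrix, rows = truth (`PA`, `EP`, `MB`),
#'   columns = predictions.
#' @return List with `per_class_pct`, `overall_pct`, `pa_vs_rest_pct`,
#'   `correct`, `n`.
#' @examples
#' classification_rates(reference_confusion("updated"))
#' @export
classification_rates <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == 3, ncol(confusion) == 3)
  n_class <- rowSums(confusion)
  if (any(n_class == 0)) stop("empty truth class in confusion matrix")
  correct <- diag(confusion)
  n <- sum(confusion)
  binary_correct <- correct[1] + sum(confusion[2:3, 2:3])
  list(per_class_pct = round(100 * correct / n_class),
       overall_pct = round(100 * sum(correct) / n, 1),
       pa_vs_rest_pct = unname(round(100 * binary_correct / n)),
       correct = unname(sum(correct)), n = n)
}

#' Evaluate a rule scheme on a labelled cohort
#'
#' Classifies every cohort row, tabulates the 3x3 confusion matrix
#' (truth x prediction) and computes the standard rates via
#' [classification_rates()].
#'
#' @param cohort Cohort data.frame with `true_class` in `PA`/`EP`/`MB`
#'   (rows with `OTHER:` labels are dropped with a message).
#' @param scheme An [mrs_scheme()].
#' @return An object of class `mrs_evaluation`: list with `confusion`,
#'   `per_class_pct`, `overall_pct`, `pa_vs_rest_pct`, `correct`, `n`,
#'   `predictions`, `scheme_name`.
#' @export
evaluate_scheme <- function(cohort, scheme) {
  stopifnot(is.data.frame(cohort))
  other <- !cohort$true_class %in% MRS_CLASSES
  if (any(other)) {
    message("dropping ", sum(other), " case(s) outside PA/EP/MB")
    cohort <- cohort[!other, , drop = FALSE]
  }
  if (!nrow(cohort)) stop("empty cohort")
  pred <- predict(scheme, cohort)
  confusion <- table(truth = factor(cohort$true_class, MRS_CLASSES),
                     predicted = factor(pred$predicted_class, MRS_CLASSES))
  confusion <- unclass(confusion)
  rates <- classification_rates(confusion)
  structure(c(list(confusion = confusion), rates,
              list(predictions = pred, scheme_name = scheme$name)),
            class = "mrs_evaluation")
}

#' @export
print.mrs_evaluation <- function(x, ...) {
  cat(sprintf("Scheme '%s' on %d cases: overall %.1f%% correct (%d/%d)\n",
              x$scheme_name, x$n, x$overall_pct, x$correct, x$n))
  cat(sprintf("  per class: PA %d%%, EP %d%%, MB %d%% | PA vs rest %d%%\n",
              x$per_class_pct[["PA"]], x$per_class_pct[["EP"]],
              x$per_class_pct[["MB"]], x$pa_vs_rest_pct))
  print(x$confusion)
  invisible(x)
}

# ---- scheme config I/O ------------------------------------------------------

#' Read or write a rule scheme as YAML
#'
#' Schemes serialise to a small YAML document with `name`, `steps` (each
#' with `label` and `conditions`), `else_label` and optional `checks`, so
#' that refined schemes can be saved and reloaded by the classifier.
#'
#' @param path YAML file path.
#' @return `read_scheme` returns an [mrs_scheme()]; `write_scheme`
#'   returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$steps) || is.null(y$else_label))
    stop("scheme config must contain 'steps' and 'else_label'")
  steps <- lapply(y$steps, function(st)
    list(label = st$label,
         conditions = lapply(st$conditions, function(cn)
           cond(cn$ratio, cn$op, as.numeric(cn$cutoff)))))
  checks <- lapply(y$checks %||% list(), function(ch)
    list(ratio = ch$ratio, op = ch$op, cutoff = as.numeric(ch$cutoff),
         label = ch$label))
  mrs_scheme(steps, y$else_label, checks, name = y$name %||% "config")
}

#' @rdname read_scheme
#' @param scheme An [mrs_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "mrs_scheme"))
  yaml::write_yaml(
    list(name = scheme$name,
         steps = lapply(scheme$steps, function(st)
           list(label = st$label,
                conditions = lapply(st$conditions, function(cn)
                  list(ratio = cn$ratio, op = cn$op, cutoff = cn$cutoff)))),
         else_label = scheme$else_label,
         checks = lapply(scheme$checks, function(ch)
           list(ratio = ch$ratio, op = ch$op, cutoff = ch$cutoff,
                label = ch$label))),
    path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
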