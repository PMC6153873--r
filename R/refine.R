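#' One-way fixed-effects analysis of variance
#'
#' Classical equal-variance one-way ANOVA F test for a difference in group
#' means, used to screen metabolite ratios before cutoff refinement.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length; every group needs at least two
#'   observations.
#' @return List with `F` and `p`.
#' @examples
#' anova_oneway(c(1, 2, 3, 11, 12, 13, 21, 22, 23), rep(c("a", "b", "c"), each = 3))
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2L)) stop("every group needs >= 2 observations")
  if (stats::var(values) == 0) return(list(F = 0, p = 1))
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  F <- unname(fit$statistic)
  p <- unname(fit$p.value)
  if (!is.finite(F)) { F <- 0; p <- 1 }  # zero within- and between-group var
  list(F = F, p = p)
}

#' Two-tailed Welch t-test p-value
#'
#' Unequal-variance (Welch) two-sample t-test, the form appropriate for
#' the unequal group sizes and spreads seen in tumour cohorts. Degenerate
#' input (both groups constant and equal) yields p = 1.
#'
#' @param a,b Numeric vectors, each with >= 2 observations.
#' @return Two-tailed p-value.
#' @export
two_tailed_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("both groups need >= 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(1)
    return(.Machine$double.xmin)  # perfect separation, zero spread
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' ROC area under the curve with direction
#'
#' Computes the AUC as the probability that a random positive case
#' outscores a random negative one, with tied scores counting one half
#' (the Mann-Whitney construction). Because a ratio can indicate the
#' positive class through either high or low values, the reported AUC is
#' `max(a, 1 - a)` together with a `direction` flag recording which
#' orientation that is.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or coercible) vector, `TRUE` = positive class.
#' @return List with `auc` (in `[0.5, 1]`), `direction` (`"high"` if high
#'   scores indicate the positive class, else `"low"`) and `auc_raw` (the
#'   unoriented probability).
#' @examples
#' roc_auc(c(2, 4, 6, 1, 3, 5), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                         # midranks handle ties
  a <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = max(a, 1 - a),
       direction = if (a >= 0.5) "high" else "low",
       auc_raw = a)
}

#' Youden-style optimal cutoff
#'
#' Scans every midpoint between adjacent sorted unique scores (plus
#' sentinels beyond the data range) and returns the threshold maximising
#' sensitivity + specificity. Ties are broken toward higher specificity,
#' then deterministically toward the more conservative threshold. The
#' orientation (positive class above or below the cutoff) defaults to the
#' direction of [roc_auc()].
#'
#' @param scores Numeric scores.
#' @param labels Logical vector, `TRUE` = positive class.
#' @param direction `"high"` (positive if score > cutoff), `"low"`
#'   (positive if score < cutoff) or `"auto"`.
#' @return List with `cutoff`, `direction`, `sensitivity`, `specificity`,
#'   `youden` (sensitivity + specificity at the cutoff).
#' @examples
#' optimal_cutoff(c(1, 2, 3, 4, 5, 6), c(rep(FALSE, 3), rep(TRUE, 3)))
#' @export
optimal_cutoff <- function(scores, labels, direction = c("auto", "high", "low")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  if (direction == "auto") direction <- roc_auc(scores, labels)$direction

  u <- sort(unique(scores))
  pad <- max(1, diff(range(u)))
  cand <- c(u[1] - pad, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + pad)
  best <- NULL
  for (t in cand) {
    pos_call <- if (direction == "high") scores > t else scores < t
    sens <- sum(pos_call & labels) / n1
    spec <- sum(!pos_call & !labels) / n0
    y <- sens + spec
    better <- is.null(best) || y > best$youden + 1e-12 ||
      (abs(y - best$youden) <= 1e-12 && spec > best$specificity + 1e-12)
    if (better)
      best <- list(cutoff = t, direction = direction, sensitivity = sens,
                   specificity = spec, youden = y)
  }
  best
}

# ---- the fitting function ---------------------------------------------------

#' Refine a classification scheme from a labelled cohort
#'
#' Re-derives the two-step rule scheme from per-case ratio data with the
#' published procedure: (1) discard ratios whose one-way ANOVA across the
#' three tumour classes is not significant at `alpha`; (2) compute Welch
#' t-tests for the PA-vs-other and MB-vs-EP contrasts; (3) compute
#' ROC AUCs for the four standard contrasts (each class vs all, and EP vs
#' MB); (4) build step 1 as the conjunction of all retained ratios with
#' PA-vs-rest AUC above `auc_min`, each with a Youden-optimal cutoff; (5)
#' build step 2 from the single best EP-vs-MB ratio (next two recorded as
#' checks); (6) evaluate the resulting scheme on the input cohort.
#'
#' @param cohort Cohort data.frame with all three classes and at least
#'   four cases per class.
#' @param alpha ANOVA screening level, default 0.05.
#' @param auc_min Step-1 inclusion threshold on the PA-vs-rest AUC,
#'   default 0.9.
#' @return An object of class `mrs_refine` with components `anova`,
#'   `ttests`, `auc` (per-ratio data.frames), `step1`, `step2`, `scheme`
#'   (an [mrs_scheme()]), `evaluation` (an `mrs_evaluation`), `n`, `call`.
#' @examples
#' cohort <- sample_ratio_profiles(sim_config(c(PA = 30, EP = 30, MB = 30),
#'                                            seed = 7))
#' fit <- mrs_refine(cohort)
#' coef(fit)
#' @export
mrs_refine <- function(cohort, alpha = 0.05, auc_min = 0.9) {
  validate_cohort(cohort)
  cohort <- cohort[cohort$true_class %in% MRS_CLASSES, , drop = FALSE]
  counts <- table(factor(cohort$true_class, MRS_CLASSES))
  if (any(counts < 4L))
    stop("need >= 4 cases per class; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  cohort <- cohort[order(cohort$case_id), , drop = FALSE]  # order invariance
  cls <- cohort$true_class

  # (1) ANOVA screen
  an <- lapply(MRS_RATIOS, function(rn) anova_oneway(cohort[[rn]], cls))
  anova_tab <- data.frame(ratio = MRS_RATIOS,
                          F = vapply(an, `[[`, 0, "F"),
                          p = vapply(an, `[[`, 0, "p"))
  anova_tab$retained <- anova_tab$p < alpha
  retained <- anova_tab$ratio[anova_tab$retained]
  if (!length(retained)) stop("no ratio passes the ANOVA screen")

  # (2) two-tailed Welch t-tests
  ttests <- data.frame(
    ratio = retained,
    p_pa_vs_other = vapply(retained, function(rn)
      two_tailed_t(cohort[[rn]][cls == "PA"], cohort[[rn]][cls != "PA"]), 0),
    p_mb_vs_ep = vapply(retained, function(rn)
      two_tailed_t(cohort[[rn]][cls == "MB"], cohort[[rn]][cls == "EP"]), 0),
    row.names = NULL)

  # (3) AUCs for the four contrasts
  contrast_auc <- function(rn, pos) roc_auc(cohort[[rn]], pos)
  auc_tab <- data.frame(ratio = retained, row.names = NULL)
  auc_tab$pa_vs_all <- vapply(retained, function(rn)
    contrast_auc(rn, cls == "PA")$auc, 0)
  auc_tab$ep_vs_all <- vapply(retained, function(rn)
    contrast_auc(rn, cls == "EP")$auc, 0)
  auc_tab$mb_vs_all <- vapply(retained, function(rn)
    contrast_auc(rn, cls == "MB")$auc, 0)
  ep_mb <- cls != "PA"
  auc_tab$ep_vs_mb <- vapply(retained, function(rn)
    roc_auc(cohort[[rn]][ep_mb], cls[ep_mb] == "EP")$auc, 0)

  # (4) step 1: PA-vs-rest ratios with AUC above threshold, Youden cutoffs
  step1_ratios <- auc_tab$ratio[auc_tab$pa_vs_all > auc_min]
  if (!length(step1_ratios)) {
    warning("no ratio exceeds the step-1 AUC threshold; using the best one")
    step1_ratios <- auc_tab$ratio[which.max(auc_tab$pa_vs_all)]
  }
  step1 <- lapply(step1_ratios, function(rn) {
    oc <- optimal_cutoff(cohort[[rn]], cls == "PA")
    cond(rn, if (oc$direction == "high") ">" else "<", oc$cutoff)
  })

  # (5) step 2: best EP-vs-MB ratio + two checks (MB is the step-2 label)
  ord <- order(-auc_tab$ep_vs_mb, match(auc_tab$ratio, MRS_RATIOS))
  step2_ratio <- auc_tab$ratio[ord[1]]
  oc2 <- optimal_cutoff(cohort[[step2_ratio]][ep_mb],
                        cls[ep_mb] == "MB")
  step2 <- cond(step2_ratio, if (oc2$direction == "high") ">" else "<",
                oc2$cutoff)
  checks <- lapply(auc_tab$ratio[ord[-1]][seq_len(min(2, length(ord) - 1))],
                   function(rn) {
                     oc <- optimal_cutoff(cohort[[rn]][ep_mb],
                                          cls[ep_mb] == "MB")
                     list(ratio = rn,
                          op = if (oc$direction == "high") ">" else "<",
                          cutoff = oc$cutoff, label = "MB")
                   })

  scheme <- mrs_scheme(
    steps = list(list(label = "PA", conditions = step1),
                 list(label = "MB", conditions = list(step2))),
    else_label = "EP", checks = checks, name = "refined")

  structure(list(anova = anova_tab, ttests = ttests, auc = auc_tab,
                 step1 = step1, step2 = step2, scheme = scheme,
                 evaluation = evaluate_scheme(cohort, scheme),
                 n = as.integer(counts), call = match.call()),
            class = "mrs_refine")
}

#' @export
print.mrs_refine <- function(x, ...) {
  cat("Refined peak-height ratio classifier\n")
  cat(sprintf("cohort: PA %d, EP %d, MB %d\n", x$n[1], x$n[2], x$n[3]))
  print(x$scheme)
  cat(sprintf("training accuracy %.1f%% (%d/%d)\n",
              x$evaluation$overall_pct, x$evaluation$correct, x$evaluation$n))
  invisible(x)
}

#' @export
summary.mrs_refine <- function(object, ...) {
  structure(list(anova = object$anova, ttests = object$ttests,
                 auc = object$auc, scheme = object$scheme,
                 evaluation = object$evaluation, n = object$n),
            class = "summary.mrs_refine")
}

#' @export
print.summary.mrs_refine <- function(x, ...) {
  cat("ANOVA screen (discard p >=", 0.05, "):\n")
  print(x$anova, digits = 3, row.names = FALSE)
  cat("\nWelch t-tests on retained ratios:\n")
  print(x$ttests, digits = 3, row.names = FALSE)
  cat("\nROC AUCs:\n")
  print(x$auc, digits = 3, row.names = FALSE)
  cat("\n")
  print(x$scheme)
  cat("\n")
  print(x$evaluation)
  invisible(x)
}

#' @export
coef.mrs_refine <- function(object, ...) {
  cuts <- c(vapply(object$step1, `[[`, 0, "cutoff"), object$step2$cutoff)
  names(cuts) <- c(vapply(object$step1, `[[`, "", "ratio"),
                   object$step2$ratio)
  cuts
}

#' @export
predict.mrs_refine <- function(object, newdata, ...) {
  predict(object$scheme, newdata, ...)
}

#' @export
fitted.mrs_refine <- function(object, ...) {
  object$evaluation$predictions$predicted_class
}

#' Plot the classification axes of a refined scheme
#'
#' Scatterplots of the fitted step-1 pair (by default NAA/Cr against
#' mIns/NAA) and the step-2 ratio against Cr/tCho, with fitted cutoffs as
#' dashed lines — the standard way these two-dimensional decision regions
#' are displayed.
#'
#' @param x An `mrs_refine` object.
#' @param cohort Cohort to plot; defaults to nothing (axes only make sense
#'   with data), so pass the training cohort.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mrs_refine <- function(x, cohort, ...) {
  stopifnot(is.data.frame(cohort))
  cohort <- cohort[cohort$true_class %in% MRS_CLASSES, , drop = FALSE]
  pch_map <- c(PA = 0, EP = 16, MB = 8)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  r1 <- if (length(x$step1) >= 2) vapply(x$step1[1:2], `[[`, "", "ratio")
        else c(x$step1[[1]]$ratio, "mins_naa")
  graphics::plot(cohort[[r1[1]]], cohort[[r1[2]]],
                 pch = pch_map[cohort$true_class], xlab = r1[1], ylab = r1[2],
                 main = "step 1", ...)
  for (cn in x$step1) {
    if (cn$ratio == r1[1]) graphics::abline(v = cn$cutoff, lty = 2)
    if (cn$ratio == r1[2]) graphics::abline(h = cn$cutoff, lty = 2)
  }
  r2 <- x$step2$ratio
  r2x <- if (r2 == "cr_tcho") "mins_tcho" else "cr_tcho"
  graphics::plot(cohort[[r2]], cohort[[r2x]],
                 pch = pch_map[cohort$true_class], xlab = r2, ylab = r2x,
                 main = "step 2", ...)
  graphics::abline(v = x$step2$cutoff, lty = 2)
  invisible(x)
}
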