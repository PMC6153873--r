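test_that("one-way ANOVA matches hand-computed values", {
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_oneway(c(1, 2, 3, 11, 12, 13, 21, 22, 23), g)
  expect_equal(res$F, 300)  # between-group MS 300, within MS 1
  expect_lt(res$p, 1e-4)

  same <- anova_oneway(rep(c(1, 2, 3), 3), g)
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # p decreases monotonically as one group shifts away
  ps <- vapply(c(0.5, 1, 2, 4), function(d)
    anova_oneway(c(1, 2, 3, 1, 2, 3, 1 + d, 2 + d, 3 + d), g)$p, 0)
  expect_true(all(diff(ps) < 0))

  expect_error(anova_oneway(1:4, c("a", "a", "b", "c")), ">= 2")
})

test_that("Welch t-test reproduces the textbook example and is symmetric", {
  p <- two_tailed_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-6)  # t = 3.674
  expect_equal(p, 0.0213, tolerance = 1e-3)
  expect_identical(two_tailed_t(c(1, 2, 3), c(4, 5, 6)),
                   two_tailed_t(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(two_tailed_t(c(2, 4, 6), c(2, 4, 6)), 1)
  expect_equal(two_tailed_t(c(1, 1, 1), c(1, 1)), 1)
  expect_error(two_tailed_t(1, c(1, 2)), ">= 2")
})

test_that("AUC equals the pairwise-comparison probability", {
  sep <- roc_auc(c(10, 11, 12, 1, 2, 3), c(TRUE, TRUE, TRUE, rep(FALSE, 3)))
  expect_equal(sep$auc, 1)
  expect_equal(sep$direction, "high")

  tied <- roc_auc(rep(1, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(tied$auc, 0.5)

  inter <- roc_auc(c(2, 4, 6, 1, 3, 5), c(TRUE, TRUE, TRUE, rep(FALSE, 3)))
  expect_equal(inter$auc, 6 / 9)

  # low-direction scores are reported re-oriented
  low <- roc_auc(c(1, 2, 3, 10, 11, 12), c(TRUE, TRUE, TRUE, rep(FALSE, 3)))
  expect_equal(low$auc, 1)
  expect_equal(low$direction, "low")

  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with the brute-force oracle and pROC on random data", {
  set.seed(31)
  for (i in 1:120) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # many ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    mine <- roc_auc(scores, labels)
    oracle <- auc_brute(scores, labels)
    expect_equal(mine$auc_raw, oracle, tolerance = 1e-12)
    expect_equal(mine$auc, max(oracle, 1 - oracle), tolerance = 1e-12)
  }
  # independent library cross-check
  set.seed(8)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4) == 1
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc_raw, ref, tolerance = 1e-9)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  scores <- rlnorm(40)
  labels <- rbinom(40, 1, 0.5) == 1
  a <- roc_auc(scores, labels)$auc_raw
  expect_equal(roc_auc(log(scores), labels)$auc_raw, a)
  expect_equal(roc_auc(scores^3, labels)$auc_raw, a)
  expect_equal(roc_auc(rank(scores), labels)$auc_raw, a)
})

test_that("the optimal cutoff maximises sensitivity plus specificity", {
  oc <- optimal_cutoff(c(1, 2, 3, 4, 5, 6), c(rep(FALSE, 3), rep(TRUE, 3)))
  expect_equal(oc$cutoff, 3.5)
  expect_equal(oc$youden, 2)

  # fully interleaved identical distributions: best achievable is 1.0,
  # reached at a sentinel (all-negative call, specificity 1)
  oc2 <- optimal_cutoff(rep(1:5, 2), rep(c(TRUE, FALSE), each = 5))
  expect_equal(oc2$youden, 1)
  expect_equal(oc2$specificity, 1)

  expect_error(optimal_cutoff(1:3, rep(TRUE, 3)), "both classes")
})

test_that("optimal cutoff equals the exhaustive scan on random instances", {
  set.seed(99)
  for (i in 1:120) {
    n <- sample(4:50, 1)
    scores <- round(rnorm(n), 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    for (dir in c("high", "low")) {
      mine <- optimal_cutoff(scores, labels, direction = dir)
      oracle <- cutoff_brute(scores, labels, dir)
      expect_equal(mine$youden, oracle$youden, tolerance = 1e-12)
      expect_equal(mine$cutoff, oracle$cutoff, tolerance = 1e-12)
      # no scanned threshold does better
      expect_gte(mine$youden + 1e-12, oracle$youden)
    }
  }
})

test_that("refinement selects the generative ratios on a single cohort", {
  tab <- sample_ratio_profiles(sim_config(c(PA = 150, EP = 150, MB = 150),
                                          seed = 61))
  fit <- mrs_refine(tab)
  expect_setequal(vapply(fit$step1, `[[`, "", "ratio"),
                  c("naa_cr", "mins_naa"))
  expect_equal(fit$step2$ratio, "mins_tcho")
  expect_true(all(c("naa_cr", "mins_naa") %in% fit$anova$ratio[fit$anova$retained]))
  expect_s3_class(fit$scheme, "mrs_scheme")
  expect_gt(fit$evaluation$overall_pct, 80)
})

test_that("an uninformative ratio is discarded by the ANOVA screen", {
  # lmm09_lmm13 replaced by the same distribution in all classes: it should
  # be discarded in ~95% of replicates (type-I retention only); 60 draws
  # bound the check at >= 85% allowing 3-sigma binomial fluctuation
  discarded <- vapply(1:60, function(i) {
    tab <- sample_ratio_profiles(sim_config(c(PA = 20, EP = 20, MB = 20),
                                            seed = 500 + i))
    set.seed(1000 + i)
    tab$lmm09_lmm13 <- rlnorm(nrow(tab), 0, 0.3)
    fit <- mrs_refine(tab)
    !("lmm09_lmm13" %in% fit$anova$ratio[fit$anova$retained])
  }, TRUE)
  expect_gte(mean(discarded), 0.85)
})

test_that("refinement is invariant to the case order", {
  tab <- sample_ratio_profiles(sim_config(c(PA = 30, EP = 30, MB = 30),
                                          seed = 17))
  fit1 <- mrs_refine(tab)
  set.seed(2)
  fit2 <- mrs_refine(tab[sample(nrow(tab)), ])
  expect_equal(coef(fit1), coef(fit2))
  expect_equal(fit1$anova, fit2$anova)
  expect_equal(fit1$auc, fit2$auc)
  expect_equal(fit1$scheme$steps, fit2$scheme$steps)
})

test_that("refinement demands adequate class representation", {
  tab <- sample_ratio_profiles(sim_config(c(PA = 10, EP = 3, MB = 10), seed = 4))
  expect_error(mrs_refine(tab), ">= 4 cases")
})

test_that("the fitted object supports the standard S3 verbs", {
  tab <- sample_ratio_profiles(sim_config(c(PA = 40, EP = 40, MB = 40),
                                          seed = 23))
  fit <- mrs_refine(tab)
  expect_named(coef(fit))
  expect_output(print(fit), "Refined peak-height ratio classifier")
  expect_output(print(summary(fit)), "ANOVA screen")
  pred <- predict(fit, tab)
  expect_equal(nrow(pred), nrow(tab))
  expect_true(all(pred$predicted_class %in% c("PA", "EP", "MB")))
  # fitted values follow the (case_id-sorted) training order
  pred_sorted <- predict(fit, tab[order(tab$case_id), ])
  expect_equal(fitted(fit), pred_sorted$predicted_class)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(fit, tab))
  grDevices::dev.off()
})
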