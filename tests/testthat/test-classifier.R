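test_that("ratio computation does the arithmetic and names the culprit", {
  r <- compute_ratios(c(naa = 9, cr = 2, tcho = 4, mins = 3,
                        lmm09 = 1, lmm13 = 2))
  expect_equal(unname(r["naa_cr"]), 4.5)
  expect_equal(unname(r["cr_tcho"]), 0.5)
  expect_equal(unname(r["mins_naa"]), 1 / 3)

  all1 <- compute_ratios(setNames(rep(2, 6),
                                  c("naa", "cr", "tcho", "mins", "lmm09", "lmm13")))
  expect_true(all(all1 == 1))

  expect_error(compute_ratios(c(naa = 1, cr = 0, tcho = 1, mins = 1,
                                lmm09 = 1, lmm13 = 1)), "creatine")
  # internal consistency
  expect_equal(unname(r["naa_cr"] * r["cr_tcho"]), unname(r["naa_tcho"]),
               tolerance = 1e-6)
})

test_that("the updated scheme reproduces the published worked examples", {
  rare <- rare_tumour_profiles()
  get <- function(id) rare[rare$case_id == id, ]

  atrt <- classify_updated(get("atrt"))
  expect_equal(atrt$label, "PA")
  expect_equal(atrt$step_fired, 1L)

  diffuse <- classify_updated(get("diffuse_astrocytoma"))
  expect_equal(diffuse$label, "EP")

  gg <- classify_updated(get("ganglioglioma"))
  expect_equal(gg$label, "MB")
  expect_equal(gg$step_fired, 2L)

  hg <- classify_updated(get("high_grade"))
  expect_equal(hg$label, "EP")  # mins_tcho 0.872 sits just above the cutoff
})

test_that("cutoffs are strict: boundary values fall through", {
  r <- c(naa_cr = 2.22, mins_naa = 0.3, mins_tcho = 0.5)
  res <- classify_updated(r)
  expect_equal(res$label, "MB")
  expect_equal(res$step_fired, 2L)

  r2 <- c(naa_cr = 3, mins_naa = 0.3, mins_tcho = 0.85)
  r2["mins_naa"] <- 0.65
  expect_equal(classify_updated(r2)$label, "EP")
})

test_that("the generic engine agrees with the hard-coded updated rules", {
  set.seed(123)
  sch <- scheme_updated()
  for (i in 1:1000) {
    r <- random_ratio_vector()
    a <- classify_updated(r)
    b <- classify_with_scheme(sch, r)
    expect_identical(a$label, b$label)
    expect_identical(a$step_fired, b$step_fired)
  }
})

test_that("scheme engine handles degenerate and invalid schemes", {
  empty <- mrs_scheme(steps = list(), else_label = "EP")
  expect_equal(classify_with_scheme(empty, random_ratio_vector())$label, "EP")

  expect_error(
    mrs_scheme(steps = list(list(label = "PA", conditions = list(
      list(ratio = "nope", op = ">", cutoff = 1)))), else_label = "EP"),
    "unknown ratio")
})

test_that("the re-optimised original cutoffs classify the ATRT mean as PA", {
  atrt <- rare_tumour_profiles()[1, ]
  res <- classify_with_scheme(scheme_reoptimized(), atrt)
  expect_equal(res$label, "PA")
  # and the original cutoff of 4 also captures it (naa_cr = 4.502)
  expect_equal(classify_with_scheme(scheme_original(), atrt)$label, "PA")
})

test_that("classification is invariant to an overall intensity scaling", {
  set.seed(5)
  for (i in 1:50) {
    h <- rlnorm(6, log(c(4, 3, 5, 3, 2, 2)), 0.5)
    names(h) <- c("naa", "cr", "tcho", "mins", "lmm09", "lmm13")
    k <- runif(1, 0.1, 10)
    expect_identical(classify_updated(compute_ratios(h))$label,
                     classify_updated(compute_ratios(h * k))$label)
  }
})

test_that("scheme evaluation produces coherent confusion matrices", {
  # a perfect cohort: archetypes classified as their own class
  conf <- diag(c(5, 4, 6))
  dimnames(conf) <- list(truth = c("PA", "EP", "MB"),
                         predicted = c("PA", "EP", "MB"))
  cohort <- cohort_from_confusion(conf)
  ev <- evaluate_scheme(cohort, scheme_updated())
  expect_equal(unname(diag(ev$confusion)), c(5, 4, 6))
  expect_equal(ev$overall_pct, 100)
  expect_equal(unname(ev$per_class_pct), c(100, 100, 100))

  # row sums always match the class counts
  tab <- sample_ratio_profiles(sim_config(c(PA = 30, EP = 20, MB = 25), seed = 3))
  ev2 <- evaluate_scheme(tab, scheme_updated())
  expect_equal(unname(rowSums(ev2$confusion)), c(30, 20, 25))
  expect_equal(ev2$overall_pct,
               round(100 * sum(diag(ev2$confusion)) / 75, 1))

  expect_error(evaluate_scheme(tab[0, ], scheme_updated()), "empty")
})

test_that("schemes survive a YAML round trip", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(scheme_updated(), f)
  back <- read_scheme(f)
  expect_equal(back$steps, scheme_updated()$steps)
  expect_equal(back$else_label, "EP")
  set.seed(77)
  for (i in 1:100) {
    r <- random_ratio_vector()
    expect_identical(classify_with_scheme(back, r)$label,
                     classify_updated(r)$label)
  }

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: broken", "steps:",
               "- label: PA", "  conditions:",
               "  - ratio: not_a_ratio", "    op: '>'", "    cutoff: 1",
               "else_label: EP"), bad)
  expect_error(read_scheme(bad), "unknown ratio")
})
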