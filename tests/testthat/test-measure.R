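flat_axis <- function(n = 1024) seq(4.5, 0, length.out = n)

test_that("noise estimation is unbiased and robust to a linear trend", {
  zero <- mrs_spectrum(flat_axis(), rep(0, 1024))
  nz <- estimate_noise(zero)
  expect_equal(as.numeric(nz), 0)
  expect_equal(attr(nz, "flag"), "zero_noise")

  # Monte-Carlo over seeds: sd estimate from ~90 points of the default
  # region should concentrate near the true sd of 1
  ests <- vapply(1:100, function(i) {
    set.seed(i)
    s <- mrs_spectrum(flat_axis(512), rnorm(512, sd = 1))
    as.numeric(estimate_noise(s))
  }, 0)
  expect_gt(mean(ests), 0.8)
  expect_lt(mean(ests), 1.2)
  expect_true(all(ests > 0.6 & ests < 1.4))

  set.seed(42)
  noise <- rnorm(512, sd = 1)
  ax <- flat_axis(512)
  plainest <- as.numeric(estimate_noise(mrs_spectrum(ax, noise)))
  sloped <- as.numeric(estimate_noise(mrs_spectrum(ax, noise + 2 * ax)))
  expect_equal(sloped, plainest, tolerance = 0.1)
})

test_that("noise region preconditions are enforced", {
  s <- mrs_spectrum(flat_axis(), rep(0, 1024))
  expect_error(estimate_noise(s, c(4.4, 5.0)), "outside")
  expect_error(estimate_noise(s, c(3.0, 3.4)), "overlaps")
  expect_error(estimate_noise(s, c(4.40, 4.45)), "fewer than 32")
})

test_that("baseline flatness follows the 2-sigma criterion", {
  set.seed(7)
  ax <- flat_axis()
  noise_only <- mrs_spectrum(ax, rnorm(1024, sd = 0.05))
  expect_equal(assess_baseline(noise_only), "flat")

  peaks <- synthesize_spectrum(standard_heights,
                               sim_config(noise_sd = 0.05), seed = 8)
  expect_equal(assess_baseline(peaks), "flat")

  hump <- mrs_spectrum(ax, rnorm(1024, sd = 0.05) +
                         0.5 * exp(-(ax - 2.5)^2 / (2 * 0.5^2)))
  expect_equal(assess_baseline(hump), "non_flat")
})

test_that("peak height measurement matches the closed form", {
  cfg <- sim_config()
  s <- synthesize_spectrum(c(cr = 10), cfg)
  h <- measure_peak_height(s, c(2.9, 3.1), "flat",
                           baseline_level = 0)
  expect_equal(as.numeric(h), 10, tolerance = 0.1)

  # constant offset is removed through the global baseline level
  s_off <- mrs_spectrum(s$ppm, s$intensity + 3)
  lev <- median(mrspeaks:::baseline_fit(s_off))
  h_off <- measure_peak_height(s_off, c(2.9, 3.1), "flat", baseline_level = lev)
  expect_equal(as.numeric(h_off), 10, tolerance = 0.1)

  expect_error(measure_peak_height(s, c(9, 10), "flat"), "empty")
  edge <- measure_peak_height(s, c(2.5, 3.03 - 0.02), "flat")
  expect_equal(attr(edge, "flag"), "apex_on_edge")
})

test_that("local-base mode agrees with the analytic overlap oracle", {
  # two overlapping Lorentzians; the local base interpolates the valleys
  cfg <- sim_config(linewidth = 0.05)
  s <- synthesize_spectrum(c(cr = 8, tcho = 10), cfg)
  h <- measure_peak_height(s, c(2.9, 3.1), "local_base")

  dense <- seq(2.0, 4.0, by = 1e-4)
  y <- analytic_spectrum(dense, list(cr = 8, tcho = 10), linewidth = 0.05)
  apex_i <- which(dense > 2.9 & dense < 3.1)[
    which.max(y[dense > 2.9 & dense < 3.1])]
  # flanking minima of the analytic curve around the Cr apex
  dy <- diff(y)
  mins <- which(dy[-1] > 0 & dy[-length(dy)] <= 0) + 1
  left <- max(c(1, mins[mins < apex_i]))
  right <- min(c(length(y), mins[mins > apex_i]))
  base <- approx(dense[c(left, right)], y[c(left, right)],
                 xout = dense[apex_i])$y
  oracle <- y[apex_i] - base
  expect_equal(as.numeric(h), oracle, tolerance = 0.02 * oracle)
})

test_that("the NAA rule distinguishes narrow peaks from broad envelopes", {
  cfg <- sim_config(noise_sd = 0.05)
  sharp <- synthesize_spectrum(c(naa = 8, tcho = 6), cfg, seed = 5)
  m <- measure_naa(sharp)
  expect_equal(m$naa_mode, "narrow")
  expect_equal(m$height, 8, tolerance = 0.4)

  # broad envelope spanning ~2.0-2.5 ppm with no narrow line: the value at
  # 2.0 ppm of the closed-form hump is reported in broad mode
  ax <- flat_axis()
  hump <- 3 * exp(-(ax - 2.3)^2 / (2 * 0.25^2))
  set.seed(11)
  s <- mrs_spectrum(ax, hump + rnorm(1024, sd = 0.05))
  m2 <- measure_naa(s, noise_sd = 0.05)
  expect_equal(m2$naa_mode, "broad")
  expect_equal(m2$height, 3 * exp(-(2.0 - 2.3)^2 / (2 * 0.25^2)),
               tolerance = 0.15)

  flat <- mrs_spectrum(ax, rep(0, 1024))
  m3 <- measure_naa(flat, noise_sd = 0.01)
  expect_equal(m3$naa_mode, "broad")
  expect_equal(m3$height, 0)
})

test_that("measure_all recovers simulated heights and is deterministic", {
  cfg <- sim_config(noise_sd = 0.05)
  s <- synthesize_spectrum(standard_heights, cfg, seed = 3)
  pk <- measure_all(s)
  expect_s3_class(pk, "mrs_peaks")
  rel_err <- abs(pk$heights - standard_heights) / standard_heights
  expect_true(all(rel_err < 0.05))
  expect_equal(pk$naa_mode, "narrow")
  expect_identical(pk, measure_all(s))

  zero <- mrs_spectrum(flat_axis(), rep(0, 1024))
  pk0 <- measure_all(zero)
  expect_true(all(pk0$heights == 0))
})

test_that("heights are offset-invariant (flat mode) and scale linearly", {
  cfg <- sim_config(noise_sd = 0.03)
  s <- synthesize_spectrum(standard_heights, cfg, seed = 9)
  pk <- measure_all(s)

  s_off <- mrs_spectrum(s$ppm, s$intensity + 5)
  pk_off <- measure_all(s_off)
  expect_equal(pk_off$heights, pk$heights, tolerance = 0.02)

  s_scaled <- mrs_spectrum(s$ppm, 4 * s$intensity)
  pk_scaled <- measure_all(s_scaled)
  expect_equal(pk_scaled$heights, 4 * pk$heights, tolerance = 1e-8)
})
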