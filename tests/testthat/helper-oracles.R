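# Independent oracles and small fixture builders used across the suite.

# Pairwise-comparison AUC: P(score_pos > score_neg), ties counting 1/2.
auc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive threshold scan for the Youden-optimal cutoff, coded
# independently of optimal_cutoff(): tabulates sens/spec at every midpoint
# candidate and picks max youden, ties to higher specificity.
cutoff_brute <- function(scores, labels, direction) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  pad <- max(1, diff(range(u)))
  cand <- c(u[1] - pad, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + pad)
  rows <- t(vapply(cand, function(t) {
    call_pos <- if (direction == "high") scores > t else scores < t
    c(sens = mean(call_pos[labels]), spec = mean(!call_pos[!labels]))
  }, c(sens = 0, spec = 0)))
  youden <- rows[, "sens"] + rows[, "spec"]
  keep <- which(youden > max(youden) - 1e-12)
  best <- keep[which.max(rows[keep, "spec"])]
  list(cutoff = cand[best], youden = youden[best])
}

# Closed-form Youden-optimal threshold for a log-normal positive class
# against a log-normal mixture, from the generative parameters (plnorm
# only, no package code). direction "high": positive class above cutoff.
true_youden_lognorm <- function(pos, mix, direction, interval) {
  sens <- function(t) {
    v <- plnorm(t, pos$meanlog, pos$sdlog)
    if (direction == "high") 1 - v else v
  }
  spec <- function(t) {
    v <- sum(vapply(mix, function(m)
      m$w * plnorm(t, m$meanlog, m$sdlog), 0))
    if (direction == "high") v else 1 - v
  }
  opt <- optimize(function(lt) sens(exp(lt)) + spec(exp(lt)),
                  interval = log(interval), maximum = TRUE, tol = 1e-9)
  exp(opt$maximum)
}

# Generative truth for the three fitted cutoffs under the default
# simulation parameters (equal class weights).
generative_truths <- function(params = default_ratio_params()) {
  ml <- function(cl, num, den)
    log(params[[cl]][[num]]$med) - log(params[[cl]][[den]]$med)
  sl <- function(cl, num, den)
    sqrt(params[[cl]][[num]]$sdlog^2 + params[[cl]][[den]]$sdlog^2)
  list(
    naa_cr = true_youden_lognorm(
      pos = list(meanlog = ml("PA", "naa", "cr"), sdlog = sl("PA", "naa", "cr")),
      mix = list(list(w = .5, meanlog = ml("EP", "naa", "cr"),
                      sdlog = sl("EP", "naa", "cr")),
                 list(w = .5, meanlog = ml("MB", "naa", "cr"),
                      sdlog = sl("MB", "naa", "cr"))),
      direction = "high", interval = c(0.3, 10)),
    mins_naa = true_youden_lognorm(
      pos = list(meanlog = ml("PA", "mins", "naa"), sdlog = sl("PA", "mins", "naa")),
      mix = list(list(w = .5, meanlog = ml("EP", "mins", "naa"),
                      sdlog = sl("EP", "mins", "naa")),
                 list(w = .5, meanlog = ml("MB", "mins", "naa"),
                      sdlog = sl("MB", "mins", "naa"))),
      direction = "low", interval = c(0.1, 5)),
    mins_tcho = true_youden_lognorm(
      pos = list(meanlog = ml("MB", "mins", "tcho"), sdlog = sl("MB", "mins", "tcho")),
      mix = list(list(w = 1, meanlog = ml("EP", "mins", "tcho"),
                      sdlog = sl("EP", "mins", "tcho"))),
      direction = "low", interval = c(0.1, 5)))
}

# Noise-free closed-form spectrum model matching synthesize_spectrum()
# (Lorentzian gamma = linewidth, Gaussian LMM humps), for dense-grid
# oracle evaluation.
analytic_spectrum <- function(ppm, heights, linewidth = 0.03, lmm_width = 0.07,
                              centres = c(naa = 2.02, cr = 3.03, tcho = 3.20,
                                          mins = 3.56)) {
  y <- numeric(length(ppm))
  for (pk in names(centres))
    if (!is.null(heights[[pk]]) && heights[[pk]] > 0)
      y <- y + heights[[pk]] * linewidth^2 /
        ((ppm - centres[[pk]])^2 + linewidth^2)
  lmm <- c(lmm09 = 0.90, lmm13 = 1.30)
  for (pk in names(lmm))
    if (!is.null(heights[[pk]]) && heights[[pk]] > 0)
      y <- y + heights[[pk]] * exp(-(ppm - lmm[[pk]])^2 / (2 * lmm_width^2))
  y
}

# a random but internally consistent ratio vector built from latent heights
random_ratio_vector <- function() {
  h <- stats::rlnorm(6, meanlog = log(c(4, 3, 5, 3, 2, 2.5)), sdlog = 0.6)
  names(h) <- c("naa", "cr", "tcho", "mins", "lmm09", "lmm13")
  compute_ratios(h)
}

standard_heights <- c(naa = 8, cr = 4, tcho = 6, mins = 5, lmm09 = 2, lmm13 = 3)
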