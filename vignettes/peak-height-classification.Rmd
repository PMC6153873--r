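---
title: "Peak-height classification of childhood cerebellar tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-height classification of childhood cerebellar tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrspeaks)
```

## The problem and the method

Pilocytic astrocytoma (PA), medulloblastoma (MB) and ependymoma (EP)
account for most childhood cerebellar tumours, and their preoperative
distinction matters for surgical planning and counselling. In-vivo
^1^H MR spectroscopy at 1.5 T (single-voxel PRESS, short echo time
28–35 ms) measures the metabolite profile of the tumour non-invasively,
but most published classifiers need processing machinery that is not
available at the scanner console. The approach implemented here is
deliberately minimal: read peak *heights* — not fitted areas — for six
resonances directly off the scanner-processed spectrum, form ratios, and
apply two rules.

The six measured peaks are N-acetyl aspartate (NAA, 2.02 ppm), creatine
(Cr, 3.03 ppm), total choline (tCho, 3.20 ppm), myo-inositol (mIns,
3.56 ppm) and the lipid/macromolecule resonances at 0.9 and 1.3 ppm
(LMM0.9, LMM1.3). Heights are unitless (arbitrary units) and only their
nine pairwise ratios enter the classifier, which removes the overall
scaling freedom of scanner output: `mrspeaks` verifies this scale
invariance by property test.

The updated two-step decision scheme is:

* **Step 1** — call **PA** if NAA/Cr > 2.22 **and** mIns/NAA < 0.65.
  PA shows strikingly low creatine and low myo-inositol for its NAA
  level, so both conditions point the same way.
* **Step 2** — otherwise call **MB** if mIns/tCho < 0.85, else **EP**.
  Ependymoma carries high myo-inositol; medulloblastoma's very high
  choline suppresses all x/tCho ratios.

Comparisons are strict: a case sitting exactly on a cutoff falls
through to the next step. Cr/tCho and NAA/tCho serve as plausibility
checks on a step-2 assignment; they never override the label, only
raise flags, because no published override rule exists.

Two sibling schemes ship alongside: `scheme_original()` (a documented
*reconstruction* of the first-generation scheme — its exact step
structure was never restated, only its three ratios, the NAA/Cr cutoff
of 4, and its re-optimised cutoffs) and `scheme_reoptimized()` (same
structure with cutoffs 2.22 / 1.35 / 0.45).

## Measuring peak heights

`measure_all()` operationalises manual height reading:

1. **Noise** is the sd of linearly detrended intensities in a peak-free
   region, by default 4.05–4.45 ppm (present on the default axis and
   clear of every window).
2. **Baseline flatness**: a lowess baseline is fitted through the
   peak-free points (peak windows inflated by 0.25 ppm so Lorentzian
   tails do not pull it). If its maximal deviation from its median stays
   within 2× the noise sd, the baseline is "flat" and every height is
   measured from the single global baseline level; otherwise each height
   is measured from the base of the individual peak — a linear
   interpolation between the nearest flanking local minima — to the
   apex. The 2-sigma criterion encodes "visually flat = flat to within
   noise"; no numeric criterion is standard.
3. **NAA narrow/broad rule**: short-TE spectra often show a broad
   envelope at 2.0–2.5 ppm (lipids, macromolecules, Glx). If a local
   maximum in 1.95–2.10 ppm has prominence above 2× noise, NAA is
   taken from that narrow line; otherwise the envelope height at
   2.0 ppm is used, and the result is flagged `broad`. Extrema are
   detected on a 7-point running mean so that noise wiggles on a broad
   envelope are not mistaken for a narrow line; heights themselves are
   always read from the raw trace.

Because software measurement is deterministic, the triplicate manual
re-measurement used in clinical practice is replaced by a single
computed value.

Quality control mirrors clinical screening: Cr and tCho must be
visually separated (operationalised as the inter-apex valley dipping at
least 10% below the lower apex — the 10% depth is a package choice) and
the tCho height must be at least five times the noise level (inclusive,
reading "at least" literally). QC is monotone in noise by construction
and verified by property test.

## The refinement procedure

`mrs_refine()` re-derives the scheme from a labelled cohort,
reproducing the published pipeline as a deterministic algorithm:

1. one-way equal-variance ANOVA across the three classes; ratios with
   p ≥ 0.05 are discarded (no multiple-testing correction is applied,
   matching the original procedure; this is a screening step, not an
   inferential claim);
2. two-tailed Welch t-tests for PA-vs-other and MB-vs-EP (Welch chosen
   because group sizes and spreads are unequal);
3. ROC AUCs for the four contrasts (each class vs all, EP vs MB),
   computed by the Mann–Whitney pairwise construction with ties
   counting ½ and reported as `max(a, 1-a)` with a direction flag,
   since a ratio can separate in either orientation;
4. step 1 = all ratios with PA-vs-rest AUC > 0.9, as a conjunction,
   each cutoff chosen by maximising sensitivity + specificity over all
   midpoints between adjacent unique scores (with sentinels); ties go
   to the higher-specificity threshold, making the scan reproducible
   and oracle-checkable;
5. step 2 = the single best EP-vs-MB ratio, with the next two recorded
   as checks;
6. evaluation of the fitted scheme on the training cohort.

The fitted object behaves like an R model: `print()`, `summary()`,
`coef()` (the cutoffs), `predict(fit, newdata)`, `fitted()` and
`plot(fit, cohort)` (the two classification-axes scatterplots).

```{r}
cohort <- sample_ratio_profiles(sim_config(c(PA = 100, EP = 100, MB = 100),
                                           seed = 1))
fit <- mrs_refine(cohort)
fit
coef(fit)
```

## What the synthetic generator emulates — and what it does not

No per-case patient ratios are published, so everything stochastic in
this package is validated on synthetic cohorts. Per class, the
generator draws latent log-normal heights for NAA, Cr, mIns, LMM0.9 and
LMM1.3 relative to tCho, with tCho carrying its own log-normal spread.
This latent-height construction has two deliberate consequences:

* the nine ratios of any generated case are exactly mutually consistent
  (mIns/NAA ≡ (mIns/tCho)/(NAA/tCho)), as they are for real measured
  heights;
* all x/tCho ratios share the tCho noise while ratios between two
  metabolites cancel it — the same variance structure that makes
  height ratios attractive in practice.

Log-normals are used because ratios are positive and right-skewed. The
class medians and spreads (see `default_ratio_params()`) are a one-time
calibration chosen so that large simulated cohorts reproduce the
*qualitative* discrimination structure of the reference evaluation —
NAA/Cr near-perfect and mIns/NAA strong for PA-vs-rest (the only two
AUCs above 0.9), mIns/tCho the dominant EP/MB discriminator, the other
six ratios moderate-to-weak — and an updated-scheme accuracy of roughly
90% with the great majority of PA cases satisfying the step-1 rule.
They are *not* published values, and passing simulation tests shows the
pipeline recovers the structure of data shaped like this model, not
that it would perform identically on real multicentre spectra.

Spectra are synthesised at the processed-spectrum level: Lorentzian
metabolite lines (the `linewidth` parameter is the half-width at
half-maximum, default 0.03 ppm, which keeps Cr and tCho visually
resolved at 1.5 T), Gaussian LMM humps (sd 0.07 ppm), an optional
slowly varying sinusoidal baseline, an optional residual-water tail at
4.7 ppm, and white Gaussian noise. The default axis is 1024 points over
0–4.5 ppm, descending (display convention). Peak centres are snapped to
the nearest grid point (≤ half a grid step, far below any linewidth) so
a noise-free apex equals the requested height exactly. The myo-inositol
position is not universal across vendors and is configurable
(`mins_ppm`, default 3.56 ppm). There is no FID/k-space simulation, no
eddy-current or water-suppression modelling, no multiplet structure —
notably, the mIns multiplet at 3 T would look different, and the tool
is calibrated for 1.5 T only.

## Numerical choices and degenerate inputs

* Zero denominators (Cr, tCho, NAA or LMM1.3 heights of 0) make ratios
  undefined; `compute_ratios()` refuses them by name rather than
  emitting `Inf`.
* A perfectly noiseless trace gives noise sd 0, which is flagged; QC
  then cannot run (the SNR rule divides by noise), which is the correct
  outcome for a degenerate input.
* The published rare-tumour table contains two exact zeros (the diffuse
  astrocytoma has no measurable 1.3-ppm signal), so cohort validation
  accepts zero ratio *values* while ratio *computation* requires
  positive denominators.
* ANOVA on groups with zero variance everywhere returns F = 0, p = 1.
* The Youden scan breaks ties toward higher specificity; on fully
  interleaved score distributions the optimum (sensitivity +
  specificity = 1) is reached at a sentinel threshold, i.e. "call
  nobody positive", which is reported as such rather than hidden.
* If no ratio clears the step-1 AUC threshold of 0.9, the best
  available ratio is used with a warning rather than failing — a small
  cohort can legitimately lack a 0.9-AUC separator.

## Problem sizes used in validation

The shipped test suite exercises the stochastic claims at sizes chosen
to balance statistical resolution against runtime: oracle equivalence
for AUC and Youden cutoffs on ~150 random instances of up to 50 cases;
cutoff recovery on ten cohorts of 200 cases per class (median relative
error against the closed-form generative optimum, tolerance 15%) and
twenty cohorts of 100 per class (tolerance 10%); height recovery on 100
synthetic spectra at SNR ≥ 40 (median relative error below 5%); and the
ANOVA type-I behaviour on 60 replicates. The whole suite runs in well
under a minute.

## Known limitations

* The original scheme is a reconstruction (flagged in its name); its
  published step structure may have differed in detail.
* The printed re-optimised overall rate of 64.2% is inconsistent with
  the stated per-class counts (14 + 7 + 14 correct of 52) and is
  therefore not reproduced or asserted anywhere.
* Whether the QC-outlier pilocytic astrocytoma counts inside "48 of 53"
  is ambiguous in the source material; the package reports rates from
  explicit confusion counts so the ambiguity never enters a
  computation.
* Heights are apex readings; no lineshape fitting is attempted, so a
  strongly overlapped mIns/tCho region at poor shim will bias heights
  in ways QC is meant to catch, not correct.
* DICOM MR spectroscopy parsing is out of scope; spectra enter as
  two-column CSV exports.
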