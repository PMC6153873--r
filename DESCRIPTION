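Package: mrspeaks
Title: Peak-Height Classification of Childhood Cerebellar Tumours from MR Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rule-based diagnosis of childhood cerebellar tumours
    (pilocytic astrocytoma, medulloblastoma, ependymoma) from 1.5-T short
    echo-time single-voxel proton MR spectroscopy. Measures metabolite peak
    heights (NAA, creatine, total choline, myo-inositol, lipid/macromolecule
    resonances) from processed spectra, applies spectral quality control,
    forms peak-height ratios and classifies cases with a configurable
    two-step decision scheme. A refinement procedure re-derives the scheme
    from a labelled cohort by one-way ANOVA screening, Welch t-tests,
    ROC-AUC ranking and Youden-style cutoff optimisation. A synthetic
    spectrum and cohort simulator supports end-to-end validation without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
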