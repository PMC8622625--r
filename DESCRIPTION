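Package: ftmslipids
Title: Untargeted FT-MS Lipidomics of Paired Cancer and Non-Cancer Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for untargeted Fourier-transform mass
    spectrometry (FT-MS) lipidomics of paired cancer/non-cancer tissue
    samples. Provides cross-spectrum peak correspondence by elemental
    molecular formula (EMF) voting, per-sample median normalization with
    left-censored imputation, a missing-value-aware Kendall-tau
    correlation for sample quality control, dual differential-abundance
    testing (moderated linear models with an instrument covariate plus a
    two-part zero-inflated statistic) under Benjamini-Hochberg control,
    and hypergeometric lipid-category enrichment with a sphingolipid
    m/z split. A synthetic-cohort generator emulates the paired
    two-class, two-instrument study design with isotopologue peaks,
    assignment ambiguity, and missing-not-at-random intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
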