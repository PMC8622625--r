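---
title: "Methods: untargeted FT-MS lipidomics of paired tissue samples"
author: "ftmslipids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted FT-MS lipidomics of paired tissue samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftmslipids)
```

## The analysis problem

Direct-infusion ultra-high-resolution (FT-MS) lipidomics of tissue produces,
per sample, a list of characterized peaks with candidate isotope-resolved
molecular formula (IMF) assignments. Comparing paired cancer and non-cancer
tissue across a patient cohort then faces four coupled obstacles:

* **assignment ambiguity** — a peak may carry several candidate elemental
  molecular formulas (EMFs), and the same compound must be recognized as the
  same feature across spectra;
* **severe, informative missingness** — a feature absent from a spectrum is
  usually below the detection limit, i.e. missing-not-at-random
  (left-censored), so discarding or mean-imputing missingness destroys
  signal;
* **instrument batches** — spectra acquired on different instruments differ
  systematically, often more than cancer differs from non-cancer;
* **zero-inflated abundances** — a feature can differ between classes in
  detection rate, in abundance when detected, or both.

This package implements one coherent pipeline for that setting:
correspondence of peaks across spectra by *EMF voting*; per-sample median
normalization; per-class left-censored imputation; a missing-value-aware
Kendall-tau correlation used for sample quality control and clustering; dual
differential-abundance testing (an empirical-Bayes moderated linear model
with an instrument covariate, plus a two-part zero-inflated statistic) under
Benjamini–Hochberg control; and category-level hypergeometric enrichment with
a sphingolipid m/z split. A synthetic-cohort generator reproduces the
statistical structure of such a study so every stage can be tested against a
known ground truth.

## Peak correspondence by EMF voting

Peaks from all spectra are pooled, sorted by m/z, and chained into groups by
single linkage: consecutive peaks join a group when their gap is at most
`tol_ppm` (default 5 ppm, typical FT-MS mass accuracy) of their mean m/z.
Each group may keep only one peak per spectrum; when a spectrum contributes
two, the more intense stays and the other is demoted to a singleton group.

Within a group, every spectrum casts one ballot per *distinct* candidate EMF
it proposes for its peak (one ballot per spectrum per EMF, so a spectrum
with many candidate IMFs cannot dominate). The EMF with the most ballots
wins iff its count strictly exceeds `min_support` (default 0.5) times the
number of spectra in the group. Ties break deterministically: smallest mean
absolute ppm error between observed m/z and the candidate's theoretical ion
m/z, then lexicographic order of the formula string. The winner's
isotopologue index and adduct are the modal pair among its supporting
candidates. Corresponded features are isotopologue-level: each
(EMF, isotopologue, adduct) triple is its own feature.

Features whose supporting candidates disagree on the lipid category, or
carry a classifier multiplicity flag, are labelled `multiple`; these and
`not-lipid` features are kept in the matrix but excluded from
category-level analyses. Features are then filtered to those present in at
least 25% (inclusive) of *either* disease class, which bounds sparsity
enough for PCA and correlation analyses to be meaningful. The filter is
applied before sample QC; `refilter_after_qc` recomputes it on the reduced
cohort when requested.

## Normalization and imputation

Each intensity is divided by the median intensity over **all** characterized
peaks of its sample (not only corresponded ones), making profiles unitless
with per-sample median 1 and removing loading/injection scale. Analyses run
on log2 intensities so effects read as log2 fold changes.

Missing entries are treated as below-detection. For each tissue class, all
observed log2 intensities are pooled; the class's lower bound is the
`q = 0.025` quantile of that pool (the lower end of its central 95%
interval, a quantile interval rather than a mean ± t·SE interval — the
pooled distribution is far from normal). Every missing entry of the class is
replaced by **half of the bound on the raw scale**, i.e. bound − 1 on the
log2 scale; halving on the raw scale keeps the rule well-defined regardless
of the bound's sign in log units. Imputation feeds the linear model and the
fold changes only. Correlation, co-occurrence and the two-part test consume
the unimputed data, since for those the missingness pattern *is*
information. A feature observed in only one class therefore shows an
extreme fold change — a deliberate, interpretable artefact of bound
imputation rather than a bug.

## Missing-value-aware Kendall tau

`ici_kendall_tau()` treats every missing entry as a value strictly below all
observed entries of its vector, with all missing entries mutually tied (a
missing–missing pair is a tie). With that substitution the statistic is
Kendall's tau-b over all n(n−1)/2 index pairs:

tau = (C − D) / sqrt((P − Tx)(P − Ty)),

with C/D the concordant/discordant counts, P the pair total and Tx/Ty the
tied-pair counts per vector. It reduces exactly to classical tau-b when
nothing is missing and is invariant under strictly increasing transforms.
The missing-as-lowest tie convention is the basic left-censored form;
information-content rescaling variants exist but no downstream quantity here
uses them. The O(n²) pair computation runs in compiled code; an O(n log n)
counting scheme would change nothing contractually and is deliberately not
implemented at these problem sizes.

Feature–feature correlations instead use pairwise-complete observations with
classical tau-b (`observed_only = TRUE`): across features, shared
missingness would otherwise manufacture spurious positive correlation, and
co-occurrence is analyzed separately and explicitly via the Jaccard matrix.

## Sample quality control

Per sample: (i) the median tau to all other samples of the same disease
class; (ii) the fraction of its observed features lying outside the Tukey
fences (five-number-summary hinges ± 1.5 IQR, box-plot convention rather
than interpolated quantiles) of that feature's observed same-class values.
Per class, Tukey fences are then applied to the two per-sample statistic
distributions, and a sample is removed only when it fails **both**: median
correlation below the lower fence *and* outlier fraction above the upper
fence. The conjunction makes the rule conservative; on clean synthetic
cohorts it removes nothing, and it isolates a genuinely corrupted sample
exactly.

## Differential abundance

Samples are analyzed unpaired, although the generator produces paired
samples: with cohorts of this size the aim is differences distinct even
across patient-level biological variance, and the pipeline must behave when
pairing is ignored. Two tests run per feature:

* **Moderated linear model** (imputed log2 data): per-feature OLS on
  intercept + disease + instrument, disease contrast extracted, residual
  variances shrunk toward a scaled-inverse-chi-square prior moment-matched
  on the log variances, t taken against the posterior variance with
  augmented degrees of freedom. This is the standard limma moderated-t
  construction and the implementation uses limma (`lmFit` + `eBayes`, plain
  `eBayes` without trend or robust options). The instrument covariate is
  essential: the batch shift typically exceeds the disease effect.
* **Two-part zero-inflated test** (unimputed data): a two-proportion score
  statistic z_B on detection rates (dropped when pooled presence is 0% or
  100%), plus a tie-corrected Wilcoxon rank-sum normal approximation z_C on
  the observed values (dropped when either class has fewer than two
  observations); X² = z_B² + z_C² against chi-square with df = number of
  live parts, p = 1 when both are degenerate. This closed-form statistic
  targets the same null as semi-parametric zero-inflated regression
  estimators — no difference in detection rate and none in conditional
  abundance — while remaining dependency-free and exactly testable.

P-values are BH-adjusted per test; a feature is significant when either
adjusted p ≤ α (default 0.01), with provenance recorded. Fold change is the
cancer-minus-non-cancer mean difference on imputed log2 data; its sign
defines the direction used by enrichment. Sample dendrograms use 1 − tau
distance, average linkage, and smallest-first leaf ordering (at each merge
the subtree with smaller total internal distance goes first), which makes
heatmap layouts deterministic.

## Category enrichment

The enrichment universe is the singly categorized lipid features. Besides
the five LipidMaps-style categories (FA, GP, PR, SP, ST), sphingolipids are
annotated `SP-low` (m/z < 700) or `SP-high` (m/z ≥ 700, boundary inclusive
on the high side): sphingolipid biology splits naturally around that mass
(predominantly phosphosphingolipids above, mixtures with ceramides below).
More- and less-abundant significant sets are tested independently; each of
the 7 annotations gets an exact upper-tail hypergeometric p-value
P(X ≥ k), computed by direct log-space pmf summation, and BH adjustment is
applied **across the 7 annotations within one direction** (14 tests total,
two families). Expected counts are nK/N exactly. The SP-low/SP-high
annotations overlap SP by construction; no overlap correction is applied —
the two-annotation split is reported alongside, not instead of, the parent
category. All seven rows are always emitted, with n = 0 rows degenerating
to p = 1, so tables from different cohorts align.

`run_table1_check()` exposes this computation from bare counts
(N, per-direction K, per-annotation n and k), so the category-level table
can be recomputed from printed counts without spectra or simulation.

## The synthetic cohort generator

`sim_config()` defaults describe the emulated study: 40 patients, one
cancer and one non-cancer sample each; both samples of a patient on one of
two instruments (57% on the first); 300 EMFs with category proportions
matching the observed single-category universe composition
(FA 12 : GP 205 : PR 5 : SP 281 : ST 23); category-level log2 shifts in
cancer of +2 (ST), −1 (GP) and +1 (SP at m/z ≥ 700); patient, instrument
and residual log2 standard deviations 0.5, 1.0 and 0.3 (instrument largest,
so the leading principal component tracks instrument, as observed in real
cohorts); baseline log2 abundance N(20, 2²).

Each feature's latent log2 abundance is baseline + class effect + patient
effect + instrument effect + noise. Missingness is **left-censoring on the
latent abundance**: per class, values below the `censor_quantile` (default
0.25) quantile of the class's latent pool are omitted — exactly the
missingness model the imputation rule presumes. Each surviving EMF emits
`isotopologue_count = 3` peaks (m+0, m+1, m+2) with a fixed geometric
intensity decay of 0.3 per step — a deliberate simplification; real
isotopologue envelopes depend on carbon count. Observed m/z jitters around
the theoretical ion m/z with 1 ppm standard deviation.

Formulas are lipid-like CHNOP compositions (H ≈ 1.8 C) capped at
C130 H230 N7 O28 P3 with ion m/z ≤ 1605, under H/Na/K/NH4 positive adducts.
A fraction `ambiguity_rate = 0.2` of peaks carries a decoy candidate EMF
built by a CH2↔N swap, which preserves nominal mass and is the closest
perturbation available under the CHNOP caps (exact-mass offset ≈ 12.6 mDa,
i.e. 9–16 ppm across the lipid m/z range; no element-count perturbation
lands within 5 ppm, so decoys are near-isobars at unit mass resolution
rather than sub-5-ppm isobars). Decoys exercise the voting logic: they can
at most tie in sparse groups, where the ppm tie-break resolves in favour of
the mass-consistent candidate.

What the generator does **not** emulate: profile-mode peak shapes, noise
floors and resolution effects; chromatography; negative-mode adducts;
realistic isotopologue envelopes; correlated lipid co-regulation beyond the
shared category effects; and cohort-specific feature counts. Passing tests
therefore demonstrate correctness of the statistical machinery under the
assumed generative model, not instrument-level fidelity.

## Numerical and design choices

* Quantiles of pooled intensity distributions use R's default type-7
  interpolation; hinges for fences use the Tukey five-number convention.
* Medians of even-length sets are means of the central pair.
* All voting and clustering tie-breaks are deterministic (ppm error, then
  lexicographic; alphabetical adduct; stable orders), so pipelines rerun
  byte-identically. All randomness flows from the single generator seed.
* The 25% presence filter, α = 0.01, q = 0.025, m/z 700 split and 5 ppm
  tolerance are the pipeline defaults and are all configurable.
* Two m/z-colliding features (within tolerance) merge into one group; the
  per-spectrum demotion rule then emits the weaker peaks as singleton
  features. Collisions are rare at realistic feature densities and the
  affected features remain correctly assigned.
* Test and workflow problem sizes (40 patients, 300 EMFs, 3 isotopologues;
  20 replicate seeds for operating-characteristic checks) are desk-scale
  choices that keep the whole suite fast while leaving every statistical
  check well-powered.

## Known limitations

* The EMF ballot is unweighted (no intensity or assignment-score weights);
  weighting is a contract-compatible extension.
* The two-part statistic is a score/rank approximation; its small-sample
  size is validated empirically (type-I error within [0.03, 0.07] at
  nominal 0.05 with 20 samples per class) rather than exact.
* Missing–missing pairs are counted as ties in both vectors; alternative
  conventions (e.g. treating them as concordant) would shift correlations
  upward and are worth a sensitivity analysis if QC decisions look
  marginal.
* PCA handles missingness by feature-mean substitution before centering —
  the simplest convention consistent with normalized-intensity input; on
  very sparse features this shrinks scores toward the origin.
* Patient pairing is generated but not modelled; a mixed-effects extension
  would gain power at the cost of the closed-form machinery.
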