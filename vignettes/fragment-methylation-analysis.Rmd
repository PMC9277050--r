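---
title: "Fragment-unit RRBS differential methylation and clinical association"
author: "fragmeth package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-unit RRBS differential methylation and clinical association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

Reduced representation bisulfite sequencing (RRBS) enriches a genome for
CpG-dense regions by digesting it with MspI (recognition site CCGG) and
size-selecting fragments. Rather than testing single CpG sites, this
package uses the MspI fragments of 40–220 bp themselves as the basic
analysis units, alongside three region-level unit types: CpG islands,
promoters (±2,000 bp around the transcription start site) and gene
bodies. Per-CpG methylated/unmethylated read counts are aggregated to
unit-level methylation fractions per sample; units are compared between a
case and a control group; a unit is a differentially methylated fragment
(DMF) when it passes the triple threshold *P* < 0.05, *Q* < 0.05 (Benjamini–
Hochberg) and > 25 percentage points absolute difference in group mean
methylation. Significant fragments are annotated to genes via promoter and
gene-body overlap, and genes with promoter-associated DMFs become
candidate biomarkers. A continuous methylation biomarker measured in a
clinical cohort is then dichotomized at the control *mean + 2SD*, compared
across patient groups with the conventional contingency/rank tests, and
carried into Kaplan–Meier, log-rank and Cox proportional-hazards survival
analysis with a *P* < 0.200 univariate entry rule for the multivariate
model.

# Coordinate conventions

Internally every interval is a `GRanges`, i.e. 1-based with closed ends,
the convention of the Bioconductor ecosystem this package is built on.
External file dialects are converted at the parser boundary:

* gene-model TSVs are 0-based with an exclusive TES (`readGeneModels`),
* Bismark-style coverage files are 1-based with start = end at the
  cytosine (`readCoverage`),
* BED tracks are 0-based half-open, handled by `rtracklayer`.

Keeping a single internal convention and converting only at the edges is
what prevents off-by-one drift; the documented examples state both forms
where it matters.

# In-silico digestion

MspI cleaves C^CGG, one base into its site, so with sites at 1-based
starts $s_1 < s_2$ the fragment between them is $[s_1+1,\, s_2]$, of width
$s_2-s_1$: it begins with the CGG left by the upstream cut and ends with
the C ahead of the downstream cut. Every internal fragment therefore
contains at least one CpG. CCGG is its own reverse complement, so a
forward-strand scan is complete. Terminal contig segments are not flanked
by two cuts and are excluded by default (`include_terminal` re-adds
them). Size bounds 40 and 220 bp are inclusive at both ends; the analysis
the package follows states the range without specifying openness, and the
inclusive reading is adopted and documented here.

# Unit methylation and the per-unit test

`unitMethylation` sums methylated and total counts over the CpGs of a
unit, per sample, counting only CpGs with coverage ≥ `min_cov` (default 5
reads). A unit is kept only when every sample has ≥ `min_sites` covered
CpGs (default 1), so the unit × sample matrix is complete and no
comparison mixes units observed in different sample subsets. Cells with
no covered CpG are missing (`NA`), never zero.

Group means are **unweighted means of per-sample fractions** — a mean
over patients, matching the reading of "mean methylation difference" —
not read-pooled ratios, so a deeply sequenced sample cannot dominate the
effect estimate.

Two per-unit tests are provided, and the choice matters:

* **`test = "ttest"` (default)** — pooled-variance two-sample *t* test on
  the per-sample unit fractions. Each sample contributes one observation,
  so between-sample biological variability (the beta-binomial
  overdispersion that bisulfite data always shows) is absorbed into the
  empirical variance and the test keeps its nominal size.
* **`test = "fisher"`** — two-sided Fisher exact test on counts pooled
  within each group, the classical choice for unreplicated designs. With
  replicated overdispersed samples, pooling discards the between-sample
  variance; the implied design effect is roughly $1 + (\bar d - 1)\phi$
  (read depth $\bar d$, dispersion $\phi$), about 4 at the simulator's
  defaults, making the pooled test strongly anti-conservative: on a
  simulated null methylome it flagged roughly a sixth of all units at
  *Q* < 0.05, versus none for the *t* test. That measurement decided the
  default. Fisher remains available (it is the only option at one sample
  per group) and is verified against exhaustive hypergeometric
  enumeration in the test suite.

The published analysis this package re-implements does not name its
per-fragment test or its *Q*-value method; Benjamini–Hochberg is adopted
for *Q* as the conventional reading of "*Q*" alongside "*P*" in
methylation studies. A consequence, stated plainly: genome-scale counts
reported for the original cohort (e.g. the number of DMFs) are not
reproducible from the publication alone and are not treated as targets;
the package's correctness is instead demonstrated on simulated data with
known truth.

# CpG islands

The analysis defines no island rule, so an externally supplied BED track
is honored verbatim (`readCgiTrack`), with a Gardiner-Garden-style
detector as the built-in alternative (`detectCgi`): 200 bp windows at
1 bp step qualifying when GC ≥ 0.50 and observed/expected CpG
$= n_{CpG} L/(n_C n_G) \ge 0.60$, merged, with merged runs ≥ 200 bp
kept. Detection is idempotent up to window granularity: re-running the
detector on a detected island returns the island.

# The synthetic-data generator

The generator exists so every downstream stage is testable with no
external download; it defines the study conditions and is not tuned per
test.

* **Design**: 5 cases vs 4 controls, the discovery-cohort design of the
  study the pipeline re-implements.
* **Baseline methylation** $\mu = 0.45$: the study's printed per-sample
  global methylation levels lie between 38.9% and 51.2%.
* **Dispersion** $\phi = 0.1$ and **depth** Poisson(30) per CpG per
  sample: no depth or dispersion figures are published for the original
  libraries; these are conventional values for bone-marrow RRBS. The
  beta-binomial is parameterized so that the per-CpG methylation
  probability has mean $\mu$ and variance $\mu(1-\mu)\phi$.
* **CpG density** 0.025 per bp: the toy genome stands in for the
  CpG-enriched, MspI-accessible fraction that reduced-representation
  libraries actually capture, not a genome-wide average. Retained
  fragments then carry ~3.5 CpGs on average (every fragment starts with
  one by construction), consistent with real RRBS fragment content.
* **CCGG placement**: the background is scrubbed of all CCGG occurrences,
  then motifs are planted at the requested rate — so `ccgg_rate = 0`
  really yields a digest with no fragments, and the expected site count
  is binomial and checkable.
* **Planted effects** act at the unit level (all CpGs of a unit shifted
  equally in case samples, clamped to [0,1] with a warning), matching the
  fragment-level granularity of the analysis.
* **Islands** are planted as ~600 bp segments of i.i.d. composition with
  C and G at 0.30 each, giving GC ≈ 0.6 and CpG O/E ≈ 1 — comfortably
  inside the detector's criteria, so recovery of planted islands is a
  meaningful check.
* **Survival cohorts**: exponential event times with hazard
  $h_0 e^{\beta\,\text{hyper}}$ and independent exponential censoring —
  closed-form truth for parameter-recovery tests. Mutation-flag
  frequencies default to the few-percent range of a real MDS cohort.

What the simulation does **not** emulate: read-level artifacts (bisulfite
conversion failure, mapping bias), SNP interference, batch effects,
spatially correlated methylation along a fragment, or non-proportional
hazards. Passing tests therefore demonstrate the statistical machinery is
correct under the stated model, not that the pipeline is robust to every
real-data pathology.

# Clinical statistics

The biomarker cutoff is control mean + 2 × sample SD (n−1 denominator;
the original report does not say sample vs population SD — both are one
flag apart, and the sample SD is the default). A value must strictly
exceed the cutoff to be called hypermethylated: "hypermethylated" should
exceed the control envelope, so a value exactly at the boundary is not.

Test dispatch follows clinical-table convention: continuous variables via
Mann–Whitney (exact permutation distribution when the combined n ≤ 12
without ties, tie-corrected normal approximation otherwise; a pooled
*t* test on request), 2×2 tables via Fisher's exact test when any
expected cell is below 5 and Pearson chi-square (no continuity
correction) otherwise, larger r×c tables via chi-square. The two-sided
Fisher p uses the minimum-likelihood rule — summing all tables with the
observed margins whose probability does not exceed the observed table's —
which is the rule that reproduces the published mutation-table p-values
(0.266, 0.016, 0.406, 0.340, …); doubling the one tail does not.

# Survival analysis

Kaplan–Meier, log-rank and Cox proportional hazards are implemented in
the package (with the `survival` package serving as an independent
cross-check in the test suite): the Cox contracts here — Efron tie
handling, Newton–Raphson with step-halving on any likelihood decrease,
convergence at max |score| < 1e−7 within 50 iterations, standard errors
from the inverse observed information, explicit flagging of monotone
likelihoods — are part of the package's specification, and
`coxPartialLik` exposes the likelihood, analytic score and information so
they can be verified directly (the suite checks the score against central
differences to 1e−5). Breslow ties and Wald inference (HR with
exp(coef ± 1.96·se) intervals) follow the presentation conventions of
clinical Cox tables. The multivariate model takes exactly the covariates
with univariate Wald *P* strictly below 0.200.

# Numerical and degenerate-input choices

* Zero-variance two-sample *t*: *p* = 1 when means are equal, 0 otherwise,
  with a warning — rather than NaN.
* Fisher on a table with an all-zero margin: *p* = 1 with a warning.
* Zero-coverage cells are missing, and a unit uncovered in any sample is
  dropped before testing.
* An empty digest, empty gene list or empty methylation matrix returns an
  empty object (with a warning where informative), not an error, except
  where the operation is meaningless (e.g. Kaplan–Meier on no subjects).
* Spearman correlation on a constant vector is undefined and returned as
  `NA` with a warning.

# Problem sizes used in the checks

The packaged checks run on one simulated contig of 150–200 kb (giving
800–1,100 size-selected fragments, of which ≥ 500 enter the null
calibration and 250 carry planted ±0.4 effects) and 200 replicate
survival cohorts of n = 1000 for the Cox recovery study. These sizes give
binomial standard errors of a percentage point or two on the reported
rates, which is adequate for the stated tolerances.

# Known limitations

* The per-fragment test menu is *t* vs pooled Fisher; beta-binomial
  regression and smoothing-based DMR callers are out of scope.
* Promoters are a fixed symmetric ±2 kb window; no isoform-aware TSS
  handling.
* Only forward-strand C positions of CpGs are modeled; strand-merged
  counts are assumed upstream (the simulator emits merged counts).
* Cox: no time-varying covariates, stratification, competing risks or
  proportionality diagnostics.
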