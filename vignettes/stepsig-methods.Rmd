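---
title: "Methods: step thresholding, signature scoring, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step thresholding, signature scoring, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepsig)
```

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite does not itself compute.

## The one-step model

A gene that "switches" between a low and a high expression state across a
cohort has, after sorting its values ascending, an approximate step shape.
`fit_step()` fits that shape exactly: for each split position $k \in
1..n-1$ the fitted curve is piecewise constant at the two segment means,
and the returned $k$ minimizes the residual sum of squares. All positions
are evaluated; the minimum segment size is 1 on each side and no
pseudo-points are added at the ends. Ties in the SSE are broken by the
smallest $k$ — deterministic and order-stable, which is what makes the
constant vector well-defined (it returns $k = 1$ with threshold equal to
the constant).

Sorting before fitting is deliberate: a single monotone "up" step on sorted
values captures both up- and down-switching genes, since the direction of
the original profile is normalized away. Fitting unsorted profiles is not
offered.

The step-sharpness statistic is the F-like ratio

$$F = \frac{(SSE_{null} - SSE_{step})/(M-1)}{SSE_{step}/(n - M)}$$

with $SSE_{null}$ the residual SS around the grand mean. The degrees of
freedom $M$ default to 3 (low mean, high mean, step position) but are an
explicit `dof` parameter of `fit_step()`: the authoritative form of the
equation is not recoverable from our source material beyond this structure,
so the value is parameterized rather than hard-coded. Two edge regimes are
handled by sentinels so downstream comparisons stay exact: a zero-residual
(perfect) step returns `Inf`, and a step explaining nothing returns 0; a
fit with $n \le M$ is still valid as a threshold estimate but carries an
`NA` statistic.

The threshold $SThr = (\mu_{low} + \mu_{high})/2$ always lies within the
data range. Thresholds are a *per-gene, per-dataset* quantity: they are
recomputed on all pooled samples of whatever cohort is being analyzed and
are never transferred between cohorts. `binarize()` labels values against
$SThr$ with an optional symmetric `gap` creating an "intermediate" band;
the default `gap = 0` is binary, with values exactly at the threshold
going "low" (a stated tie rule, since equality does happen on gridded
expression data).

## Normalization and the composite score

`threshold_normalize()` maps expression to
$(expr - SThr)/(3\sigma)$ — zero at the threshold, one at three standard
deviations above it. Choices worth stating:

* $\sigma$ is the per-gene *sample* standard deviation ($n-1$ denominator)
  across all samples of the analyzed dataset. The source description does
  not fix the denominator; $n-1$ is the conventional estimator and the
  difference is immaterial at cohort sizes.
* Zero-variance genes cannot be scaled. They are assigned 0 (the value a
  threshold-centered score should give an uninformative gene), flagged in
  the result's `degenerate` field, and never silently dropped — so a
  signature keeps the same length across datasets where some member genes
  are censored or flat.

The composite score is the **sum** of normalized values over the signature
genes — additive in disjoint signatures and invariant to gene order, two
properties the test suite asserts. A mean option exists behind
`average = TRUE` only because cross-signature comparability differs;
the sum is the default and the definition.

Classification uses the Mann-Whitney AUC (`roc_auc()`): the probability a
random positive-class sample outscores a random negative one, ties
counting one half. The positive class is always named explicitly by the
caller; silent auto-orientation (picking whichever direction gives
AUC ≥ 0.5) would hide a sign error, so it is not offered.

## The differential-expression stage and its honesty clause

`differential_expression()` is deliberately *not* a negative-binomial GLM.
The pipeline's contract downstream of DE is only a gene list passing
"raw $P \le 0.05$ and fold-change $\ge 2$", and that contract is preserved
with a transparent engine: per-gene two-sided Welch t-tests on log2(TPM+1)
values, with fold-change as the ratio of linear TPM arm means under a
pseudocount of 1 (bounded for all-zero genes, negligible for
well-expressed ones). Consequences to be aware of:

* Power at small $n$ is below a moderated or count-model engine; the
  synthetic recovery tests quantify what the stand-in achieves in its
  stated regime (fold 4, 10/arm: ≥ 90% recovery).
* Selection is on **raw** p by default, because that is the stated filter
  rule; BH-adjusted values are always computed and reported, and
  `use_adjusted = TRUE` switches the rule.
* Fold-change is a linear-mean ratio, not a shrunken log2FC.

Technical replicates, where present, should be collapsed (summed) to
biological samples before DE; the package operates on whatever columns it
is given and does not guess replicate structure.

`bh_adjust()` is the classic step-up procedure (delegated to
`stats::p.adjust(method = "BH")` and oracle-tested against a from-scratch
implementation). `gene_set_enrichment()` is the hypergeometric upper tail
on set overlaps within a user-supplied universe, with fold enrichment as
observed-over-expected hit fraction; it handles gene *sets*, not ontology
DAG structure — parent/child redundancy in GO-style collections is the
user's concern.

## Cohort statistics

`multivariate_ols()` models a marker (any real response — binary
positivity or continuous expression both fit the contract) as a linear
combination of all covariate columns via ordinary least squares, with
t-based two-sided p-values and $t_{0.975,\,n-p}$ confidence intervals.
Character covariates are dummy-coded against the alphabetically first
level — deterministic, and stated here because coefficient signs depend on
it. Rank-deficient designs are an error naming the collinear columns, not
a silent drop.

`km_logrank()` wraps the product-limit estimator and the two-group
log-rank test from the `survival` package behind the pipeline's contract
(Greenwood standard errors are reported but treated as display-only), and
the implementation is cross-checked in the tests against a hand-coded
observed-minus-expected enumeration. With zero events the curves are still
returned and the test is `NA` with a warning — a degenerate dataset should
not crash a pipeline that can still draw its curves.

`stratify_by_metagene()` dichotomizes at the cohort **median** of the
per-sample mean signature expression, ties going "low". The external tool
this emulates documents only "default settings using mean expression"; the
median cut is the conventional default and is recorded here as an
assumption, not a fact about that tool.

## The synthetic world

`generate_counts()` draws a two-arm cohort with the structure the analysis
assumes — and only that structure:

* **Counts**: negative binomial, parameterized by (mean, size) with a
  constant size (`dispersion`, default 10, i.e. overdispersion ≈ 0.1 —
  typical of bulk RNA-seq). Per-gene baseline means are log-normal
  (sdlog 1) around `baseline_mean` (default 100 counts) so the dynamic
  range of real libraries is roughly represented.
* **The planted signature**: the first `n_signature_genes` genes (default
  29, the signature size the pipeline is built around) have their mean
  multiplied by `signature_fold` (default 4) in the positive arm only.
  Fold 1 is the exact null.
* **Sample size**: default 10 per arm. The source experiment's per-arm
  library count is not stated beyond replicate structure, so this is a
  free parameter chosen to make the recovery regime testable.
* **Gene lengths**: uniform on 500–5000 bp, so TPM's length normalization
  is non-trivially exercised.
* **Covariates**: age (normal, 62 ± 10), stage (ordinal 1–4), location
  (left/right), drawn independently of arm — they exercise the OLS stage
  and its null calibration.
* **Survival**: exponential with hazard $0.02\,e^{\beta z}$, where $z$ is
  the standardized latent signature activity (mean log2 count over planted
  genes) and $\beta$ = `survival_link` (default −0.5: high signature,
  longer survival). Censoring is independent with probability
  `censor_rate` (default 0.3), censored times drawn uniformly before the
  event.

One master seed feeds deterministic per-stage sub-streams (counts,
lengths, covariates, survival), so a stage can be regenerated
independently and identical configs give bitwise-identical cohorts.

What the generator does **not** emulate — hence what a green test does not
establish: library-size heterogeneity, batch effects, GC/length bias
beyond the TPM identity, gene–gene correlation, single-cell structure, and
non-proportional hazards. A pipeline that recovers planted signatures here
has demonstrated its arithmetic and its statistical calibration, not
robustness to real-data artifacts.

## Numerical choices and degenerate inputs

* `fit_step` evaluates each split with plain two-pass means and residual
  sums — $O(n^2)$ per gene but bit-for-bit comparable with a brute-force
  oracle, including on gridded data with exact SSE ties. Cohort matrices
  at typical sizes fit in well under a second per thousand genes.
* AUC uses midranks, so tie handling is exact rather than
  perturbation-based.
* Fold-change pseudocount 1 bounds ratios for empty genes without moving
  large-count ratios.
* TPM errors on an all-zero sample column (no library to normalize) and
  refuses non-positive gene lengths.
* All tabular outputs key rows by gene/sample *labels*, never positional
  indices, to avoid 0/1-based ambiguity at file boundaries.
* The pipeline's JSON config (YAML was considered; JSON chosen since a
  parser is guaranteed present) is validated before any stage runs, CLI
  flags override file values, and each output directory's
  `manifest.json` carries the seed, thresholds, and full configuration
  needed to regenerate it.

## Known limitations

The DE stand-in trades power for transparency (above). Thresholds assume
the cohort actually spans both expression states of a signature gene — on
a cohort where a gene never switches, the step fit still returns a
threshold, but it reflects noise; the step statistic is the diagnostic to
consult. Survival stratification is a median dichotomy, not an optimal
cutpoint search, and no proportional-hazards model is provided. The AUC is
computed on the composite score; any other discriminant is out of scope.
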