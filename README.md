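# stepsig

StepMiner thresholding and composite gene-signature scoring for bulk
transcriptomics cohorts.

## The problem

A recurring pattern in translational transcriptomics: derive an upregulated
gene signature from a controlled two-arm experiment (e.g. marker-expressing
vs control samples), then deploy that signature across independent patient
cohorts — scoring each sample, testing whether the score separates clinical
groups, and asking whether it stratifies survival. `stepsig` implements that
pipeline as a tested, reusable R package for computational biologists who
want the scoring machinery without a web service or one-off scripts.

## The model

**Per-gene thresholding (StepMiner).** For a gene with expression values
$X_1,\dots,X_n$ (log2(TPM+1), all samples pooled), sort ascending and fit a
one-step function: for each split $k$ the fitted values are the segment
means $\mu_{low} = \mathrm{mean}(X_{(1..k)})$, $\mu_{high} =
\mathrm{mean}(X_{(k+1..n)})$. The chosen $k$ minimizes
$SSE = \sum_i (X_{(i)} - \hat X_i)^2$, and an F-like regression statistic

$$F = \frac{(SSE_{null} - SSE_{step})/(M-1)}{SSE_{step}/(n-M)}, \qquad M = 3$$

measures step sharpness against the flat fit around the grand mean. The
**threshold** is $SThr = (\mu_{low} + \mu_{high})/2$ — the expression level
of the gene's switching event; values can be binarized high/low against it.

**Signature scoring.** Each gene is rescaled by a modified Z-score centered
on its threshold, $(expr - SThr)/(3\,\sigma)$, with $\sigma$ the per-gene
standard deviation across the cohort. The **composite score** of a sample is
the sum of these normalized values over the signature genes; samples are
ordered by score, groups compared by two-sided Welch t-tests, and
classification quantified by the Mann-Whitney ROC AUC.

**Signature derivation.** From a two-arm count matrix: TPM summarization,
log2(TPM+1), per-gene Welch t-tests, and selection of genes with raw
P ≤ 0.05 and linear fold-change ≥ 2 (BH-adjusted p reported alongside; a
deliberate, documented simplification of a count-model DE engine — see the
methods vignette). Hypergeometric enrichment against GMT gene sets,
multivariate OLS of a marker on clinical covariates, and Kaplan-Meier /
log-rank survival stratified by the signature metagene (mean expression,
median cut) round out the cohort-level statistics.

A synthetic-cohort generator (negative-binomial counts with a planted
upregulated signature, covariates, and score-linked survival) makes every
stage testable without external data.

## Worked example

```r
library(stepsig)

cfg <- synthetic_config(n_genes = 500, n_signature_genes = 29,
                        samples_per_group = 10, signature_fold = 4, seed = 42)
cohort <- generate_counts(cfg)
expr <- log_transform(tpm(cohort$counts, cohort$gene_lengths))

fit_step(expr["gene_0001", ])
#> StepMiner one-step fit (n = 20)
#>   k = 9, mu_low = 10.45, mu_high = 12.08, SThr = 11.27
#>   SSE(step) = 3.618, SSE(null) = 16.81, statistic = 30.99

res <- run_analysis(expr, cohort$metadata$group,
                    test = "positive", control = "control",
                    survival_df = cohort$metadata[, c("time", "event")])
length(res$signature)                                   # 29
sum(res$signature %in% cohort$truth$signature)          # 29 (all planted genes)
res$auc                                                 # 1
head(res$scores[order(-res$scores$score), ], 3)
#>    sample    score rank
#> 19 pos_09 9.646224   20
#> 17 pos_07 9.481326   19
#> 16 pos_06 8.655880   18
res$compare$tests[, c("t", "p")]                        # t = -35.27, p = 8.2e-18
res$survival
#> Kaplan-Meier / log-rank, strata: high (n=10), low (n=10)
#>   log-rank chi-square = 7.481 (1 df), p = 0.006234
```

Reading: the differential-expression stage recovers exactly the 29 planted
genes; the composite score separates the two arms perfectly (AUC 1, the
regime the method is designed for at fold-change 4); the per-gene fit shows
a sharp step (statistic 31) with its threshold at 11.27 log2(TPM+1); and the
high-metagene stratum differs in survival (log-rank p = 0.006, consistent
with the generator's protective score-survival link).

## Command line

```sh
Rscript inst/cli/stepsig simulate  --out sim --seed 1
Rscript inst/cli/stepsig threshold --matrix expr.tsv --out fits.tsv
Rscript inst/cli/stepsig score     --matrix expr.tsv --signature sig.txt --out scores.tsv
Rscript inst/cli/stepsig run       --config config.json
```

Subcommands: `simulate`, `threshold`, `score`, `deg`, `enrich`, `classify`,
`survival`, `run` (full pipeline from a JSON config; every output directory
gets a `manifest.json` with the seed and thresholds needed to regenerate it).

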