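---
title: "Methods: modification patterns, signature scoring and microenvironment profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modification patterns, signature scoring and microenvironment profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

This vignette documents the statistical model behind each stage of
`run_pattern_analysis()`, the numerical choices the implementation makes, and
the scope and limits of the bundled synthetic-cohort generator. Everything
below runs at desk scale (seconds) on data produced by `generate_cohort()`.

```{r setup}
library(modpattern)
```

## Overview of the workflow

The pipeline takes a log2 expression matrix (genes x samples), a matching
clinical table with survival times and event indicators, and a small panel of
*regulator* genes. It then:

1. clusters samples into **modification patterns** by resampling-based
   consensus clustering of the regulator panel;
2. compares survival between patterns (Kaplan-Meier + log-rank);
3. derives **pattern differential genes** with an empirical-Bayes moderated
   t-test and a joint q-value / fold-change filter;
4. consensus-clusters the significant genes' expression into **gene clusters**;
5. screens the differential genes by univariate Cox regression into
   *protective* (hazard ratio < 1) and *risk* (hazard ratio > 1) genes;
6. summarises each sample by the **m6Ascore**
   `PC1(protective block) - PC1(risk block)` and dichotomises it at a
   maximally selected log-rank cutpoint;
7. profiles the microenvironment by nu-SVR signature deconvolution and
   rank-based (ssGSEA) immune/stromal scores;
8. runs phenotype-permutation GSEA and hypergeometric over-representation;
9. evaluates the score by IPCW time-dependent AUC; and
10. summarises immunotherapy response (CR/PR/SD/PD) by score group.

## Consensus clustering (`run_consensus`, `select_k`)

For each of `reps` repetitions, `floor(p_item * n)` samples are drawn without
replacement and partitioned by average-linkage hierarchical clustering on
1 - Pearson correlation distance (one tree per repetition, cut at every
candidate k). The consensus matrix entry for a pair of samples is the number
of times they co-clustered divided by the number of times they were co-sampled;
pairs never drawn together get consensus 0, with a warning. The final
partition at each k is average-linkage clustering of `1 - M_k`, with labels
canonicalised by decreasing cluster size (ties broken by smallest member
index), so "pattern A" is reproducible across runs.

Numerical choices worth knowing:

- **Gene median-centering** (`center_genes = TRUE`) is applied before
  clustering. Raw per-gene baselines dominate sample-sample Pearson
  correlations (all samples look alike along the baseline direction) and wash
  out subgroup structure; row-centering is the standard preprocessing for
  expression consensus clustering. Disable it only if your matrix is already
  centred.
- **Model selection** integrates the empirical CDF of the upper-triangle
  consensus entries by the trapezoid rule on a 1001-point grid to get an area
  `A_k`; the relative delta area is `(A_k - A_{k-1}) / A_{k-1}` (for the
  smallest k, `A_k` itself). The chosen k is the largest k with delta area
  above the threshold (default 0.1); if none exceeds it, the elbow (argmax) is
  used.
- `k_range` must lie in `[2, n/3]` so every candidate cluster can hold at
  least three samples.

```{r consensus}
co <- generate_cohort(cohort_config(n_samples = 90, seed = 7))
cons <- run_consensus(co$expr[co$truth$regulators, ], k_range = 2:4,
                      reps = 100, seed = 7)
cons
table(pattern = cons$assignments$k2, truth = co$truth$cluster)
```

## Moderated differential expression (`moderated_ttest`, `filter_degs`)

Per-gene pooled variances `s_g^2` on `d_g` degrees of freedom are shrunk
toward a prior `s_0^2` with prior degrees of freedom `d_0`:
`posterior = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)`, and the moderated t is
referenced to `d_0 + d_g` degrees of freedom. The prior is fitted by method
of moments on the log sample variances (digamma/trigamma moment equations,
trigamma inverted by Newton iteration); when the spread of log variances does
not exceed its sampling expectation, `d_0 = Inf` and all genes share `s_0^2`.
Zero-variance genes therefore never divide by zero. `logFC` is
mean(first group level) - mean(second), in log2 units. The default
significance filter is `q < 0.05` (Benjamini-Hochberg) and `|logFC| > 1`,
both strict.

## Prognostic screen and score (`screen_prognostic`, `compute_m6ascore`)

Each candidate gene enters a univariate Cox model (Breslow tie handling; the
choice matters only with heavily tied times and is recorded here for
reproducibility). Genes with Wald p below `alpha` are labelled `protective`
(HR < 1) or `risk` (HR > 1); monotone-likelihood fits are flagged `diverged`
rather than silently reported.

The m6Ascore reads the "difference of two signature scores" construction as
**two separate PCAs**: the protective and risk blocks are z-scored
(population divisor) and decomposed independently, and the score is
`PC1(protective) - PC1(risk)`. A joint single-PCA variant is available as
`mode = "joint"`. Because a principal component's sign is arbitrary, PC1 is
oriented to correlate positively with the per-sample mean of the standardised
block (falling back to making the largest-magnitude loading positive); with
that convention, high scores mean high protective-block expression and low
risk-block expression, and identical protective and risk sets give a score of
exactly zero.

The score is dichotomised at the maximally selected log-rank cutpoint: every
split leaving at least `ceiling(minprop * n)` samples on each side (default
`minprop = 0.1`) is scanned, and the cutpoint maximising the standardized
log-rank statistic wins, ties resolved toward the median. A sample is `high`
iff its score strictly exceeds the cutpoint.

```{r score}
scr <- screen_prognostic(co$expr, co$clin)
sc <- compute_m6ascore(co$expr, scr)
cor(sc$m6ascore, co$truth$latent_score)
```

## Microenvironment (`deconvolve`, `ssgsea`, `estimate_scores`)

Deconvolution regresses a linear-scale bulk profile on a cell-type signature
matrix with linear-kernel nu-SVR over `nu in {0.25, 0.5, 0.75}` (lowest
reconstruction RMSE wins), clips negative coefficients and normalises to a
simplex. A raw-scale non-negative least-squares backend is exact on noiseless
mixtures and serves as the reference implementation; it is also the automatic
fallback when every nu yields all-nonpositive weights. Expression given on
the log2 scale is back-transformed with `2^x - 1` first.

ssGSEA ranks genes within each sample and scores a set as the summed
difference between the rank-weighted hit ECDF (weights `rank^alpha`, default
`alpha = 0.25`) and the unweighted miss ECDF; it is exactly invariant to
per-sample monotone transforms. The immune/stromal "infiltration scores" are
ssGSEA scores of the two signature sets, and the combined score is their sum;
the non-linear tumor-purity transform of the original ESTIMATE method is
deliberately not reproduced because the analysis only uses the three scores.

## Enrichment and evaluation

GSEA uses the classic weighted running sum (hit increments `|stat|^w`
normalised to 1, miss decrements `1/(N - N_h)`), a **phenotype-label**
permutation null (preserving inter-gene correlation), sign-matched NES
normalisation, add-one permutation p-values, and the pooled positive/negative
null FDR. Time-dependent AUC is the Uno-type cumulative/dynamic estimator
with inverse-probability-of-censoring weights `1/G(T-)` from the censoring
Kaplan-Meier curve; evaluation times with no cases or no controls return `NA`
with a warning.

## The synthetic-cohort generator

`generate_cohort()` draws, from named substreams of one root seed: balanced
cluster labels; a cell-type signature matrix with strong own-type markers;
Dirichlet mixing fractions whose immune/stromal weights are tilted by
`(1 + fraction_shift)` in cluster B; a log2 expression matrix with a shifted
regulator panel, protective/risk differential blocks and signature genes
carrying the linear-scale mixture signal; exponential survival with hazard
`baseline_hazard * exp(-score_log_hr * latent)` where the latent score is the
mean protective z-score minus the mean risk z-score; uniform censoring whose
window is root-solved so the expected censored fraction hits
`censoring_rate`; and a logit response model on the latent score.

Default sizes (200 samples, 25 regulators, 40 protective / 30 risk / 200 null
genes, 5 cell types x 8 markers) are the package's own choices: large enough
that every stage has signal and calibration can be measured, small enough
that the full pipeline runs in seconds. The generator emulates the
*statistical structure the analysis assumes* — it is a correctness and
calibration instrument, not a biological simulator: expression noise is
Gaussian on the log scale, survival is exponential (Weibull behind a flag),
and the mixture signal only enters the signature genes.

```{r pipeline}
cfg <- pipeline_config(reps = 60, n_perm = 50, seed = 7,
                       k_range = c(2, 3), out_dir = tempfile("run"))
report <- suppressMessages(run_pattern_analysis(cfg, cohort = co))
report
```

## Limitations

- Consensus clustering inherits hierarchical clustering's sensitivity to
  outliers; `method = "kmeans"` is available but makes per-rep trees
  non-nested across k.
- The moderated t assumes roughly exchangeable gene variances; grossly
  heteroscedastic blocks weaken the shrinkage prior.
- The SVR deconvolution is a point estimate on standardised scales; its
  permutation p-value tests reconstruction quality, not identifiability of
  collinear signatures.
- The maxstat cutpoint p-value is *not* corrected for the cutpoint search;
  downstream log-rank p-values on the dichotomised score are optimistic and
  should be read as descriptive.
- All defaults were chosen for the synthetic scale; real cohorts warrant
  revisiting `reps`, `n_perm` and the screening `alpha`.
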