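# sctpurity

Estimation and correction of **off-target cell-type contamination** in
single-cell-type RNA-seq (sctRNA-seq) — experiments that enrich and pool one
cell type per sample (LCM-seq, TRAP-seq, FACS or manual sorting) and sequence
the pool. Such pools are rarely pure: mRNA from surrounding cell bodies and
processes is captured along with the target cells, and when the amount of
captured off-target material differs between experimental groups (as
morphology-altering disorders make likely), it produces spurious differential
expression.

`sctpurity` is for anyone analyzing pooled cell-type RNA-seq against a
single-cell reference atlas: it scores each sample's contamination, and feeds
those scores into differential expression as covariates.

## The method

Given an annotated single-cell reference and a test matrix of pooled samples
(all expression as log2(1 + CPM)):

1. **Markers** — one-vs-rest two-part (hurdle) tests select cell-type marker
   genes: detection-fraction difference ≥ 0.40, fold change ≥ 2, FDR ≤ 0.01,
   each gene assigned to at most one type.
2. **Centroids** — each reference type is collapsed to per-gene truncated
   interquartile means (middle 50% of cells) of log2(1 + CPM).
3. **Bootstrap correlation** — each sample is correlated (Pearson) with every
   centroid on random 60% subsamples of the markers (equal numbers per type),
   10,000 iterations; the mean is the consensus correlation
   `cor(log2(1+CPM)_markers,test , centroid)`.
4. **Scaling** — consensus correlations are divided by the *expected*
   correlation of a pure cell of the sample's labeled type, estimated from
   held-out reference cells. The **scaled contamination coefficient** reads:
   1.0 = behaving like a pure cell, > 1.0 = off-target contamination.
5. **Correction** — the coefficients of the top 4 off-target types enter a
   per-gene negative-binomial GLM (log link, median-of-ratios size factors,
   ML gene-wise dispersion, Wald test, BH correction, DEGs at FDR < 0.1) as
   mean-centered covariates; per-gene AIC compares the covariate and minimal
   models.

A negative-binomial simulator with planted identities, known DE truth and
condition-confounded contamination quantifies what correction buys
(false-positive fraction, false-negative fraction, AUROC).

## Worked example

Simulate a contaminated two-cluster experiment, estimate contamination for
the cluster-1 samples, and compare corrected vs uncorrected differential
expression against the planted truth:

```r
library(sctpurity)
library(dplyr)

cfg <- sim_config(n_genes = 1000, n_de = 150, contamination = "high",
                  confound = "high", ref_cells_per_type = 150)
sim <- simulate_sct(cfg, seed = 1)

ann1 <- filter(sim$annotations, group == "type1")
prof <- estimate_contamination(sim$counts[, ann1$column_id], ann1,
                               sim$centroids, sim$markers, sim$expected,
                               n_iter = 1000, seed = 2)
glance(prof)
#> # A tibble: 2 × 5
#>   labeled_type reference_type n_samples mean_consensus_r mean_scaled
#>   <chr>        <chr>              <int>            <dbl>       <dbl>
#> 1 type1        type1                 20            0.899       0.972
#> 2 type1        type2                 20            0.581       1.78
```

Type-1 samples behave like pure type-1 cells against their own centroid
(scaled coefficient 0.97 ≈ 1), but correlate with type 2 at 1.8× the
pure-cell expectation — the planted contamination. Feeding the coefficients
into the DE model:

```r
covars <- rank_off_target(prof, k = 4)
de_plain <- run_de(sim$counts[, ann1$column_id], ann1)
de_corr  <- run_de(sim$counts[, ann1$column_id], ann1, covariates = covars)
bind_rows(uncorrected = evaluate_calls(de_plain, sim$gene_truth),
          corrected   = evaluate_calls(de_corr,  sim$gene_truth), .id = "model")
#> # A tibble: 2 × 7
#>   model         fpf   fnf auroc n_called n_true_de n_genes
#>   <chr>       <dbl> <dbl> <dbl>    <int>     <int>   <int>
#> 1 uncorrected 0.782 0.230 0.770      522       148    1096
#> 2 corrected   0.469 0.824 0.710       49       148    1096
```

Under this severely confounded scenario the uncorrected analysis is
dominated by false positives (78% of its calls); adding the covariates
removes most false calls at a substantial cost in power — the covariate is
nearly collinear with the condition, so the condition effect is identified
only from within-arm contamination variation (see the methods vignette,
`vignettes/contamination-correction.Rmd`).

Real data enter through `read_counts()` (dense TSV or MatrixMarket + id
sidecars) and `read_annotations()`; `inst/cli/sctpurity.R` exposes the same
pipeline as a `markers / centroids / expected / estimate / simulate / de /
evaluate` command-line tool.

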