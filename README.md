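# txdiv — transcriptome diversity analysis for RNA-seq

Bulk RNA-seq measures *relative* expression: the reads a gene receives
depend on every other gene in the library. A single per-sample number —
**transcriptome diversity**, the Shannon entropy of a sample's gene-level
transcript probabilities — captures how evenly reads are spread across
genes, and turns out to be a major, usually unmodelled, axis of variation
in expression matrices: it correlates with the expression of most genes,
with leading principal components, and with the "hidden" latent factors
(PEER-style covariates) routinely used as nuisance terms in eQTL studies.

`txdiv` is for analysts of bulk (or single-cell, at the pseudobulk level)
count matrices who want to measure that axis and quantify its footprint.

## The statistic

For a sample with counts `c_i` and effective gene lengths `l_i` (bp), the
probability of observing a transcript of gene `i` is

```
p_i = (c_i / l_i) / sum_j (c_j / l_j)
```

(equivalently `p_i = TPM_i / sum_j TPM_j`; both routes give identical
probabilities). Shannon entropy and normalized transcriptome diversity are

```
H   = - sum_i p_i log2(p_i)          (bits;  0 <= H <= log2 G)
H_s = H / log2(G)                    (0 = one gene dominates, 1 = even)
```

with `G` the number of expressed genes in the sample.

Downstream, the package provides:

- **Normalization** — TPM and a from-definition TMM (trimmed mean of
  M-values; verified against edgeR to 1e-8), the rank inverse-normal
  ("rankit") transform, and the `TMM >= 1 in >= 20% of samples` gene filter.
- **Association** — per-gene OLS of rankit expression on rankit `H_s`
  (slope `gamma`, t-test, BH-FDR), association summaries, and a
  gene-attribute regression (length, GC, mean expression) explaining which
  genes track diversity.
- **Variance decomposition** — PCA plus `v_total = sum_i r_i^2 v_i`, the
  total matrix variance explained by any per-sample query vector.
- **Latent factors** — a pluggable factor engine (rankit-PCA default,
  external factor TSVs accepted), the sample-size factor-count rule
  (15/30/45/60), factor–covariate correlations, and an accounting of how
  much factor-explained variance a covariate absorbs
  (`delta_median = median r1^2 − median r2^2` between intact and
  covariate-residualized factors).
- **Simulation** — a compositional count simulator with planted per-sample
  evenness (`m_i ∝ a_i^tau`), depth–evenness coupling, and sex/batch
  effects, so every stage has a ground-truth recovery test.

## Worked example

```r
library(txdiv)

sim <- simulate_dataset(sim_config(n_genes = 500, n_samples = 60,
                                   depth_log_mean = log(1e5), seed = 42))
d <- transcriptome_diversity(sim$counts, sim$annotation)
head(d, 3)
#>   sample_id H_bits    H_s n_expressed library_size
#> 1     s0001  7.922 0.8847         496       110124
#> 2     s0002  6.806 0.7654         475        81172
#> 3     s0003  7.576 0.8458         497       117214

tmm  <- compute_tmm(sim$counts)
expr <- tmm$expression[filter_genes(tmm$expression), ]
attr(expr, "unit") <- "tmm_cpm"

assoc <- associate(expr, d$H_s)
summarize_associations(assoc)
#>   n_tested n_significant pct_significant n_positive n_negative pct_positive_of_significant
#> 1      500           461            92.2        292        169                       63.34

p <- expr_pca(expr)
query_variance(p, d$H_s)$v_total
#> [1] 0.9865

f <- infer_factors(expr)                      # 15 factors at 60 samples
account(expr, f, d$H_s, "H_s", pca = p)
#> Accounting of factor-explained variance by 'H_s'
#>   median r^2 intact:        0.7887
#>   median r^2 residualized:  0.1343
#>   delta median r^2:         0.6544 (65.4% of per-gene variance)
#>   v_total(factors):         0.9921
#>   accounted fraction:       0.6596
#>   Mann-Whitney p:           5.51e-154
```

Reading the output: 92.2% of genes are significantly associated with
diversity (63% positively); the diversity vector explains 98.7% of this
matrix's variance because the planted evenness axis is its dominant driver
at these simulation settings; and residualizing diversity out of the 15
latent factors drops the median per-gene factor r² from 0.79 to 0.13 — on
real tissue data these numbers are far smaller, but the mechanics are
identical. `run_pipeline()` chains all stages from one config (R list or
YAML) and writes per-stage TSVs plus a JSON report.

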