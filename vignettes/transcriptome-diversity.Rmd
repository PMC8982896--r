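---
title: "Measuring transcriptome diversity and its footprint on expression matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcriptome diversity and its footprint on expression matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txdiv)
```

## The model

RNA-seq counts are compositional: a library of $N$ reads is, to a good
approximation, a multinomial draw over genes, with per-gene read
probability proportional to (molar transcript abundance) × (effective
length). Any sample-level change in how evenly those probabilities are
spread — library preparation, RNA integrity, cell-type mixture — moves the
*relative* expression of every gene at once, and no per-gene scaling
factor can undo it.

`txdiv` measures that evenness directly. For one sample with counts $c_i$
and effective lengths $l_i$,

$$p_i = \frac{c_i / l_i}{\sum_j c_j / l_j}, \qquad
  H = -\sum_i p_i \log_2 p_i, \qquad
  H_s = \frac{H}{\log_2 G},$$

where $G$ is the number of expressed genes ($p_i > 0$). $H_s \in [0, 1]$:
0 when one gene carries every read, 1 when reads are spread evenly.
Working from TPM instead of counts gives identical $p_i$ (length
cancellation), which the suite verifies to $10^{-9}$ on fuzzed samples.
Conventions: $0 \log 0 = 0$; a sample with $G \le 1$ gets $H_s = 0$ (the
zero-diversity limit) with a warning.

`transcriptome_diversity()` defaults to a per-sample $G$, so the
denominator tracks each sample's expressed-gene set. That follows the
definition above, but it means two samples with equal $H$ and different
$G$ get different $H_s$; when strict cross-sample comparability matters
more than per-sample normalization, `g_mode = "global"` shares one
denominator, $\log_2$ of the number of genes expressed anywhere. Both are
exposed because the choice is genuinely open; per-sample is the default
because it keeps $H_s = 1$ attainable for every sample.

## Quantifying the footprint

Three instruments, all rank-based so that marginal distribution shape and
monotone unit changes cannot drive results:

**Per-gene association.** Each gene's expression $y$ and the covariate $x$
(usually $H_s$) are rank inverse-normal transformed —
$\Phi^{-1}\!\big(({\rm rank} - 0.5)/n\big)$, ties averaged — and the OLS
slope $\gamma$ in $y = \beta_0 + \gamma x + \epsilon$ is t-tested, with
Benjamini–Hochberg control across genes (significance is called at
$q < 0.05$, strictly). On untied input the transform maps both sides onto
the same quantile grid, so a strictly monotone relationship gives
$\gamma = \pm 1$ exactly — a useful calibration point the tests exploit.
An attribute regression then asks which gene properties predict
association strength $|\gamma|$: log length, GC fraction and log mean
expression, standardized, jointly in one OLS ($-\log_{10} p$ is available
as an alternative response, but it conflates effect size with precision).

**Variance decomposition.** PCA of the expression matrix (samples as
observations, genes centered, not scaled — `prcomp` defaults). For a query
vector $q$, both $q$ and each PC's sample scores are rankit-transformed,
$r_i^2$ is their squared Pearson correlation, and

$$v_{\rm total} = \sum_i r_i^2 v_i$$

with $v_i$ the PC's variance share. All retained PCs (eigenvalue
$> 10^{-12}$) are included by default. Note "loadings" in the expression
literature often means these per-sample scores; this package consistently
says *scores*. Because rankit is nonlinear, a query equal to PC1's own
scores yields $r_1^2 = 1$ but chance-level $r_k^2 \approx 1/(n-1)$ on the
other PCs, so the self-query $v_{\rm total}$ sits slightly *above* $v_1$
— by about $(1 - v_1)/(n - 1)$ — rather than exactly at it. For the same
reason the null expectation of $v_{\rm total}$ for an independent query
is $\approx 1/(n-1)$, not 0.

**Factor accounting.** Latent expression factors (PEER-style) are, by
default, the top-$N$ PCs of the gene-wise rankit-transformed filtered
matrix; externally computed factors load via `read_factors()`, and every
downstream computation is agnostic to the engine. $N$ follows the
sample-size rule 15/30/45/60 (boundaries 150/250/350). For a covariate
$z$: per-gene $r_1^2$ (rankit expression on all intact factors),
$r_2^2$ (same, factors with $z$ regressed out), and

$$\Delta = {\rm median}(r_1^2) - {\rm median}(r_2^2),$$

with a two-sided Mann–Whitney test between the two $r^2$ distributions.
$\Delta$ is the headline quantity; the normalized ratio
$\Delta / v_{\rm total}({\rm factors})$ is also reported
(`accounted_fraction`) since both conventions appear in practice and they
differ when the factors capture much less than all of the matrix
variance. Covariates are residualized one at a time, not jointly, so each
covariate's accounting is marginal.

One numerical guard matters here: when the covariate is (numerically)
identical to a factor, its residual column collapses to $\sim 10^{-14}$
noise, which QR with per-column relative tolerance would happily keep as
an extra — entirely spurious — regressor direction, inflating $r_2^2$ by
about $1/(n - k)$. `gene_factor_r2()` therefore drops factor columns with
standard deviation below $10^{-8}$ of the largest column's.

## Normalization choices

- **TPM**: counts over length, rescaled to $10^6$ per sample.
- **TMM** is implemented from its definition (reference sample by the
  75th-percentile rule; genes zero in either sample excluded; 30% M-tail
  and 5% A-tail rank trims; inverse-variance precision weights; factors
  rescaled to geometric mean 1) and is verified against
  `edgeR::calcNormFactors` to $10^{-8}$ on random matrices. TMM
  expression is counts per million of the effective library size
  (library size × factor). Because the precision weights depend on
  absolute counts, TMM factors are invariant to scaling a sample's counts
  only approximately (well under 1%), exactly as in the reference
  implementation.
- **Rankit** uses offset $({\rm rank} - 0.5)/n$ with average ties. Other
  offsets (Blom, $({\rm rank} - 3/8)/(n + 1/4)$) differ by a monotone
  reparameterization of the same grid and would not change any rank-based
  conclusion.
- **Gene filter**: keep genes with TMM $\ge 1$ in $\ge 20\%$ of samples,
  both thresholds inclusive ("at least"), applied before factor
  inference. A gene at exactly 20% is kept.

Statistical plumbing is delegated to base R — `p.adjust("BH")`,
`wilcox.test` (exact null when the combined $n \le 12$ and untied, else
normal approximation with tie and continuity corrections),
`kruskal.test`, `cor.test(method = "spearman", exact = FALSE)` — and each
is cross-checked in the suite against a literal implementation of its
definition (step-up recursion, enumeration of all group assignments,
tie-corrected rank-sum formula).

## What the simulator emulates

`simulate_dataset()` generates the ground truth every recovery test needs:

| parameter | default | emulates |
|---|---|---|
| `n_genes`, `n_samples` | 2000 × 200 | a mid-sized cohort |
| `abundance_sigma` | 1.5 | log-normal baseline abundances (a few genes dominate, as in real libraries) |
| `tau_range` | 0.6–1.4 | per-sample evenness: molar profile $m_i \propto a_i^{\tau}$, entropy strictly decreasing in $\tau$ |
| `depth_log_mean`, `depth_log_sd` | $\log 10^6$, 0.1 | sequencing depth, log-normal |
| `depth_tau_corr` | −0.3 | deeper libraries are more diverse (Gaussian copula on $\tau$, log depth) |
| `length_range` | 200–10000 bp | read probability $\propto m_i l_i$, making length correction consequential |
| `gc_beta_params` | (5, 5) | GC fractions for the attribute regression |
| `sex_effect_sd`, `batch_effect_sd` | 0.3, 0.2 | log2 fold-changes on an `affected_fraction` (10%) of genes, multiplicative then renormalized |

Counts are multinomial per sample, so column sums equal library sizes by
construction and all compositional closure effects are real. The truth
records the analytic expected association sign per gene,
$\mathrm{sign}\!\big(-(\log a_i - \sum_j a_j \log a_j)\big)$: as diversity
rises ($\tau$ falls), genes below the abundance-weighted mean
log-abundance gain relative expression. With right-skewed $\log a$ the
majority of signs is positive — the simulator reproduces the
empirically familiar excess of positive diversity–expression correlations
as a structural property, not a tuned one.

Two scale notes on that sign. It is defined on the *proportion* (TPM)
scale; TMM recentres each sample on its trimmed-median gene, which moves
the sign-flip threshold, so sign-recovery tests run on TPM. And it is a
local (at $\tau = 1$) linearization: genes lying between the
abundance-weighted means at the two ends of the $\tau$ range can be
non-monotone in $\tau$, but those genes have weak associations and rarely
reach significance.

What the simulator does **not** model: RNA-integrity decay profiles,
UMIs, isoform structure, paired-end fragment effects, or overdispersion
beyond multinomial sampling. Passing recovery tests therefore show the
estimators are correct under clean compositional sampling, not that real
tissue data will be as well-behaved; on real data the diversity axis
typically carries a few percent of matrix variance, not the dominant
share it carries under these defaults.

## Problem sizes and numerics

The test suite runs recovery at 2000 genes × 200 samples × $10^6$ reads
(the "standard study"), where entropy estimates are within 1% of their
molar targets and sampling noise in $H_s$ is $\sim 3 \times 10^{-4}$;
oracle-equivalence checks use 100+ random small instances per operation.
Depth equalization (`downsample_diversity`) resamples multinomially (the
hypergeometric difference is negligible at these depths) and preserves
the $H_s$ ranking with Spearman $\rho > 0.99$. Entropy is computed
directly in double precision with `log2`; no special handling is needed
at gene-level scales. Degenerate inputs fail loudly: all-zero samples,
constant covariates, saturated factor fits, rank-deficient attribute
designs (with the collinear column named).

## Known limitations

- The factor engine is a PCA stand-in: it shares PEER's purpose
  (capturing broad expression variance components) but not its
  variational-Bayes shrinkage, so factor-by-factor comparisons with
  published PEER covariates should use `read_factors()` with the real
  thing.
- `accounted_fraction` and `delta_median` answer slightly different
  questions; report whichever convention your comparison target uses.
- Mann–Whitney p-values on the two $r^2$ distributions treat genes as
  independent, which co-expression violates; treat them as descriptive.
- Attribute-regression coefficients are standardized effect sizes, and
  length/mean-expression are log-transformed first; coefficients are not
  comparable to regressions on raw scales.
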