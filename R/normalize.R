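#' Transcripts-per-million normalization
#'
#' Divides each gene's counts by its effective length (bp), then rescales each
#' sample so the length-normalized values sum to one million. An all-zero
#' sample is left as an all-zero column with a warning.
#'
#' @param counts gene-by-sample count matrix (see [validate_counts()]).
#' @param annotation data.frame from [read_annotation()]; must annotate every
#'   gene present in `counts`.
#' @return expression matrix with attribute `unit = "tpm"`; each non-zero
#'   column sums to 1e6.
#' @export
compute_tpm <- function(counts, annotation) {
  validate_counts(counts)
  len <- annotation$effective_length[match(rownames(counts), annotation$gene_id)]
  if (anyNA(len))
    stopf("no effective length for gene '%s'",
          rownames(counts)[which(is.na(len))[1L]])
  rate <- counts / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warnf("all-zero sample(s): %s; TPM left at zero",
          paste(colnames(counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2L, denom, "/") * 1e6
  attr(tpm, "unit") <- "tpm"
  tpm
}

#' TMM normalization factors and TMM-scaled expression
#'
#' Between-sample scaling by the trimmed mean of M-values: a reference sample
#' is chosen as the one whose 75th-percentile count proportion is closest to
#' the mean of those percentiles; for every sample, genes with a zero count in
#' either the sample or the reference are excluded, per-gene log2 proportion
#' ratios (M) and mean log2 proportions (A) are formed, the M tails
#' (`logratio_trim` each side) and A tails (`sum_trim` each side) are trimmed
#' by rank, and the factor is 2 to the precision-weighted mean of the
#' surviving M values. Factors are rescaled to geometric mean one. The
#' returned expression is counts per million of the effective library size
#' (library size times factor).
#'
#' @param counts gene-by-sample count matrix; >= 2 samples, every sample with
#'   a positive total.
#' @param logratio_trim,sum_trim trim fractions for the M and A tails
#'   (defaults 0.30 and 0.05, the method's standard values).
#' @return list with `factors` (named per-sample scaling factors,
#'   geometric mean 1), `ref_sample` (reference id), and `expression`
#'   (matrix with attribute `unit = "tmm_cpm"`).
#' @export
compute_tmm <- function(counts, logratio_trim = 0.30, sum_trim = 0.05) {
  validate_counts(counts)
  if (ncol(counts) < 2L) stopf("TMM needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stopf("sample(s) with zero total count: %s",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  # reference: sample whose upper-quartile proportion is nearest the mean;
  # genes unexpressed everywhere carry no information and are left out
  expressed <- counts[rowSums(counts) > 0, , drop = FALSE]
  f75 <- apply(sweep(expressed, 2L, lib, "/"), 2L, quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  nf <- vapply(seq_len(ncol(counts)), function(s) {
    tmm_pair_factor(counts[, s], counts[, ref], lib[s], lib[ref],
                    logratio_trim, sum_trim)
  }, numeric(1L))
  nf <- nf / exp(mean(log(nf)))
  names(nf) <- colnames(counts)
  expr <- sweep(counts, 2L, lib * nf, "/") * 1e6
  attr(expr, "unit") <- "tmm_cpm"
  list(factors = nf, ref_sample = colnames(counts)[ref], expression = expr)
}

# one sample against the reference; the doubly-trimmed weighted mean of
# log-ratios of proportions
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1;      hiS <- n + 1 - loS
  rL <- rank(logR); rS <- rank(absE)
  keep2 <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
  f <- sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f) || abs(f) < 1e-6) f <- 0
  2^f
}

#' Rank inverse-normal (rankit) transform
#'
#' Maps values to standard-normal quantiles by rank: ties get their average
#' rank and the output is `qnorm((rank - 0.5) / n)`. This makes downstream
#' regressions and correlations invariant to any strictly monotone transform
#' of the input.
#'
#' @param v numeric vector, length >= 2, not all values identical.
#' @return numeric vector of normal scores, mean approximately 0.
#' @export
rankit <- function(v) {
  if (length(v) < 2L) stopf("rankit needs >= 2 values")
  if (anyNA(v)) stopf("rankit input contains NA")
  if (length(unique(v)) == 1L)
    stopf("rankit input is constant; transform undefined")
  qnorm((rank(v, ties.method = "average") - 0.5) / length(v))
}

#' Expression-based gene filter
#'
#' Keeps a gene when its TMM-scaled expression reaches at least `min_value`
#' in at least `min_fraction` of samples (both thresholds inclusive) -- the
#' low-expression filter applied before latent-factor inference.
#'
#' @param expr expression matrix with unit `tmm_cpm`.
#' @param min_value expression threshold (default 1).
#' @param min_fraction fraction-of-samples threshold in (0, 1] (default 0.2).
#' @return named logical vector, one entry per gene, in matrix gene order.
#' @export
filter_genes <- function(expr, min_value = 1, min_fraction = 0.2) {
  if (!identical(attr(expr, "unit"), "tmm_cpm"))
    stopf("filter_genes expects a TMM-scaled matrix (unit 'tmm_cpm')")
  assert_scalar_num(min_fraction, "min_fraction")
  if (min_fraction <= 0 || min_fraction > 1)
    stopf("min_fraction must lie in (0, 1]")
  keep <- rowMeans(expr >= min_value) >= min_fraction
  names(keep) <- rownames(expr)
  keep
}
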