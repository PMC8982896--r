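#' Per-gene transcript probabilities for one sample
#'
#' The probability of observing a transcript of gene i in the library. From
#' counts, each count is divided by the gene's effective length before
#' closing the vector to sum one (longer genes attract more reads per
#' transcript); from TPM, values are already length-corrected and are simply
#' renormalized. Both routes give identical probabilities on the same sample.
#'
#' @param x numeric vector for one sample: raw counts (`mode = "counts"`) or
#'   TPM values (`mode = "tpm"`).
#' @param lengths per-gene effective lengths in bp; required in counts mode.
#' @param mode `"counts"` or `"tpm"`.
#' @return numeric probability vector summing to 1; zero-count genes get 0.
#' @export
abundance <- function(x, lengths = NULL, mode = c("counts", "tpm")) {
  mode <- match.arg(mode)
  if (anyNA(x) || any(x < 0)) stopf("abundance input must be non-negative")
  if (mode == "counts") {
    if (is.null(lengths)) stopf("counts mode requires effective lengths")
    if (length(lengths) != length(x))
      stopf("lengths (%d) and counts (%d) differ in length",
            length(lengths), length(x))
    if (any(lengths <= 0)) stopf("effective lengths must be positive")
    x <- x / lengths
  }
  tot <- sum(x)
  if (tot == 0) stopf("degenerate sample: all values are zero")
  x / tot
}

#' Shannon entropy of a transcript probability vector
#'
#' `H = -sum(p_i * log2(p_i))` in bits, with the convention
#' `0 * log2(0) = 0`, so only expressed genes contribute. H ranges from 0
#' (all transcripts from one gene) to `log2(G)` (uniform over the G
#' expressed genes).
#'
#' @param p probability vector (non-negative, summing to 1 within 1e-6).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(p) {
  if (anyNA(p) || any(p < 0)) stopf("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stopf("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p)) + 0  # + 0 avoids IEEE negative zero when H = 0
}

#' Per-sample transcriptome diversity
#'
#' For every sample, computes the Shannon entropy H of its transcript
#' probabilities and the normalized diversity `H_s = H / log2(G)`, where G is
#' the number of expressed genes. `H_s` ranges from 0 (one gene carries all
#' reads) to 1 (reads spread evenly over all expressed genes) and is the
#' cross-sample comparable statistic.
#'
#' By default G is counted per sample, so the denominator varies with each
#' sample's expressed-gene set; `g_mode = "global"` instead uses the number
#' of genes expressed in at least one sample, giving a shared denominator.
#' A sample with G <= 1 has H = 0 and its `H_s` is defined as 0 (with a
#' warning), the zero-diversity limit.
#'
#' @param x gene-by-sample matrix of counts or of TPM values.
#' @param annotation gene annotation (required when `from = "counts"`).
#' @param from `"counts"` or `"tpm"` -- how to form probabilities.
#' @param g_mode `"per-sample"` (default) or `"global"` normalization G.
#' @return data.frame with one row per sample (input order):
#'   `sample_id`, `H_bits`, `H_s`, `n_expressed`, `library_size`.
#' @export
transcriptome_diversity <- function(x, annotation = NULL,
                                    from = c("counts", "tpm"),
                                    g_mode = c("per-sample", "global")) {
  from <- match.arg(from)
  g_mode <- match.arg(g_mode)
  if (!is.matrix(x)) stopf("x must be a gene-by-sample matrix")
  lengths <- NULL
  if (from == "counts") {
    if (is.null(annotation)) stopf("counts mode requires an annotation")
    lengths <- annotation$effective_length[match(rownames(x),
                                                 annotation$gene_id)]
    if (anyNA(lengths))
      stopf("no effective length for gene '%s'",
            rownames(x)[which(is.na(lengths))[1L]])
  }
  g_global <- sum(rowSums(x) > 0)
  res <- lapply(seq_len(ncol(x)), function(s) {
    v <- x[, s]
    g <- sum(v > 0)
    if (g == 0L) stopf("degenerate sample '%s': all values zero", colnames(x)[s])
    p <- abundance(v, lengths = lengths, mode = from)
    h <- shannon_entropy(p)
    g_norm <- if (g_mode == "global") g_global else g
    if (g_norm <= 1L) {
      warnf("sample '%s' expresses <= 1 gene; H_s set to 0", colnames(x)[s])
      hs <- 0
    } else {
      hs <- h / log2(g_norm)
    }
    c(h = h, hs = hs, g = g)
  })
  res <- do.call(rbind, res)
  data.frame(sample_id = colnames(x),
             H_bits = res[, "h"],
             H_s = res[, "hs"],
             n_expressed = as.integer(res[, "g"]),
             library_size = if (from == "counts") colSums(x) else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Diversity after depth equalization
#'
#' Multinomially resamples each sample's reads down to a common target depth
#' (probabilities equal to the observed count proportions) and recomputes
#' transcriptome diversity. Used to check that depth differences, not
#' biology, are not driving the diversity ranking.
#'
#' @param counts gene-by-sample count matrix.
#' @param annotation gene annotation table.
#' @param target_depth integer read total per sample, or `"auto"` for the
#'   minimum observed library size.
#' @param seed integer seed; resampling is fully reproducible.
#' @inheritParams transcriptome_diversity
#' @return as [transcriptome_diversity()], computed on the resampled counts.
#' @export
downsample_diversity <- function(counts, annotation, target_depth = "auto",
                                 seed = 1L, g_mode = c("per-sample", "global")) {
  validate_counts(counts)
  lib <- colSums(counts)
  if (identical(target_depth, "auto")) target_depth <- min(lib)
  assert_scalar_num(target_depth, "target_depth", lo = 1)
  if (any(lib < target_depth))
    stopf("target depth %d exceeds library size of sample(s): %s",
          as.integer(target_depth),
          paste(colnames(counts)[lib < target_depth], collapse = ", "))
  set.seed(as.integer(seed))
  down <- vapply(seq_len(ncol(counts)), function(s) {
    as.numeric(rmultinom(1L, size = as.integer(target_depth),
                         prob = counts[, s] / lib[s]))
  }, numeric(nrow(counts)))
  dimnames(down) <- dimnames(counts)
  transcriptome_diversity(down, annotation, from = "counts", g_mode = g_mode)
}

#' Within-sample expression variance
#'
#' Per sample, the variance across genes of the expression values (n - 1
#' denominator). Low-diversity samples are dominated by a few highly
#' expressed genes and so show high within-sample variance; the statistic is
#' the standard diagnostic to pair with `H_s` via Spearman correlation.
#'
#' @param expr gene-by-sample expression matrix (any unit).
#' @return named numeric vector, one variance per sample.
#' @export
within_sample_variance <- function(expr) {
  if (!is.matrix(expr) || nrow(expr) < 2L)
    stopf("within_sample_variance needs a matrix with >= 2 genes")
  apply(expr, 2L, var)
}
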