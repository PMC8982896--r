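#' Gene-wise association of expression with a sample covariate
#'
#' For every gene, fits ordinary least squares `y = b0 + gamma * x + e` with
#' both the gene's expression `y` and the covariate `x` rank
#' inverse-normal transformed (see [rankit()]), reports the slope `gamma`,
#' its two-sided t-test, BH-adjusted q-values across all tested genes, and
#' the Spearman correlation computed on the untransformed values. Genes with
#' constant expression cannot be transformed and are flagged (`tested =
#' FALSE`, statistics `NA`) rather than dropped.
#'
#' Because both sides are reduced to normal scores, `gamma` and its p-value
#' are invariant under any strictly monotone transform of covariate or
#' expression, and `gamma = 1` exactly when expression is a strictly
#' increasing function of an untied covariate.
#'
#' @param expr gene-by-sample expression matrix (any unit).
#' @param covariate numeric vector, one value per sample (e.g. the `H_s`
#'   column of [transcriptome_diversity()]).
#' @return data.frame, one row per gene: `gene_id`, `gamma`, `t_stat`,
#'   `p_value`, `q_value`, `spearman_rho`, `mean_expression`, `tested`.
#' @export
associate <- function(expr, covariate) {
  if (!is.matrix(expr)) stopf("expr must be a gene-by-sample matrix")
  n <- ncol(expr)
  if (length(covariate) != n)
    stopf("covariate length (%d) != number of samples (%d)",
          length(covariate), n)
  if (n < 4L) stopf("associate needs >= 4 samples")
  if (anyNA(covariate)) stopf("covariate contains NA")
  if (length(unique(covariate)) == 1L)
    stopf("covariate is constant; association undefined")

  x <- rankit(covariate)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  cov_rank <- rank(covariate, ties.method = "average")

  tested <- apply(expr, 1L, function(v) length(unique(v)) > 1L)
  gamma <- t_stat <- p <- rho <- rep(NA_real_, nrow(expr))
  if (any(tested)) {
    Y <- t(apply(expr[tested, , drop = FALSE], 1L, rankit))  # genes x samples
    Yc <- Y - rowMeans(Y)
    g <- as.numeric(Yc %*% xc) / sxx
    res_ss <- rowSums(Yc^2) - g^2 * sxx
    res_ss[res_ss < 0] <- 0
    se <- sqrt(res_ss / (n - 2L) / sxx)
    tt <- ifelse(se > 0, g / se, sign(g) * Inf)
    pv <- pmax(2 * pt(abs(tt), df = n - 2L, lower.tail = FALSE),
               .Machine$double.xmin)
    R <- t(apply(expr[tested, , drop = FALSE], 1L, rank, ties.method = "average"))
    rr <- suppressWarnings(as.numeric(cor(t(R), cov_rank)))
    gamma[tested] <- g; t_stat[tested] <- tt; p[tested] <- pv; rho[tested] <- rr
  }
  q <- rep(NA_real_, nrow(expr))
  q[tested] <- bh_adjust(p[tested])
  data.frame(gene_id = rownames(expr), gamma = gamma, t_stat = t_stat,
             p_value = p, q_value = q, spearman_rho = rho,
             mean_expression = rowMeans(expr), tested = tested,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity. Inputs must be valid
#' p-values in (0, 1]. Significance calls downstream use `q < 0.05`
#' strictly.
#'
#' @param p numeric vector of p-values.
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (anyNA(p) || any(p <= 0 | p > 1))
    stopf("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation with t-approximated p-value
#'
#' Average-rank tie handling; the p-value uses the t approximation
#' (`exact = FALSE`), appropriate at the sample sizes this package targets.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stopf("spearman needs two equal-length vectors of length >= 2")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("constant input; correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration null when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `U` (statistic for `x`) and two-sided `p`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("mann_whitney needs >= 2 values per group")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= 12L && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis rank-sum test
#'
#' Chi-square approximation with tie correction, for comparing a numeric
#' outcome across >= 2 groups.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `H_stat`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("kruskal_wallis needs a list of >= 2 groups")
  kt <- stats::kruskal.test(groups)
  list(H_stat = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Summary of an association table
#'
#' Counts and percentages of genes significantly associated with the
#' covariate (`q < alpha`, strict), and among the significant ones the split
#' into positive (`gamma > 0`) and negative slopes.
#'
#' @param assoc data.frame from [associate()].
#' @param alpha FDR threshold, default 0.05.
#' @return one-row data.frame: `n_tested`, `n_significant`, `pct_significant`,
#'   `n_positive`, `n_negative`, `pct_positive_of_significant`.
#' @export
summarize_associations <- function(assoc, alpha = 0.05) {
  if (nrow(assoc) == 0L) stopf("empty association table")
  assert_scalar_num(alpha, "alpha", lo = 1e-12, hi = 1)
  tested <- assoc[assoc$tested, , drop = FALSE]
  sig <- tested$q_value < alpha
  n_sig <- sum(sig)
  n_pos <- sum(sig & tested$gamma > 0)
  n_neg <- sum(sig & tested$gamma < 0)
  data.frame(n_tested = nrow(tested),
             n_significant = n_sig,
             pct_significant = 100 * n_sig / nrow(tested),
             n_positive = n_pos,
             n_negative = n_neg,
             pct_positive_of_significant =
               if (n_sig > 0) 100 * n_pos / n_sig else NA_real_)
}

#' Which gene attributes predict the strength of association?
#'
#' Multiple OLS of a per-gene association level on gene length, GC fraction
#' and mean expression jointly (with intercept). The response is `|gamma|`
#' from the rankit-scale per-gene regressions by default, or `-log10(p)`
#' with `response = "neglog10p"`. Length and mean expression are
#' log-transformed and all three predictors standardized, so coefficients
#' are comparable effect sizes per predictor SD. p-values are two-sided
#' t-tests, BH-adjusted across the three coefficients.
#'
#' @param assoc data.frame from [associate()].
#' @param annotation gene annotation covering every tested gene.
#' @param response `"abs_gamma"` (default) or `"neglog10p"`.
#' @return data.frame with rows `length`, `gc`, `mean_expression`:
#'   `estimate`, `t_stat`, `p_value`, `q_value`, plus attribute `n_genes`.
#' @export
attribute_regression <- function(assoc, annotation,
                                 response = c("abs_gamma", "neglog10p")) {
  response <- match.arg(response)
  tested <- assoc[assoc$tested, , drop = FALSE]
  idx <- match(tested$gene_id, annotation$gene_id)
  if (anyNA(idx))
    stopf("annotation missing gene '%s'", tested$gene_id[which(is.na(idx))[1L]])
  y <- if (response == "abs_gamma") abs(tested$gamma)
       else -log10(tested$p_value)
  std <- function(v, name) {
    if (sd(v) == 0) stopf("predictor '%s' is constant; design is rank-deficient",
                          name)
    (v - mean(v)) / sd(v)
  }
  X <- cbind(length = std(log(annotation$effective_length[idx]), "length"),
             gc = std(annotation$gc_fraction[idx], "gc"),
             mean_expression = std(log(tested$mean_expression +
                                       min(tested$mean_expression[tested$mean_expression > 0],
                                           1) * 1e-3), "mean_expression"))
  D <- cbind(intercept = 1, X)
  if (qr(D)$rank < ncol(D)) {
    # name a collinear column for the error
    drop1_rank <- vapply(colnames(X), function(cn)
      qr(D[, setdiff(colnames(D), cn), drop = FALSE])$rank, integer(1L))
    culprit <- names(drop1_rank)[drop1_rank == max(drop1_rank)][1L]
    stopf("rank-deficient design: column '%s' is collinear", culprit)
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)$coefficients[-1L, , drop = FALSE]
  out <- data.frame(term = colnames(X),
                    estimate = sm[, "Estimate"],
                    t_stat = sm[, "t value"],
                    p_value = sm[, "Pr(>|t|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$q_value <- bh_adjust(out$p_value)
  attr(out, "n_genes") <- nrow(tested)
  out
}
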