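#' Recommended latent-factor count for a sample size
#'
#' The piecewise rule tying the number of inferred expression factors to
#' cohort size: 15 for up to 150 samples, 30 for 151-250, 45 for 251-350,
#' and 60 for more than 350 samples.
#'
#' @param n_samples positive integer.
#' @return integer factor count.
#' @export
select_factor_count <- function(n_samples) {
  assert_scalar_num(n_samples, "n_samples", lo = 1)
  if (n_samples <= 150) 15L
  else if (n_samples <= 250) 30L
  else if (n_samples <= 350) 45L
  else 60L
}

#' Infer latent expression factors
#'
#' Default engine standing in for PEER-style covariates: every retained gene
#' is rank inverse-normal transformed across samples, PCA is run with
#' samples as observations, and the top-N per-sample scores are returned as
#' factors. Externally computed factors (e.g. true PEER covariates) can be
#' loaded with [read_factors()] instead; every downstream computation only
#' needs the per-sample factor values, whatever their origin.
#'
#' @param expr gene-by-sample expression matrix, already gene-filtered
#'   (see [filter_genes()]).
#' @param n_factors integer, or `"auto"` to apply [select_factor_count()].
#' @return samples-by-factors matrix (columns `factor_1..factor_N`) with
#'   attributes `provenance = "internal-PCA"` and `variance_fraction`
#'   (each factor's share of the rankit expression variance).
#' @export
infer_factors <- function(expr, n_factors = "auto") {
  if (!is.matrix(expr) || ncol(expr) < 3L)
    stopf("infer_factors needs a matrix with >= 3 samples")
  if (identical(n_factors, "auto")) n_factors <- select_factor_count(ncol(expr))
  assert_scalar_num(n_factors, "n_factors", lo = 1)
  n_factors <- as.integer(n_factors)
  max_rank <- min(ncol(expr) - 1L, nrow(expr))
  if (n_factors > max_rank)
    stopf("n_factors = %d exceeds the matrix rank bound %d", n_factors, max_rank)
  ok <- apply(expr, 1L, function(v) length(unique(v)) > 1L)
  if (!all(ok)) {
    warnf("%d constant gene(s) dropped before factor inference", sum(!ok))
    expr <- expr[ok, , drop = FALSE]
  }
  Y <- t(apply(expr, 1L, rankit))
  pc <- expr_pca(Y)
  if (n_factors > pc$n_pcs)
    stopf("n_factors = %d exceeds the effective rank %d", n_factors, pc$n_pcs)
  f <- pc$scores[, seq_len(n_factors), drop = FALSE]
  colnames(f) <- paste0("factor_", seq_len(n_factors))
  rownames(f) <- colnames(expr)
  attr(f, "provenance") <- "internal-PCA"
  attr(f, "variance_fraction") <- pc$variance_fraction[seq_len(n_factors)]
  f
}

#' Correlation of each factor with a covariate
#'
#' Per-factor Spearman correlation with BH adjustment across factors and a
#' `significant` flag at q < 0.05. Constant factor columns are skipped with
#' a warning. If a [expr_pca()] of the expression matrix is supplied, each
#' factor's share of the matrix variance (via [query_variance()]) is
#' appended, pairing correlation strength with variance captured.
#'
#' @param factors samples-by-factors matrix.
#' @param covariate per-sample numeric vector, non-constant.
#' @param pca optional [expr_pca()] result for the variance-share column.
#' @return data.frame: `factor_id`, `spearman_rho`, `p`, `q`, `significant`
#'   (and `v_share` when `pca` is given).
#' @export
factor_covariate_correlations <- function(factors, covariate, pca = NULL) {
  if (length(covariate) != nrow(factors))
    stopf("covariate length != number of samples")
  if (sd(covariate) == 0) stopf("constant covariate; correlation undefined")
  ok <- apply(factors, 2L, sd) > 0
  if (!all(ok))
    warnf("constant factor column(s) skipped: %s",
          paste(colnames(factors)[!ok], collapse = ", "))
  res <- lapply(which(ok), function(k) spearman(covariate, factors[, k]))
  out <- data.frame(factor_id = colnames(factors)[ok],
                    spearman_rho = vapply(res, `[[`, numeric(1L), "rho"),
                    p = vapply(res, `[[`, numeric(1L), "p"),
                    stringsAsFactors = FALSE)
  out$q <- bh_adjust(pmin(pmax(out$p, .Machine$double.xmin), 1))
  out$significant <- out$q < 0.05
  if (!is.null(pca))
    out$v_share <- vapply(which(ok), function(k)
      query_variance(pca, factors[, k])$v_total, numeric(1L))
  out
}

#' Regress a covariate out of every factor
#'
#' Per factor, ordinary least squares on intercept plus the covariate; the
#' returned factor set holds the residuals, each exactly uncorrelated with
#' the covariate. Residualizing twice equals once.
#'
#' @param factors samples-by-factors matrix.
#' @param covariate per-sample numeric (or 2-level categorical) vector.
#' @return residual factor matrix, same shape and dimnames, provenance
#'   tagged `"residualized"`.
#' @export
residualize <- function(factors, covariate) {
  covariate <- covariate_as_numeric(covariate)
  if (length(covariate) != nrow(factors))
    stopf("covariate length != number of samples")
  if (sd(covariate) == 0) stopf("constant covariate; nothing to regress out")
  X <- cbind(1, covariate)
  r <- as.matrix(lm.fit(X, factors)$residuals)
  dimnames(r) <- dimnames(factors)
  attr(r, "provenance") <- "residualized"
  r
}

# categorical 2-level covariates (sex, batch) enter regressions as 0/1
covariate_as_numeric <- function(covariate) {
  if (is.numeric(covariate)) return(covariate)
  f <- factor(covariate)
  if (nlevels(f) != 2L)
    stopf("non-numeric covariates must have exactly 2 levels (got %d)",
          nlevels(f))
  as.numeric(f) - 1
}

#' Per-gene variance explained by a factor set
#'
#' For every gene, the rank inverse-normal transformed expression is
#' regressed on all factors jointly (with intercept); the coefficient of
#' determination r^2 is returned. Requires more samples than factors plus
#' intercept, otherwise the fit is saturated.
#'
#' @param expr gene-by-sample expression matrix.
#' @param factors samples-by-factors matrix with matching samples.
#' @return named numeric vector of per-gene r^2 in \[0, 1\]; constant genes
#'   get `NA`.
#' @export
gene_factor_r2 <- function(expr, factors) {
  if (ncol(expr) != nrow(factors))
    stopf("expression has %d samples but factors have %d",
          ncol(expr), nrow(factors))
  if (!is.null(rownames(factors)) && !is.null(colnames(expr)))
    check_ids_match(colnames(expr), rownames(factors), "factor sample")
  # a residualized factor that was (numerically) identical to the covariate
  # collapses to noise of near-zero scale; such columns carry no signal and
  # must not act as extra regressors
  col_sd <- apply(factors, 2L, sd)
  live <- col_sd > 1e-8 * max(col_sd)
  factors <- factors[, live, drop = FALSE]
  k <- ncol(factors)
  n <- ncol(expr)
  if (n <= k + 1L)
    stopf("saturated fit: %d samples for %d factors + intercept", n, k)
  tested <- apply(expr, 1L, function(v) length(unique(v)) > 1L)
  r2 <- rep(NA_real_, nrow(expr))
  names(r2) <- rownames(expr)
  if (!any(tested)) return(r2)
  Y <- apply(expr[tested, , drop = FALSE], 1L, rankit)  # samples x genes
  qr_x <- qr(cbind(1, factors))
  fitted <- qr.fitted(qr_x, Y)
  Yc <- sweep(Y, 2L, colMeans(Y))
  Fc <- sweep(fitted, 2L, colMeans(Y))
  r2[tested] <- colSums(Fc^2) / colSums(Yc^2)
  pmin(pmax(r2, 0), 1)
}

#' How much factor-explained variance does a covariate account for?
#'
#' Computes per-gene r^2 of expression on the intact factors (`r1_sq`) and
#' on the factors with the covariate regressed out (`r2_sq`), their medians,
#' the headline `delta_median = median(r1_sq) - median(r2_sq)`, the
#' normalized `accounted_fraction = delta_median / v_total(factors)` (the
#' share of the factor-explained matrix variance attributable to the
#' covariate), and a two-sided Mann-Whitney p comparing the two r^2
#' distributions. Works for any per-sample covariate (diversity, sex,
#' batch, depth, ...), one at a time.
#'
#' @param expr gene-by-sample expression matrix.
#' @param factors samples-by-factors matrix.
#' @param covariate per-sample vector (numeric or 2-level categorical).
#' @param covariate_name label carried into the result.
#' @param pca optional [expr_pca()] of `expr`, reused for
#'   `v_total(factors)`; computed when absent.
#' @return list of class `txdiv_accounting`: `r1_sq`, `r2_sq` (per gene),
#'   `median_r1_sq`, `median_r2_sq`, `delta_median`, `v_total_factors`,
#'   `accounted_fraction`, `mw_p`, `covariate`.
#' @export
account <- function(expr, factors, covariate, covariate_name = "covariate",
                    pca = NULL) {
  cov_num <- covariate_as_numeric(covariate)
  if (sd(cov_num) == 0) stopf("degenerate covariate '%s'", covariate_name)
  r1 <- gene_factor_r2(expr, factors)
  fr <- residualize(factors, cov_num)
  r2 <- gene_factor_r2(expr, fr)
  m1 <- median(r1, na.rm = TRUE)
  m2 <- median(r2, na.rm = TRUE)
  if (is.null(pca)) pca <- expr_pca(expr)
  vt <- query_variance(pca, factors)$v_total
  ok <- !is.na(r1) & !is.na(r2)
  mw <- mann_whitney(r1[ok], r2[ok])
  structure(list(r1_sq = r1, r2_sq = r2,
                 median_r1_sq = m1, median_r2_sq = m2,
                 delta_median = m1 - m2,
                 v_total_factors = vt,
                 accounted_fraction = if (vt > 0) (m1 - m2) / vt else NA_real_,
                 mw_p = mw$p,
                 covariate = covariate_name),
            class = "txdiv_accounting")
}

#' @export
print.txdiv_accounting <- function(x, ...) {
  cat(sprintf("Accounting of factor-explained variance by '%s'\n", x$covariate))
  cat(sprintf("  median r^2 intact:        %.4f\n", x$median_r1_sq))
  cat(sprintf("  median r^2 residualized:  %.4f\n", x$median_r2_sq))
  cat(sprintf("  delta median r^2:         %.4f (%.1f%% of per-gene variance)\n",
              x$delta_median, 100 * x$delta_median))
  cat(sprintf("  v_total(factors):         %.4f\n", x$v_total_factors))
  cat(sprintf("  accounted fraction:       %.4f\n", x$accounted_fraction))
  cat(sprintf("  Mann-Whitney p:           %.3g\n", x$mw_p))
  invisible(x)
}
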