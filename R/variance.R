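#' PCA of an expression matrix
#'
#' Principal component analysis with samples as observations and genes as
#' variables; genes are centered, not scaled. Returns per-sample scores
#' (often called "loadings" in the expression literature -- here they are
#' the per-sample coordinates on each PC) and each PC's share of the total
#' centered variance. Components with eigenvalue below `tol` are dropped.
#'
#' @param expr gene-by-sample expression matrix (>= 2 genes, >= 2 samples).
#' @param tol eigenvalue floor below which components are discarded.
#' @return object of class `txdiv_pca`: list with `scores` (samples x PCs),
#'   `variance_fraction` (per retained PC, sums to 1), `sdev`, `n_pcs`.
#' @export
expr_pca <- function(expr, tol = 1e-12) {
  if (!is.matrix(expr) || ncol(expr) < 2L || nrow(expr) < 2L)
    stopf("PCA needs >= 2 samples and >= 2 genes")
  pc <- prcomp(t(expr), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > tol
  v <- ev[keep] / sum(ev[keep])
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 variance_fraction = v,
                 sdev = pc$sdev[keep],
                 n_pcs = sum(keep)),
            class = "txdiv_pca")
}

#' Variance of the expression matrix explained by a query vector
#'
#' For each principal component, both the query and the PC's sample scores
#' are rank inverse-normal transformed and the squared Pearson correlation
#' `r_i^2` is taken; the total variance explained by the query is
#' `v_total = sum(r_i^2 * v_i)` over the included PCs, where `v_i` is PC i's
#' variance share. With a matrix of query columns, `r_i^2` is the multiple
#' coefficient of determination of PC i regressed on all (rankit) columns
#' jointly -- used to measure the variance captured by a whole factor set.
#'
#' @param pca a [expr_pca()] result.
#' @param query per-sample numeric vector (non-constant), or a
#'   samples-by-queries matrix.
#' @param n_pcs number of leading PCs to include (default all retained).
#' @return list with `r_sq` (per included PC), `v` (their variance shares)
#'   and `v_total`.
#' @export
query_variance <- function(pca, query, n_pcs = NULL) {
  stopifnot(inherits(pca, "txdiv_pca"))
  if (is.null(n_pcs)) n_pcs <- pca$n_pcs
  if (n_pcs < 1L || n_pcs > pca$n_pcs)
    stopf("n_pcs must lie in [1, %d]", pca$n_pcs)
  Q <- if (is.matrix(query)) query else matrix(query, ncol = 1L)
  if (nrow(Q) != nrow(pca$scores))
    stopf("query has %d rows but the PCA has %d samples",
          nrow(Q), nrow(pca$scores))
  if (anyNA(Q)) stopf("query contains NA")
  if (any(apply(Q, 2L, sd) == 0))
    stopf("constant query column; variance explained undefined")
  Qr <- apply(Q, 2L, rankit)
  if (!is.matrix(Qr)) Qr <- matrix(Qr, ncol = ncol(Q))
  r_sq <- vapply(seq_len(n_pcs), function(i) {
    y <- rankit(pca$scores[, i])
    fit <- lm.fit(cbind(1, Qr), y)
    yc <- y - mean(y)
    1 - sum(fit$residuals^2) / sum(yc^2)
  }, numeric(1L))
  v <- pca$variance_fraction[seq_len(n_pcs)]
  list(r_sq = r_sq, v = v, v_total = sum(r_sq * v))
}

#' Per-PC correlation of a query with sample scores
#'
#' Spearman correlation (t-approximated p) of the query against the sample
#' scores of the first `top_k` PCs, BH-adjusted over those k tests, plus the
#' identity of the most-correlated PC -- the record used to describe which
#' axis of an expression matrix a covariate tracks.
#'
#' @inheritParams query_variance
#' @param top_k number of leading PCs to test (default `min(8, n_pcs)`).
#' @return data.frame with one row per tested PC: `pc`, `spearman_rho`, `p`,
#'   `q`, `variance_fraction`; attributes `best_pc`, `best_rho` give the
#'   argmax-|rho| PC and its signed correlation.
#' @export
pc_correlation_table <- function(pca, query, top_k = min(8L, pca$n_pcs)) {
  stopifnot(inherits(pca, "txdiv_pca"))
  if (top_k < 1L || top_k > pca$n_pcs)
    stopf("top_k must lie in [1, %d]", pca$n_pcs)
  res <- lapply(seq_len(top_k), function(i)
    spearman(query, pca$scores[, i]))
  out <- data.frame(pc = seq_len(top_k),
                    spearman_rho = vapply(res, `[[`, numeric(1L), "rho"),
                    p = vapply(res, `[[`, numeric(1L), "p"),
                    variance_fraction = pca$variance_fraction[seq_len(top_k)])
  out$q <- bh_adjust(pmin(pmax(out$p, .Machine$double.xmin), 1))
  best <- which.max(abs(out$spearman_rho))
  attr(out, "best_pc") <- out$pc[best]
  attr(out, "best_rho") <- out$spearman_rho[best]
  out
}
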