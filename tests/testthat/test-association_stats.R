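test_that("rankit OLS recovers exact unit slopes for monotone expression", {
  set.seed(20)
  x <- runif(20)
  e <- rbind(up = exp(3 * x), down = -x^3)
  colnames(e) <- paste0("s", 1:20)
  a <- associate(e, x)
  expect_equal(a$gamma, c(1, -1))
  expect_true(all(a$q_value < 1e-10))
  expect_equal(a$spearman_rho, c(1, -1))

  # antisymmetry under negating the covariate
  a2 <- associate(e, -x)
  expect_equal(a2$gamma, -a$gamma)
  expect_equal(a2$p_value, a$p_value)

  # invariance of p-values under strictly monotone covariate transforms
  set.seed(21)
  em <- matrix(rnorm(5 * 20), 5, 20,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  a3 <- associate(em, x)
  a4 <- associate(em, exp(10 * x))
  expect_equal(a3$p_value, a4$p_value, tolerance = 1e-12)

  # constant genes are flagged, not dropped
  ec <- rbind(em, flat = rep(1, 20))
  a5 <- associate(ec, x)
  expect_false(a5$tested[6])
  expect_true(is.na(a5$gamma[6]))
  expect_identical(nrow(a5), 6L)

  expect_error(associate(em, rep(1, 20)), "constant")
  expect_error(associate(em[, 1:3], x[1:3]), ">= 4 samples")
})

test_that("null expression keeps the type-I error near nominal", {
  set.seed(3)
  e <- matrix(rnorm(1000 * 50), 1000, 50,
              dimnames = list(paste0("g", 1:1000), paste0("s", 1:50)))
  a <- associate(e, rnorm(50))
  expect_gte(mean(a$p_value < 0.05), 0.03)
  expect_lte(mean(a$p_value < 0.05), 0.07)
})

test_that("BH adjustment equals the literal step-up on hand and random cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.6)), c(0.015, 0.06, 0.6))
  expect_identical(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.4)), "0, 1")

  # literal step-up oracle: q_(i) = min_{j >= i} p_(j) * m / j
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    ps <- p[o]
    q[m] <- ps[m]
    for (i in (m - 1):1) q[i] <- min(q[i + 1], ps[i] * m / i)
    out <- numeric(m); out[o] <- pmin(q, 1); out
  }
  set.seed(9)
  for (i in 1:200) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    p[p == 0] <- 0.5
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("rank tests match enumeration and hand arithmetic", {
  s <- spearman(c(1, 2, 3), c(1, 4, 9))
  expect_equal(s$rho, 1)
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "constant")

  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)

  # exact vs normal-approximation agreement at combined n = 12, no ties
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    p_pkg <- mann_whitney(x, y)$p
    p_approx <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(p_pkg, p_exact)
    expect_lt(abs(p_exact - p_approx), 0.02)
  }

  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H_stat, 7.2)
  expect_equal(kw$df, 2)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
})

test_that("association summaries count significance and direction", {
  assoc <- data.frame(gene_id = paste0("g", 1:4),
                      gamma = c(0.5, 0.4, 0.8, -0.2),
                      t_stat = 1, p_value = 0.01,
                      q_value = c(0.01, 0.02, 0.04, 0.5),
                      spearman_rho = 0.1, mean_expression = 1,
                      tested = TRUE)
  s <- summarize_associations(assoc)
  expect_equal(s$pct_significant, 75)
  expect_equal(s$pct_positive_of_significant, 100)
  expect_equal(s$n_negative, 0)

  assoc$q_value <- rep(0.5, 4)
  s2 <- summarize_associations(assoc)
  expect_equal(s2$pct_significant, 0)
  expect_true(is.na(s2$pct_positive_of_significant))
})

test_that("attribute regression recovers a planted length effect", {
  one_rep <- function(seed, planted = 2) {
    set.seed(seed)
    ng <- 300
    len <- round(exp(runif(ng, log(200), log(10000))))
    ann <- data.frame(gene_id = paste0("g", 1:ng), effective_length = len,
                      gc_fraction = rbeta(ng, 5, 5))
    z_len <- as.numeric(scale(log(len)))
    gamma <- 10 + planted * z_len + rnorm(ng)   # offset keeps |gamma| = gamma
    assoc <- data.frame(gene_id = ann$gene_id, gamma = gamma, t_stat = 1,
                        p_value = 0.5, q_value = 0.5, spearman_rho = 0,
                        mean_expression = exp(rnorm(ng, 3, 1)), tested = TRUE)
    attribute_regression(assoc, ann)
  }
  res <- lapply(1:100, one_rep)
  len_row <- lapply(res, function(r) r[r$term == "length", ])
  covered <- vapply(len_row, function(r)
    abs(r$estimate - 2) < 3 * abs(r$estimate / r$t_stat), logical(1))
  expect_gte(mean(covered), 0.9)
  others_ns <- vapply(res, function(r)
    all(r$q_value[r$term != "length"] >= 0.05), logical(1))
  expect_gte(mean(others_ns), 0.85)

  # null response: each coefficient significant only at chance level
  null_res <- lapply(101:200, function(s) one_rep(s, planted = 0))
  # remove the planted slope: refit with gamma independent of predictors
  null_sig <- vapply(null_res, function(r)
    r$p_value[r$term == "gc"] < 0.05, logical(1))
  expect_lte(mean(null_sig), 0.12)

  # collinear predictors are rejected with a named column
  set.seed(5)
  ann <- data.frame(gene_id = paste0("g", 1:50),
                    effective_length = round(seq(300, 4000, length.out = 50)))
  ann$gc_fraction <- as.numeric(scale(log(ann$effective_length))) * 0.1 + 0.5
  assoc <- data.frame(gene_id = ann$gene_id, gamma = rnorm(50), t_stat = 1,
                      p_value = 0.5, q_value = 0.5, spearman_rho = 0,
                      mean_expression = exp(rnorm(50)), tested = TRUE)
  expect_error(attribute_regression(assoc, ann), "collinear")
})
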