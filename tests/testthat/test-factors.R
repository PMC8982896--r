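test_that("factor-count rule reproduces its thresholds and is non-decreasing", {
  expect_identical(select_factor_count(120), 15L)
  expect_identical(select_factor_count(300), 45L)
  expect_identical(select_factor_count(851), 60L)
  expect_identical(vapply(c(150, 151, 250, 251, 350, 351),
                          select_factor_count, integer(1)),
                   c(15L, 30L, 30L, 45L, 45L, 60L))
  counts <- vapply(1:400, select_factor_count, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("factor inference recovers a planted axis and applies the rule", {
  set.seed(40)
  axis <- rnorm(30)
  e <- outer(rexp(120), axis)
  e <- e + matrix(rnorm(length(e), sd = 1e-8), nrow(e))  # break exact ties
  dimnames(e) <- list(paste0("g", 1:120), paste0("s", 1:30))
  attr(e, "unit") <- "tmm_cpm"
  f <- infer_factors(e, n_factors = 1)
  expect_equal(abs(cor(f[, 1], axis, method = "spearman")), 1)
  expect_identical(attr(f, "provenance"), "internal-PCA")

  big <- matrix(rnorm(100 * 400), 100, 400,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:400)))
  fa <- infer_factors(big)   # auto
  expect_identical(ncol(fa), 60L)
  expect_identical(colnames(fa)[1], "factor_1")

  small <- matrix(rnorm(80 * 50), 80, 50,
                  dimnames = list(paste0("g", 1:80), paste0("s", 1:50)))
  expect_error(infer_factors(small, n_factors = 100), "rank")
})

test_that("factor-covariate correlations flag the matching factor", {
  set.seed(41)
  f <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(paste0("s", 1:40), paste0("factor_", 1:5)))
  tab <- factor_covariate_correlations(f, f[, 3])
  expect_equal(abs(tab$spearman_rho[3]), 1)
  expect_lt(tab$q[3], 1e-10)
  expect_true(tab$significant[3])

  f2 <- f; f2[, 2] <- 1
  expect_warning(tab2 <- factor_covariate_correlations(f2, f[, 3]),
                 "factor_2")
  expect_identical(nrow(tab2), 4L)
  expect_error(factor_covariate_correlations(f, rep(2, 40)), "constant")
})

test_that("residualization is exact OLS, idempotent, and decorrelates", {
  set.seed(42)
  f <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(paste0("s", 1:50), paste0("factor_", 1:4)))
  cv <- rnorm(50)
  r <- residualize(f, cv)
  expect_lt(max(abs(cor(r, cv))), 1e-10)
  expect_equal(residualize(r, cv), r, tolerance = 1e-10,
               ignore_attr = "provenance")
  # closed-form simple-OLS oracle per column
  for (k in 1:4) {
    b <- cov(f[, k], cv) / var(cv)
    a <- mean(f[, k]) - b * mean(cv)
    expect_equal(unname(r[, k]), unname(f[, k] - a - b * cv),
                 tolerance = 1e-12)
  }
  # an exact multiple of the covariate residualizes to ~zero
  fz <- cbind(factor_1 = 2 * cv, factor_2 = f[, 2])
  rownames(fz) <- rownames(f)
  expect_lt(max(abs(residualize(fz, cv)[, 1])), 1e-10)
  # a centered factor orthogonal to the centered covariate is unchanged
  orth <- lm.fit(cbind(1, cv), f[, 3])$residuals
  fo <- cbind(factor_1 = orth); rownames(fo) <- rownames(f)
  expect_equal(unname(residualize(fo, cv)[, 1]), unname(orth),
               tolerance = 1e-10)
  expect_error(residualize(f, rep(1, 50)), "constant")
})

test_that("per-gene factor r2 hits its exact and null expectations", {
  set.seed(43)
  f <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(paste0("s", 1:100), paste0("factor_", 1:10)))
  e <- matrix(rnorm(500 * 100), 500, 100,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:100)))
  # a gene whose normal scores ARE a factor is fitted perfectly: make the
  # factor a rankit grid so the transform is the identity on it
  f[, 1] <- rankit(f[, 1])
  e[1, ] <- f[, 1]
  r2 <- gene_factor_r2(e, f)
  expect_equal(unname(r2[1]), 1, tolerance = 1e-9)
  expect_true(all(r2 >= 0 & r2 <= 1))
  # null expectation k/(n-1) = 10/99
  expect_lt(abs(mean(r2[-1]) - 10 / 99), 0.015)

  expect_error(gene_factor_r2(e[, 1:10], f[1:10, ]), "saturated")
})

test_that("accounting separates coupled from orthogonal covariates", {
  sim <- simulate_dataset(sim_config(n_genes = 400, n_samples = 60,
                                     depth_log_mean = log(1e5), seed = 44))
  tmm <- compute_tmm(sim$counts)
  keep <- filter_genes(tmm$expression)
  expr <- tmm$expression[keep, , drop = FALSE]
  attr(expr, "unit") <- "tmm_cpm"
  p <- expr_pca(expr)
  f <- infer_factors(expr, n_factors = 8)

  # covariate orthogonal to every factor: nothing to account for
  set.seed(45)
  ortho <- lm.fit(cbind(1, f), rnorm(60))$residuals
  acc0 <- account(expr, f, ortho, "orthogonal", pca = p)
  expect_lt(abs(acc0$delta_median), 1e-6)
  expect_gt(acc0$mw_p, 0.9)

  # covariate equal to factor k: matches a literal drop-one-factor refit
  acc3 <- account(expr, f, f[, 3], "factor_3", pca = p)
  drop3 <- gene_factor_r2(expr, f[, -3, drop = FALSE])
  expect_equal(unname(acc3$r2_sq), unname(drop3), tolerance = 1e-8)
  expect_equal(acc3$delta_median,
               median(acc3$r1_sq) - median(drop3), tolerance = 1e-12)
  expect_gt(acc3$delta_median, 0)

  # permuted covariates give delta_median centered at zero
  set.seed(46)
  hs <- transcriptome_diversity(sim$counts, sim$annotation)$H_s
  perm_delta <- vapply(1:60, function(i)
    account(expr, f, sample(hs), "perm", pca = p)$delta_median, numeric(1))
  expect_lt(abs(mean(perm_delta)), 0.02)

  # two-level categorical covariates are accepted
  acc_sex <- account(expr, f, sim$truth$sex, "sex", pca = p)
  expect_true(is.finite(acc_sex$delta_median))
  expect_error(account(expr, f, rep("x", 60), "bad"), "2 levels")
  expect_output(print(acc3), "delta median")
})
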