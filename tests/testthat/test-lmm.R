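# brute-force per-SNP OLS through the normal equations, as oracle
naive_linreg <- function(g, y) {
  t(vapply(seq_len(ncol(g)), function(j) {
    X <- cbind(1, g[, j])
    if (var(g[, j]) == 0) return(c(0, NA, 1))
    XtXi <- solve(t(X) %*% X)
    b <- XtXi %*% t(X) %*% y
    r <- y - X %*% b
    s2 <- sum(r^2) / (length(y) - 2)
    se <- sqrt(s2 * XtXi[2, 2])
    tval <- b[2] / se
    c(b[2], se, 2 * pt(-abs(tval), length(y) - 2))
  }, numeric(3)))
}

test_that("per-SNP linear regression matches hand cases and the oracle", {
  # perfect fit: beta = 1, p underflows toward zero
  a <- gwas_linreg(cbind(v1 = c(0, 1, 2, 0, 1)), c(1, 2, 3, 1, 2))
  expect_equal(a$beta, 1)
  expect_lt(a$p_value, 1e-10)
  # orthogonal trait: beta = 0
  b <- gwas_linreg(cbind(v1 = c(0, 1, 0, 1)), c(1, 1, -1, -1))
  expect_equal(b$beta, 0)
  # random instance vs brute-force normal equations
  set.seed(50)
  g <- matrix(sample(0:2, 50 * 20, replace = TRUE), 50, 20)
  y <- rnorm(50)
  res <- gwas_linreg(g, y)
  oracle <- naive_linreg(g, y)
  expect_equal(res$beta, oracle[, 1], tolerance = 1e-10)
  expect_equal(res$se, oracle[, 2], tolerance = 1e-10)
  expect_equal(res$p_value, oracle[, 3], tolerance = 1e-10)
  expect_error(gwas_linreg(g, rep(1, 50)), "constant")
})

test_that("zero-variance variants are reported with p = 1, keeping rows", {
  g <- cbind(a = c(0, 1, 2, 1), b = c(1, 1, 1, 1))
  res <- gwas_linreg(g, c(0.1, 0.9, 2.2, 1.1))
  expect_equal(nrow(res), 2)
  expect_equal(res$beta[2], 0)
  expect_equal(res$p_value[2], 1)
})

test_that("p-values decrease monotonically in |beta/se| within a scan", {
  set.seed(7)
  g <- matrix(sample(0:2, 80 * 50, replace = TRUE), 80, 50)
  y <- rnorm(80) + g[, 3]
  res <- gwas_linreg(g, y)
  z <- abs(res$beta / res$se)
  expect_equal(order(res$p_value), order(-z))
})

test_that("identity kinship reduces the LMM to OLS", {
  set.seed(8)
  n <- 60
  g <- matrix(sample(0:2, n * 30, replace = TRUE), n, 30)
  y <- rnorm(n) + 0.5 * g[, 5]
  K <- structure(diag(n), sample_ids = as.character(1:n),
                 method = "identity", class = c("kinship", "matrix", "array"))
  fit <- fit_lmm_null(y, K)
  # likelihood is flat in delta; total variance equals the OLS REML variance
  expect_equal(fit$sigma_g2 + fit$sigma_e2, var(y), tolerance = 1e-6)
  lmm <- gwas_lmm(g, y, fit = fit)
  ols <- gwas_linreg(g, y)
  expect_equal(lmm$beta, ols$beta, tolerance = 1e-8)
  # Wald chi-square vs t reference: compare through the z statistics, which
  # the two tests share up to the (documented) reference distribution
  z_lmm <- abs(lmm$beta / lmm$se)
  z_ols <- abs(ols$beta / ols$se)
  # LMM uses df = n - 2 residual variance too, so z agrees tightly
  expect_equal(z_lmm, z_ols, tolerance = 1e-6)
  p_from_z <- pchisq(z_ols^2, 1, lower.tail = FALSE)
  expect_equal(lmm$p_value, p_from_z, tolerance = 1e-6)
})

test_that("a noiseless trait drives the variance estimate to zero", {
  g <- simulate_genotypes(30, 50, seed = 9)
  K <- compute_kinship(mean_impute(g))
  fit <- fit_lmm_null(rep(2.5, 30), K)
  expect_lt(fit$sigma_g2 + fit$sigma_e2, 1e-8)
})

test_that("variance components satisfy their identities", {
  g <- simulate_genotypes(80, 400, seed = 10)
  sim <- simulate_phenotype(g, 20, 0.5, seed = 11)
  K <- compute_kinship(g$dosages)
  fit <- fit_lmm_null(sim$phenotypes$value, K)
  expect_gte(fit$sigma_g2, 0)
  expect_gte(fit$sigma_e2, 0)
  expect_equal(fit$h2, 1 / (1 + fit$delta), tolerance = 1e-8)
  expect_equal(fit$sigma_e2 / fit$sigma_g2, fit$delta, tolerance = 1e-8)
  expect_error(fit_lmm_null(sim$phenotypes$value, K,
                            X = cbind(1, 1)), "rank deficient")
})

test_that("adding a constant to the trait changes no p-value", {
  g <- simulate_genotypes(60, 100, seed = 12)
  sim <- simulate_phenotype(g, 5, 0.4, seed = 13)
  y <- sim$phenotypes$value
  K <- compute_kinship(g$dosages)
  a <- gwas_lmm(g, y, K)
  b <- gwas_lmm(g, y + 17.3, K)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
  c_ <- gwas_linreg(g, y)
  d_ <- gwas_linreg(g, y + 17.3)
  expect_equal(c_$p_value, d_$p_value, tolerance = 1e-9)
})

test_that("per-SNP delta refits never lower the per-SNP likelihood", {
  g <- simulate_genotypes(50, 30, seed = 14)
  sim <- simulate_phenotype(g, 3, 0.5, seed = 15)
  K <- compute_kinship(g$dosages)
  fixed <- gwas_lmm(g, sim$phenotypes$value, K)
  refit <- gwas_lmm(g, sim$phenotypes$value, K, refit_delta_per_snp = TRUE)
  ok <- !is.na(fixed$loglik)
  expect_true(all(refit$loglik[ok] >= fixed$loglik[ok] - 1e-8))
})

test_that("a large-effect SNP is the top hit of the mixed-model scan", {
  hits <- 0
  for (seed in 1:8) {
    g <- simulate_genotypes(150, 300, seed = 500 + seed)
    sim <- simulate_phenotype(g, 1, 0.25, seed = 600 + seed)
    K <- compute_kinship(g$dosages)
    res <- gwas_lmm(g, sim$phenotypes$value, K)
    if (which.min(res$p_value) == sim$truth$causal_indices) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("genomic inflation matches its definition and is monotone", {
  expect_equal(genomic_inflation(rep(0.5, 10)), 1.0)
  set.seed(16)
  p <- runif(1e5)
  lam <- genomic_inflation(p)
  expect_gt(lam, 0.98); expect_lt(lam, 1.02)
  expect_gt(genomic_inflation(p / 2), lam)
  expect_error(genomic_inflation(numeric(0)), "empty")
  expect_error(genomic_inflation(c(0.5, 0)), "0, 1")
  expect_error(genomic_inflation(c(0.5, 1.2)), "0, 1")
})

test_that("LMM p-values are uniform under an unstructured null", {
  g <- simulate_genotypes(200, 2000, seed = 17)
  set.seed(18)
  y <- rnorm(200)
  K <- compute_kinship(g$dosages)
  res <- gwas_lmm(g, y, K)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
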