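test_that("pearson correlation matches hand cases and the direct formula", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  a <- c(0.3, -1.2, 2.2, 0.5)
  expect_equal(pearson_correlation(a, -a), -1.0)
  set.seed(1)
  x <- rnorm(100); y <- rnorm(100)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), oracle, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

test_that("bland-altman statistics are exact on forced cases", {
  ba <- bland_altman(1:5, 1:5)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)
  ba2 <- bland_altman(2:6, 1:5)
  expect_equal(ba2$bias, 1)
  expect_equal(ba2$sd_diff, 0)
  ba3 <- bland_altman(c(1, -1), c(0, 0))
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$sd_diff, sqrt(2))
  expect_equal(ba3$loa_high, 1.96 * sqrt(2))
  expect_equal(ba3$points$difference, c(1, -1))
})

test_that("gblup shrinks toward the training mean for a pure-noise trait", {
  g <- simulate_genotypes(80, 300, seed = 2)
  K <- compute_kinship(g$dosages)
  set.seed(3)
  y <- rnorm(80, mean = 5)
  pred <- gblup_predict(K, y[1:60], 1:60, 61:80)
  # strong shrinkage: predictions hug the training mean, far tighter than
  # the phenotype spread
  expect_lt(sd(pred), 0.2 * sd(y))
  expect_lt(abs(mean(pred) - mean(y[1:60])), 0.2 * sd(y))
  expect_error(gblup_predict(K, y[1:60], 1:60, 55:80), "overlap")
})

test_that("gblup recovers a duplicated sample's heritable phenotype", {
  g <- simulate_genotypes(100, 500, seed = 4)
  g$dosages[100, ] <- g$dosages[1, ]  # test sample == training sample 1
  sim <- simulate_phenotype(g, 40, 1, seed = 5)
  y <- sim$phenotypes$value
  K <- compute_kinship(g$dosages)
  pred <- gblup_predict(K, y[1:99], 1:99, 100L)
  expect_lt(abs(pred - y[1]), 0.1 * sd(y))
})

test_that("hold-out prediction is reproducible and model-count consistent", {
  g <- simulate_genotypes(60, 100, seed = 6)
  sim <- simulate_phenotype(g, 10, 0.7, seed = 7)
  y <- sim$phenotypes$value
  cfg <- ml_config("random_forest", n_trees = 50)
  a <- gp_holdout(g, y, "random_forest", n_holdout = 15, n_models = 1,
                  cfg = cfg, seed = 11)
  b <- gp_holdout(g, y, "random_forest", n_holdout = 15, n_models = 1,
                  cfg = cfg, seed = 11)
  expect_identical(a$predicted, b$predicted)
  # n_models = 1 equals a single direct train/predict with the same seed
  set.seed(11)
  holdout <- sort(sample.int(60, 15))
  train <- setdiff(1:60, holdout)
  seed1 <- sample.int(.Machine$integer.max, 1)
  fitted <- gwaskit:::fit_learner(mean_impute(g)[train, ], y[train], cfg,
                                  seed = seed1)
  direct <- fitted$predict(mean_impute(g)[holdout, ])
  expect_equal(a$predicted, unname(direct), tolerance = 1e-12)
  expect_equal(attr(a, "holdout"), holdout)
})

test_that("perfect predictions give r = 1 and degenerate agreement limits", {
  g <- simulate_genotypes(40, 50, seed = 8)
  sim <- simulate_phenotype(g, 5, 1, seed = 9)
  y <- sim$phenotypes$value
  # fabricate a gp_result-like check through the public summaries
  r <- pearson_correlation(y, y)
  ba <- bland_altman(y, y)
  expect_equal(r, 1.0)
  expect_equal(c(ba$bias, ba$loa_low, ba$loa_high), c(0, 0, 0))
})

test_that("a constant observed vector yields NA r but a Bland-Altman report", {
  g <- simulate_genotypes(40, 50, seed = 10)
  pred <- gp_holdout(g, rep(0, 40), "ridge", n_holdout = 5, n_models = 1,
                     seed = 2)
  expect_true(is.na(attr(pred, "pearson_r")))
  ba <- attr(pred, "bland_altman")
  expect_true(is.finite(ba$bias) && is.finite(ba$loa_high))
})

test_that("gblup collapses n_models with a note", {
  g <- simulate_genotypes(50, 80, seed = 11)
  sim <- simulate_phenotype(g, 10, 0.6, seed = 12)
  pred <- gp_holdout(g, sim$phenotypes$value, "gblup", n_holdout = 10,
                     n_models = 10, seed = 3)
  expect_equal(ncol(attr(pred, "per_model")), 1)
  expect_match(attr(pred, "note"), "deterministic")
  expect_error(gp_holdout(g, sim$phenotypes$value, "gblup",
                          n_holdout = 49), "n_holdout")
})

test_that("ridge prediction is near-perfect for a noiseless additive trait", {
  # with more samples than markers the GCV ridge approaches the OLS limit,
  # which interpolates a noiseless 5-marker trait exactly
  g <- simulate_genotypes(500, 300, seed = 13)
  sim <- simulate_phenotype(g, 5, 1, seed = 14)
  pred <- gp_holdout(g, sim$phenotypes$value, "ridge", n_holdout = 30,
                     n_models = 1, seed = 4)
  expect_gt(attr(pred, "pearson_r"), 0.9)
})
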