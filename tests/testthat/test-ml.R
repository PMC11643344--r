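small_cfg <- function(learner, n_iterations = 3, seed = 1) {
  ml_config(learner, n_iterations = n_iterations, n_trees = 50,
            max_depth = 3, seed = seed)
}

test_that("a constant trait yields all-zero importances for every learner", {
  g <- simulate_genotypes(40, 30, seed = 1)
  y <- rep(3, 40)
  for (learner in c("random_forest", "gradient_boosted_trees", "ridge")) {
    imp <- ml_gwas(g, y, small_cfg(learner))
    expect_equal(imp$score, rep(0, 30), tolerance = 1e-12)
  }
})

test_that("mean aggregation equals the summed score over iterations", {
  g <- simulate_genotypes(60, 40, seed = 2)
  sim <- simulate_phenotype(g, 3, 0.5, seed = 3)
  y <- sim$phenotypes$value
  cfg_sum <- small_cfg("random_forest", n_iterations = 4, seed = 9)
  cfg_mean <- cfg_sum; cfg_mean$aggregate <- "mean"
  a <- ml_gwas(g, y, cfg_sum)
  b <- ml_gwas(g, y, cfg_mean)
  expect_equal(b$score, a$score / 4, tolerance = 1e-12)
})

test_that("identical seed and config reproduce the result exactly", {
  g <- simulate_genotypes(50, 40, seed = 4)
  sim <- simulate_phenotype(g, 3, 0.5, seed = 5)
  y <- sim$phenotypes$value
  for (learner in c("random_forest", "gradient_boosted_trees", "ridge")) {
    a <- ml_gwas(g, y, small_cfg(learner, seed = 11))
    b <- ml_gwas(g, y, small_cfg(learner, seed = 11))
    expect_identical(a$score, b$score)
    expect_identical(attr(a, "r2"), attr(b, "r2"))
  }
})

test_that("summed scores are invariant to iteration order", {
  g <- simulate_genotypes(50, 40, seed = 6)
  sim <- simulate_phenotype(g, 3, 0.5, seed = 7)
  y <- sim$phenotypes$value
  seeds <- c(101L, 202L, 303L)
  a <- ml_gwas(g, y, small_cfg("random_forest"), iteration_seeds = seeds)
  b <- ml_gwas(g, y, small_cfg("random_forest"),
               iteration_seeds = rev(seeds))
  expect_equal(sort(attr(a, "r2")), sort(attr(b, "r2")))
  expect_equal(a$score, b$score, tolerance = 1e-12)
})

test_that("tree importances are non-negative; boosting gains sum to <= 1", {
  g <- simulate_genotypes(60, 50, seed = 8)
  sim <- simulate_phenotype(g, 5, 0.6, seed = 9)
  y <- sim$phenotypes$value
  rf <- ml_gwas(g, y, small_cfg("random_forest", n_iterations = 1))
  expect_true(all(rf$score >= 0))
  xgb <- ml_gwas(g, y, small_cfg("gradient_boosted_trees",
                                 n_iterations = 1))
  expect_true(all(xgb$score >= 0))
  expect_lte(sum(xgb$score), 1 + 1e-8)  # normalized native gain, 1 iteration
})

test_that("ridge gives duplicated variants identical scores", {
  g <- simulate_genotypes(50, 20, seed = 10)
  g$dosages[, 2] <- g$dosages[, 1]
  sim <- simulate_phenotype(g, 4, 0.8, seed = 11)
  imp <- ridge_gwas_scores(g, sim$phenotypes$value,
                           small_cfg("ridge", n_iterations = 2))
  expect_equal(imp$score[1], imp$score[2], tolerance = 1e-8)
})

test_that("ridge scores peak at a strong linear signal and vanish at zero y", {
  top_hits <- 0
  for (seed in 1:10) {
    g <- simulate_genotypes(80, 60, seed = 20 + seed)
    z <- scale(mean_impute(g))
    y <- drop(z[, 7]) + rnorm(80, sd = 0.2)
    imp <- ridge_gwas_scores(g, y, small_cfg("ridge", n_iterations = 2,
                                             seed = seed))
    if (which.max(imp$score) == 7) top_hits <- top_hits + 1
  }
  expect_gte(top_hits, 9)
  g0 <- simulate_genotypes(40, 20, seed = 31)
  imp0 <- ridge_gwas_scores(g0, rep(0, 40), small_cfg("ridge"))
  expect_equal(imp0$score, rep(0, 20))
})

test_that("tree learners rank a strong designed marker first", {
  # one causal SNP explaining 30% of variance; desk-scale replicate count
  hits <- c(random_forest = 0, gradient_boosted_trees = 0)
  for (seed in 1:5) {
    g <- simulate_genotypes(150, 200, seed = 40 + seed)
    sim <- simulate_phenotype(g, 1, 0.3, seed = 50 + seed)
    y <- sim$phenotypes$value
    for (learner in names(hits)) {
      imp <- ml_gwas(g, y, small_cfg(learner, n_iterations = 5,
                                     seed = seed))
      if (which.max(imp$score) == sim$truth$causal_indices)
        hits[learner] <- hits[learner] + 1
    }
  }
  expect_gte(hits[["random_forest"]], 4)
  expect_gte(hits[["gradient_boosted_trees"]], 4)
})

test_that("split bookkeeping rejects impossible configurations", {
  g <- simulate_genotypes(20, 10, seed = 60)
  y <- rnorm(20)
  expect_error(ml_gwas(g$dosages[1:5, ], y[1:5], small_cfg("ridge")),
               "at least 10")
  expect_error(ml_config("ridge", n_iterations = 0), "n_iterations")
  expect_error(ml_config("ridge", train_fraction = 1), "train_fraction")
})
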