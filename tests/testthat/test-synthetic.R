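# Hudson-style Fst estimator, independent of the generator's internals
hudson_fst <- function(d, pop) {
  p1 <- colMeans(d[pop == 1, , drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(d[pop == 2, , drop = FALSE], na.rm = TRUE) / 2
  n1 <- sum(pop == 1); n2 <- sum(pop == 2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

test_that("the generator honours its dimensional contract", {
  g <- simulate_genotypes(25, 40, seed = 1)
  expect_equal(dim(g), c(25, 40))
  expect_equal(sum(is.na(g$dosages)), 0)
  expect_equal(length(g$population), 25)
  g2 <- simulate_genotypes(30, 50, missing_rate = 0.1, seed = 2)
  expect_gt(sum(is.na(g2$dosages)), 0)
  expect_lt(mean(is.na(g2$dosages)), 0.2)
})

test_that("the full validation-scale shape request is honoured", {
  g <- simulate_genotypes(2000, 90010, seed = 3)
  expect_equal(dim(g), c(2000, 90010))
  expect_equal(nrow(g$variants), 90010)
  rm(g); invisible(gc())
})

test_that("simulated MAFs respect the requested ancestral range", {
  g <- simulate_genotypes(400, 300, maf_range = c(0.2, 0.4), seed = 4)
  qc <- compute_variant_qc(g)
  # binomial sampling noise around the ancestral frequency at n = 400:
  # 4 sd of a binomial proportion is < 0.05 here
  expect_true(all(qc$maf > 0.2 - 0.05))
  f <- colMeans(g$dosages) / 2
  expect_true(all(pmin(f, 1 - f) < 0.4 + 0.05))
})

test_that("two-population draws show the requested differentiation", {
  fsts <- vapply(1:10, function(seed) {
    g <- simulate_genotypes(200, 2000, n_pops = 2, fst = 0.1, seed = seed)
    hudson_fst(g$dosages, g$population)
  }, numeric(1))
  expect_gt(mean(fsts), 0.05)
  expect_lt(mean(fsts), 0.15)
})

test_that("identical seeds reproduce the genotypes exactly", {
  a <- simulate_genotypes(20, 30, n_pops = 2, fst = 0.05,
                          missing_rate = 0.05, seed = 9)
  b <- simulate_genotypes(20, 30, n_pops = 2, fst = 0.05,
                          missing_rate = 0.05, seed = 9)
  expect_identical(a$dosages, b$dosages)
})

test_that("the phenotype variance split is exact at the sample level", {
  g <- simulate_genotypes(100, 200, seed = 5)
  for (h2 in c(0, 0.3, 0.5, 0.8, 1)) {
    sim <- simulate_phenotype(g, 10, h2, seed = 6)
    y <- sim$phenotypes$value
    gval <- sqrt(h2) * sim$truth$genetic_value
    expect_equal(var(gval) / var(y), h2, tolerance = 1e-10)
  }
  # h2 = 1: the phenotype is an exact function of the causal dosages
  sim1 <- simulate_phenotype(g, 10, 1, seed = 7)
  expect_equal(sim1$phenotypes$value, unname(sim1$truth$genetic_value),
               tolerance = 1e-12)
  # h2 = 0: phenotype decorrelated from the genetic value
  rs <- vapply(1:10, function(s) {
    g5 <- simulate_genotypes(500, 100, seed = 100 + s)
    sm <- simulate_phenotype(g5, 10, 0, seed = 200 + s)
    abs(cor(sm$phenotypes$value, sm$truth$genetic_value))
  }, numeric(1))
  expect_lt(median(rs), 0.15)
  expect_error(simulate_phenotype(g, 0, 0.5), "contradictory")
})

test_that("qualitative traits are balanced 0/1 classes", {
  for (n in c(100, 101)) {
    g <- simulate_genotypes(n, 50, seed = n)
    sim <- simulate_phenotype(g, 5, 0.6, trait_type = "qualitative",
                              seed = 8)
    y <- sim$phenotypes$value
    expect_true(all(y %in% c(0, 1)))
    expect_lte(abs(sum(y == 0) - sum(y == 1)), 1)
  }
})

test_that("fixture bundles are deterministic and cross-format consistent", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  f1 <- write_fixture_set(d1, "single_causal", seed = 5)
  f2 <- write_fixture_set(d2, "single_causal", seed = 5)
  for (k in names(f1)) {
    expect_identical(readBin(f1[[k]], "raw", file.size(f1[[k]])),
                     readBin(f2[[k]], "raw", file.size(f2[[k]])),
                     label = k)
  }
  g_vcf <- read_vcf(f1$vcf)
  g_bed <- read_plink(file.path(d1, "single_causal"))
  expect_identical(unname(g_vcf$dosages), unname(g_bed$dosages))
  expect_equal(g_vcf$variants$a1, g_bed$variants$a1)
})

test_that("the hand-specified toy bundle has its documented statistics", {
  d <- file.path(tempdir(), "toy")
  unlink(d, recursive = TRUE)
  write_fixture_set(d, "toy4x3", seed = 1)
  g <- read_vcf(file.path(d, "toy4x3.vcf"))
  qc <- compute_variant_qc(g)
  expect_equal(qc$maf, c(0.375, 0.5, 0))
  expect_equal(qc$missing_rate, c(0, 0.25, 0))
  truth <- jsonlite::read_json(file.path(d, "toy4x3_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$maf, qc$maf)
  expect_error(write_fixture_set(tempdir(), "nope"), "arg")
})
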