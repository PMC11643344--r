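#' Configuration for machine-learning GWAS and prediction
#'
#' Defaults follow the validated protocol: 10 iterations of randomized
#' 70/30 train/test splits; tree learners with 200 trees of maximum depth
#' 3; per-SNP importances summed across iterations (mean and median are
#' available as alternative scoring approaches).
#'
#' @param learner one of `"random_forest"`, `"gradient_boosted_trees"`,
#'   `"ridge"`.
#' @param n_iterations number of randomized splits (default 10).
#' @param train_fraction fraction of samples in each training split
#'   (default 0.7).
#' @param n_trees trees per model for the tree learners (default 200).
#' @param max_depth maximum tree depth (default 3).
#' @param aggregate `"sum"` (default), `"mean"` or `"median"` across
#'   iterations.
#' @param seed integer master seed.
#' @return an `ml_config` list.
#' @export
ml_config <- function(learner = c("random_forest", "gradient_boosted_trees",
                                  "ridge"),
                      n_iterations = 10L, train_fraction = 0.7,
                      n_trees = 200L, max_depth = 3L,
                      aggregate = c("sum", "mean", "median"), seed = 1L) {
  learner <- match.arg(learner)
  aggregate <- match.arg(aggregate)
  stopifnot(n_iterations >= 1, train_fraction > 0, train_fraction < 1,
            n_trees >= 1, max_depth >= 1)
  structure(list(learner = learner, n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), aggregate = aggregate,
                 seed = as.integer(seed)),
            class = "ml_config")
}

#' Machine-learning association scan by repeated-split importance
#'
#' For each of `n_iterations` seeded randomized splits, a learner is
#' trained on `round(train_fraction * n)` samples and its per-variant
#' feature-importance vector is recorded together with the R-squared on
#' the held-out split; the final per-SNP score aggregates the iteration
#' vectors elementwise (`sum` by default). Tree learners use their native
#' importances (impurity decrease for random forest, total gain for
#' gradient boosting); ridge uses the absolute coefficient on per-variant
#' standardized inputs. Importances are not re-normalized before
#' aggregation.
#'
#' @param g_imputed [geno_data] or dosage matrix (mean-imputed if needed).
#' @param y trait vector, finite.
#' @param cfg an [ml_config()].
#' @param iteration_seeds optional integer vector of per-iteration seeds
#'   (length `n_iterations`); derived from `cfg$seed` by default.
#' @return an `importance_result` data.frame (`chrom`, `pos`,
#'   `variant_id`, `score`) with attributes `r2` (per-iteration test
#'   R-squared) and `config`.
#' @export
ml_gwas <- function(g_imputed, y, cfg = ml_config(), iteration_seeds = NULL) {
  d <- impute_if_needed(g_imputed)
  vt <- variant_frame(g_imputed, ncol(d))
  y <- as.numeric(y)
  n <- nrow(d)
  stopifnot(length(y) == n)
  if (any(!is.finite(y))) stop("trait vector must be finite", call. = FALSE)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  n_train <- round(cfg$train_fraction * n)
  if (n_train < 2) stop("training split smaller than 2 samples", call. = FALSE)
  if (is.null(colnames(d))) colnames(d) <- paste0("v", seq_len(ncol(d)))

  if (is.null(iteration_seeds)) {
    set.seed(cfg$seed)
    iteration_seeds <- sample.int(.Machine$integer.max, cfg$n_iterations)
  }
  stopifnot(length(iteration_seeds) == cfg$n_iterations)

  m <- ncol(d)
  imp <- matrix(0, nrow = m, ncol = cfg$n_iterations)
  r2 <- numeric(cfg$n_iterations)
  for (t in seq_len(cfg$n_iterations)) {
    set.seed(iteration_seeds[t])
    train <- sample.int(n, n_train)
    test <- setdiff(seq_len(n), train)
    fitted <- fit_learner(d[train, , drop = FALSE], y[train], cfg,
                          seed = iteration_seeds[t])
    imp[, t] <- fitted$importance
    pred <- fitted$predict(d[test, , drop = FALSE])
    ss_tot <- sum((y[test] - mean(y[test]))^2)
    r2[t] <- if (ss_tot > 0) 1 - sum((y[test] - pred)^2) / ss_tot else NA_real_
  }
  score <- switch(cfg$aggregate,
                  sum = rowSums(imp),
                  mean = rowMeans(imp),
                  median = apply(imp, 1, stats::median))
  out <- data.frame(chrom = vt$chrom, pos = vt$pos, variant_id = vt$id,
                    score = score, stringsAsFactors = FALSE)
  structure(out, r2 = r2, config = cfg, iteration_seeds = iteration_seeds,
            method = cfg$learner,
            class = c("importance_result", "data.frame"))
}

#' Ridge-regression association scores
#'
#' Specialization of [ml_gwas()] with `learner = "ridge"`: on each train
#' split the penalty is chosen by generalized cross-validation over a
#' log-spaced grid on `[1e-3, 1e3]` and the importance is the absolute
#' standardized coefficient.
#'
#' @inheritParams ml_gwas
#' @export
ridge_gwas_scores <- function(g_imputed, y, cfg = ml_config("ridge"),
                              iteration_seeds = NULL) {
  cfg$learner <- "ridge"
  ml_gwas(g_imputed, y, cfg, iteration_seeds)
}

#' @export
print.importance_result <- function(x, n_top = 6, ...) {
  cfg <- attr(x, "config")
  cat("ML importance scan (", cfg$learner, "): ", nrow(x), " variants, ",
      cfg$n_iterations, " x ", round(100 * cfg$train_fraction),
      "/", round(100 * (1 - cfg$train_fraction)),
      " splits, aggregate = ", cfg$aggregate, "\n", sep = "")
  cat("  test R^2 per iteration: ",
      paste(format(attr(x, "r2"), digits = 2), collapse = " "), "\n", sep = "")
  cat("Top markers:\n")
  print.data.frame(utils::head(x[order(-x$score), ], n_top),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

# ---- learners -------------------------------------------------------------

# Fit one learner on a training block; returns the full-length importance
# vector and a prediction closure. All learners are forced single-threaded
# and seeded so results are reproducible bit for bit.
fit_learner <- function(x_train, y_train, cfg, seed) {
  switch(cfg$learner,
         random_forest = fit_rf(x_train, y_train, cfg, seed),
         gradient_boosted_trees = fit_gbt(x_train, y_train, cfg, seed),
         ridge = fit_ridge_gcv(x_train, y_train))
}

fit_rf <- function(x, y, cfg, seed) {
  fit <- ranger::ranger(x = x, y = y, num.trees = cfg$n_trees,
                        max.depth = cfg$max_depth, importance = "impurity",
                        num.threads = 1, seed = seed,
                        respect.unordered.factors = "ignore")
  imp <- fit$variable.importance[colnames(x)]
  imp[is.na(imp)] <- 0
  list(importance = unname(imp),
       predict = function(newx)
         stats::predict(fit, data = newx, num.threads = 1)$predictions)
}

fit_gbt <- function(x, y, cfg, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  params <- list(max_depth = cfg$max_depth, objective = "reg:squarederror",
                 nthread = 1, seed = seed)
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = cfg$n_trees, verbose = 0)
  imp_tab <- tryCatch(xgboost::xgb.importance(model = bst),
                      error = function(e) NULL)
  imp <- stats::setNames(numeric(ncol(x)), colnames(x))
  if (!is.null(imp_tab) && nrow(imp_tab) > 0)
    imp[imp_tab$Feature] <- imp_tab$Gain
  list(importance = unname(imp),
       predict = function(newx)
         stats::predict(bst, xgboost::xgb.DMatrix(newx, nthread = 1)))
}

# Ridge regression on standardized predictors with GCV-selected penalty.
# Solved through the SVD of the standardized training matrix, so the
# high-dimensional (m >> n) case costs O(n^2 m).
fit_ridge_gcv <- function(x, y, lambda_grid = 10^seq(-3, 3, length.out = 13)) {
  n <- nrow(x)
  mu_x <- colMeans(x)
  sd_x <- sqrt(colMeans(x^2) - mu_x^2) * sqrt(n / max(n - 1, 1))
  ok <- sd_x > 1e-12
  xs <- sweep(x[, ok, drop = FALSE], 2, mu_x[ok], "-")
  xs <- sweep(xs, 2, sd_x[ok], "/")
  mu_y <- mean(y)
  yc <- y - mu_y

  coefs <- numeric(ncol(x))
  if (any(ok) && stats::var(y) > 0) {
    sv <- svd(xs)
    d2 <- sv$d^2
    uty <- drop(crossprod(sv$u, yc))
    gcv <- vapply(lambda_grid, function(lam) {
      shrink <- d2 / (d2 + lam)
      fit <- sv$u %*% (shrink * uty)
      rss <- sum((yc - fit)^2)
      df <- sum(shrink) + 1  # +1 for the (implicit) intercept
      n * rss / (n - df)^2
    }, numeric(1))
    lam <- lambda_grid[which.min(gcv)]
    b <- sv$v %*% ((sv$d / (sv$d^2 + lam)) * uty)
    coefs[ok] <- drop(b)
  }
  list(importance = abs(coefs),
       coef = coefs,
       predict = function(newx) {
         z <- sweep(newx[, ok, drop = FALSE], 2, mu_x[ok], "-")
         z <- sweep(z, 2, sd_x[ok], "/")
         mu_y + drop(z %*% coefs[ok])
       })
}

# ---- genomic prediction ---------------------------------------------------

#' Hold-out genomic prediction
#'
#' Draws one seeded random hold-out set, trains `n_models` models on the
#' remaining samples (differing only by learner seed), predicts the
#' held-out phenotypes as the per-sample mean across models, and summarizes
#' agreement with Pearson correlation and Bland-Altman statistics. GBLUP is
#' deterministic, so `n_models` collapses to a single model (noted in the
#' result).
#'
#' @param g_imputed [geno_data] or dosage matrix (mean-imputed if needed).
#' @param y trait vector, finite.
#' @param method `"gblup"`, `"random_forest"`, `"gradient_boosted_trees"`
#'   or `"ridge"`.
#' @param n_holdout held-out sample count (default 30).
#' @param n_models models trained on the remaining pool (default 10).
#' @param cfg an [ml_config()] supplying tree/split settings.
#' @param seed seed for the hold-out draw and model seeds.
#' @param K optional precomputed `kinship` matrix (gblup only; computed
#'   from the genotypes when absent).
#' @return a `gp_result`: data.frame of `iid`, `observed`, `predicted`,
#'   with attributes `pearson_r`, `bland_altman`, `per_model` (matrix of
#'   per-model predictions), `holdout` (indices), `method`, `note`.
#' @export
gp_holdout <- function(g_imputed, y, method = c("gblup", "random_forest",
                                                "gradient_boosted_trees",
                                                "ridge"),
                       n_holdout = 30L, n_models = 10L, cfg = ml_config(),
                       seed = 1L, K = NULL) {
  method <- match.arg(method)
  d <- impute_if_needed(g_imputed)
  y <- as.numeric(y)
  n <- nrow(d)
  stopifnot(length(y) == n)
  if (any(!is.finite(y))) stop("trait vector must be finite", call. = FALSE)
  if (n_holdout >= n - 2)
    stop("n_holdout must be smaller than n - 2", call. = FALSE)
  if (is.null(colnames(d))) colnames(d) <- paste0("v", seq_len(ncol(d)))

  set.seed(seed)
  holdout <- sort(sample.int(n, n_holdout))
  train <- setdiff(seq_len(n), holdout)
  note <- NULL

  if (method == "gblup") {
    if (n_models > 1)
      note <- "gblup is deterministic; n_models collapsed to 1"
    n_models <- 1L
    if (is.null(K)) K <- compute_kinship(d)
    preds <- matrix(gblup_predict(K, y[train], train, holdout), ncol = 1)
  } else {
    model_seeds <- sample.int(.Machine$integer.max, n_models)
    preds <- vapply(seq_len(n_models), function(i) {
      cfg_i <- cfg
      cfg_i$learner <- method
      fitted <- fit_learner(d[train, , drop = FALSE], y[train], cfg_i,
                            seed = model_seeds[i])
      fitted$predict(d[holdout, , drop = FALSE])
    }, numeric(n_holdout))
    preds <- matrix(preds, nrow = n_holdout)
  }
  predicted <- rowMeans(preds)
  observed <- y[holdout]
  r <- tryCatch(pearson_correlation(predicted, observed),
                error = function(e) NA_real_)
  ba <- bland_altman(predicted, observed)
  iid <- rownames(d)[holdout] %||% as.character(holdout)
  out <- data.frame(iid = iid, observed = observed, predicted = predicted,
                    stringsAsFactors = FALSE)
  structure(out, pearson_r = r, bland_altman = ba, per_model = preds,
            holdout = holdout, method = method, note = note, seed = seed,
            class = c("gp_result", "data.frame"))
}

#' @export
print.gp_result <- function(x, ...) {
  ba <- attr(x, "bland_altman")
  cat("Genomic prediction (", attr(x, "method"), "): ", nrow(x),
      " held-out samples\n", sep = "")
  cat("  Pearson r = ", format(attr(x, "pearson_r"), digits = 4), "\n",
      sep = "")
  cat("  Bland-Altman bias = ", format(ba$bias, digits = 4),
      ", limits of agreement [", format(ba$loa_low, digits = 4), ", ",
      format(ba$loa_high, digits = 4), "]\n", sep = "")
  if (!is.null(attr(x, "note"))) cat("  note: ", attr(x, "note"), "\n",
                                     sep = "")
  invisible(x)
}

#' GBLUP predictions for a set of test samples
#'
#' Estimates variance components on the training block with
#' [fit_lmm_null()], then predicts test genetic values as
#' `ghat_test = K[test, train] (K[train, train] + delta I)^-1
#' (y_train - mu)` and returns `mu + ghat_test`.
#'
#' @param K `kinship` matrix covering all samples.
#' @param y_train phenotypes of the training samples.
#' @param train_idx,test_idx disjoint index sets into `K`.
#' @return numeric predictions for `test_idx`.
#' @export
gblup_predict <- function(K, y_train, train_idx, test_idx) {
  if (length(intersect(train_idx, test_idx)))
    stop("train and test index sets overlap", call. = FALSE)
  Ktt <- unclass(K)[train_idx, train_idx, drop = FALSE]
  fit <- fit_lmm_null(y_train, Ktt)
  mu <- fit$beta[1]
  delta <- min(fit$delta, 1e8)
  A <- Ktt + diag(delta, nrow(Ktt))
  rhs <- tryCatch(solve(A, y_train - mu), error = function(e)
    stop("kinship system is numerically singular: ", conditionMessage(e),
         call. = FALSE))
  drop(unclass(K)[test_idx, train_idx, drop = FALSE] %*% rhs) + mu
}

#' Pearson product-moment correlation
#'
#' @param a,b numeric vectors of equal length (at least 3), both
#'   non-constant.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  stats::cor(a, b)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `predicted - observed`; `bias` is their mean and the
#' limits of agreement are `bias +/- 1.96 * sd(differences)` (unbiased sd).
#'
#' @param predicted,observed numeric vectors of equal length (at least 2).
#' @return list with `bias`, `sd_diff`, `loa_low`, `loa_high` and `points`
#'   (data.frame of per-pair `mean` and `difference`).
#' @export
bland_altman <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 2)
  diffs <- predicted - observed
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  list(bias = bias, sd_diff = sd_diff,
       loa_low = bias - 1.96 * sd_diff,
       loa_high = bias + 1.96 * sd_diff,
       points = data.frame(mean = (predicted + observed) / 2,
                           difference = diffs))
}

#' Export an importance or prediction result as TSV with a JSON sidecar
#' @param x an `importance_result` or `gp_result`.
#' @param path output TSV; the config echo goes to `paste0(path, ".json")`.
#' @export
write_ml_result <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list()
  if (inherits(x, "importance_result")) {
    side$config <- unclass(attr(x, "config"))
    side$r2 <- attr(x, "r2")
  } else if (inherits(x, "gp_result")) {
    ba <- attr(x, "bland_altman")
    side <- list(method = attr(x, "method"),
                 pearson_r = attr(x, "pearson_r"),
                 bland_altman = ba[c("bias", "sd_diff", "loa_low",
                                     "loa_high")],
                 seed = attr(x, "seed"))
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
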