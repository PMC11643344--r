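#' Per-SNP ordinary linear regression GWAS
#'
#' Fits `y = b0 + b1 * g + e` independently for every variant, without any
#' relatedness correction. Effects are per copy of the A1 allele; p-values
#' are two-sided t-tests with `n - 2` degrees of freedom. Zero-variance
#' variants are reported with `beta = 0`, `se = NA`, `p = 1` so the output
#' stays row-aligned with the input variants.
#'
#' @param g_imputed a [geno_data] object or dosage matrix; missing calls
#'   are mean-imputed automatically.
#' @param y numeric trait vector, one value per sample, all finite.
#' @return an `assoc_result` data.frame: `chrom`, `pos`, `variant_id`,
#'   `beta`, `se`, `p_value`; method metadata in attributes.
#' @export
gwas_linreg <- function(g_imputed, y) {
  d <- impute_if_needed(g_imputed)
  vt <- variant_frame(g_imputed, ncol(d))
  y <- as.numeric(y)
  stopifnot(nrow(d) == length(y))
  if (any(!is.finite(y))) stop("trait vector must be finite; drop masked ",
                               "samples first", call. = FALSE)
  n <- length(y)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::var(y) == 0) stop("trait is constant; association undefined",
                               call. = FALSE)
  yc <- y - mean(y)
  gc_ <- sweep(d, 2, colMeans(d), "-")
  sxx <- colSums(gc_^2)
  sxy <- colSums(gc_ * yc)
  syy <- sum(yc^2)
  ok <- sxx > 0
  beta <- ifelse(ok, sxy / sxx, 0)
  ssr <- pmax(syy - beta * sxy, 0)
  sigma2 <- ssr / (n - 2)
  se <- ifelse(ok, sqrt(sigma2 / sxx), NA_real_)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!ok] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  assoc_result(vt, beta, se, p, method = "lm", n = n)
}

#' Fit the null linear mixed model by spectral decomposition
#'
#' Fits `y ~ N(X beta, sigma_g^2 K + sigma_e^2 I)` in the fast single-
#' decomposition style: the kinship matrix is eigendecomposed once
#' (`K = U S U'`), the data are rotated (`y~ = U'y`, `X~ = U'X`) so the
#' covariance is diagonal with weights `S_i + delta` where
#' `delta = sigma_e^2 / sigma_g^2`, and for each candidate `delta` the
#' fixed effects and `sigma_g^2` are profiled analytically. `delta` is
#' optimized over a 100-point log-spaced grid on `[1e-5, 1e5]` followed by
#' bracketed refinement between the best grid neighbours. REML is the
#' default criterion.
#'
#' @param y numeric trait vector, finite, length n.
#' @param K `kinship` matrix over the same n samples.
#' @param X fixed-effect design matrix including the intercept; default an
#'   intercept-only column.
#' @param method `"reml"` (default) or `"ml"`.
#' @return an object of class `lmm_fit` with elements `sigma_g2`,
#'   `sigma_e2`, `delta`, `h2` (`= 1 / (1 + delta)`), `loglik`, `beta`
#'   (GLS fixed effects), the cached decomposition (`U`, `S`, `yr`, `Xr`)
#'   and the profiled grid (`profile`).
#' @export
fit_lmm_null <- function(y, K, X = NULL, method = c("reml", "ml")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stop("trait vector must be finite", call. = FALSE)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  q <- ncol(X)
  if (qr(X)$rank < q) stop("covariate matrix X is rank deficient",
                           call. = FALSE)
  if (n < q + 2) stop("need at least rank(X) + 2 samples", call. = FALSE)

  eig <- eigen(unclass(K), symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values), 1))
    stop("kinship matrix is not positive semi-definite within tolerance",
         call. = FALSE)
  S <- pmax(eig$values, 0)
  U <- eig$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)

  prof <- function(delta) reml_profile(yr, Xr, S, delta, method)
  grid <- 10^seq(-5, 5, length.out = 100)
  ll <- vapply(grid, function(d) prof(d)$loglik, numeric(1))
  i <- which.max(ll)
  lo <- log10(grid[max(1L, i - 1L)])
  hi <- log10(grid[min(length(grid), i + 1L)])
  opt <- stats::optimize(function(ld) prof(10^ld)$loglik,
                         interval = c(lo, hi), maximum = TRUE)
  delta <- if (opt$objective > ll[i]) 10^opt$maximum else grid[i]
  best <- prof(delta)

  structure(list(sigma_g2 = best$sigma_g2,
                 sigma_e2 = delta * best$sigma_g2,
                 delta = delta,
                 h2 = 1 / (1 + delta),
                 loglik = best$loglik,
                 beta = drop(best$beta),
                 method = method,
                 n = n, q = q,
                 U = U, S = S, yr = yr, Xr = Xr, X = X,
                 profile = list(delta = grid, loglik = ll)),
            class = "lmm_fit")
}

# Profiled (RE)ML pieces at a fixed variance ratio delta, in rotated space.
reml_profile <- function(yr, Xr, S, delta, method) {
  n <- length(yr)
  q <- ncol(Xr)
  w <- 1 / (S + delta)
  XtWX <- crossprod(Xr, Xr * w)
  beta <- solve(XtWX, crossprod(Xr, yr * w))
  r <- yr - drop(Xr %*% beta)
  rss <- sum(w * r^2)
  if (method == "reml") {
    df <- n - q
    sg2 <- rss / df
    if (sg2 < 1e-300) return(list(loglik = Inf, sigma_g2 = 0, beta = beta))
    ll <- -0.5 * (df * log(2 * pi * sg2) + sum(log(S + delta)) + df -
                    determinant(crossprod(Xr))$modulus +
                    determinant(XtWX)$modulus)
  } else {
    sg2 <- rss / n
    if (sg2 < 1e-300) return(list(loglik = Inf, sigma_g2 = 0, beta = beta))
    ll <- -0.5 * (n * log(2 * pi * sg2) + sum(log(S + delta)) + n)
  }
  list(loglik = as.numeric(ll), sigma_g2 = sg2, beta = beta)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model null fit (", toupper(x$method), ")\n", sep = "")
  cat("  n = ", x$n, ", fixed effects = ", x$q, "\n", sep = "")
  cat("  sigma_g^2 = ", format(x$sigma_g2, digits = 4),
      "  sigma_e^2 = ", format(x$sigma_e2, digits = 4), "\n", sep = "")
  cat("  delta = ", format(x$delta, digits = 4),
      "  h2 = ", format(x$h2, digits = 4), "\n", sep = "")
  cat("  log-likelihood = ", format(x$loglik, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
summary.lmm_fit <- function(object, ...) {
  out <- object[c("sigma_g2", "sigma_e2", "delta", "h2", "loglik",
                  "method", "n", "q")]
  out$beta <- object$beta
  class(out) <- "summary.lmm_fit"
  out
}

#' @export
print.summary.lmm_fit <- function(x, ...) {
  cat("Variance components (", toupper(x$method), "):\n", sep = "")
  print(unlist(x[c("sigma_g2", "sigma_e2", "delta", "h2")]))
  cat("Fixed effects:\n")
  print(x$beta)
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$beta

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$q + 2, class = "logLik")
}

#' Mixed-model association scan
#'
#' Tests each variant as a fixed effect in the linear mixed model, with the
#' variance ratio `delta` held at the null-model estimate (the fast
#' approximation) or re-optimized per SNP. Effects and standard errors are
#' computed by generalized least squares in the rotated (eigen) space;
#' p-values are two-sided Wald chi-square tests with 1 df. Zero-variance
#' variants get `beta = 0`, `p = 1`.
#'
#' @param g_imputed [geno_data] or dosage matrix (mean-imputed if needed).
#' @param y trait vector.
#' @param K `kinship` matrix (ignored when `fit` is supplied).
#' @param fit optional [fit_lmm_null()] result to reuse.
#' @param refit_delta_per_snp re-optimize `delta` for every SNP (slower,
#'   never a worse per-SNP likelihood).
#' @return an `assoc_result` data.frame with columns `chrom`, `pos`,
#'   `variant_id`, `beta`, `se`, `p_value`, `loglik`.
#' @export
gwas_lmm <- function(g_imputed, y, K = NULL, fit = NULL,
                     refit_delta_per_snp = FALSE) {
  d <- impute_if_needed(g_imputed)
  vt <- variant_frame(g_imputed, ncol(d))
  y <- as.numeric(y)
  if (is.null(fit)) {
    if (is.null(K)) stop("supply K or a null-model fit", call. = FALSE)
    fit <- fit_lmm_null(y, K)
  }
  n <- fit$n
  q <- fit$q
  stopifnot(nrow(d) == n, length(y) == n)
  S <- fit$S
  Xr <- fit$Xr
  yr <- fit$yr
  Gr <- crossprod(fit$U, d)
  gvar <- colMeans(d^2) - colMeans(d)^2
  ok <- gvar > 1e-12

  if (!refit_delta_per_snp) {
    res <- lmm_scan_fixed_delta(Gr, yr, Xr, S, fit$delta)
  } else {
    m <- ncol(Gr)
    res <- list(beta = numeric(m), se = numeric(m), p = numeric(m),
                loglik = numeric(m))
    for (j in seq_len(m)) {
      if (!ok[j]) next
      X1r <- cbind(Xr, Gr[, j])
      grid <- 10^seq(-5, 5, length.out = 100)
      ll <- vapply(grid, function(dl)
        reml_profile(yr, X1r, S, dl, "reml")$loglik, numeric(1))
      i <- which.max(ll)
      opt <- stats::optimize(function(ld)
        reml_profile(yr, X1r, S, 10^ld, "reml")$loglik,
        interval = log10(grid[c(max(1L, i - 1L),
                                min(length(grid), i + 1L))]),
        maximum = TRUE)
      dj <- if (opt$objective > ll[i]) 10^opt$maximum else grid[i]
      pr <- reml_profile(yr, X1r, S, dj, "reml")
      w <- 1 / (S + dj)
      covb <- solve(crossprod(X1r, X1r * w)) * pr$sigma_g2
      res$beta[j] <- pr$beta[q + 1]
      res$se[j] <- sqrt(covb[q + 1, q + 1])
      res$p[j] <- stats::pchisq((res$beta[j] / res$se[j])^2, 1,
                                lower.tail = FALSE)
      res$loglik[j] <- pr$loglik
    }
  }
  res$beta[!ok] <- 0
  res$se[!ok] <- NA_real_
  res$p[!ok] <- 1
  res$loglik[!ok] <- NA_real_
  res$p <- pmin(pmax(res$p, .Machine$double.xmin), 1)
  out <- assoc_result(vt, res$beta, res$se, res$p, method = "lmm", n = n)
  out$loglik <- res$loglik
  attr(out, "delta") <- fit$delta
  attr(out, "h2") <- fit$h2
  out
}

# Vectorized GLS scan at fixed delta; REML-flavoured per-SNP loglik.
lmm_scan_fixed_delta <- function(Gr, yr, Xr, S, delta) {
  n <- length(yr)
  q <- ncol(Xr)
  w <- 1 / (S + delta)
  A <- crossprod(Xr, Xr * w)
  Ai <- solve(A)
  XWy <- drop(crossprod(Xr, yr * w))
  yWy <- sum(w * yr^2)
  GWX <- crossprod(Gr, Xr * w)            # m x q
  gWy <- drop(crossprod(Gr, yr * w))
  gWg <- colSums(w * Gr^2)
  M <- GWX %*% Ai
  denom <- gWg - rowSums(M * GWX)
  numer <- gWy - drop(M %*% XWy)
  denom_ok <- denom > 1e-12
  beta <- ifelse(denom_ok, numer / denom, 0)
  rss0 <- yWy - sum(XWy * drop(Ai %*% XWy))
  rss <- pmax(rss0 - beta * numer, 0)
  df <- n - q - 1
  sg2 <- rss / df
  se <- ifelse(denom_ok & sg2 > 0, sqrt(sg2 / denom), NA_real_)
  p <- stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
  p[!denom_ok] <- 1

  # per-SNP REML loglik of the [X, g] model at this delta
  AU <- crossprod(Xr)
  GXU <- crossprod(Gr, Xr)
  gg <- colSums(Gr^2)
  denomU <- gg - rowSums((GXU %*% solve(AU)) * GXU)
  ld_wx <- as.numeric(determinant(A)$modulus) + log(pmax(denom, 1e-300))
  ld_x <- as.numeric(determinant(AU)$modulus) + log(pmax(denomU, 1e-300))
  ll <- -0.5 * (df * log(2 * pi * sg2) + sum(log(S + delta)) + df -
                  ld_x + ld_wx)
  ll[!denom_ok] <- NA_real_
  list(beta = beta, se = se, p = p, loglik = ll)
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(qchisq(1 - p, df = 1)) / 0.4549364`, the median
#' association chi-square statistic over its null median. Values near 1
#' indicate a calibrated test; inflation above 1 suggests confounding such
#' as population structure.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return `lambda_gc`, a positive scalar.
#' @export
genomic_inflation <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

# ---- association-result container ----

assoc_result <- function(vt, beta, se, p, method, n) {
  out <- data.frame(chrom = vt$chrom, pos = vt$pos, variant_id = vt$id,
                    beta = beta, se = se, p_value = p,
                    stringsAsFactors = FALSE)
  structure(out, method = method, n_samples = n,
            class = c("assoc_result", "data.frame"))
}

variant_frame <- function(g, m) {
  if (inherits(g, "geno_data")) {
    data.frame(chrom = g$variants$chrom, pos = g$variants$pos,
               id = g$variants$id, stringsAsFactors = FALSE)
  } else {
    ids <- colnames(g) %||% paste0("v", seq_len(m))
    data.frame(chrom = "1", pos = seq_len(m), id = ids,
               stringsAsFactors = FALSE)
  }
}

impute_if_needed <- function(g) {
  d <- as_dosage_matrix(g)
  if (anyNA(d)) mean_impute(d) else d
}

#' @export
print.assoc_result <- function(x, n_top = 6, ...) {
  cat("Association scan (", attr(x, "method"), "): ",
      nrow(x), " variants, ", attr(x, "n_samples"), " samples\n", sep = "")
  top <- x[order(x$p_value), , drop = FALSE]
  cat("Top hits:\n")
  print.data.frame(utils::head(top, n_top), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export an association result as TSV
#' @param x an `assoc_result`.
#' @param path output file.
#' @export
write_assoc <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
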