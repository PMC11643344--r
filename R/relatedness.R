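#' Genomic relationship (kinship) matrix
#'
#' Builds an n x n kinship matrix from a complete (imputed) dosage matrix.
#' With `method = "standardized"` each variant is centred at `2 f_j` and
#' scaled by `sqrt(2 f_j (1 - f_j))` (unit-variance SNPs under
#' Hardy-Weinberg), where `f_j` is the A1 allele frequency estimated from
#' the analyzed cohort; `K = W W' / m`. With `method = "centered"` columns
#' are centred only. Zero-variance variants carry no relatedness
#' information and are excluded from both `W` and `m`.
#'
#' @param g_imputed complete dosage matrix (see [mean_impute()]) or a
#'   [geno_data] object without missing calls.
#' @param method `"standardized"` (default) or `"centered"`.
#' @return a `kinship` matrix with `sample_ids` and `method` attributes.
#' @export
compute_kinship <- function(g_imputed, method = c("standardized", "centered")) {
  method <- match.arg(method)
  d <- as_dosage_matrix(g_imputed)
  if (anyNA(d)) stop("dosage matrix contains missing values; run ",
                     "mean_impute() first", call. = FALSE)
  mu <- colMeans(d)
  v <- colMeans(d^2) - mu^2
  use <- which(v > 1e-12)
  if (!length(use))
    stop("all variants have zero variance; kinship is undefined",
         call. = FALSE)
  d <- d[, use, drop = FALSE]
  m <- length(use)
  if (method == "standardized") {
    f <- colMeans(d) / 2
    W <- sweep(d, 2, 2 * f, "-")
    W <- sweep(W, 2, sqrt(2 * f * (1 - f)), "/")
  } else {
    W <- sweep(d, 2, colMeans(d), "-")
  }
  K <- tcrossprod(W) / m
  K <- (K + t(K)) / 2
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  dimnames(K) <- list(ids, ids)
  structure(K, sample_ids = ids, method = method, n_variants_used = m,
            class = c("kinship", "matrix", "array"))
}

#' @export
print.kinship <- function(x, ...) {
  cat("kinship matrix (", attr(x, "method"), "): ", nrow(x), " x ", ncol(x),
      " over ", attr(x, "n_variants_used"), " variants\n", sep = "")
  cat("  diagonal mean ", format(mean(diag(x)), digits = 4),
      ", off-diagonal range [",
      format(min(x[upper.tri(x)]), digits = 3), ", ",
      format(max(x[upper.tri(x)]), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Write / read a kinship matrix as TSV with a sample-ID header
#' @param K a `kinship` matrix.
#' @param path output file.
#' @export
write_kinship <- function(K, path) {
  utils::write.table(as.data.frame(unclass(K)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  K <- as.matrix(tab)
  rownames(K) <- colnames(K)
  structure(K, sample_ids = colnames(K), method = "loaded",
            class = c("kinship", "matrix", "array"))
}

#' Principal components of the genotype matrix
#'
#' Projects samples onto the leading eigenvectors of the per-variant
#' centred (not re-standardized) dosage matrix. Component signs are fixed
#' deterministically by making the largest-magnitude variant loading of
#' each component positive.
#'
#' @param g_imputed complete dosage matrix or [geno_data] without missing
#'   calls.
#' @param k number of components, `k <= min(n - 1, m)`.
#' @return list with `scores` (n x k), `variance_explained` (k fractions,
#'   non-increasing) and `loadings` (m x k).
#' @export
compute_pca <- function(g_imputed, k = 2) {
  d <- as_dosage_matrix(g_imputed)
  if (anyNA(d)) stop("run mean_impute() first", call. = FALSE)
  n <- nrow(d); m <- ncol(d)
  if (k > min(n - 1, m))
    stop("k = ", k, " exceeds min(n - 1, m) = ", min(n - 1, m), call. = FALSE)
  dc <- sweep(d, 2, colMeans(d), "-")
  sv <- svd(dc, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- sv$d^2
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       variance_explained = (ev / sum(ev))[seq_len(k)],
       loadings = loadings)
}

#' Hierarchical-clustering leaf order for kinship heatmaps
#'
#' Average-linkage hierarchical clustering on the distance
#' `d(i, j) = max(K) - K[i, j]` (a max-shift rather than `1 - K`, so kinship
#' entries above 1 remain valid distances). Deterministic given the input.
#'
#' @param K a `kinship` matrix.
#' @return integer permutation of `1..n` (the dendrogram leaf order).
#' @export
cluster_order <- function(K) {
  n <- nrow(K)
  if (n == 1) return(1L)
  d <- stats::as.dist(max(K) - K)
  stats::hclust(d, method = "average")$order
}
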