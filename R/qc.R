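#' Per-variant quality-control statistics
#'
#' Computes, per variant, the minor allele frequency over non-missing calls,
#' the missing-call rate over all samples and the heterozygote rate over
#' non-missing calls. A variant with every call missing gets `maf = NA`
#' and `het_rate = NA` (undefined) and `missing_rate = 1`.
#'
#' @param g a [geno_data] object or dosage matrix.
#' @return data.frame with columns `variant_id`, `maf`, `missing_rate`,
#'   `het_rate`, one row per variant.
#' @export
compute_variant_qc <- function(g) {
  d <- as_dosage_matrix(g)
  if (nrow(d) < 1) stop("need at least one sample", call. = FALSE)
  n <- nrow(d)
  nonmiss <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * nonmiss)  # NaN when nonmiss == 0
  maf <- pmin(f, 1 - f)
  maf[nonmiss == 0] <- NA_real_
  het <- colSums(d == 1, na.rm = TRUE) / nonmiss
  het[nonmiss == 0] <- NA_real_
  data.frame(variant_id = colnames(d) %||% as.character(seq_len(ncol(d))),
             maf = maf, missing_rate = (n - nonmiss) / n, het_rate = het,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter variants on missing rate and minor allele frequency
#'
#' A variant is kept iff `missing_rate <= missing_max` AND `maf >= maf_min`
#' (boundaries inclusive, matching PLINK `--geno`/`--maf` semantics).
#' Variants with every call missing are always removed. Original variant
#' order is preserved.
#'
#' @param g a [geno_data] object.
#' @param qc optional precomputed [compute_variant_qc()] result.
#' @param maf_min minimum MAF in `[0, 0.5]`.
#' @param missing_max maximum missing rate in `[0, 1]`.
#' @return list with `geno` (filtered [geno_data]), `kept` (integer indices
#'   of retained variants in the input), and `qc` (the QC table used).
#'   If nothing survives, a warning is raised and `geno` is the empty set.
#' @export
filter_variants <- function(g, qc = NULL, maf_min = 0, missing_max = 1) {
  stopifnot(inherits(g, "geno_data"),
            maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  if (is.null(qc)) qc <- compute_variant_qc(g)
  keep <- which(!is.na(qc$maf) & qc$missing_rate <= missing_max &
                  qc$maf >= maf_min)
  if (!length(keep))
    warning("no variants pass the filters (maf >= ", maf_min,
            ", missing <= ", missing_max, ")", call. = FALSE)
  list(geno = subset_variants(g, keep), kept = keep, qc = qc)
}

#' Replace missing dosages by the per-variant mean
#'
#' Each missing cell is replaced by the mean of the non-missing dosages of
#' its variant; non-missing cells are unchanged. The result is a
#' real-valued complete matrix suitable for kinship, PCA, regression and
#' the machine-learning learners.
#'
#' @param g a [geno_data] object or dosage matrix.
#' @return numeric matrix with no missing values.
#' @export
mean_impute <- function(g) {
  d <- as_dosage_matrix(g)
  nonmiss <- colSums(!is.na(d))
  if (any(nonmiss == 0)) {
    bad <- which(nonmiss == 0)[1]
    id <- colnames(d)[bad] %||% bad
    stop("variant ", id, " has no non-missing calls; remove it before ",
         "imputation (see filter_variants)", call. = FALSE)
  }
  na_idx <- which(is.na(d))
  if (length(na_idx)) {
    mu <- colSums(d, na.rm = TRUE) / nonmiss
    d[na_idx] <- mu[(na_idx - 1L) %/% nrow(d) + 1L]
  }
  d
}

#' Binned genotype and sample summaries
#'
#' Deterministic summaries backing the data-report panels: per-sample
#' heterozygosity, a MAF histogram with bins of width 0.05 on `[0, 0.5]`,
#' and per-chromosome marker-density histograms over fixed-width basepair
#' bins.
#'
#' @param g a [geno_data] object.
#' @param qc optional precomputed QC table.
#' @param density_bin_bp density bin width in basepairs (default 1 Mbp).
#' @return list with `het` (per-sample heterozygosity, named),
#'   `maf_hist` (`breaks`, `counts`; counts sum to the number of variants
#'   with defined MAF), and `density` (per chromosome: `breaks`, `counts`;
#'   all counts sum to the number of variants).
#' @export
genotype_summary <- function(g, qc = NULL, density_bin_bp = 1e6) {
  stopifnot(inherits(g, "geno_data"))
  if (is.null(qc)) qc <- compute_variant_qc(g)
  d <- g$dosages
  nonmiss_row <- rowSums(!is.na(d))
  het <- rowSums(d == 1, na.rm = TRUE) / pmax(nonmiss_row, 1)
  names(het) <- rownames(d)

  maf_breaks <- seq(0, 0.5, by = 0.05)
  maf_ok <- qc$maf[!is.na(qc$maf)]
  maf_counts <- as.vector(table(cut(maf_ok, maf_breaks, include.lowest = TRUE,
                                    right = TRUE)))

  density <- lapply(split(g$variants$pos, g$variants$chrom), function(pos) {
    top <- max(pos, 1)
    breaks <- seq(0, ceiling(top / density_bin_bp) * density_bin_bp,
                  by = density_bin_bp)
    counts <- as.vector(table(cut(pos, breaks, include.lowest = TRUE,
                                  right = TRUE)))
    list(breaks = breaks, counts = counts)
  })

  list(het = het,
       maf_hist = list(breaks = maf_breaks, counts = maf_counts),
       density = density)
}

#' Write a per-variant QC report as TSV
#'
#' @param qc a [compute_variant_qc()] table.
#' @param kept integer indices of retained variants (e.g. from
#'   [filter_variants()]); used to fill the `kept` flag column.
#' @param path output file.
#' @export
write_qc_report <- function(qc, kept = seq_len(nrow(qc)), path) {
  qc$kept <- seq_len(nrow(qc)) %in% kept
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
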