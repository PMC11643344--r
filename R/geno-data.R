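#' Genotype dataset container
#'
#' Bundles an additive-dosage matrix with its variant and sample metadata.
#' Dosages count copies of the A1 allele (the allele listed first in the
#' variant table, by convention the minor allele of the loaded cohort), so
#' each non-missing entry is 0, 1 or 2; missing calls are `NA`.
#'
#' @param dosages numeric matrix, samples x variants; entries in
#'   `{0, 1, 2, NA}`. Row names are individual IDs, column names variant IDs.
#' @param variants data.frame with BIM semantics: columns `chrom`, `id`,
#'   `cm` (genetic distance, 0 when unknown), `pos` (1-based bp), `a1`
#'   (counted allele), `a2`.
#' @param samples data.frame with FAM semantics: columns `fid`, `iid`,
#'   `pat`, `mat`, `sex` (0/1/2), `phen` (default phenotype, -9 = missing).
#' @return an object of class `geno_data`.
#' @export
geno_data <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  if (storage.mode(dosages) != "double") storage.mode(dosages) <- "double"
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  if (nrow(variants) != ncol(dosages))
    stop("variant table has ", nrow(variants), " rows but dosage matrix has ",
         ncol(dosages), " columns", call. = FALSE)
  if (nrow(samples) != nrow(dosages))
    stop("sample table has ", nrow(samples), " rows but dosage matrix has ",
         nrow(dosages), " rows", call. = FALSE)
  # validate in column blocks so huge matrices never allocate large
  # logical intermediates
  chunk <- max(1L, as.integer(2e7 / max(nrow(dosages), 1L)))
  for (start in if (ncol(dosages)) seq(1L, ncol(dosages), by = chunk)
       else integer(0)) {
    jj <- start:min(start + chunk - 1L, ncol(dosages))
    x <- dosages[, jj, drop = FALSE]
    bad <- x[!is.na(x) & !(x == 0 | x == 1 | x == 2)]
    if (length(bad))
      stop("dosages must be 0, 1, 2 or NA; found ", bad[1], call. = FALSE)
  }
  if (anyDuplicated(variants$id))
    stop("variant IDs are not unique", call. = FALSE)
  if (anyDuplicated(paste(samples$fid, samples$iid, sep = "\r")))
    stop("(fid, iid) sample ID pairs are not unique", call. = FALSE)
  if (!identical(rownames(dosages), as.character(samples$iid)))
    rownames(dosages) <- samples$iid
  if (!identical(colnames(dosages), as.character(variants$id)))
    colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "geno_data")
}

#' @export
print.geno_data <- function(x, ...) {
  cat("geno_data: ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " variants\n", sep = "")
  nm <- sum(is.na(x$dosages))
  cat("  missing calls: ", nm, " (",
      format(100 * nm / length(x$dosages), digits = 3), "%)\n", sep = "")
  chr <- unique(x$variants$chrom)
  cat("  chromosomes: ", paste(utils::head(chr, 8), collapse = ", "),
      if (length(chr) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_data <- function(x) dim(x$dosages)

# Internal: coerce geno_data or bare matrix to a dosage matrix.
as_dosage_matrix <- function(g) {
  if (inherits(g, "geno_data")) g$dosages
  else if (is.matrix(g)) g
  else stop("expected a geno_data object or a dosage matrix", call. = FALSE)
}

# Internal: subset a geno_data by variant index, preserving order.
subset_variants <- function(g, keep) {
  geno_data(g$dosages[, keep, drop = FALSE],
            g$variants[keep, , drop = FALSE],
            g$samples)
}

default_fam <- function(iid, fid = iid) {
  data.frame(fid = as.character(fid), iid = as.character(iid),
             pat = "0", mat = "0", sex = 0L, phen = -9,
             stringsAsFactors = FALSE)
}
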