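#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file into additive dosages. Sites with
#' more than one ALT allele or with symbolic alleles (`<...>`, breakends)
#' are skipped and tallied. After counting ALT copies, the counted allele
#' (A1) is set to the minor allele of the loaded cohort; at a 50/50 tie the
#' ALT allele is A1. Any genotype with a missing allele slot (`.`) becomes
#' a missing call; both `/` and `|` separators are accepted.
#'
#' @param path VCF file (plain text).
#' @return a [geno_data] object with an extra element `n_skipped`, the
#'   number of multiallelic/symbolic records dropped.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 500L)
  if (!length(head_lines) || !grepl("^##fileformat=VCF", head_lines[1]))
    stop("not a VCF file (missing ##fileformat header line): ", path,
         call. = FALSE)
  chrom_line <- grep("^#CHROM\t", head_lines, value = TRUE)
  if (!length(chrom_line))
    stop("malformed VCF: no #CHROM column header line found in ", path,
         call. = FALSE)
  ncols <- length(strsplit(chrom_line[1], "\t", fixed = TRUE)[[1]])
  if (ncols < 10)
    stop("VCF has no sample columns: ", path, call. = FALSE)

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  symbolic <- grepl("[][<>]", alt) | grepl("[][<>]", ref)
  multi <- grepl(",", alt, fixed = TRUE)
  keep <- !(symbolic | multi) & !is.na(alt)
  n_skipped <- sum(!keep)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  samp <- colnames(vcf@gt)[-1]
  m <- nrow(fix)
  n <- length(samp)

  # ALT-allele count per genotype; any "." slot -> missing
  alt_count <- function(x) {
    miss <- is.na(x) | grepl(".", x, fixed = TRUE)
    cnt <- nchar(x) - nchar(gsub("1", "", x, fixed = TRUE))
    cnt[miss] <- NA_real_
    cnt
  }
  dos <- matrix(alt_count(as.vector(gt)), nrow = m, ncol = n)
  dos <- t(dos)  # samples x variants

  # assign A1 to the minor allele of this cohort; tie -> ALT is A1
  a1 <- alt[keep]
  a2 <- ref[keep]
  if (m > 0) {
    nonmiss <- colSums(!is.na(dos))
    f_alt <- ifelse(nonmiss > 0, colSums(dos, na.rm = TRUE) / (2 * nonmiss), 0)
    flip <- f_alt > 0.5
    if (any(flip)) {
      dos[, flip] <- 2 - dos[, flip, drop = FALSE]
      tmp <- a1[flip]; a1[flip] <- a2[flip]; a2[flip] <- tmp
    }
  }

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[is.na(ids) | ids == ".", "CHROM"], ":",
           fix[is.na(ids) | ids == ".", "POS"])
  variants <- data.frame(chrom = fix[, "CHROM"], id = ids, cm = 0,
                         pos = as.integer(fix[, "POS"]), a1 = a1, a2 = a2,
                         stringsAsFactors = FALSE)
  out <- geno_data(dos, variants, default_fam(samp))
  out$n_skipped <- n_skipped
  out
}

#' Convert a VCF file to a filtered PLINK binary triple
#'
#' Reads a VCF with [read_vcf()], applies the missing-rate filter and then
#' the minor-allele-frequency filter (see [filter_variants()] for the
#' boundary rules: a variant is kept when `missing_rate <= missing_max` and
#' `maf >= maf_min`), and writes the surviving variants as a PLINK
#' BED/BIM/FAM triple.
#'
#' @param vcf_path input VCF.
#' @param prefix output PLINK path stem.
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`.
#' @param missing_max maximum per-variant missing-call rate, in `[0, 1]`.
#' @return a `conversion_report` list: `n_in` (VCF data records),
#'   `n_kept`, `n_skipped_multiallelic`, `n_removed_missing`,
#'   `n_removed_maf`. Counts are additive:
#'   `n_in == n_kept + n_skipped_multiallelic + n_removed_missing +
#'   n_removed_maf`.
#' @export
convert_vcf_to_plink <- function(vcf_path, prefix, maf_min = 0,
                                 missing_max = 1) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  g <- read_vcf(vcf_path)
  qc <- compute_variant_qc(g)
  pass_missing <- !is.na(qc$maf) & qc$missing_rate <= missing_max
  pass_maf <- pass_missing & qc$maf >= maf_min
  keep <- which(pass_maf)
  write_plink(subset_variants(g, keep), prefix)
  structure(list(n_in = ncol(g$dosages) + g$n_skipped,
                 n_kept = length(keep),
                 n_skipped_multiallelic = g$n_skipped,
                 n_removed_missing = sum(!pass_missing),
                 n_removed_maf = sum(pass_missing & !pass_maf)),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("VCF -> PLINK conversion\n")
  cat("  records in VCF:        ", x$n_in, "\n")
  cat("  multiallelic/symbolic: ", x$n_skipped_multiallelic, "\n")
  cat("  removed (missing rate):", x$n_removed_missing, "\n")
  cat("  removed (MAF):         ", x$n_removed_maf, "\n")
  cat("  variants written:      ", x$n_kept, "\n")
  invisible(x)
}

# Internal: write a geno_data object as a minimal VCF 4.2 file (used by the
# simulator's fixture bundles). A1 is written as ALT so that dosages equal
# ALT-allele counts.
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples$iid), collapse = "\t")),
             con)
  gt_lut <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_lut[d + 1])
    v <- g$variants[j, ]
    writeLines(paste(c(v$chrom, v$pos, v$id, v$a2, v$a1, ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
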