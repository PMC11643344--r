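# Shared fixture builders. Everything is generated in code at test time.

# random geno_data with optional missing calls
random_geno <- function(n, m, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) d[runif(n * m) < miss] <- NA
  storage.mode(d) <- "double"
  variants <- data.frame(chrom = as.character(rep_len(1:2, m)),
                         id = paste0("v", seq_len(m)), cm = 0,
                         pos = seq_len(m) * 100L,
                         a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  samples <- data.frame(fid = paste0("f", seq_len(n)),
                        iid = paste0("i", seq_len(n)),
                        pat = "0", mat = "0", sex = 0L, phen = -9,
                        stringsAsFactors = FALSE)
  geno_data(d, variants, samples)
}

# hand-written VCF text, independent of the package's own writer
write_test_vcf <- function(path, records, samples = paste0("s", 1:4)) {
  # records: list of c(chrom, pos, id, ref, alt, gt...) character vectors
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r[1:5], ".", "PASS", ".", "GT", r[-(1:5)]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# brute-force per-variant QC recount (the independent oracle)
naive_qc <- function(d) {
  t(vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    nm <- sum(!is.na(x))
    f <- if (nm > 0) sum(x, na.rm = TRUE) / (2 * nm) else NA_real_
    c(maf = if (nm > 0) min(f, 1 - f) else NA_real_,
      missing_rate = mean(is.na(x)),
      het_rate = if (nm > 0) sum(x == 1, na.rm = TRUE) / nm else NA_real_)
  }, numeric(3)))
}
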