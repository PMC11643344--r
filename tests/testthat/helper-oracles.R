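# Independent brute-force oracles shared across test files. These stay
# deliberately naive (line-by-line, per-column loops) so they cannot share
# a defect with the vectorized implementations they check.

# line-by-line recount of a VCF conversion report
naive_convert_report <- function(vcf_path, maf_min, missing_max) {
  lines <- grep("^#", readLines(vcf_path), invert = TRUE, value = TRUE)
  n_in <- length(lines)
  n_multi <- 0L; n_miss <- 0L; n_maf <- 0L; n_kept <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (grepl(",", f[5]) || grepl("[<>]", f[5])) {
      n_multi <- n_multi + 1L
      next
    }
    gts <- sub(":.*", "", f[-(1:9)])
    alt <- ifelse(grepl("\\.", gts), NA,
                  vapply(strsplit(gts, "[/|]"), function(a)
                    sum(a == "1"), numeric(1)))
    n <- length(alt)
    nm <- sum(!is.na(alt))
    miss_rate <- (n - nm) / n
    if (nm == 0 || miss_rate > missing_max) { n_miss <- n_miss + 1L; next }
    fr <- sum(alt, na.rm = TRUE) / (2 * nm)
    if (min(fr, 1 - fr) < maf_min) { n_maf <- n_maf + 1L; next }
    n_kept <- n_kept + 1L
  }
  list(n_in = n_in, n_kept = n_kept, n_skipped_multiallelic = n_multi,
       n_removed_missing = n_miss, n_removed_maf = n_maf)
}

# random VCF text fixture with sprinkled missing and multiallelic records
random_vcf_fixture <- function(path, n = 20, m = 50, seed = 1) {
  set.seed(seed)
  recs <- lapply(seq_len(m), function(j) {
    f <- runif(1, 0, 0.6)
    gt <- replicate(n, paste(rbinom(2, 1, f), collapse = "/"))
    gt[runif(n) < 0.1] <- "./."
    alt <- if (runif(1) < 0.1) "G,T" else "G"
    c("1", as.character(j), paste0("r", j), "A", alt, gt)
  })
  write_test_vcf(path, recs, samples = paste0("s", seq_len(n)))
  path
}
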