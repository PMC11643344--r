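#' Simulate genotypes under the Balding-Nichols model
#'
#' Draws ancestral allele frequencies uniformly on `maf_range`; with
#' `n_pops > 1` and `fst > 0`, each population's frequency is a
#' Beta(`p (1 - fst) / fst`, `(1 - p)(1 - fst) / fst`) draw around the
#' ancestral value, producing allele-frequency differentiation with the
#' requested expected Fst. Genotypes are Binomial(2, p_pop) per sample;
#' samples are split evenly across populations; missing calls are masked
#' i.i.d. Fully deterministic given the seed. Variants are laid out on 5
#' chromosomes with evenly spaced positions.
#'
#' @param n_samples,n_variants dimensions of the output.
#' @param n_pops number of populations (default 1).
#' @param fst Balding-Nichols differentiation parameter (default 0).
#' @param maf_range ancestral-frequency range (default `c(0.05, 0.5)`).
#' @param missing_rate i.i.d. missing-call probability (default 0).
#' @param seed integer seed.
#' @param n_chrom number of chromosomes variants are spread over.
#' @return a [geno_data] object with an extra `population` element
#'   (integer label per sample).
#' @export
simulate_genotypes <- function(n_samples, n_variants, n_pops = 1L,
                               fst = 0, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 1L, n_chrom = 5L) {
  stopifnot(n_samples >= 1, n_variants >= 1, n_pops >= 1,
            fst >= 0, fst < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  pop <- sort(rep_len(seq_len(n_pops), n_samples))
  p_anc <- stats::runif(n_variants, maf_range[1], maf_range[2])

  # per-population allele frequencies
  if (n_pops > 1 && fst > 0) {
    a <- (1 - fst) / fst
    pf <- vapply(seq_len(n_pops), function(k)
      stats::rbeta(n_variants, p_anc * a, (1 - p_anc) * a),
      numeric(n_variants))
    pf <- matrix(pf, nrow = n_variants)
  } else {
    pf <- matrix(rep(p_anc, n_pops), nrow = n_variants)
  }

  # column-chunked generation bounds peak memory on large requests
  d <- matrix(0, nrow = n_samples, ncol = n_variants)
  chunk <- max(1L, as.integer(2e7 / n_samples))
  for (start in seq(1L, n_variants, by = chunk)) {
    jj <- start:min(start + chunk - 1L, n_variants)
    for (k in seq_len(n_pops)) {
      rows <- which(pop == k)
      d[rows, jj] <- stats::rbinom(length(rows) * length(jj), 2L,
                                   rep(pf[jj, k], each = length(rows)))
    }
    if (missing_rate > 0) {
      blk <- d[, jj, drop = FALSE]
      blk[stats::runif(length(blk)) < missing_rate] <- NA_real_
      d[, jj] <- blk
    }
  }

  chrom <- as.character(sort(rep_len(seq_len(n_chrom), n_variants)))
  pos <- integer(n_variants)
  for (c_ in unique(chrom)) {
    idx <- which(chrom == c_)
    pos[idx] <- seq_along(idx) * 10000L
  }
  variants <- data.frame(chrom = chrom,
                         id = sprintf("snp%06d", seq_len(n_variants)),
                         cm = 0, pos = pos,
                         a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  samples <- default_fam(sprintf("ind%04d", seq_len(n_samples)))
  dimnames(d) <- list(samples$iid, variants$id)  # in place; avoids a copy
  g <- geno_data(d, variants, samples)
  g$population <- pop
  g
}

#' Simulate a phenotype with designed causal markers
#'
#' Samples `n_causal` causal variants (without replacement, among variants
#' with MAF >= 0.05), assigns standard-normal effects to their standardized
#' dosages, and combines the genetic value `G` with orthogonalized noise so
#' that the in-sample variance ratio `var(G) / var(y)` equals `h2`
#' *exactly* (sample-level scaling, giving parameter-recovery tests a
#' sharp target):
#' `y = sqrt(h2) * std(G) + sqrt(1 - h2) * std(noise_perp)`.
#' Qualitative traits threshold the quantitative liability at its median,
#' yielding 0/1 classes whose counts differ by at most one.
#'
#' @param g a [geno_data] object (missing calls are mean-imputed for the
#'   genetic value).
#' @param n_causal number of causal variants.
#' @param h2 target heritability in `[0, 1]`.
#' @param trait_type `"quantitative"` (default) or `"qualitative"`.
#' @param seed integer seed.
#' @return list with `phenotypes` (data.frame `fid`, `iid`, `value`) and
#'   `truth` (list: `causal_indices`, `causal_effects`, `true_h2`,
#'   `trait_type`, `population_labels`, `genetic_value`).
#' @export
simulate_phenotype <- function(g, n_causal, h2,
                               trait_type = c("quantitative", "qualitative"),
                               seed = 1L) {
  trait_type <- match.arg(trait_type)
  stopifnot(inherits(g, "geno_data"), n_causal <= ncol(g$dosages),
            h2 >= 0, h2 <= 1)
  if (h2 > 0 && n_causal == 0)
    stop("h2 > 0 with no causal variants is contradictory", call. = FALSE)
  set.seed(seed)
  d <- impute_if_needed(g)
  n <- nrow(d)

  if (n_causal > 0) {
    qc <- compute_variant_qc(g)
    eligible <- which(!is.na(qc$maf) & qc$maf >= 0.05)
    if (length(eligible) < n_causal)
      stop("only ", length(eligible), " variants have MAF >= 0.05; cannot ",
           "place ", n_causal, " causal markers", call. = FALSE)
    causal <- sort(sample(eligible, n_causal))
    effects <- stats::rnorm(n_causal)
    Z <- scale(d[, causal, drop = FALSE])
    Z[is.nan(Z)] <- 0
    gval <- drop(Z %*% effects)
  } else {
    causal <- integer(0)
    effects <- numeric(0)
    gval <- numeric(n)
  }

  noise <- stats::rnorm(n)
  std <- function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else v * 0
  }
  gs <- std(gval)
  # project the genetic direction out of the noise so the variance split
  # is exact, then standardize the remainder
  e_perp <- if (stats::sd(gs) > 0)
    noise - gs * (sum(noise * gs) / sum(gs^2)) else noise
  es <- std(e_perp)
  y <- sqrt(h2) * gs + sqrt(1 - h2) * es

  if (trait_type == "qualitative")
    y <- as.numeric(y > stats::median(y))

  list(phenotypes = data.frame(fid = g$samples$fid, iid = g$samples$iid,
                               value = y, stringsAsFactors = FALSE),
       truth = list(causal_indices = causal,
                    causal_effects = effects,
                    true_h2 = h2,
                    trait_type = trait_type,
                    population_labels = g$population %||%
                      rep(1L, n),
                    genetic_value = gs))
}

#' Write a deterministic simulation fixture bundle
#'
#' Produces a named scenario as a VCF, a PLINK triple, a phenotype CSV and
#' a truth JSON under `output_dir`. Bundles are byte-identical for a given
#' seed. `toy4x3` is a hand-specified 4-sample x 3-variant set (one
#' missing call) whose derived statistics are documented in the bundle's
#' README; the other scenarios are simulator draws: `structured_null`
#' (2 populations, Fst 0.1, trait independent of genotype),
#' `single_causal` (one marker explaining 30% of variance) and
#' `gp_benchmark` (50 causal markers, h2 = 0.6).
#'
#' @param output_dir directory (created if needed).
#' @param scenario one of `"toy4x3"`, `"structured_null"`,
#'   `"single_causal"`, `"gp_benchmark"`.
#' @param seed integer seed.
#' @return (invisibly) named list of written file paths.
#' @export
write_fixture_set <- function(output_dir, scenario = c("toy4x3",
                                                       "structured_null",
                                                       "single_causal",
                                                       "gp_benchmark"),
                              seed = 1L) {
  scenario <- match.arg(scenario)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(output_dir, scenario)

  if (scenario == "toy4x3") {
    # dosages hand-chosen so the derived MAFs are 0.375, 0.5 and 0.0
    d <- matrix(c(0, 1, 2, 2,
                  2, NA, 0, 1,
                  0, 0, 0, 0), nrow = 4)
    variants <- data.frame(chrom = c("1", "1", "2"),
                           id = c("t1", "t2", "t3"), cm = 0,
                           pos = c(100L, 200L, 100L),
                           a1 = c("A", "A", "A"), a2 = c("G", "G", "G"),
                           stringsAsFactors = FALSE)
    g <- geno_data(d, variants, default_fam(paste0("s", 1:4)))
    truth <- list(scenario = scenario, maf = c(0.375, 0.5, 0),
                  missing_rate = c(0, 0.25, 0), causal_indices = integer(0))
    pheno <- data.frame(fid = g$samples$fid, iid = g$samples$iid,
                        value = c(1.5, 2.5, 3.5, 3.0))
    writeLines(c(
      "toy4x3 fixture: 4 samples x 3 variants, dosages by variant:",
      "  t1: 0 1 2 2   -> A1 freq 5/8, MAF 0.375, het rate 1/4",
      "  t2: 2 . 0 1   -> A1 freq 3/6, MAF 0.5, missing rate 1/4",
      "  t3: 0 0 0 0   -> monomorphic, MAF 0.0",
      "The VCF stores A1 as ALT, so ALT counts equal these dosages",
      "(t1 is flipped to REF-minor on load, leaving MAF unchanged)."),
      file.path(output_dir, "toy4x3_README.txt"))
  } else {
    params <- switch(scenario,
      structured_null = list(n = 100L, m = 500L, pops = 2L, fst = 0.1,
                             n_causal = 0L, h2 = 0),
      single_causal = list(n = 150L, m = 500L, pops = 1L, fst = 0,
                           n_causal = 1L, h2 = 0.3),
      gp_benchmark = list(n = 200L, m = 1000L, pops = 1L, fst = 0,
                          n_causal = 50L, h2 = 0.6))
    g <- simulate_genotypes(params$n, params$m, n_pops = params$pops,
                            fst = params$fst, seed = seed)
    sim <- simulate_phenotype(g, params$n_causal, params$h2, seed = seed + 1L)
    pheno <- sim$phenotypes
    truth <- c(list(scenario = scenario, seed = seed), params,
               sim$truth[c("causal_indices", "causal_effects", "true_h2",
                           "trait_type")])
  }

  # write the VCF from the raw dosages, then round-trip through read_vcf so
  # the PLINK triple matches the VCF's on-load representation exactly
  vcf_path <- paste0(pre, ".vcf")
  write_vcf(g, vcf_path)
  g_loaded <- read_vcf(vcf_path)
  write_plink(g_loaded, pre)
  utils::write.csv(pheno, paste0(pre, "_pheno.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(truth, paste0(pre, "_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(vcf = vcf_path, bed = paste0(pre, ".bed"),
                 bim = paste0(pre, ".bim"), fam = paste0(pre, ".fam"),
                 pheno = paste0(pre, "_pheno.csv"),
                 truth = paste0(pre, "_truth.json")))
}
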