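#' Read a PLINK 1 binary genotype triple
#'
#' Reads `prefix.bed`, `prefix.bim` and `prefix.fam`. The BED file must be
#' in SNP-major order (magic bytes `0x6C 0x1B 0x01`). Two-bit codes are
#' decoded as 00 = 2 copies of A1, 10 = 1 copy, 11 = 0 copies,
#' 01 = missing; within a byte samples occupy low-order bit pairs first and
#' trailing pad bits are ignored.
#'
#' @param prefix path stem of the `.bed`/`.bim`/`.fam` files.
#' @return a [geno_data] object.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  fam <- utils::read.table(paths[3], header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "phen"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  bim <- utils::read.table(paths[2], header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B) ||
      raw[3] != as.raw(0x01))
    stop("not a SNP-major PLINK 1 BED file (bad magic bytes): ", paths[1],
         call. = FALSE)
  nb <- ceiling(n / 4)
  if (length(raw) != 3 + nb * m)
    stop("BED file ", paths[1], " is truncated or inconsistent: expected ",
         3 + nb * m, " bytes for ", n, " samples x ", m, " variants, found ",
         length(raw), call. = FALSE)

  dosages <- decode_bed_bytes(raw[-(1:3)], n, m)
  geno_data(dosages, bim, fam)
}

# raw payload -> n x m dosage matrix (low-order bit pair = first sample)
decode_bed_bytes <- function(bytes, n, m) {
  nb <- ceiling(n / 4)
  v <- as.integer(bytes)
  codes <- matrix(0L, nrow = 4L * nb, ncol = m)
  codes[seq(1, 4 * nb, by = 4), ] <- v %% 4L
  codes[seq(2, 4 * nb, by = 4), ] <- (v %/% 4L) %% 4L
  codes[seq(3, 4 * nb, by = 4), ] <- (v %/% 16L) %% 4L
  codes[seq(4, 4 * nb, by = 4), ] <- (v %/% 64L) %% 4L
  # code -> dosage: 00 -> 2, 01 -> NA, 10 -> 1, 11 -> 0
  lut <- c(2, NA, 1, 0)
  matrix(lut[codes[seq_len(n), , drop = FALSE] + 1L], nrow = n, ncol = m)
}

# n x m dosage matrix -> raw payload (pad bit pairs are zero)
encode_bed_bytes <- function(dosages) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  nb <- ceiling(n / 4)
  # dosage -> code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  codes <- matrix(0L, nrow = 4L * nb, ncol = m)
  d <- dosages
  cd <- ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  codes[seq_len(n), ] <- cd
  dim(codes) <- c(4L, nb * m)
  as.raw(codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] + 64L * codes[4, ])
}

#' Write a PLINK 1 binary genotype triple
#'
#' Bit-exact inverse of [read_plink()]: writes a SNP-major BED file with
#' magic bytes `0x6C 0x1B 0x01` plus whitespace-delimited 6-column BIM and
#' FAM files.
#'
#' @param g a [geno_data] object.
#' @param prefix output path stem.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "geno_data"))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  if (ncol(g$dosages) > 0)
    writeBin(encode_bed_bytes(g$dosages), con)
  utils::write.table(g$variants[, c("chrom", "id", "cm", "pos", "a1", "a2")],
                     paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(g$samples[, c("fid", "iid", "pat", "mat", "sex", "phen")],
                     paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read and align a phenotype table to genotype sample order
#'
#' Parses a delimited text file (comma, tab or whitespace separated,
#' auto-detected) with either two columns (`IID value`) or three or more
#' (`FID IID value`), detected by column count. Values that fail numeric
#' parsing (including `NA`) and the PLINK missing sentinel -9 are masked.
#'
#' @param path phenotype file.
#' @param samples the `samples` data.frame of a [geno_data] object (or any
#'   data.frame with `fid`/`iid` columns) giving the target sample order.
#' @param match_on `"iid"` (default) matches on individual ID alone;
#'   `"fid_iid"` requires the family ID to match as well.
#' @param header set `TRUE` if the first line is a header; by default a
#'   header line is detected by a non-numeric value column entry.
#' @return list with `values` (numeric vector in genotype sample order, `NA`
#'   where masked), `n_matched`, `n_unmatched` (file rows with no genotype
#'   match), `n_nonnumeric` (matched rows masked for unparseable values).
#' @export
read_phenotypes <- function(path, samples, match_on = c("iid", "fid_iid"),
                            header = NA) {
  match_on <- match.arg(match_on)
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           blank.lines.skip = TRUE)
  if (ncol(tab) < 2)
    stop("phenotype file must have at least 2 columns (IID value)",
         call. = FALSE)
  vcol <- if (ncol(tab) >= 3) 3L else 2L
  if (is.na(header))
    header <- is.na(suppressWarnings(as.numeric(tab[1, vcol]))) &&
      !(tab[1, vcol] %in% c("NA", "na", ""))
  if (isTRUE(header)) tab <- tab[-1, , drop = FALSE]

  if (ncol(tab) >= 3) {
    fid <- tab[[1]]; iid <- tab[[2]]
  } else {
    fid <- tab[[1]]; iid <- tab[[1]]
  }
  vals <- suppressWarnings(as.numeric(tab[[vcol]]))
  nonnum <- is.na(vals)
  vals[!nonnum & vals == -9] <- NA

  key_file <- if (match_on == "fid_iid") paste(fid, iid, sep = "\r") else iid
  key_geno <- if (match_on == "fid_iid")
    paste(samples$fid, samples$iid, sep = "\r") else samples$iid
  if (anyDuplicated(key_file))
    stop("duplicate sample IDs in phenotype file", call. = FALSE)

  idx <- match(key_geno, key_file)
  n_matched <- sum(!is.na(idx))
  if (n_matched == 0)
    stop("no phenotype sample IDs match the genotype samples; ",
         "check the ID scheme (FID/IID vs IID)", call. = FALSE)
  out <- rep(NA_real_, length(key_geno))
  out[!is.na(idx)] <- vals[idx[!is.na(idx)]]
  names(out) <- samples$iid
  list(values = out,
       n_matched = n_matched,
       n_unmatched = sum(!(key_file %in% key_geno)),
       n_nonnumeric = sum(nonnum[stats::na.omit(idx)]))
}
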