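#' Plot output specification
#'
#' @param path output image file; the format is taken from the extension
#'   unless `format` is given.
#' @param format `"svg"` or `"png"`.
#' @param width,height image size in pixels.
#' @param significance_threshold p-value for the Manhattan significance
#'   line; `NULL` (default) means Bonferroni `0.05 / m` at plot time.
#' @return a `plot_spec` list.
#' @export
plot_spec <- function(path, format = NULL, width = 900, height = 600,
                      significance_threshold = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "svg"
  format <- match.arg(format, c("svg", "png"))
  stopifnot(width > 0, height > 0)
  if (!is.null(significance_threshold))
    stopifnot(significance_threshold > 0, significance_threshold < 1)
  structure(list(path = path, format = format, width = width,
                 height = height,
                 significance_threshold = significance_threshold),
            class = "plot_spec")
}

open_device <- function(spec) {
  if (spec$format == "png") {
    grDevices::png(spec$path, width = spec$width, height = spec$height)
  } else {
    grDevices::svg(spec$path, width = spec$width / 96,
                   height = spec$height / 96)
  }
}

with_device <- function(spec, expr) {
  open_device(spec)
  on.exit(grDevices::dev.off())
  force(expr)
}

write_sidecar <- function(spec, summary) {
  jsonlite::write_json(summary, paste0(spec$path, ".json"),
                       auto_unbox = TRUE, digits = NA)
}

# cumulative genome x-coordinate; chromosomes in order of appearance
genome_coords <- function(chrom, pos) {
  chrom <- factor(chrom, levels = unique(chrom))
  offs <- c(0, cumsum(tapply(pos, chrom, max) + 1))
  list(x = pos + offs[as.integer(chrom)],
       chrom_index = as.integer(chrom),
       centers = tapply(pos + offs[as.integer(chrom)], chrom, mean),
       labels = levels(chrom))
}

#' Manhattan plot
#'
#' Regression results (`assoc_result`) are drawn as `-log10(p)` against
#' the cumulative genome coordinate with a significance line (Bonferroni
#' `0.05 / m` unless the spec overrides it); importance results
#' (`importance_result`) are drawn as the aggregated score with no
#' threshold line. Chromosomes alternate between two fixed colours.
#'
#' @param assoc an `assoc_result` or `importance_result`.
#' @param spec a [plot_spec()].
#' @return (invisibly) a summary list `n_points`, `threshold_line_y`,
#'   `n_above`, also written as a JSON sidecar next to the image.
#' @export
manhattan_plot <- function(assoc, spec) {
  stopifnot(nrow(assoc) > 0)
  if (any(is.na(assoc$pos)))
    stop("variant ", assoc$variant_id[which(is.na(assoc$pos))[1]],
         " has no position", call. = FALSE)
  is_imp <- inherits(assoc, "importance_result") ||
    (is.null(assoc$p_value) && !is.null(assoc$score))
  if (is_imp) {
    yv <- assoc$score
    ylab <- "aggregated importance"
    thr_y <- NA_real_
  } else {
    yv <- -log10(assoc$p_value)
    ylab <- expression(-log[10](italic(p)))
    thr <- spec$significance_threshold %||% (0.05 / nrow(assoc))
    thr_y <- -log10(thr)
  }
  keep <- is.finite(yv)
  co <- genome_coords(assoc$chrom[keep], assoc$pos[keep])
  pal <- c("#26547C", "#EF8354")
  with_device(spec, {
    graphics::par(mar = c(4, 4, 2, 1))
    graphics::plot(co$x, yv[keep], pch = 20, cex = 0.6,
                   col = pal[1 + co$chrom_index %% 2],
                   xlab = "genome position", ylab = ylab, xaxt = "n",
                   main = attr(assoc, "method") %||% "")
    graphics::axis(1, at = co$centers, labels = co$labels)
    if (!is.na(thr_y))
      graphics::abline(h = thr_y, col = "red3", lty = 2)
  })
  summary <- list(n_points = sum(keep),
                  threshold_line_y = thr_y,
                  n_above = if (is.na(thr_y)) NA_integer_
                            else sum(yv[keep] > thr_y))
  write_sidecar(spec, summary)
  invisible(summary)
}

#' @export
plot.assoc_result <- function(x, path = tempfile(fileext = ".svg"), ...) {
  manhattan_plot(x, plot_spec(path, ...))
}

#' QQ plot of association p-values
#'
#' Observed `-log10(p)` against expected quantiles `-log10((i - 0.5) / n)`
#' for sorted ranks, annotated with the genomic inflation factor from
#' [genomic_inflation()].
#'
#' @param p_values vector of p-values in `(0, 1]`.
#' @param spec a [plot_spec()].
#' @return (invisibly) list `lambda_gc`, `max_observed`, `max_expected`;
#'   also written as a JSON sidecar.
#' @export
qq_plot <- function(p_values, spec) {
  lambda <- genomic_inflation(p_values)  # validates the input
  n <- length(p_values)
  exp_q <- -log10((seq_len(n) - 0.5) / n)
  obs_q <- -log10(sort(p_values))
  with_device(spec, {
    graphics::par(mar = c(4, 4, 2, 1))
    graphics::plot(rev(exp_q), rev(obs_q), pch = 20, cex = 0.6,
                   xlab = expression(Expected ~ -log[10](italic(p))),
                   ylab = expression(Observed ~ -log[10](italic(p))))
    graphics::abline(0, 1, col = "red3")
    graphics::legend("topleft", bty = "n",
                     legend = bquote(lambda[GC] == .(round(lambda, 3))))
  })
  summary <- list(lambda_gc = lambda, max_observed = max(obs_q),
                  max_expected = max(exp_q))
  write_sidecar(spec, summary)
  invisible(summary)
}

#' Genomic-prediction evaluation plots
#'
#' Writes a predicted-vs-observed correlation scatter (identity and
#' least-squares lines, annotated Pearson r) and a Bland-Altman plot with
#' the bias and limits-of-agreement lines. All annotated numbers are taken
#' from the `gp_result` attributes; nothing is recomputed here.
#'
#' @param pred a `gp_result` from [gp_holdout()].
#' @param spec a [plot_spec()]; `spec$path` is used as a stem, producing
#'   `<stem>_correlation.<fmt>` and `<stem>_bland_altman.<fmt>`.
#' @return (invisibly) list `pearson_r`, `bland_altman`, `files`.
#' @export
gp_plots <- function(pred, spec) {
  stopifnot(inherits(pred, "gp_result"))
  r <- attr(pred, "pearson_r")
  ba <- attr(pred, "bland_altman")
  stem <- sub("\\.(svg|png)$", "", spec$path, ignore.case = TRUE)
  f_corr <- paste0(stem, "_correlation.", spec$format)
  f_ba <- paste0(stem, "_bland_altman.", spec$format)

  sc <- spec; sc$path <- f_corr
  with_device(sc, {
    graphics::par(mar = c(4, 4, 2, 1))
    graphics::plot(pred$observed, pred$predicted, pch = 19,
                   col = "#26547C", xlab = "observed phenotype",
                   ylab = "predicted phenotype",
                   main = attr(pred, "method"))
    graphics::abline(0, 1, col = "grey60", lty = 2)
    if (stats::sd(pred$observed) > 0)
      graphics::abline(stats::lm(predicted ~ observed, data = pred),
                       col = "red3")
    graphics::legend("topleft", bty = "n",
                     legend = paste0("Pearson r = ", format(r, digits = 3)))
  })
  sb <- spec; sb$path <- f_ba
  with_device(sb, {
    graphics::par(mar = c(4, 4, 2, 1))
    graphics::plot(ba$points$mean, ba$points$difference, pch = 19,
                   col = "#26547C", xlab = "mean of predicted and observed",
                   ylab = "difference (predicted - observed)",
                   main = "Bland-Altman")
    graphics::abline(h = ba$bias, col = "red3")
    graphics::abline(h = c(ba$loa_low, ba$loa_high), col = "red3", lty = 2)
  })
  summary <- list(pearson_r = r,
                  bland_altman = ba[c("bias", "sd_diff", "loa_low",
                                      "loa_high")],
                  files = c(f_corr, f_ba))
  write_sidecar(sc, summary)
  invisible(summary)
}

#' Genotype/phenotype data-report panels
#'
#' Renders the summary panels from already-computed typed results: MAF
#' histogram, per-chromosome marker density, per-sample heterozygosity,
#' PCA scatter, hierarchically clustered kinship heatmap, heritability bar
#' with the delta profile-likelihood curve, and a phenotype histogram.
#' No statistic is computed inside this layer; each panel echoes the
#' numbers of the object it is given.
#'
#' @param dir output directory.
#' @param summary a [genotype_summary()] result.
#' @param pca optional [compute_pca()] result.
#' @param K optional `kinship` matrix (heatmap ordered by
#'   [cluster_order()]).
#' @param fit optional `lmm_fit` (heritability panel).
#' @param phenotype optional numeric phenotype vector (histogram).
#' @param format `"svg"` or `"png"`.
#' @return (invisibly) list of written file paths plus the pass-through
#'   values used (`maf_counts`, `heatmap_order`, `h2`).
#' @export
data_reports <- function(dir, summary = NULL, pca = NULL, K = NULL,
                         fit = NULL, phenotype = NULL, format = "svg") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  out <- list()
  mk <- function(name) plot_spec(file.path(dir, paste0(name, ".", format)),
                                 format = format)
  if (!is.null(summary)) {
    sp <- mk("maf_histogram")
    with_device(sp, {
      mh <- summary$maf_hist
      graphics::barplot(mh$counts, names.arg = sprintf("%.2f",
                                                       utils::head(mh$breaks, -1)),
                        col = "#26547C", xlab = "MAF bin (lower edge)",
                        ylab = "variants", main = "MAF spectrum")
    })
    files <- c(files, sp$path)
    out$maf_counts <- summary$maf_hist$counts

    sp <- mk("marker_density")
    with_device(sp, {
      nchr <- length(summary$density)
      graphics::par(mfrow = c(nchr, 1), mar = c(2, 4, 1.5, 1))
      for (chr in names(summary$density)) {
        dd <- summary$density[[chr]]
        graphics::barplot(dd$counts, col = "#EF8354", border = NA,
                          main = paste("chr", chr), ylab = "variants")
      }
    })
    files <- c(files, sp$path)

    sp <- mk("heterozygosity")
    with_device(sp, {
      graphics::hist(summary$het, breaks = 20, col = "#26547C",
                     xlab = "per-sample heterozygosity", main = "")
    })
    files <- c(files, sp$path)
  }
  if (!is.null(pca)) {
    sp <- mk("pca")
    with_device(sp, {
      ve <- 100 * pca$variance_explained
      graphics::plot(pca$scores[, 1], pca$scores[, 2], pch = 19,
                     col = "#26547C",
                     xlab = sprintf("PC1 (%.1f%%)", ve[1]),
                     ylab = sprintf("PC2 (%.1f%%)", ve[2]))
    })
    files <- c(files, sp$path)
  }
  if (!is.null(K)) {
    ord <- cluster_order(K)
    sp <- mk("kinship_heatmap")
    with_device(sp, {
      Ko <- unclass(K)[ord, ord]
      graphics::image(seq_len(nrow(Ko)), seq_len(ncol(Ko)),
                      Ko[, rev(seq_len(ncol(Ko)))],
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                      xlab = "", ylab = "", axes = FALSE,
                      main = "clustered kinship")
    })
    files <- c(files, sp$path)
    out$heatmap_order <- ord
  }
  if (!is.null(fit)) {
    sp <- mk("heritability")
    with_device(sp, {
      graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
      graphics::barplot(fit$h2, ylim = c(0, 1), col = "#26547C",
                        names.arg = "h2", ylab = "pseudo-heritability")
      pr <- fit$profile
      graphics::plot(log10(pr$delta), pr$loglik, type = "l",
                     xlab = expression(log[10](delta)),
                     ylab = "REML log-likelihood")
      graphics::abline(v = log10(fit$delta), col = "red3", lty = 2)
    })
    files <- c(files, sp$path)
    out$h2 <- fit$h2
  }
  if (!is.null(phenotype)) {
    sp <- mk("phenotype_histogram")
    with_device(sp, {
      graphics::hist(phenotype[is.finite(phenotype)], breaks = 20,
                     col = "#EF8354", xlab = "phenotype", main = "")
    })
    files <- c(files, sp$path)
  }
  out$files <- files
  invisible(out)
}
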