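#' Conditional Q-Q series
#'
#' For each conditioning threshold, restricts the joined SNP set to
#' `-log10(p2) >= threshold` and computes the Q-Q curve of the primary trait:
#' y = -log10 nominal p, x = -log10 empirical cdf value q = N_p/N within the
#' subset. Under the global null the curve lies on x = y in expectation;
#' pleiotropic enrichment appears as successive leftward deflections with
#' increasing threshold. Points are restricted to y below `y_max` (default
#' 7.3, i.e. above the genome-wide significance level 5e-8) to focus on the
#' sub-threshold polygenic signal.
#'
#' @param joined Joined table from [join_sumstats()].
#' @param thresholds Conditioning thresholds on the -log10(p2) scale
#'   (default `c(0, 1, 2, 3)`).
#' @param y_max Upper bound on -log10 p1 for plotted points (default 7.3).
#' @param min_subset_size Series from subsets smaller than this are flagged in
#'   the `flagged` column but still returned (default 100).
#' @param primary Primary trait (1 or 2).
#' @return Tibble with columns `threshold`, `x`, `y`, `n_subset`, `flagged`,
#'   sorted by x within each threshold.
#' @export
conditional_qq <- function(joined, thresholds = c(0, 1, 2, 3), y_max = 7.3,
                           min_subset_size = 100, primary = 1) {
  out <- vector("list", length(thresholds))
  for (k in seq_along(thresholds)) {
    sub <- conditional_subset(joined, thresholds[k],
                              secondary = if (primary == 1) 2 else 1)
    p <- if (primary == 1) sub$p1 else sub$p2
    n_sub <- length(p)
    if (n_sub == 0L) {
      out[[k]] <- tibble::tibble(threshold = thresholds[k], x = numeric(),
                                 y = numeric(), n_subset = integer(),
                                 flagged = logical())
      next
    }
    cdf <- p_ecdf(p)
    pu <- sort(unique(p))
    q <- ecdf_evaluate(cdf, pu)
    y <- -log10(pu)
    x <- -log10(q)
    keep <- y < y_max
    ord <- order(x[keep])
    out[[k]] <- tibble::tibble(
      threshold = thresholds[k],
      x = x[keep][ord], y = y[keep][ord],
      n_subset = n_sub,
      flagged = n_sub < min_subset_size
    )
  }
  do.call(rbind, out)
}

#' Conditional TDR curves from Q-Q series
#'
#' Pointwise conservative true discovery rate `TDR = 1 - p/q` (clipped to
#' \[0, 1\]) along each conditional Q-Q series.
#'
#' @param qq Tibble from [conditional_qq()].
#' @return Tibble with `threshold`, `p`, `q`, `tdr`.
#' @export
tdr_curves <- function(qq) {
  p <- 10^(-qq$y)
  q <- 10^(-qq$x)
  tibble::tibble(
    threshold = qq$threshold, p = p, q = q,
    tdr = pmin(pmax(1 - p / q, 0), 1)
  )
}

#' Plot conditional Q-Q curves
#'
#' @param qq Tibble from [conditional_qq()].
#' @return A ggplot object (x = -log10 empirical quantile, y = -log10 nominal
#'   p, one curve per conditioning threshold, dotted null line x = y).
#' @export
plot_qq <- function(qq) {
  qq$series <- factor(qq$threshold,
                      labels = paste0("-log10(p2) >= ",
                                      sort(unique(qq$threshold))))
  ggplot2::ggplot(qq, ggplot2::aes(x = x, y = y, colour = series)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(-log[10] ~ "empirical q"),
                  y = expression(-log[10] ~ "nominal p"),
                  colour = "conditioning") +
    ggplot2::theme_minimal()
}

#' Plot conditional TDR curves
#'
#' @param curves Tibble from [tdr_curves()].
#' @return A ggplot object (x = -log10 nominal p, y = TDR).
#' @export
plot_tdr <- function(curves) {
  curves$series <- factor(curves$threshold,
                          labels = paste0("-log10(p2) >= ",
                                          sort(unique(curves$threshold))))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = -log10(p), y = tdr, colour = series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(-log[10] ~ "nominal p"),
                  y = "conditional TDR", colour = "conditioning") +
    ggplot2::theme_minimal()
}

#' Data table behind a conditional/conjunction Manhattan plot
#'
#' Assembles exactly the numbers the plot shows: per-SNP -log10 FDR with
#' significance (FDR below threshold) and representative flags taken from a
#' locus table, so the figure is a view of already-computed results and never
#' recomputes them.
#'
#' @param assignments Per-SNP tibble with `snp`, `chrom`, `pos` and the FDR
#'   column named by `fdr_col` (conditional) — for conjunction mode pass the
#'   table carrying `conjfdr`.
#' @param loci A `locus_table` from [significant_loci()] /
#'   [conjunction_loci()]; its representative SNPs are outlined.
#' @param fdr_col FDR column name (default `"condfdr_1"`).
#' @param fdr_threshold Significance threshold (default 0.05).
#' @return Tibble with `snp`, `chrom`, `pos`, `fdr`, `neglog10_fdr`,
#'   `significant`, `representative`.
#' @export
manhattan_data <- function(assignments, loci, fdr_col = "condfdr_1",
                           fdr_threshold = 0.05) {
  reps <- loci$snp[loci$representative]
  tibble::tibble(
    snp = assignments$snp,
    chrom = assignments$chrom,
    pos = assignments$pos,
    fdr = assignments[[fdr_col]],
    neglog10_fdr = -log10(assignments[[fdr_col]]),
    significant = assignments[[fdr_col]] < fdr_threshold,
    representative = assignments$snp %in% reps
  )
}

#' Manhattan plot of conditional or conjunction FDR
#'
#' y is -log10 FDR by genomic position; SNPs below the FDR threshold are drawn
#' large, LD-pruned locus representatives are outlined.
#'
#' @param md Tibble from [manhattan_data()].
#' @param fdr_threshold Significance threshold drawn as a horizontal line
#'   (default 0.05, i.e. -log10 FDR = 1.3).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(md, fdr_threshold = 0.05) {
  md$chrom_f <- factor(md$chrom, levels = unique(md$chrom[order(
    suppressWarnings(as.numeric(md$chrom)), md$chrom)]))
  md <- md[order(md$chrom_f, md$pos), ]
  md$index <- seq_len(nrow(md))
  gg <- ggplot2::ggplot(md, ggplot2::aes(x = index, y = neglog10_fdr,
                                         colour = chrom_f)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_point(data = md[md$significant, ], size = 2,
                        show.legend = FALSE) +
    ggplot2::geom_point(data = md[md$representative, ], size = 2.6,
                        shape = 21, colour = "black", fill = NA) +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "SNP (genome order)", y = expression(-log[10] ~ "FDR")) +
    ggplot2::theme_minimal()
  gg
}
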