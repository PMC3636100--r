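#' Greedy LD pruning of a ranked SNP list
#'
#' Iterates the list in the given (rank) order and keeps a SNP iff its
#' r-squared with every already-kept SNP is at or below the threshold. This is
#' the standard pruning used to reduce FDR-ranked GWAS hits to independent
#' representatives; output preserves rank order. SNP pairs absent from the LD
#' table are treated as r-squared 0.
#'
#' @param snps Character vector of SNP ids, best-ranked first.
#' @param ld An `ld_table` (see [read_ld()], [ld_table()]).
#' @param r2_threshold Prune SNPs with r-squared strictly above this value
#'   (default 0.2) to any kept SNP.
#' @return Character vector of retained SNP ids, in rank order.
#' @export
ld_prune <- function(snps, ld, r2_threshold = 0.2) {
  stopifnot(inherits(ld, "ld_table"), r2_threshold >= 0, r2_threshold <= 1)
  kept <- character(0)
  kept_set <- new.env(parent = emptyenv())
  for (s in snps) {
    nb <- ld_neighbors(ld, s, r2_threshold)
    blocked <- FALSE
    for (b in nb) {
      if (!is.null(get0(b, envir = kept_set, inherits = FALSE))) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) {
      kept <- c(kept, s)
      kept_set[[s]] <- TRUE
    }
  }
  kept
}

# rank assignments ascending by fdr, ties by smaller p, then chrom, then pos
rank_assignments <- function(df, fdr_col, p_col) {
  ord <- order(df[[fdr_col]], df[[p_col]], df$chrom, df$pos)
  df[ord, ]
}

# single-linkage grouping of significant SNPs over r2 > threshold
single_linkage_groups <- function(snps, ld, r2_threshold) {
  n <- length(snps)
  group <- seq_len(n)
  idx <- stats::setNames(seq_len(n), snps)
  find <- function(i) {
    while (group[i] != i) i <- group[i]
    i
  }
  for (i in seq_len(n)) {
    nb <- ld_neighbors(ld, snps[i], r2_threshold)
    for (b in nb) {
      j <- unname(idx[b])
      if (!is.na(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) group[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Independent significant loci from per-SNP FDR assignments
#'
#' Filters to SNPs below the FDR threshold, ranks them ascending by FDR (ties
#' broken by smaller nominal p, then chromosome and position), LD-prunes the
#' ranked list, and groups the significant SNPs into loci by single linkage
#' over r-squared above the pruning threshold. Every significant SNP is listed
#' under its locus; the pruned survivor (minimum FDR in its LD group) is
#' flagged as the representative. Loci are numbered consecutively in genome
#' order (chromosome, then position of the representative).
#'
#' @param assignments Tibble with columns `snp`, `chrom`, `pos`, a p-value
#'   column and an FDR column (see `fdr_col`, `p_col`).
#' @param ld An `ld_table`.
#' @param fdr_threshold Report SNPs with FDR strictly below this (default
#'   0.05).
#' @param r2_threshold LD pruning threshold (default 0.2).
#' @param fdr_col,p_col Names of the FDR and p-value columns (defaults
#'   `"condfdr_1"`, `"p1"`).
#' @return A `locus_table` tibble: `locus`, `snp`, `chrom`, `pos`, the p and
#'   FDR columns, `representative` (logical). Empty (zero-row) when nothing is
#'   significant.
#' @export
significant_loci <- function(assignments, ld, fdr_threshold = 0.05,
                             r2_threshold = 0.2, fdr_col = "condfdr_1",
                             p_col = "p1") {
  if (nrow(assignments) == 0L) stop("empty assignment table", call. = FALSE)
  sig <- assignments[assignments[[fdr_col]] < fdr_threshold, ]
  if (nrow(sig) == 0L) {
    out <- tibble::tibble(locus = integer(), snp = character(),
                          chrom = character(), pos = integer())
    out[[p_col]] <- numeric(); out[[fdr_col]] <- numeric()
    out$representative <- logical()
    class(out) <- c("locus_table", class(out))
    return(out)
  }
  sig <- rank_assignments(sig, fdr_col, p_col)
  reps <- ld_prune(sig$snp, ld, r2_threshold)
  groups <- single_linkage_groups(sig$snp, ld, r2_threshold)
  sig$representative <- sig$snp %in% reps
  # genome-order locus numbering by each group's representative
  grp_ids <- unique(groups)
  rep_row <- vapply(grp_ids, function(g) which(groups == g)[1], integer(1))
  ord <- order(sig$chrom[rep_row], sig$pos[rep_row])
  locus_of_group <- stats::setNames(seq_along(grp_ids), grp_ids[ord])
  sig$locus <- unname(locus_of_group[as.character(groups)])
  keep_cols <- c("locus", "snp", "chrom", "pos", p_col, fdr_col,
                 "representative")
  extra <- setdiff(names(sig), keep_cols)
  out <- sig[order(sig$locus, sig[[fdr_col]]), c(keep_cols, extra)]
  class(out) <- c("locus_table", class(out))
  out
}

#' Pleiotropic loci via the conjunction FDR
#'
#' Computes the per-SNP conjunction FDR as the maximum of the two conditional
#' FDRs and reports independent loci below the threshold, carrying both
#' traits' z-scores and the allele columns so opposite-direction effects remain
#' visible (they are reported, never dropped).
#'
#' @param assignments Tibble over the joined SNP set with columns `condfdr_1`,
#'   `condfdr_2`, `p1`, `p2`, `z1`, `z2`, `a1`, `a2` (see [condfdr_assign()]).
#' @inheritParams significant_loci
#' @return A `locus_table` with a `conjfdr` column.
#' @export
conjunction_loci <- function(assignments, ld, fdr_threshold = 0.05,
                             r2_threshold = 0.2) {
  assignments$conjfdr <- conjunction_fdr(assignments$condfdr_1,
                                         assignments$condfdr_2)
  significant_loci(assignments, ld, fdr_threshold, r2_threshold,
                   fdr_col = "conjfdr", p_col = "p1")
}

#' Count independent loci with a significant member
#'
#' For a table already grouped into loci (a `locus` column), counts the loci
#' whose FDR column contains at least one value below the threshold.
#'
#' @param tbl Data frame with a `locus` column and the FDR column.
#' @param fdr_col Name of the FDR column.
#' @param threshold Significance threshold (default 0.05).
#' @return Integer count of distinct loci.
#' @export
count_significant_loci <- function(tbl, fdr_col, threshold = 0.05) {
  hit <- tbl[[fdr_col]] < threshold
  length(unique(tbl$locus[hit]))
}
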