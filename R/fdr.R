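#' Empirical cdf of a p-value set
#'
#' The estimator `q = N_p / N`, where `N_p` counts p-values less than or equal
#' to the evaluation point (ties inclusive) and `N` is the subset size. This is
#' the empirical quantile plotted on the x-axis of the Q-Q diagnostics and the
#' denominator of the conservative FDR estimate p/q.
#'
#' @param pvals Non-empty numeric vector of p-values.
#' @return An object of class `p_ecdf` with fields `sorted_p` and `n`.
#' @seealso [ecdf_evaluate()]
#' @export
p_ecdf <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0L) {
    stop("cannot build an empirical cdf from an empty p-value set",
         call. = FALSE)
  }
  structure(list(sorted_p = sort(pvals), n = length(pvals)), class = "p_ecdf")
}

#' @export
print.p_ecdf <- function(x, ...) {
  cat("<p_ecdf> over", x$n, "p-value(s)\n")
  invisible(x)
}

#' Evaluate an empirical cdf
#'
#' @param cdf A `p_ecdf`.
#' @param p Numeric vector of evaluation points.
#' @return `(# stored p-values <= p) / n`, vectorised over `p`.
#' @export
ecdf_evaluate <- function(cdf, p) {
  stopifnot(inherits(cdf, "p_ecdf"))
  findInterval(p, cdf$sorted_p) / cdf$n
}

#' Subset one trait's SNPs by their p-value in the other trait
#'
#' Returns the rows of a joined table whose secondary p-value satisfies
#' `-log10(p2) >= threshold` (equivalently `p2 <= 10^-threshold`, ties
#' inclusive). Subsets are cumulative, not disjoint strata: a stricter
#' threshold's subset is nested within every looser one.
#'
#' @param joined Joined table from [join_sumstats()] (columns `p1`, `p2`).
#' @param threshold Conditioning cutoff on the -log10(p2) scale; 0 keeps all.
#' @param secondary Which trait conditions the subset: `2` (default, condition
#'   on `p2`) or `1`.
#' @return The subset of `joined` rows.
#' @export
conditional_subset <- function(joined, threshold, secondary = 2) {
  if (nrow(joined) == 0L) stop("empty joined SNP set", call. = FALSE)
  p_cond <- if (secondary == 2) joined$p2 else joined$p1
  joined[-log10(p_cond) >= threshold, ]
}

#' Conservative FDR estimate p/q
#'
#' The Empirical Bayes FDR estimate obtained by replacing the p-value cdf with
#' its empirical counterpart and setting the null proportion to one:
#' `min(p/q, 1)`. It is biased upward (conservative) relative to the Bayes FDR.
#' Cells with `q = 0` (p below the subset's smallest p-value) return 1 with a
#' warning, again conservatively.
#'
#' @param p Nominal p-value(s).
#' @param q Matched empirical cdf value(s) `N_p/N`.
#' @return FDR estimate(s) in (0, 1].
#' @export
fdr_estimate <- function(p, q) {
  stopifnot(length(p) == length(q) || length(p) == 1L || length(q) == 1L)
  out <- ifelse(q > 0, pmin(p / q, 1), 1)
  if (any(q == 0)) {
    warning("q = 0 for ", sum(q == 0), " point(s); returning FDR 1 ",
            "(conservative)", call. = FALSE)
  }
  out
}

#' Conservative TDR estimate 1 - p/q
#'
#' @inheritParams fdr_estimate
#' @return TDR estimate(s) in \[0, 1).
#' @export
tdr_estimate <- function(p, q) {
  1 - suppressWarnings(fdr_estimate(p, q))
}

#' Build a two-dimensional conditional FDR look-up table
#'
#' For every grid node `(grid1[i], grid2[j])` the table holds the conservative
#' conditional FDR of the primary trait at nominal p-value `10^-grid1[i]`,
#' estimated from the empirical cdf of primary p-values restricted to SNPs with
#' `-log10(p2) >= grid2[j]`. The null proportion is set to one throughout.
#' Conditioning columns whose subset holds fewer than `min_subset_size` SNPs
#' inherit the nearest looser (smaller threshold) populated column and are
#' flagged; `q = 0` cells get FDR 1 and are flagged.
#'
#' @param joined Joined table from [join_sumstats()].
#' @param grid1 Strictly increasing -log10 p thresholds for the primary trait
#'   (default 0 to 10 by 0.1).
#' @param grid2 Strictly increasing -log10 p conditioning thresholds for the
#'   secondary trait (same default).
#' @param min_subset_size Minimum SNPs per conditioning subset (default 100).
#' @param primary Which trait is primary: `1` (default; conditions on `p2`)
#'   or `2`.
#' @return A `cond_fdr_table`: grids, FDR value matrix
#'   (`length(grid1) x length(grid2)`), flag matrices `inherited` (columns
#'   filled from a looser threshold) and `q_zero`, and per-column subset sizes.
#' @export
build_lookup <- function(joined, grid1 = seq(0, 10, by = 0.1),
                         grid2 = seq(0, 10, by = 0.1),
                         min_subset_size = 100, primary = 1) {
  if (nrow(joined) == 0L) stop("empty joined SNP set", call. = FALSE)
  if (is.unsorted(grid1, strictly = TRUE) ||
      is.unsorted(grid2, strictly = TRUE)) {
    stop("grids must be strictly increasing", call. = FALSE)
  }
  p_primary <- if (primary == 1) joined$p1 else joined$p2
  p_cond <- if (primary == 1) joined$p2 else joined$p1
  neglog_cond <- -log10(p_cond)
  p_eval <- 10^(-grid1)

  n1 <- length(grid1); n2 <- length(grid2)
  values <- matrix(NA_real_, n1, n2)
  q_zero <- matrix(FALSE, n1, n2)
  inherited <- logical(n2)
  n_subset <- integer(n2)

  last_good <- NA_integer_
  for (j in seq_len(n2)) {
    sel <- neglog_cond >= grid2[j]
    n_subset[j] <- sum(sel)
    if (n_subset[j] >= min_subset_size) {
      cdf <- p_ecdf(p_primary[sel])
      q <- ecdf_evaluate(cdf, p_eval)
      values[, j] <- suppressWarnings(fdr_estimate(p_eval, q))
      q_zero[, j] <- q == 0
      last_good <- j
    } else if (!is.na(last_good)) {
      values[, j] <- values[, last_good]
      q_zero[, j] <- q_zero[, last_good]
      inherited[j] <- TRUE
    } else {
      inherited[j] <- TRUE  # filled after the loop if any column succeeded
    }
  }
  if (is.na(last_good)) {
    stop("every conditioning subset has fewer than ", min_subset_size,
         " SNPs; cannot build the look-up table", call. = FALSE)
  }
  # leading under-populated columns (possible when grid2[1] > 0)
  for (j in seq_len(n2)) {
    if (anyNA(values[, j])) {
      values[, j] <- values[, last_good]
      q_zero[, j] <- q_zero[, last_good]
    }
  }
  structure(
    list(grid1 = grid1, grid2 = grid2, values = values,
         inherited = inherited, q_zero = q_zero, n_subset = n_subset,
         pi0_assumption = 1, min_subset_size = min_subset_size,
         primary = primary),
    class = "cond_fdr_table"
  )
}

#' @export
print.cond_fdr_table <- function(x, ...) {
  cat(sprintf(paste0("<cond_fdr_table> %d x %d grid, primary trait %d, ",
                     "%d inherited column(s)\n"),
              length(x$grid1), length(x$grid2), x$primary, sum(x$inherited)))
  invisible(x)
}

#' Interpolate a conditional FDR from the look-up table
#'
#' Bilinear interpolation of log10(FDR) in the `(-log10 p1, -log10 p2)` plane,
#' clamped to the table boundary outside the grid; queries at grid nodes return
#' the node value exactly.
#'
#' @param table A `cond_fdr_table` from [build_lookup()].
#' @param p1 Primary-trait p-value(s).
#' @param p2 Secondary-trait p-value(s) (recycled against `p1`).
#' @return Conditional FDR value(s) in (0, 1].
#' @export
lookup_fdr <- function(table, p1, p2) {
  stopifnot(inherits(table, "cond_fdr_table"))
  n <- max(length(p1), length(p2))
  x <- rep_len(-log10(p1), n)
  y <- rep_len(-log10(p2), n)
  g1 <- table$grid1; g2 <- table$grid2
  x <- pmin(pmax(x, g1[1]), g1[length(g1)])
  y <- pmin(pmax(y, g2[1]), g2[length(g2)])
  # snap to grid values so p = 10^-g round-trips to the node exactly
  snap <- function(v, g, tol = 1e-9) {
    k <- pmin(pmax(findInterval(v + tol, g), 1L), length(g))
    hit <- abs(v - g[k]) <= tol
    v[hit] <- g[k][hit]
    v
  }
  x <- snap(x, g1)
  y <- snap(y, g2)
  i <- pmin(pmax(findInterval(x, g1), 1L), length(g1) - 1L)
  j <- pmin(pmax(findInterval(y, g2), 1L), length(g2) - 1L)
  tx <- (x - g1[i]) / (g1[i + 1L] - g1[i])
  ty <- (y - g2[j]) / (g2[j + 1L] - g2[j])
  lv <- log10(table$values)
  v00 <- lv[cbind(i, j)]
  v10 <- lv[cbind(i + 1L, j)]
  v01 <- lv[cbind(i, j + 1L)]
  v11 <- lv[cbind(i + 1L, j + 1L)]
  interp <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  out <- pmin(10^interp, 1)
  # queries sitting exactly on a node return the stored value bit-identically
  node_i <- match(x, g1)
  node_j <- match(y, g2)
  hit <- !is.na(node_i) & !is.na(node_j)
  out[hit] <- table$values[cbind(node_i[hit], node_j[hit])]
  out
}

#' Conjunction FDR via the maximum rule
#'
#' The conjunction FDR — the posterior probability that a SNP is null for at
#' least one of the two traits — is conservatively estimated as the maximum of
#' the two conditional FDRs (trait 1 given trait 2, and vice versa).
#'
#' @param fdr_1_given_2 Conditional FDR of trait 1 given trait 2, in (0, 1].
#' @param fdr_2_given_1 Conditional FDR of trait 2 given trait 1, in (0, 1].
#' @return Elementwise maximum, in (0, 1].
#' @examples
#' conjunction_fdr(0.044, 0.01872)  # 0.044
#' @export
conjunction_fdr <- function(fdr_1_given_2, fdr_2_given_1) {
  for (v in list(fdr_1_given_2, fdr_2_given_1)) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0 | v > 1)) {
      stop("conditional FDR values must lie in (0, 1]", call. = FALSE)
    }
  }
  pmax(fdr_1_given_2, fdr_2_given_1)
}

#' Full conditional/conjunction FDR assignment for a SNP pair set
#'
#' Builds both directions' look-up tables and assigns each shared SNP its
#' conditional FDR in both directions plus the conjunction FDR (max rule).
#'
#' @param joined Joined table from [join_sumstats()].
#' @param grid_step Grid spacing on the -log10 p scale (default 0.1, from 0
#'   to 10 on both axes).
#' @param min_subset_size Minimum SNPs per conditioning subset (default 100).
#' @return List with `snps` (the joined tibble plus columns `condfdr_1`
#'   = FDR trait1|trait2, `condfdr_2` = FDR trait2|trait1, `conjfdr`),
#'   `table_1` and `table_2` (the two `cond_fdr_table`s).
#' @export
condfdr_assign <- function(joined, grid_step = 0.1, min_subset_size = 100) {
  grid <- seq(0, 10, by = grid_step)
  t1 <- build_lookup(joined, grid, grid, min_subset_size, primary = 1)
  t2 <- build_lookup(joined, grid, grid, min_subset_size, primary = 2)
  out <- joined
  out$condfdr_1 <- lookup_fdr(t1, joined$p1, joined$p2)
  out$condfdr_2 <- lookup_fdr(t2, joined$p2, joined$p1)
  out$conjfdr <- conjunction_fdr(out$condfdr_1, out$condfdr_2)
  list(snps = out, table_1 = t1, table_2 = t2)
}

#' Serialise a conditional FDR look-up table to delimited text
#'
#' Writes the FDR matrix with grid headers (first column = grid1, remaining
#' column names = grid2 values), preceded by optional provenance comments.
#'
#' @param table A `cond_fdr_table`.
#' @param path Output path.
#' @param header_lines Optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_lookup <- function(table, path, header_lines = NULL) {
  df <- data.frame(neglog10_p1 = table$grid1, table$values)
  names(df)[-1] <- paste0("cond_", format(table$grid2, trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
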