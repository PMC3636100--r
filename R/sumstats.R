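#' Read GWAS summary statistics
#'
#' Reads a tab/whitespace-delimited summary-statistics file with a header and
#' returns a validated tibble. Canonical column names are `SNP`, `CHR`, `BP`,
#' `A1`, `A2`, `P`, `Z` and `CATEGORY`; files using other names are mapped via
#' `column_map`. Only `SNP` and `P` are required.
#'
#' Rows with missing or unparseable p-values are dropped (and counted in a
#' message); p-values of zero (or underflowing) are clipped up to `p_floor` so
#' that -log10(p) stays finite. If a `Z` column is present, its magnitude is
#' checked against the two-sided p-value and discrepant rows (beyond 0.5%
#' relative) trigger a warning.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector or list mapping canonical names to
#'   file column names, e.g. `c(P = "pval")`.
#' @param p_floor Smallest representable p-value; p below (or equal to 0) is
#'   clipped to this floor. Default `1e-300`.
#' @return A tibble with columns `snp`, `chrom`, `pos`, `a1`, `a2`, `p`, `z`,
#'   `category` (one of `"genic"`, `"intergenic"`, `"unknown"`). Missing
#'   optional fields are `NA`. The number of dropped rows is attached as
#'   attribute `"n_dropped"`.
#' @seealso [write_sumstats()], [annotate_category()], [join_sumstats()]
#' @export
read_sumstats <- function(path, column_map = NULL, p_floor = 1e-300) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
  if (nrow(raw) == 0L) {
    stop("empty summary-statistics file: ", path, call. = FALSE)
  }
  canonical <- c("SNP", "CHR", "BP", "A1", "A2", "P", "Z", "CATEGORY")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    bad <- setdiff(names(column_map), canonical)
    if (length(bad) > 0L) {
      stop("unknown canonical column(s) in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  pick <- function(canon) {
    nm <- map[[canon]]
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  for (required in c("SNP", "P")) {
    if (!(map[[required]] %in% names(raw))) {
      stop("required column '", required, "' (file column '", map[[required]],
           "') not found in ", path, call. = FALSE)
    }
  }

  n_in <- nrow(raw)
  p <- suppressWarnings(as.numeric(pick("P")))
  keep <- !is.na(p) & p <= 1
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " row(s) with missing/unparseable p dropped from ", path)
  }
  clipped <- keep & p < p_floor
  if (any(clipped)) {
    warning(sum(clipped), " p-value(s) at or below 0 (or underflowing) ",
            "clipped to the floor ", p_floor, call. = FALSE)
    p[clipped] <- p_floor
  }

  as_chr <- function(x, n) if (is.null(x)) rep(NA_character_, n) else as.character(x)
  out <- tibble::tibble(
    snp = as.character(pick("SNP")),
    chrom = as_chr(pick("CHR"), n_in),
    pos = if (is.null(pick("BP"))) rep(NA_integer_, n_in) else as.integer(pick("BP")),
    a1 = as_chr(pick("A1"), n_in),
    a2 = as_chr(pick("A2"), n_in),
    p = p,
    z = if (is.null(pick("Z"))) rep(NA_real_, n_in) else as.numeric(pick("Z")),
    category = as_chr(pick("CATEGORY"), n_in)
  )[keep, ]
  out$category[is.na(out$category)] <- "unknown"
  bad_cat <- !out$category %in% c("genic", "intergenic", "unknown")
  if (any(bad_cat)) {
    warning(sum(bad_cat), " unrecognised CATEGORY value(s) set to 'unknown'",
            call. = FALSE)
    out$category[bad_cat] <- "unknown"
  }
  if (anyDuplicated(out$snp)) {
    dup <- unique(out$snp[duplicated(out$snp)])
    warning(length(dup), " duplicated SNP id(s); keeping first occurrence",
            call. = FALSE)
    out <- out[!duplicated(out$snp), ]
  }
  # cross-check Z against P where both given
  have_z <- !is.na(out$z)
  if (any(have_z)) {
    p_from_z <- z_to_p(out$z[have_z])
    off <- abs(p_from_z - out$p[have_z]) > 0.005 * out$p[have_z]
    if (any(off)) {
      warning(sum(off), " row(s) where |z| and p disagree beyond 0.5% relative",
              call. = FALSE)
    }
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write GWAS summary statistics
#'
#' Writes the canonical columns (`SNP CHR BP A1 A2 P Z CATEGORY`) as
#' tab-delimited text; round-trips with [read_sumstats()].
#'
#' @param stats Tibble from [read_sumstats()] or [simulate_pair()].
#' @param path Output path.
#' @param header_lines Optional character vector of provenance lines written as
#'   `#`-prefixed comments before the table.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path, header_lines = NULL) {
  out <- data.frame(
    SNP = stats$snp, CHR = stats$chrom, BP = stats$pos,
    A1 = stats$a1, A2 = stats$a2, P = stats$p, Z = stats$z,
    CATEGORY = stats$category
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert two-sided p-values to z-scores
#'
#' `|z|` is the standard-normal upper quantile of `p/2`; the sign is taken from
#' `direction` when supplied (e.g. the sign of the effect of the A1 allele) and
#' the magnitude is returned otherwise.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param direction Optional numeric vector; only its sign is used. `NA` or 0
#'   entries leave the magnitude unsigned.
#' @return Numeric vector of z-scores.
#' @examples
#' p_to_z(0.3173105)       # ~1
#' p_to_z(3.52e-5)         # ~4.137
#' @export
p_to_z <- function(p, direction = NULL) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p must be in (0, 1]", call. = FALSE)
  }
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  z[p == 1] <- 0  # qnorm(0.5, lower=FALSE) is exactly 0 anyway; be explicit
  if (!is.null(direction)) {
    s <- sign(direction)
    s[is.na(s) | s == 0] <- 1
    z <- z * s
  }
  z
}

#' Convert z-scores to two-sided p-values
#'
#' `p = 2 * (1 - Phi(|z|))`, computed in the tail-stable form; inverse of
#' [p_to_z()] to within 1e-10 relative for p >= 1e-300.
#'
#' @param z Numeric vector of finite z-scores (sign is ignored).
#' @return Numeric vector of p-values in (0, 1].
#' @export
z_to_p <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("z must be finite", call. = FALSE)
  }
  pmin(2 * stats::pnorm(abs(z), lower.tail = FALSE), 1)
}

#' Read a PLINK-style pairwise LD table
#'
#' Consumes the `SNP_A`, `SNP_B` and `R2` columns of a PLINK `.ld` text file
#' (extra columns such as `CHR_A`/`BP_A` are ignored). The table is symmetric
#' by construction; duplicated pairs keep the maximum r-squared and self-pairs
#' are dropped. Absent pairs are treated as r-squared 0 by [ld_r2()].
#'
#' @param path Path to the `.ld` file (header required). An empty file (header
#'   only, or zero bytes) yields a valid empty table.
#' @return An object of class `ld_table`.
#' @seealso [ld_r2()], [ld_prune()]
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("LD file not found: ", path, call. = FALSE)
  info <- file.info(path)
  if (info$size == 0) return(ld_table(character(), character(), numeric()))
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0L) return(ld_table(character(), character(), numeric()))
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(raw))) {
    stop("LD file must have columns SNP_A, SNP_B, R2: ", path, call. = FALSE)
  }
  r2 <- suppressWarnings(as.numeric(raw$R2))
  bad <- which(is.na(r2) | r2 < 0 | r2 > 1)
  if (length(bad) > 0L) {
    # +1 for the header line
    stop("R2 outside [0,1] (or unparseable) at line ", bad[1] + 1L, " of ",
         path, call. = FALSE)
  }
  ld_table(as.character(raw$SNP_A), as.character(raw$SNP_B), r2)
}

#' Construct an LD table from pair vectors
#'
#' @param snp_a,snp_b Character vectors of SNP ids (unordered pairs).
#' @param r2 Numeric vector of squared correlations in \[0, 1\].
#' @return An `ld_table`: a data frame of normalised unique pairs with max-r2
#'   de-duplication, plus a prebuilt adjacency index for fast neighbour lookup.
#' @export
ld_table <- function(snp_a, snp_b, r2) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_b) == length(r2))
  keep <- snp_a != snp_b  # self-pairs carry no pruning information
  snp_a <- snp_a[keep]; snp_b <- snp_b[keep]; r2 <- r2[keep]
  lo <- pmin(snp_a, snp_b)
  hi <- pmax(snp_a, snp_b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    r2 <- tapply(r2, key, max)
    pairs <- do.call(rbind, strsplit(names(r2), "\r", fixed = TRUE))
    lo <- pairs[, 1]; hi <- pairs[, 2]; r2 <- unname(r2)
    key <- paste(lo, hi, sep = "\r")
  }
  adjacency <- NULL
  if (length(lo) > 0L) {
    adjacency <- split(
      data.frame(other = c(hi, lo), r2 = c(r2, r2), stringsAsFactors = FALSE),
      c(lo, hi)
    )
  }
  structure(
    list(pairs = data.frame(snp_a = lo, snp_b = hi, r2 = r2,
                            stringsAsFactors = FALSE),
         key = key, adjacency = adjacency),
    class = "ld_table"
  )
}

#' @export
print.ld_table <- function(x, ...) {
  cat("<ld_table> with", nrow(x$pairs), "SNP pair(s)\n")
  invisible(x)
}

#' Query pairwise r-squared
#'
#' @param ld An `ld_table`.
#' @param snp_a,snp_b Character vectors (recycled) of SNP ids.
#' @return Numeric vector of r-squared values; unordered pair lookup, absent
#'   pairs give 0.
#' @export
ld_r2 <- function(ld, snp_a, snp_b) {
  stopifnot(inherits(ld, "ld_table"))
  key <- paste(pmin(snp_a, snp_b), pmax(snp_a, snp_b), sep = "\r")
  idx <- match(key, ld$key)
  out <- ld$pairs$r2[idx]
  out[is.na(out)] <- 0
  out
}

# neighbours of one SNP with r2 above a threshold (internal)
ld_neighbors <- function(ld, snp, r2_threshold = 0) {
  adj <- ld$adjacency[[snp]]
  if (is.null(adj)) return(character())
  adj$other[adj$r2 > r2_threshold]
}

#' Read a BED3 file of genic intervals
#'
#' BED is 0-based, half-open. Lines must have at least three fields
#' (chrom, start, end); additional fields are ignored. A malformed line raises
#' an input error naming the line.
#'
#' @param path Path to a BED3 text file (no header).
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop("malformed BED line ", i, " (need >= 3 fields): ", path,
           call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0L || end < start) {
      stop("malformed BED line ", i, " (bad coordinates): ", path,
           call. = FALSE)
    }
    out[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Annotate SNPs as genic or intergenic
#'
#' A SNP at 1-based position `x` is genic iff `x - 1` falls inside a 0-based
#' half-open genic interval on the same chromosome; all other SNPs are
#' intergenic. The result is independent of interval order and of overlaps
#' among intervals.
#'
#' @param stats Summary-statistics tibble (needs `chrom` and `pos`).
#' @param regions Genic intervals: a data frame with `chrom`, `start`, `end`
#'   (BED convention) as returned by [read_bed()], or a path to a BED3 file.
#' @return `stats` with the `category` column set to `"genic"`/`"intergenic"`.
#' @export
annotate_category <- function(stats, regions) {
  if (is.character(regions) && length(regions) == 1L) {
    regions <- read_bed(regions)
  }
  genic <- rep(FALSE, nrow(stats))
  if (nrow(regions) > 0L) {
    if (any(is.na(stats$chrom)) || any(is.na(stats$pos))) {
      stop("annotation requires chrom and pos for every SNP", call. = FALSE)
    }
    for (chr in unique(regions$chrom)) {
      on_chr <- which(stats$chrom == chr)
      if (length(on_chr) == 0L) next
      reg <- regions[regions$chrom == chr & regions$end > regions$start, ]
      if (nrow(reg) == 0L) next
      # BED [start, end) 0-based == 1-based closed [start+1, end]
      iv <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
      qs <- IRanges::IRanges(start = stats$pos[on_chr], width = 1L)
      hit <- IRanges::overlapsAny(qs, iv)
      genic[on_chr] <- hit
    }
  }
  stats$category <- ifelse(genic, "genic", "intergenic")
  stats
}

#' Join two traits' summary statistics by SNP id
#'
#' Takes the intersection of the two SNP sets by id (counts are reported in a
#' message) and returns one row per shared SNP. Alleles are carried from the
#' first trait; pairs whose a1/a2 disagree across traits (ignoring order) are
#' kept with a warning, matching an id-based join with no allele harmonisation.
#'
#' @param trait1,trait2 Summary-statistics tibbles (see [read_sumstats()]).
#' @return Tibble with columns `snp`, `chrom`, `pos`, `a1`, `a2`, `category`
#'   (from trait 1), `p1`, `z1`, `p2`, `z2`.
#' @export
join_sumstats <- function(trait1, trait2) {
  shared <- intersect(trait1$snp, trait2$snp)
  if (length(shared) == 0L) {
    stop("no SNP ids shared between the two traits", call. = FALSE)
  }
  message(length(shared), " shared SNP(s); ",
          nrow(trait1) - length(shared), " only in trait 1, ",
          nrow(trait2) - length(shared), " only in trait 2")
  i1 <- match(shared, trait1$snp)
  i2 <- match(shared, trait2$snp)
  mismatch <- !is.na(trait1$a1[i1]) & !is.na(trait2$a1[i2]) &
    !((trait1$a1[i1] == trait2$a1[i2] & trait1$a2[i1] == trait2$a2[i2]) |
        (trait1$a1[i1] == trait2$a2[i2] & trait1$a2[i1] == trait2$a1[i2]))
  if (any(mismatch)) {
    warning(sum(mismatch), " SNP(s) with discordant alleles across traits ",
            "(kept; join is by id only)", call. = FALSE)
  }
  tibble::tibble(
    snp = shared,
    chrom = trait1$chrom[i1],
    pos = trait1$pos[i1],
    a1 = trait1$a1[i1],
    a2 = trait1$a2[i1],
    category = trait1$category[i1],
    p1 = trait1$p[i1],
    z1 = trait1$z[i1],
    p2 = trait2$p[i2],
    z2 = trait2$z[i2]
  )
}
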