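#' Simulation parameters for paired GWAS summary statistics
#'
#' Defines a four-groups generative scenario for two traits' z-scores: each
#' SNP belongs to one of four components (null/null, non-null trait 1 only,
#' non-null trait 2 only, non-null both) with proportions `pi`; z-scores are
#' zero-mean Gaussian with the null variance, plus the trait's extra variance
#' where non-null, and correlation `rho3` between the non-null effects in the
#' pleiotropic component. Optional per-trait inflation multiplies z by
#' sqrt(lambda). Optional LD blocks give consecutive SNPs a common component
#' and equicorrelated z-scores at the stated within-block r-squared.
#'
#' The defaults describe a highly polygenic pair of traits with ~1.2% of SNPs
#' non-null in both, null variance 1, and a non-null variance component small
#' enough that unconditional discoveries at local fdr 0.05 are rare (about 1
#' per 10^4 SNPs).
#'
#' @param n_snps Number of SNPs.
#' @param pi Four component proportions (sum to 1).
#' @param sigma0_sq Length-2 (or scalar, recycled) null variance per trait.
#' @param sigma1_sq Length-2 (or scalar) extra non-null variance per trait.
#' @param rho3 Correlation of non-null effects in the pleiotropic component,
#'   in (-1, 1).
#' @param inflation Length-2 (or scalar) genomic inflation lambda per trait.
#' @param ld_block_size SNPs per LD block (1 = no LD).
#' @param ld_r2 Within-block r-squared (used when `ld_block_size > 1`).
#' @param genic_fraction Fraction of SNPs labelled genic (rest intergenic).
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_snps = 1e5,
                              pi = c(0.97, 0.009, 0.009, 0.012),
                              sigma0_sq = c(1, 1), sigma1_sq = c(2, 2),
                              rho3 = 0, inflation = c(1, 1),
                              ld_block_size = 1, ld_r2 = 0.8,
                              genic_fraction = 0.5, seed = 42) {
  sigma0_sq <- rep_len(sigma0_sq, 2)
  sigma1_sq <- rep_len(sigma1_sq, 2)
  inflation <- rep_len(inflation, 2)
  if (length(pi) != 4L || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be four non-negative proportions summing to 1",
         call. = FALSE)
  }
  if (any(sigma0_sq <= 0) || any(sigma1_sq < 0)) {
    stop("variances must be positive (null) / non-negative (extra)",
         call. = FALSE)
  }
  if (abs(rho3) >= 1) stop("|rho3| must be < 1", call. = FALSE)
  if (any(inflation <= 0)) stop("inflation must be positive", call. = FALSE)
  if (ld_block_size < 1) stop("ld_block_size must be >= 1", call. = FALSE)
  structure(
    list(n_snps = as.integer(n_snps), pi = pi, sigma0_sq = sigma0_sq,
         sigma1_sq = sigma1_sq, rho3 = rho3, inflation = inflation,
         ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
         genic_fraction = genic_fraction, seed = as.integer(seed)),
    class = "simulation_params"
  )
}

# deterministic SNP id / map layout shared by simulate_pair and simulate_ld
sim_snp_map <- function(n) {
  chrom <- as.character(rep_len(rep(1:22, each = ceiling(n / 22)), n))
  pos <- integer(n)
  for (chr in unique(chrom)) {
    on <- which(chrom == chr)
    pos[on] <- seq_along(on) * 5000L  # 5 kb spacing
  }
  list(snp = paste0("rs", seq_len(n)), chrom = chrom, pos = pos)
}

#' Simulate a pair of GWAS summary-statistic sets with known truth
#'
#' Draws per-SNP (or per-LD-block) component labels from the four-groups
#' proportions, bivariate z-scores from the component's Gaussian, applies
#' optional inflation, and converts to two-sided p-values. With LD blocks of
#' size m > 1, all SNPs in a block share the component label and their
#' z-scores are equicorrelated at the block r-squared (each SNP's z is the
#' scaled shared block signal plus independent noise from the same component
#' distribution, preserving the marginal variance). Deterministic given the
#' seed.
#'
#' @param params A `simulation_params` object.
#' @return List with `trait1` and `trait2` (summary-statistics tibbles with
#'   `snp`, `chrom`, `pos`, `a1`, `a2`, `p`, `z`, `category`) and `truth`
#'   (tibble with per-SNP `component` in 0:3 and logicals `null1`, `null2`).
#' @export
simulate_pair <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_snps
  map <- sim_snp_map(n)

  block <- if (params$ld_block_size > 1) {
    rep(seq_len(ceiling(n / params$ld_block_size)),
        each = params$ld_block_size)[seq_len(n)]
  } else seq_len(n)
  n_block <- max(block)
  comp_block <- sample.int(4, n_block, replace = TRUE, prob = params$pi) - 1L
  comp <- comp_block[block]

  draw_component_z <- function(comp_vec) {
    m <- length(comp_vec)
    z <- matrix(0, m, 2)
    s0 <- params$sigma0_sq
    s1 <- params$sigma1_sq
    sd1 <- sqrt(s0[1] + ifelse(comp_vec %in% c(1L, 3L), s1[1], 0))
    sd2 <- sqrt(s0[2] + ifelse(comp_vec %in% c(2L, 3L), s1[2], 0))
    e1 <- stats::rnorm(m)
    e2 <- stats::rnorm(m)
    # correlate the non-null effect parts in the pleiotropic component
    rho <- params$rho3
    if (rho != 0) {
      c3 <- comp_vec == 3L
      if (any(c3)) {
        u1 <- stats::rnorm(sum(c3))
        u2 <- rho * u1 + sqrt(1 - rho^2) * stats::rnorm(sum(c3))
        z[c3, 1] <- sqrt(s0[1]) * e1[c3] + sqrt(s1[1]) * u1
        z[c3, 2] <- sqrt(s0[2]) * e2[c3] + sqrt(s1[2]) * u2
      }
      rest <- !c3
      z[rest, 1] <- sd1[rest] * e1[rest]
      z[rest, 2] <- sd2[rest] * e2[rest]
    } else {
      z[, 1] <- sd1 * e1
      z[, 2] <- sd2 * e2
    }
    z
  }

  if (params$ld_block_size > 1) {
    r2 <- params$ld_r2
    shared <- draw_component_z(comp_block)   # one shared signal per block
    noise <- draw_component_z(comp)          # idiosyncratic, same component
    z <- sqrt(r2) * shared[block, , drop = FALSE] + sqrt(1 - r2) * noise
  } else {
    z <- draw_component_z(comp)
  }
  z[, 1] <- z[, 1] * sqrt(params$inflation[1])
  z[, 2] <- z[, 2] * sqrt(params$inflation[2])

  category <- ifelse(stats::runif(n) < params$genic_fraction,
                     "genic", "intergenic")
  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, n, replace = TRUE)
  a2_pick <- sample(3L, n, replace = TRUE)
  a2 <- vapply(seq_len(n), function(i) setdiff(alleles, a1[i])[a2_pick[i]],
               character(1))

  mk <- function(col) tibble::tibble(
    snp = map$snp, chrom = map$chrom, pos = map$pos, a1 = a1, a2 = a2,
    p = z_to_p(z[, col]), z = z[, col], category = category
  )
  list(
    trait1 = mk(1),
    trait2 = mk(2),
    truth = tibble::tibble(
      snp = map$snp, component = comp,
      null1 = !(comp %in% c(1L, 3L)),
      null2 = !(comp %in% c(2L, 3L))
    )
  )
}

#' Simulate the matching LD table
#'
#' Consecutive SNPs are grouped into blocks of `ld_block_size`; every
#' within-block pair is assigned the stated r-squared and across-block pairs
#' are absent (r-squared 0). Matches the block structure used by
#' [simulate_pair()] for the same parameters.
#'
#' @param params A `simulation_params` object.
#' @return An `ld_table` (empty when `ld_block_size` is 1).
#' @export
simulate_ld <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  m <- params$ld_block_size
  n <- params$n_snps
  if (m <= 1L) return(ld_table(character(), character(), numeric()))
  map <- sim_snp_map(n)
  block <- rep(seq_len(ceiling(n / m)), each = m)[seq_len(n)]
  pairs_a <- character(0); pairs_b <- character(0)
  by_block <- split(map$snp, block)
  for (ids in by_block) {
    k <- length(ids)
    if (k < 2L) next
    cmb <- utils::combn(ids, 2L)
    pairs_a <- c(pairs_a, cmb[1, ])
    pairs_b <- c(pairs_b, cmb[2, ])
  }
  ld_table(pairs_a, pairs_b, rep(params$ld_r2, length(pairs_a)))
}

#' Write simulated truth labels
#'
#' @param truth Truth tibble from [simulate_pair()].
#' @param path Output path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
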