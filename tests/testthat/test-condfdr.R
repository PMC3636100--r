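test_that("the empirical cdf counts ties inclusively", {
  cdf <- p_ecdf(c(0.1, 0.2, 0.3))
  expect_equal(ecdf_evaluate(cdf, 0.2), 2 / 3)
  expect_equal(ecdf_evaluate(cdf, 0.05), 0)
  expect_equal(ecdf_evaluate(cdf, 1), 1)
  expect_error(p_ecdf(numeric()), "empty")
})

test_that("the empirical cdf equals rank/n at every sorted value", {
  set.seed(21)
  p <- runif(57)
  cdf <- p_ecdf(p)
  sp <- sort(p)
  # brute-force count oracle at every threshold
  brute <- vapply(sp, function(t) sum(p <= t) / length(p), numeric(1))
  expect_equal(ecdf_evaluate(cdf, sp), brute)
  expect_equal(ecdf_evaluate(cdf, sp), seq_along(sp) / length(sp))
  # non-decreasing
  q <- ecdf_evaluate(cdf, sort(runif(200)))
  expect_false(is.unsorted(q))
})

test_that("conditional subsets honour inclusive thresholds and nest", {
  prm <- simulation_params(n_snps = 5000, seed = 11)
  j <- simulate_joined(prm)
  s0 <- conditional_subset(j, 0)
  expect_equal(nrow(s0), nrow(j))  # threshold 0 keeps every SNP (p <= 1)
  s3 <- conditional_subset(j, 3)
  expect_true(all(s3$p2 <= 1e-3))
  subs <- lapply(c(0, 1, 2, 3), conditional_subset, joined = j)
  for (k in 2:4) {
    expect_true(all(subs[[k]]$snp %in% subs[[k - 1]]$snp))
  }
  expect_error(conditional_subset(j[0, ], 0), "empty")
})

test_that("fdr and tdr estimates follow p/q with conservative edge policy", {
  expect_equal(fdr_estimate(0.01, 0.2), 0.05)
  expect_equal(fdr_estimate(0.3, 0.3), 1)
  # -log10 FDR equals the horizontal Q-Q shift log10(q) - log10(p)
  expect_equal(-log10(fdr_estimate(0.01, 0.2)), log10(0.2) - log10(0.01))
  expect_equal(-log10(fdr_estimate(0.01, 0.2)), 1.301, tolerance = 1e-3)
  expect_warning(v <- fdr_estimate(0.01, 0), "q = 0")
  expect_equal(v, 1)
  expect_equal(tdr_estimate(0.01, 0.2), 0.95)
  expect_equal(tdr_estimate(0.3, 0.3), 0)
  p <- runif(20); q <- runif(20, 0.01, 1)
  expect_equal(tdr_estimate(p, q) + fdr_estimate(p, q), rep(1, 20))
})

test_that("look-up columns reproduce direct per-cell computation", {
  prm <- simulation_params(n_snps = 2e4, seed = 12)
  j <- simulate_joined(prm)
  grid <- seq(0, 6, by = 0.5)
  tab <- build_lookup(j, grid, grid, min_subset_size = 50)
  # column at threshold 0 is the unconditional estimate
  cdf_all <- p_ecdf(j$p1)
  p_eval <- 10^(-grid)
  expected <- suppressWarnings(
    fdr_estimate(p_eval, ecdf_evaluate(cdf_all, p_eval)))
  expect_identical(tab$values[, 1], expected)
  # a mid-grid column recomputed directly
  jcol <- 5
  sub <- j[-log10(j$p2) >= grid[jcol], ]
  cdf_sub <- p_ecdf(sub$p1)
  expected_j <- suppressWarnings(
    fdr_estimate(p_eval, ecdf_evaluate(cdf_sub, p_eval)))
  expect_identical(tab$values[, jcol], expected_j)
  expect_true(all(tab$values > 0 & tab$values <= 1))
})

test_that("independent traits give near-constant rows; pleiotropy decreasing", {
  # independent: no shared non-null component
  prm0 <- simulation_params(n_snps = 1e5, pi = c(0.98, 0.01, 0.01, 0),
                            seed = 13)
  j0 <- simulate_joined(prm0)
  grid2 <- c(0, 1, 2)
  tab0 <- build_lookup(j0, seq(0, 4, 0.5), grid2, min_subset_size = 100)
  # compare FDR at -log10 p1 = 2.5 across conditioning columns
  row <- which(tab0$grid1 == 2.5)
  vals <- tab0$values[row, ]
  expect_lt(max(abs(log(vals / vals[1]))), 0.5)  # within ~65% of each other
  # pleiotropic: conditioning enriches, FDR decreases along grid2
  prm1 <- simulation_params(n_snps = 1e5, pi = c(0.95, 0.005, 0.005, 0.04),
                            sigma1_sq = c(4, 4), seed = 14)
  j1 <- simulate_joined(prm1)
  tab1 <- build_lookup(j1, seq(0, 4, 0.5), grid2, min_subset_size = 100)
  avg <- colMeans(log10(tab1$values[tab1$grid1 >= 2, ]))
  expect_true(all(diff(avg) < 0))
})

test_that("under-populated conditioning columns inherit the looser column", {
  prm <- simulation_params(n_snps = 2000, seed = 15)
  j <- simulate_joined(prm)
  tab <- build_lookup(j, seq(0, 4, 1), seq(0, 6, 1), min_subset_size = 100)
  expect_true(any(tab$inherited))
  first_inherited <- which(tab$inherited)[1]
  expect_identical(tab$values[, first_inherited],
                   tab$values[, first_inherited - 1L])
  expect_error(build_lookup(j, seq(0, 4, 1), seq(5, 6, 1),
                            min_subset_size = 1e6), "fewer than")
})

test_that("bilinear interpolation is exact at nodes and bounded between them", {
  prm <- simulation_params(n_snps = 2e4, seed = 16)
  j <- simulate_joined(prm)
  grid <- seq(0, 5, by = 0.5)
  tab <- build_lookup(j, grid, grid, min_subset_size = 50)
  # node identity, bit-exact
  for (i in c(1, 4, 11)) {
    for (jj in c(1, 6, 11)) {
      expect_identical(lookup_fdr(tab, 10^(-grid[i]), 10^(-grid[jj])),
                       tab$values[i, jj])
    }
  }
  # midway along grid1 between equal node values returns that value
  tab2 <- tab
  tab2$values[3, 4] <- 0.25
  tab2$values[4, 4] <- 0.25
  mid_x <- 10^(-(grid[3] + grid[4]) / 2)
  expect_equal(lookup_fdr(tab2, mid_x, 10^(-grid[4])), 0.25)
  # random queries fall within the surrounding node range
  set.seed(17)
  for (k in 1:1000) {
    x <- runif(1, 0, 5); y <- runif(1, 0, 5)
    i <- findInterval(x, grid); jj <- findInterval(y, grid)
    i <- min(i, length(grid) - 1); jj <- min(jj, length(grid) - 1)
    corners <- tab$values[i:(i + 1), jj:(jj + 1)]
    v <- lookup_fdr(tab, 10^(-x), 10^(-y))
    expect_gte(v, min(corners) * (1 - 1e-12))
    expect_lte(v, max(corners) * (1 + 1e-12))
  }
  # clamping outside the grid
  expect_identical(lookup_fdr(tab, 10^-20, 10^-20),
                   tab$values[length(grid), length(grid)])
})

test_that("conjunction FDR is the exact maximum rule", {
  expect_equal(conjunction_fdr(0.044, 0.01872), 0.044)
  expect_equal(conjunction_fdr(0.038, 0.04536), 0.04536)
  x <- runif(10, 0.01, 1)
  expect_equal(conjunction_fdr(x, x), x)
  a <- runif(10, 0.01, 1); b <- runif(10, 0.01, 1)
  cj <- conjunction_fdr(a, b)
  expect_true(all(cj == a | cj == b))
  expect_true(all(cj >= pmin(a, b)))
  expect_error(conjunction_fdr(0, 0.5), "\\(0, 1\\]")
  expect_error(conjunction_fdr(0.5, 1.2), "\\(0, 1\\]")
})

test_that("condfdr_assign returns coherent per-SNP values", {
  prm <- simulation_params(n_snps = 2e4, pi = c(0.95, 0.005, 0.005, 0.04),
                           sigma1_sq = c(4, 4), seed = 18)
  j <- simulate_joined(prm)
  res <- condfdr_assign(j, grid_step = 0.25, min_subset_size = 50)
  expect_equal(res$snps$conjfdr,
               pmax(res$snps$condfdr_1, res$snps$condfdr_2))
  expect_true(all(res$snps$condfdr_1 > 0 & res$snps$condfdr_1 <= 1))
  expect_s3_class(res$table_1, "cond_fdr_table")
})
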