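test_that("a toy file reads through unchanged with unknown category", {
  path <- write_toy_sumstats(toy_sumstats_df())
  ss <- read_sumstats(path)
  expect_equal(nrow(ss), 3L)
  expect_equal(ss$snp, c("rs1", "rs2", "rs3"))
  expect_equal(ss$p, c(0.5, 1e-4, 0.01))
  expect_equal(ss$category, rep("unknown", 3))
  expect_equal(attr(ss, "n_dropped"), 0L)
})

test_that("p = 0 rows are retained with p clipped to the floor", {
  df <- toy_sumstats_df()
  df$P[2] <- 0
  path <- write_toy_sumstats(df)
  expect_warning(ss <- read_sumstats(path), "clipped")
  expect_equal(nrow(ss), 3L)
  expect_equal(ss$p[2], 1e-300)
  expect_warning(ss2 <- read_sumstats(path, p_floor = 1e-20), "clipped")
  expect_equal(ss2$p[2], 1e-20)
})

test_that("column_map renames resolve to the canonical read", {
  df <- toy_sumstats_df()
  names(df)[names(df) == "P"] <- "pval"
  path <- write_toy_sumstats(df)
  ss <- read_sumstats(path, column_map = c(P = "pval"))
  ref <- read_sumstats(write_toy_sumstats(toy_sumstats_df()))
  expect_equal(ss$p, ref$p)
  expect_equal(ss$snp, ref$snp)
})

test_that("missing required columns and empty files are named errors", {
  df <- toy_sumstats_df()
  df$P <- NULL
  expect_error(read_sumstats(write_toy_sumstats(df)), "'P'")
  empty <- tempfile()
  writeLines("SNP\tP", empty)
  expect_error(read_sumstats(empty), "empty")
})

test_that("rows with unparseable p are dropped and counted", {
  df <- toy_sumstats_df()
  df$P <- as.character(df$P)
  df$P[3] <- "not_a_number"
  path <- write_toy_sumstats(df)
  expect_message(ss <- read_sumstats(path), "1 row")
  expect_equal(nrow(ss), 2L)
  expect_equal(attr(ss, "n_dropped"), 1L)
})

test_that("write/read round-trips the canonical columns", {
  prm <- simulation_params(n_snps = 50, seed = 3)
  ss <- simulate_pair(prm)$trait1
  path <- tempfile(fileext = ".tsv")
  write_sumstats(ss, path, header_lines = "provenance test")
  back <- read_sumstats(path)
  expect_equal(back$snp, ss$snp)
  expect_equal(back$p, ss$p, tolerance = 1e-12)
  expect_equal(back$z, ss$z, tolerance = 1e-12)
  expect_equal(back$category, ss$category)
})

test_that("p_to_z reproduces published table z-scores and exact anchors", {
  # printed p-values vs their independently printed |z| counterparts
  expect_lt(abs(p_to_z(3.52e-5) - 4.137), 0.001)
  expect_lt(abs(p_to_z(2.96e-4) - 3.618), 0.001)
  expect_lt(abs(p_to_z(3.12e-3) - 2.955), 0.001)
  expect_identical(p_to_z(1), 0)
  # 2*(1 - Phi(1)) = 0.3173105...
  expect_equal(p_to_z(0.3173105), 1.000, tolerance = 1e-4)
  expect_equal(p_to_z(0.5, direction = -2), -p_to_z(0.5))
  expect_error(p_to_z(0), "\\(0, 1\\]")
  expect_error(p_to_z(1.5), "\\(0, 1\\]")
})

test_that("z_to_p is the two-sided inverse and is symmetric in sign", {
  expect_identical(z_to_p(0), 1)
  expect_equal(z_to_p(3.618), 2.96e-4, tolerance = 0.01)
  expect_identical(z_to_p(-1), z_to_p(1))
  expect_error(z_to_p(Inf), "finite")
  p <- 10^seq(-300, 0, length.out = 61)
  p[length(p)] <- 1
  expect_equal(z_to_p(p_to_z(p)), p, tolerance = 1e-10)
})

test_that("read_ld applies max-of-duplicates, drops self pairs, flags bad r2", {
  path <- write_ld_file(data.frame(SNP_A = c("A", "B", "A"),
                                   SNP_B = c("B", "A", "A"),
                                   R2 = c(0.5, 0.3, 1.0)))
  ld <- read_ld(path)
  expect_equal(ld_r2(ld, "A", "B"), 0.5)
  expect_equal(ld_r2(ld, "B", "A"), 0.5)
  expect_equal(nrow(ld$pairs), 1L)

  empty <- tempfile(fileext = ".ld")
  file.create(empty)
  ld0 <- read_ld(empty)
  expect_equal(ld_r2(ld0, "X", "Y"), 0)

  bad <- write_ld_file(data.frame(SNP_A = "A", SNP_B = "B", R2 = 1.7))
  expect_error(read_ld(bad), "line 2")
})

test_that("ld_r2 is symmetric and 0 for absent pairs", {
  ld <- ld_table(c("A", "B"), c("B", "C"), c(0.9, 0.4))
  expect_equal(ld_r2(ld, c("A", "B", "A"), c("B", "C", "C")),
               c(0.9, 0.4, 0))
  expect_equal(ld_r2(ld, "C", "B"), 0.4)
})

test_that("annotate_category follows BED coordinate conventions", {
  ss <- tibble::tibble(snp = c("s1", "s2"), chrom = c("1", "1"),
                       pos = c(100L, 100L), a1 = "A", a2 = "C",
                       p = 0.5, z = NA_real_, category = "unknown")
  # [99,100) covers 0-based 99 == 1-based 100
  reg <- data.frame(chrom = "1", start = 99L, end = 100L)
  expect_equal(annotate_category(ss, reg)$category, c("genic", "genic"))
  # [100,200) starts at 1-based 101
  reg2 <- data.frame(chrom = "1", start = 100L, end = 200L)
  expect_equal(annotate_category(ss, reg2)$category,
               c("intergenic", "intergenic"))
  none <- data.frame(chrom = character(), start = integer(), end = integer())
  expect_equal(annotate_category(ss, none)$category,
               c("intergenic", "intergenic"))
})

test_that("annotation is independent of interval order and overlap", {
  set.seed(9)
  ss <- tibble::tibble(snp = paste0("s", 1:200), chrom = "1",
                       pos = sample.int(5000, 200), a1 = "A", a2 = "C",
                       p = 0.5, z = NA_real_, category = "unknown")
  reg <- data.frame(chrom = "1",
                    start = c(10L, 500L, 400L, 2000L),
                    end = c(600L, 1500L, 450L, 2001L))
  a <- annotate_category(ss, reg)$category
  b <- annotate_category(ss, reg[sample.int(4), ])$category
  expect_identical(a, b)
})

test_that("malformed BED lines raise errors naming the line", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("1\t10\t20", "1\t30"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("1\t10\t20", "1\t50\t40"), path)
  expect_error(read_bed(path), "line 2")
})

test_that("join_sumstats intersects by id and reports counts", {
  prm <- simulation_params(n_snps = 30, seed = 5)
  sim <- simulate_pair(prm)
  t2 <- sim$trait2[1:20, ]
  expect_message(j <- join_sumstats(sim$trait1, t2), "20 shared")
  expect_equal(nrow(j), 20L)
  expect_equal(j$p1, sim$trait1$p[1:20])
  expect_equal(j$p2, t2$p)
  # discordant alleles warn but are kept
  t2b <- t2
  t2b$a1 <- "A"; t2b$a2 <- "A"
  t1b <- sim$trait1; t1b$a1 <- "C"; t1b$a2 <- "G"
  expect_warning(suppressMessages(join_sumstats(t1b, t2b)), "discordant")
})
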