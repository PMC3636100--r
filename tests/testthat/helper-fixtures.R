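# small programmatic fixtures shared across test files

write_toy_sumstats <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_sumstats_df <- function() {
  data.frame(
    SNP = c("rs1", "rs2", "rs3"),
    CHR = c("1", "1", "2"),
    BP = c(100L, 5000L, 250L),
    P = c(0.5, 1e-4, 0.01)
  )
}

write_ld_file <- function(df, path = tempfile(fileext = ".ld")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# joined table straight from the simulator (quiet join)
simulate_joined <- function(params) {
  sim <- simulate_pair(params)
  suppressMessages(join_sumstats(sim$trait1, sim$trait2))
}
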