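#' Read a pipeline run configuration
#'
#' Configurations are YAML with the sections used by [run_pipeline()]:
#' `simulate` (passed to [simulation_params()]), `gc` (`min_intergenic`,
#' `statistic`), `condfdr` (`grid_step`, `min_subset_size`), `loci`
#' (`fdr_threshold`, `r2_threshold`) and optional `inputs`
#' (`trait1`/`trait2`/`ld` file paths plus `column_map`) to run on real files
#' instead of simulating.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

default_run_config <- function() {
  list(
    simulate = list(n_snps = 20000, seed = 42, ld_block_size = 5),
    gc = list(min_intergenic = 100, statistic = "chisq"),
    condfdr = list(grid_step = 0.1, min_subset_size = 100),
    loci = list(fdr_threshold = 0.05, r2_threshold = 0.2),
    mixfit = list(n_restarts = 3, seed = 1),
    plot = list(enabled = TRUE)
  )
}

provenance_header <- function(stage, config) {
  c(paste0("condfdr ", as.character(utils::packageVersion("condfdr")),
           " stage=", stage),
    paste0("config: ", gsub("\n", " ", yaml::as.yaml(config))))
}

#' Run the full analysis pipeline
#'
#' Chains the stages simulate (or load) -> genomic control -> conditional /
#' conjunction FDR -> loci -> mixture fit -> plots, writing each stage's
#' tables as tab-delimited text with provenance headers into `out_dir`.
#' Deterministic stages are bit-identical across reruns with the same
#' configuration; every stochastic stage's seed comes from the configuration
#' and is echoed in the output headers. A stage failure aborts with the stage
#' named, leaving a `FAILED` marker file alongside any partial outputs.
#'
#' @param config A configuration list (see [read_run_config()]) or a YAML
#'   path; missing entries fall back to defaults.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dat <- stage("input", function() {
    if (!is.null(cfg$inputs)) {
      t1 <- read_sumstats(cfg$inputs$trait1, column_map = cfg$inputs$column_map)
      t2 <- read_sumstats(cfg$inputs$trait2, column_map = cfg$inputs$column_map)
      ld <- if (!is.null(cfg$inputs$ld)) read_ld(cfg$inputs$ld) else
        ld_table(character(), character(), numeric())
      list(trait1 = t1, trait2 = t2, ld = ld, truth = NULL)
    } else {
      params <- do.call(simulation_params, cfg$simulate)
      sim <- simulate_pair(params)
      ld <- simulate_ld(params)
      write_sumstats(sim$trait1, file.path(out_dir, "trait1.sumstats.tsv"),
                     provenance_header("simulate", cfg$simulate))
      write_sumstats(sim$trait2, file.path(out_dir, "trait2.sumstats.tsv"),
                     provenance_header("simulate", cfg$simulate))
      write_truth(sim$truth, file.path(out_dir, "truth.tsv"))
      list(trait1 = sim$trait1, trait2 = sim$trait2, ld = ld,
           truth = sim$truth)
    }
  })

  corrected <- stage("gc", function() {
    out <- list()
    gc_log <- character(0)
    for (tr in c("trait1", "trait2")) {
      gc <- lambda_gc_sumstats(dat[[tr]], min_n = cfg$gc$min_intergenic)
      out[[tr]] <- apply_gc(dat[[tr]], gc, statistic = cfg$gc$statistic)
      gc_log <- c(gc_log, sprintf("%s lambda_GC=%.4f n_intergenic=%d", tr,
                                  gc$lambda_gc, gc$n_intergenic))
    }
    writeLines(paste0("# ", c(provenance_header("gc", cfg$gc), gc_log)),
               file.path(out_dir, "genomic_control.txt"))
    out
  })

  fdr <- stage("condfdr", function() {
    joined <- suppressMessages(join_sumstats(corrected$trait1,
                                             corrected$trait2))
    res <- condfdr_assign(joined, grid_step = cfg$condfdr$grid_step,
                          min_subset_size = cfg$condfdr$min_subset_size)
    write_lookup(res$table_1, file.path(out_dir, "lookup_trait1.tsv"),
                 provenance_header("condfdr", cfg$condfdr))
    write_lookup(res$table_2, file.path(out_dir, "lookup_trait2.tsv"),
                 provenance_header("condfdr", cfg$condfdr))
    snps <- res$snps
    con <- file(file.path(out_dir, "snp_fdr.tsv"), "w")
    writeLines(paste0("# ", provenance_header("condfdr", cfg$condfdr)), con)
    utils::write.table(snps, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    res
  })

  loci_out <- stage("loci", function() {
    l1 <- significant_loci(fdr$snps, dat$ld,
                           fdr_threshold = cfg$loci$fdr_threshold,
                           r2_threshold = cfg$loci$r2_threshold,
                           fdr_col = "condfdr_1", p_col = "p1")
    l2 <- significant_loci(fdr$snps, dat$ld,
                           fdr_threshold = cfg$loci$fdr_threshold,
                           r2_threshold = cfg$loci$r2_threshold,
                           fdr_col = "condfdr_2", p_col = "p2")
    lc <- conjunction_loci(fdr$snps, dat$ld,
                           fdr_threshold = cfg$loci$fdr_threshold,
                           r2_threshold = cfg$loci$r2_threshold)
    write_locus <- function(tbl, file) {
      con <- file(file.path(out_dir, file), "w")
      writeLines(paste0("# ", provenance_header("loci", cfg$loci)), con)
      utils::write.table(tbl, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
    write_locus(l1, "loci_trait1.tsv")
    write_locus(l2, "loci_trait2.tsv")
    write_locus(lc, "loci_conjunction.tsv")
    list(trait1 = l1, trait2 = l2, conjunction = lc)
  })

  stage("mixfit", function() {
    joined <- fdr$snps
    fit1 <- fit_two_groups(joined$z1, n_restarts = cfg$mixfit$n_restarts,
                           seed = cfg$mixfit$seed)
    fit2 <- fit_two_groups(joined$z2, n_restarts = cfg$mixfit$n_restarts,
                           seed = cfg$mixfit$seed + 1)
    params_tbl <- data.frame(
      trait = c(1, 2),
      pi0 = c(fit1$pi0, fit2$pi0),
      sigma0_sq = c(fit1$sigma0_sq, fit2$sigma0_sq),
      sigma1_sq = c(fit1$sigma1_sq, fit2$sigma1_sq),
      loglik = c(fit1$loglik, fit2$loglik),
      boundary = c(fit1$boundary, fit2$boundary)
    )
    con <- file(file.path(out_dir, "mixture_fit.tsv"), "w")
    writeLines(paste0("# ", provenance_header("mixfit", cfg$mixfit)), con)
    utils::write.table(params_tbl, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    invisible(NULL)
  })

  stage("plot", function() {
    if (!isTRUE(cfg$plot$enabled)) return(invisible(NULL))
    joined <- fdr$snps
    qq <- conditional_qq(joined)
    utils::write.table(qq, file.path(out_dir, "qq_series.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tdr <- tdr_curves(qq)
    utils::write.table(tdr, file.path(out_dir, "tdr_curves.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    md <- manhattan_data(joined, loci_out$trait1)
    utils::write.table(md, file.path(out_dir, "manhattan_trait1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (pl in list(list(plot_qq(qq), "qq.png"),
                    list(plot_tdr(tdr), "tdr.png"),
                    list(plot_manhattan(md), "manhattan_trait1.png"))) {
      ggplot2::ggsave(file.path(out_dir, pl[[2]]), pl[[1]],
                      width = 7, height = 5, dpi = 120)
    }
    invisible(NULL)
  })

  invisible(out_dir)
}
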