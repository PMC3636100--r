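Package: condfdr
Title: Pleiotropy-Informed Conditional and Conjunction FDR for GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cross-trait enrichment analysis for pairs of genome-wide
    association study (GWAS) summary-statistic sets. Implements
    intergenic-SNP genomic control, conditional Q-Q and true-discovery-rate
    diagnostics, conditional false discovery rate (condFDR) estimation via
    two-dimensional look-up tables, conjunction FDR (conjFDR) via the
    maximum rule, LD-pruned independent-locus reporting, and Gaussian
    mixture-model-based polygenicity and power analyses (two-groups
    univariate and four-groups bivariate local fdr). Ships a synthetic-data
    generator for paired summary statistics with known ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ggplot2,
    yaml,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
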