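Package: sbftools
Title: Species Branch Filtering for Cross-Species Gene Expression Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the evolution of gene expression across species on
    reconciled gene trees. Implements the TPM10K normalization (a rescaling of
    transcripts-per-million that gives every library the same mean regardless
    of reference completeness), within-species tissue expression ratios that
    cancel gene-by-species counting-efficiency factors, species-overlap
    annotation of gene-tree nodes as speciation or duplication events,
    null-node marking, gene-tree quality filters, time calibration of gene
    trees against an ultrametric species tree, maximum-likelihood ancestral
    state reconstruction of log expression under Brownian motion, scaled
    per-branch expression changes classified on species-equivalent branches
    (species branch filtering, SBF), and the classical strict-ortholog
    variance-partition analysis into species-variable and tissue-variable
    genes (species tree filtering, STF). A simulator generates duplication-
    loss gene trees with known histories, Brownian trait values, counting
    efficiencies, and multinomial read counts for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phytools,
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
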