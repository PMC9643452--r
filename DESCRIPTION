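Package: replitali
Title: Replication-Coupled DNA Methylation Loss in Partially Methylated Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying replication-coupled loss of DNA methylation
    in partially methylated domains (PMDs). Annotates CpGs by immediate
    sequence context (solo-WCGW and related classes) and domain membership,
    tracks population doublings in serially passaged primary cell cultures,
    fits per-CpG methylation-versus-doubling trajectories, computes Repli-seq
    weighted-average replication-timing scores, trains and applies elastic-net
    estimators of cumulative replicative history (the RepliTali procedure),
    and provides a mechanistic simulator of division-coupled maintenance
    methylation failure used as ground truth throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    glmnet,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
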