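Package: psgscan
Title: Genome Scans for Positively Selected Genes with Branch-Site Codon Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for lineage-specific scans of positive
    selection in protein-coding genes. Filters collections of single-copy
    ortholog groups by required species and minimum group size, prunes a
    master species topology to each group, assembles codon alignments from
    protein alignments by template-guided back-translation, fits the
    branch-site codon substitution model (model A) and its null by maximum
    likelihood with a multi-start protocol, performs the likelihood ratio
    test for positive selection on a designated foreground branch, compares
    two foreground lineages to define exclusively selected gene sets, and
    tests Gene Ontology categories for overrepresentation with a binomial
    test under Bonferroni correction. Includes generators for synthetic
    ortholog collections, codon alignments evolved under branch-site
    regimes, and annotation tables with planted enrichment, so every stage
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
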