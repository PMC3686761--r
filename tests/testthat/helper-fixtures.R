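# Shared small fixtures built in code.

laurasiatherians <- c("dolphin", "cow", "bat", "dog", "horse")

mammal_pool <- c(laurasiatherians,
                 paste0("mammal", sprintf("%02d", 1:28)))

# A rooted master topology over the pool with the five focal species
# forming a clade, unit-ish branch lengths.
make_master_tree <- function(seed = 1) {
  withr::with_seed(seed, {
    tr <- ape::rtree(length(mammal_pool), tip.label = sample(mammal_pool))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
    tr
  })
}

# Tiny group builder: equal-length random sense-codon CDS per species.
make_group_members <- function(species, n_codons = 20) {
  cds <- vapply(species, function(s) {
    paste0(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
  }, character(1))
  prot <- vapply(cds, function(x) {
    paste0(translate_codons(psgscan:::split_codons(x)), collapse = "")
  }, character(1))
  tibble::tibble(species = species, protein = unname(prot),
                 cds = unname(cds))
}

# Small three-level GO DAG used across enrichment tests:
#   root <- bp, mf;  bp <- dev, metab;  dev <- neuro, kidney
toy_dag <- function() {
  go_dag(
    parents = list(root = character(),
                   bp = "root", mf = "root",
                   dev = "bp", metab = "bp",
                   neuro = "dev", kidney = "dev"),
    names = c(root = "root", bp = "biological process",
              mf = "molecular function", dev = "development",
              metab = "metabolism", neuro = "neurogenesis",
              kidney = "kidney development")
  )
}
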