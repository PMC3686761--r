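test_that("slim mapping counts ancestor-closure hits once per gene", {
  dag <- toy_dag()
  # a gene annotated below root counts for root when root is in the slim
  ann <- tibble::tibble(gene = "g1", term = "neuro")
  counts <- map_to_slim_counts(ann, dag, slim = c("root", "metab"))
  expect_equal(counts$term, "root")
  expect_equal(counts$n_genes, 1L)
  # empty slim -> empty counts
  expect_equal(nrow(map_to_slim_counts(ann, dag, character())), 0)
  # annotation to the slim term itself also hits
  ann2 <- tibble::tibble(gene = c("g1", "g1", "g2"),
                         term = c("dev", "neuro", "kidney"))
  counts2 <- map_to_slim_counts(ann2, dag, slim = c("dev", "mf"))
  expect_equal(counts2$n_genes[counts2$term == "dev"], 2L)
})

test_that("slim counts equal a brute-force transitive-closure tally", {
  set.seed(61)
  # random 3-level DAG: 4 roots, 12 mid terms, 30 leaf terms
  roots <- paste0("r", 1:4)
  mids <- paste0("m", 1:12)
  leaves <- paste0("l", 1:30)
  parents <- c(
    setNames(vector("list", 4), roots),
    setNames(lapply(mids, function(x) sample(roots, sample(1:2, 1))),
             mids),
    setNames(lapply(leaves, function(x) sample(mids, sample(1:3, 1))),
             leaves))
  dag <- go_dag(parents)
  genes <- paste0("g", 1:50)
  ann <- purrr::map_dfr(genes, function(g) {
    tibble::tibble(gene = g,
                   term = sample(c(mids, leaves), sample(1:4, 1)))
  })
  slim <- c(roots[1:2], sample(mids, 4))
  got <- map_to_slim_counts(ann, dag, slim)
  # brute force: explicit ancestor closure per annotation
  closure <- function(tm) {
    out <- character(); frontier <- tm
    while (length(frontier)) {
      out <- union(out, frontier)
      frontier <- unique(unlist(parents[frontier]))
    }
    out
  }
  expected <- sapply(slim, function(s) {
    length(unique(ann$gene[vapply(ann$term, function(tm) s %in% closure(tm),
                                  logical(1))]))
  })
  expected <- expected[expected > 0]
  expect_setequal(got$term, names(expected))
  expect_equal(got$n_genes[match(names(expected), got$term)],
               unname(as.integer(expected)))
})

test_that("binomial enrichment reproduces whole-list expected counts", {
  # a 77-gene category, 448 PSGs among 7,859 analyzed genes
  reference <- sprintf("g%04d", 1:7859)
  cat_genes <- reference[1:77]
  psg <- reference[c(1:9, 100:538)]          # 448 genes, 9 in category
  dag <- go_dag(parents = list(cat1 = character()))
  ann <- tibble::tibble(gene = cat_genes, term = "cat1")
  res <- binomial_enrichment(psg, reference, ann, dag, "cat1")
  expect_equal(round(res$expected, 1), 4.4)
  expect_equal(res$n_category, 77L)
  expect_equal(res$observed, 9L)
})

test_that("raw p-values equal exact binomial pmf summation (n <= 12)", {
  dag <- go_dag(parents = list(c1 = character()))
  for (n_cat in c(1, 3, 7, 12)) {
    for (q_idx in 1:2) {
      n_ref <- 60
      n_psg <- c(6, 21)[q_idx]
      reference <- sprintf("x%03d", 1:n_ref)
      psg <- reference[seq_len(n_psg)]
      q <- n_psg / n_ref
      for (obs in 0:min(n_cat, n_psg)) {
        # build a category with exactly obs PSG members
        cat_genes <- c(psg[seq_len(obs)],
                       setdiff(reference, psg)[seq_len(n_cat - obs)])
        ann <- tibble::tibble(gene = cat_genes, term = "c1")
        res <- binomial_enrichment(psg, reference, ann, dag, "c1")
        expect_equal(res$p_raw, oracle_binom_upper(obs, n_cat, q),
                     tolerance = 1e-12)
      }
    }
  }
  # observed = 0 -> p_raw = p_bonferroni = 1
  ann0 <- tibble::tibble(gene = "x060", term = "c1")
  res0 <- binomial_enrichment(sprintf("x%03d", 1:6), sprintf("x%03d", 1:60),
                              ann0, dag, "c1")
  expect_equal(res0$p_raw, 1)
  expect_equal(res0$p_bonferroni, 1)
})

test_that("p_raw decreases in observed; Bonferroni stays within bounds", {
  dag <- go_dag(parents = list(c1 = character(), c2 = character(),
                               c3 = character()))
  reference <- sprintf("y%03d", 1:200)
  psg <- reference[1:20]
  last <- 1.01
  for (obs in c(0, 2, 5, 9)) {
    cat_genes <- c(psg[seq_len(obs)],
                   setdiff(reference, psg)[seq_len(30 - obs)])
    ann <- dplyr::bind_rows(
      tibble::tibble(gene = cat_genes, term = "c1"),
      tibble::tibble(gene = reference[50:80], term = "c2"),
      tibble::tibble(gene = reference[100:110], term = "c3"))
    res <- binomial_enrichment(psg, reference, ann, dag,
                               c("c1", "c2", "c3"))
    r1 <- res[res$term == "c1", ]
    expect_lt(r1$p_raw, last)
    last <- r1$p_raw
    expect_true(all(res$p_bonferroni <= 1))
    expect_true(all(res$p_bonferroni >= res$p_raw))
    expect_equal(attr(res, "m_tests"), 3L)
  }
  # psg outside the reference is an error
  expect_error(binomial_enrichment(c("zzz"), reference,
                                   tibble::tibble(gene = "y001",
                                                  term = "c1"),
                                   dag, "c1"),
               "subset")
})

test_that("the OBO reader parses terms, is_a edges and obsolete flags", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root process", "",
    "[Term]", "id: GO:0000002", "name: child process",
    "is_a: GO:0000001 ! root process", "",
    "[Term]", "id: GO:0000003", "name: dead process",
    "is_a: GO:0000001", "is_obsolete: true", "",
    "[Term]", "id: GO:0000004", "name: grandchild",
    "is_a: GO:0000002 ! child process",
    "relationship: part_of GO:0000001 ! root process", "",
    "[Typedef]", "id: part_of")
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, f)
  dag <- read_obo(f)
  expect_setequal(names(dag$parents),
                  c("GO:0000001", "GO:0000002", "GO:0000004"))
  expect_equal(dag$parents[["GO:0000002"]], "GO:0000001")
  expect_equal(go_ancestors(dag, "GO:0000004"),
               c("GO:0000002", "GO:0000001"))
  # part_of traversed only on request
  expect_true("GO:0000001" %in%
                go_ancestors(dag, "GO:0000004", use_part_of = TRUE))
  expect_equal(unname(dag$names["GO:0000002"]), "child process")
})
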