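test_that("filter_groups applies the required-species and minimum-size rules", {
  set.seed(11)
  # a group with the five focal species plus 4 other mammals (9 total) is
  # excluded under a 10-species minimum
  g9 <- make_group_members(c(laurasiatherians, paste0("mammal0", 1:4)))
  g12 <- make_group_members(c(laurasiatherians, paste0("mammal0", 1:7)))
  groups <- ortholog_groups(c("g9", "g12"), list(g9, g12))
  spec <- group_filter_spec(required_species = laurasiatherians,
                            min_species = 10,
                            allowed_taxon = mammal_pool)
  kept <- filter_groups(groups, spec)
  expect_identical(kept$group_id, "g12")

  # vacuous constraints keep every group
  spec0 <- group_filter_spec(character(), 1L)
  expect_identical(filter_groups(groups, spec0)$group_id,
                   groups$group_id)

  # members outside the allowed taxon are dropped from kept groups
  gx <- make_group_members(c(laurasiatherians, "mammal01", "chicken",
                             paste0("mammal0", 2:6)))
  groups_x <- ortholog_groups("gx", list(gx))
  kept_x <- suppressMessages(filter_groups(groups_x, spec))
  expect_false("chicken" %in% kept_x$members[[1]]$species)
  expect_equal(nrow(kept_x$members[[1]]), 11)
})

test_that("filter_groups matches a brute-force predicate scan on 200 random groups", {
  set.seed(42)
  sim <- simulate_group_collection(
    species_pool = mammal_pool,
    required_species = character(),
    size_distribution = function(n) sample(3:20, n, replace = TRUE),
    n_groups = 200, n_codons = 2, seed = 99)
  groups <- sim$groups
  spec <- group_filter_spec(required_species = laurasiatherians[1:3],
                            min_species = 8,
                            allowed_taxon = mammal_pool[1:25])
  kept <- suppressMessages(filter_groups(groups, spec))
  # independent scan: set predicates applied per group
  expected <- vapply(seq_len(nrow(groups)), function(k) {
    sp <- groups$members[[k]]$species
    all(spec$required_species %in% sp) &&
      length(intersect(sp, spec$allowed_taxon)) >= spec$min_species
  }, logical(1))
  expect_identical(kept$group_id, groups$group_id[expected])

  # idempotence: filtering a filtered collection changes nothing
  again <- suppressMessages(filter_groups(kept, spec))
  expect_identical(again$group_id, kept$group_id)
  expect_identical(again$members, kept$members)

  # tightening the spec never enlarges the kept set (nesting)
  tighter <- group_filter_spec(c(spec$required_species, "dog"),
                               min_species = 10,
                               allowed_taxon = mammal_pool[1:25])
  kept2 <- suppressMessages(filter_groups(groups, tighter))
  expect_true(all(kept2$group_id %in% kept$group_id))
})

test_that("filter spec validation catches configuration errors", {
  expect_error(group_filter_spec("dolphin", 0), "min_species")
  expect_error(group_filter_spec(c("a", "b"), 1), "required")
  expect_error(group_filter_spec("emu", 1, allowed_taxon = c("cow", "dog")),
               "emu")
})

test_that("prune_master_tree yields the induced subtree", {
  master <- ape::read.tree(text = "((A,B),(C,D));")
  # all leaves: identity
  expect_equal(ape::Ntip(prune_master_tree(master, c("A", "B", "C", "D"))),
               4)
  # forced topology on a 3-subset
  pr <- prune_master_tree(master, c("A", "C", "D"))
  expect_true(ape::is.monophyletic(pr, c("C", "D")))
  expect_error(prune_master_tree(master, c("A", "Z")), "Z")
})

test_that("pruned trees preserve rooted triples and path lengths", {
  set.seed(5)
  for (rep in 1:5) {
    master <- ape::rtree(12)
    keep <- sample(master$tip.label, 6)
    pr <- prune_master_tree(master, keep)
    expect_setequal(pr$tip.label, keep)
    # every leaf triple has the same rooted-triple topology as in master
    for (tri in utils::combn(keep, 3, simplify = FALSE)) {
      expect_identical(oracle_rooted_triple(pr, tri),
                       oracle_rooted_triple(master, tri))
    }
    # path lengths between retained leaves are preserved
    d_master <- ape::cophenetic.phylo(master)[keep, keep]
    d_pruned <- ape::cophenetic.phylo(pr)[keep, keep]
    expect_equal(d_pruned, d_master, tolerance = 1e-10)
    # nested pruning: prune(prune(T, S1), S2) == prune(T, S2), S2 in S1
    sub <- sample(keep, 4)
    p1 <- prune_master_tree(pr, sub)
    p2 <- prune_master_tree(master, sub)
    expect_true(ape::all.equal.phylo(p1, p2, use.edge.length = FALSE))
  }
})

test_that("group_size_histogram tallies species counts", {
  g10 <- make_group_members(mammal_pool[1:10], n_codons = 2)
  one <- ortholog_groups("g", list(g10))
  h <- group_size_histogram(one)
  expect_equal(h$n_species, 10)
  expect_equal(h$n_groups, 1)

  set.seed(7)
  sim <- simulate_group_collection(mammal_pool, laurasiatherians,
                                   n_groups = 60, n_codons = 2, seed = 3)
  h2 <- group_size_histogram(sim$groups)
  expect_equal(sum(h2$n_groups), 60)
  direct <- table(vapply(sim$groups$members, nrow, integer(1)))
  expect_equal(h2$n_groups, as.integer(direct))
  expect_equal(h2$n_species, as.integer(names(direct)))

  empty <- ortholog_groups(character(), list())
  expect_equal(nrow(group_size_histogram(empty)), 0)
})
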