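# Scan-level tests run on deliberately small synthetic collections so the
# whole file stays within a couple of minutes.

make_scan_fixture <- function(n_null = 2, n_sel = 2, n_codons = 200,
                              seed = 71) {
  nwk <- paste0("(((dolphin:0.25,cow:0.2):0.08,(bat:0.15,dog:0.15):0.05)",
                ":0.05,horse:0.2);")
  tr <- ape::read.tree(text = nwk)
  lt <- label_foreground(tr, "dolphin")
  groups <- list(); ids <- character(); truth <- logical()
  k <- 0
  for (i in seq_len(n_null + n_sel)) {
    selected <- i > n_null
    pp <- if (selected) branch_site_params(2, 0.15, 8, 0.45, 0.35)
          else branch_site_params(2, 0.15, 1, 0.55, 0.35)
    sim <- simulate_codon_alignment(lt, pp, NULL, n_codons,
                                    seed = seed + i)
    cm <- psgscan:::codon_matrix(sim$alignment)
    k <- k + 1
    ids[k] <- sprintf("G%03d", k)
    truth[k] <- selected
    groups[[k]] <- tibble::tibble(
      species = rownames(cm),
      cds = apply(cm, 1, paste0, collapse = ""),
      protein = apply(cm, 1, function(r) {
        paste0(translate_codons(r), collapse = "")
      }))
  }
  list(groups = ortholog_groups(ids, groups), master = tr, truth = truth)
}

test_that("run_scan recovers planted selection and skips degenerate groups", {
  fx <- make_scan_fixture()
  # add a group too small to test
  tiny <- fx$groups$members[[1]][1:2, ]
  groups <- ortholog_groups(c(fx$groups$group_id, "TINY"),
                            c(fx$groups$members, list(tiny)))
  res <- run_scan(groups, fx$master, foregrounds = c("dolphin", "cow"),
                  branch_lengths = "master", quiet = TRUE)
  expect_s3_class(res, "psg_scan")
  expect_equal(nrow(res), 2 * 5)
  expect_true(all(res$status[res$group_id == "TINY"] == "skipped"))
  ok <- res[res$status == "ok", ]
  expect_true(all(ok$p_value >= 0 & ok$p_value <= 1))
  # planted-truth recovery on the dolphin foreground
  dol <- ok[ok$foreground == "dolphin", ]
  sel_ids <- fx$groups$group_id[fx$truth]
  expect_true(all(dol$significant[dol$group_id %in% sel_ids]))
  expect_false(any(dol$significant[!dol$group_id %in% sel_ids]))

  # determinism: rerunning yields an identical table
  res2 <- run_scan(groups, fx$master, foregrounds = c("dolphin", "cow"),
                   branch_lengths = "master", quiet = TRUE)
  expect_equal(as.data.frame(res), as.data.frame(res2))

  # order invariance: permuting groups permutes but does not change rows
  perm <- sample(nrow(groups))
  res3 <- run_scan(groups[perm, ], fx$master,
                   foregrounds = c("dolphin", "cow"),
                   branch_lengths = "master", quiet = TRUE)
  a <- as.data.frame(res)
  a <- a[order(a$group_id, a$foreground), ]
  b <- as.data.frame(res3)
  b <- b[order(b$group_id, b$foreground), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)

  # exclusive sets from the same table
  exc <- exclusive_psg_set(res, "dolphin", "cow")
  sig_d <- res$group_id[res$foreground == "dolphin" & res$status == "ok" &
                          res$significant]
  sig_c <- res$group_id[res$foreground == "cow" & res$status == "ok" &
                          res$significant]
  expect_setequal(exc, setdiff(sig_d, sig_c))

  # summary percentages recomputed from the raw table match the report
  sm <- summary_report(res)
  dol_row <- sm[sm$foreground == "dolphin", ]
  expect_equal(dol_row$percent_significant,
               round(100 * dol_row$n_significant / dol_row$n_tested, 1))
  hist <- attr(sm, "group_size_histogram")
  expect_equal(sum(hist$n_groups), 4)   # TINY excluded (skipped)
})

test_that("run_scan with M0 branch lengths works end to end", {
  fx <- make_scan_fixture(n_null = 1, n_sel = 0, n_codons = 100)
  res <- run_scan(fx$groups, fx$master, foregrounds = "dolphin",
                  branch_lengths = "m0", quiet = TRUE)
  expect_equal(res$status, "ok")
  expect_false(res$significant)
})

test_that("exclusive_psg_set is a plain set difference with validation", {
  tab <- tibble::tibble(
    group_id = rep(c("g1", "g2", "g3"), 2),
    foreground = rep(c("a", "b"), each = 3),
    status = "ok",
    significant = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_setequal(exclusive_psg_set(tab, "a", "b"), "g1")
  # identical significance patterns give the empty set
  tab2 <- tab; tab2$significant <- rep(c(TRUE, FALSE, FALSE), 2)
  expect_length(exclusive_psg_set(tab2, "a", "b"), 0)
  expect_error(exclusive_psg_set(tab, "a", "zebra"), "zebra")
  # random tables match brute force
  set.seed(77)
  for (r in 1:10) {
    ids <- sprintf("g%02d", 1:20)
    tabr <- tibble::tibble(
      group_id = rep(ids, 2), foreground = rep(c("a", "b"), each = 20),
      status = "ok", significant = sample(c(TRUE, FALSE), 40, TRUE))
    brute <- setdiff(
      tabr$group_id[tabr$foreground == "a" & tabr$significant],
      tabr$group_id[tabr$foreground == "b" & tabr$significant])
    expect_setequal(exclusive_psg_set(tabr, "a", "b"), brute)
  }
})

test_that("summary_report reproduces genome-scan headline arithmetic", {
  mk <- function(n_sig, n_tot, fg = "dolphin") {
    tibble::tibble(group_id = sprintf("g%05d", seq_len(n_tot)),
                   foreground = fg, status = "ok",
                   significant = c(rep(TRUE, n_sig),
                                   rep(FALSE, n_tot - n_sig)))
  }
  sm <- summary_report(dplyr::bind_rows(mk(376, 7859, "dolphin"),
                                        mk(448, 7859, "cow")))
  expect_equal(sm$percent_significant[sm$foreground == "dolphin"], 4.8)
  expect_equal(sm$percent_significant[sm$foreground == "cow"], 5.7)
  sm0 <- summary_report(mk(0, 50))
  expect_equal(sm0$percent_significant, 0)
})
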