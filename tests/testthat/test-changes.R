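test_that("change classification follows the neutral band with closed bounds", {
  expect_identical(classify_change(0), "neutral")
  expect_identical(classify_change(-2.5), "negative")
  expect_identical(classify_change(2.5), "positive")
  # boundaries are neutral
  expect_identical(classify_change(c(-2, 2)), c("neutral", "neutral"))
  expect_error(classify_change(NaN), "finite")
  # configurable band
  th <- sbf_change_thresholds(neutral_lo = -1, neutral_hi = 1)
  expect_identical(classify_change(1.5, th), "positive")
})

test_that("scaled changes divide value differences by calibrated time", {
  st <- tiny_species_tree()
  ct <- annotate_and_calibrate(congruent_gene_tree(st), st)
  tm <- tibble::tibble(node = 1:7,
                       value = c(1, 3, 2, 2, 2, 2, 2.5),
                       provenance = c(rep("observed", 4),
                                      rep("reconstructed", 3)))
  rec <- scaled_branch_changes(ct, tm, tissue = "palpon", st = st)
  expect_equal(nrow(rec), 6)
  # tip A: parent = AB node (value 2.5, age 0.3): (1 - 2.5)/0.3 = -5
  a_row <- rec[rec$child_node == 1, ]
  expect_equal(a_row$scaled_change, (1 - 2.5) / 0.3)
  expect_identical(a_row$class, "negative")
  # identical endpoint values give zero change
  d_row <- rec[rec$child_node == 4, ]
  expect_equal(d_row$scaled_change, 0)
  expect_identical(d_row$class, "neutral")
  # only branches with both endpoints valued are reported
  tm2 <- tm; tm2$value[[6]] <- NA; tm2$provenance[[6]] <- "absent"
  expect_equal(nrow(scaled_branch_changes(ct, tm2)), 3)
})

test_that("species-equivalent branches mirror the species tree", {
  st <- example_species_tree()
  ct <- annotate_and_calibrate(congruent_gene_tree(st), st)
  seb <- find_species_equivalent_branches(ct, st)
  # congruent single-copy tree: bijection onto the species-tree branches
  expect_false(any(is.na(seb$species_branch)))
  expect_setequal(seb$species_branch, LETTERS[1:12])
  expect_equal(anyDuplicated(seb$species_branch), 0)

  # a root duplication with two complete copies doubles every branch
  copy_nwk <- write_species_tree(st)
  c1 <- gsub("(\\w+):", "\\1@g1:", copy_nwk)
  c2 <- gsub("(\\w+):", "\\1@g2:", copy_nwk)
  dup_txt <- paste0("(", sub(";$", "", c1), ":0.2,",
                    sub(";$", "", c2), ":0.2);")
  ctd <- annotate_and_calibrate(read_gene_tree(text = dup_txt), st)
  sebd <- find_species_equivalent_branches(ctd, st)
  tab <- table(sebd$species_branch)
  expect_setequal(names(tab), LETTERS[1:12])
  expect_true(all(tab == 2))
  # the two stem branches under the duplication are unlabeled
  expect_equal(sum(is.na(sebd$species_branch)), 2)

  # a branch spanning grandparent -> grandchild species nodes is unlabeled
  st4 <- tiny_species_tree()
  ctl <- annotate_and_calibrate(
    read_gene_tree(text = "((A@g:0.3,C@g:0.6):0.4,D@g:1);"), st4)
  sebl <- find_species_equivalent_branches(ctl, st4)
  # tip A hangs from the ABC node but its species parent is AB: unlabeled;
  # tip C and tip D are genuine species-equivalent branches
  lab <- setNames(sebl$species_branch, sebl$child_node)
  expect_true(is.na(lab[["1"]]))
  expect_false(is.na(lab[["2"]]))
  expect_false(is.na(lab[["3"]]))
})

test_that("ratio trait maps keep only co-valued nodes", {
  num <- tibble::tibble(node = 1:3, value = c(1, NA, 3),
                        provenance = c("observed", "absent", "reconstructed"))
  den <- tibble::tibble(node = 1:3, value = c(0.5, 2, NA),
                        provenance = c("observed", "observed", "absent"))
  r <- ratio_trait_map(num, den)
  expect_equal(r$value, c(0.5, NA, NA))
  expect_identical(r$provenance, c("observed", "absent", "absent"))
})

test_that("tallies count classes per species branch and stay consistent", {
  rec <- tibble::tibble(
    tree_id = "t", parent_node = 1L, child_node = 2L,
    tissue = "palpon", scaled_change = c(-3, 0, 4),
    class = classify_change(c(-3, 0, 4)),
    species_branch = "J")
  tal <- tally_changes(rec)
  expect_equal(tal$n_negative, 1L)
  expect_equal(tal$n_neutral, 1L)
  expect_equal(tal$n_positive, 1L)
  expect_equal(tal$n_total, 3L)

  # unlabeled records do not enter; absent branches are simply missing
  rec2 <- dplyr::bind_rows(rec, dplyr::mutate(rec, species_branch = NA))
  expect_identical(tally_changes(rec2), tal)
  expect_false("A" %in% tally_changes(rec2)$species_branch)

  # negating all trait values swaps negative and positive counts exactly
  neg <- rec2
  neg$scaled_change <- -neg$scaled_change
  neg$class <- classify_change(neg$scaled_change)
  tneg <- tally_changes(neg)
  expect_equal(tneg$n_negative, tal$n_positive)
  expect_equal(tneg$n_positive, tal$n_negative)
  expect_equal(tneg$n_neutral, tal$n_neutral)

  # mean branch counts average totals over tissues
  rec3 <- dplyr::bind_rows(rec, dplyr::mutate(rec[1, ], tissue = "pne"))
  mb <- mean_branch_counts(tally_changes(rec3))
  expect_equal(mb$mean_branches, 2) # (3 + 1) / 2

  expect_identical(large_changes(rec)$scaled_change, numeric(0))
  expect_equal(large_changes(rec, 3.5)$scaled_change, 4)
})

test_that("tally totals equal the number of labeled records per branch", {
  st <- example_species_tree()
  trees <- simulate_gene_trees(st, 0.6, 0.3, n_trees = 10, seed = 71)
  recs <- list()
  for (nm in names(trees)) {
    ct <- calibrate_gene_tree(annotate_gene_tree(trees[[nm]], st), st)
    labs <- ct$phylo$tip.label
    tv <- setNames(rnorm(length(labs)), labs)
    tm <- reconstruct_ancestral_bm(ct, tv)
    recs[[nm]] <- scaled_branch_changes(ct, tm, st = st, tree_id = nm)
  }
  rec <- dplyr::bind_rows(recs)
  tal <- tally_changes(rec)
  labeled <- rec[!is.na(rec$species_branch), ]
  independent <- table(labeled$species_branch)
  expect_equal(setNames(tal$n_total, tal$species_branch),
               setNames(as.integer(independent), names(independent)))
})
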