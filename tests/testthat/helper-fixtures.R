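# Shared fixtures and independent oracles. Everything is built in code; the
# oracles deliberately use different code paths (generic least squares,
# phangorn descendant enumeration) than the implementation they check.

# four-species ultrametric tree, root age 1: ages AB = 0.3, ABC = 0.6
tiny_species_tree <- function() {
  read_species_tree(text = "(((A:0.3,B:0.3):0.3,C:0.6):0.4,D:1);")
}

# single-copy gene tree congruent with a species tree; substitution lengths
# equal the time lengths
congruent_gene_tree <- function(st, separator = "@") {
  phy <- st$phylo
  phy$tip.label <- paste0(phy$tip.label, separator, "g1")
  gene_tree(phy, separator = separator)
}

annotate_and_calibrate <- function(gt, st) {
  calibrate_gene_tree(annotate_gene_tree(gt, st), st)
}

# random gene-tree-shaped phylo with species labels drawn from a pool
random_labeled_tree <- function(n_tips, species_pool, separator = "@") {
  phy <- ape::rtree(n_tips, rooted = TRUE)
  sp <- sample(species_pool, n_tips, replace = TRUE)
  phy$tip.label <- paste0(sp, separator, "g", seq_len(n_tips))
  gene_tree(phy, separator = separator)
}

# --- independent oracle: weighted least squares ancestral states ----------
# minimize sum over branches of (v_child - v_parent)^2 / t via a generic
# least-squares solve on the branch incidence matrix
wls_asr_oracle <- function(phy, tip_values) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  x <- tip_values[phy$tip.label]
  A <- matrix(0, nrow = nrow(phy$edge), ncol = nn)
  b <- numeric(nrow(phy$edge))
  t <- pmax(phy$edge.length, 1e-9)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    w <- 1 / sqrt(t[[i]])
    A[i, p - nt] <- A[i, p - nt] - w
    if (ch > nt) A[i, ch - nt] <- A[i, ch - nt] + w
    else b[[i]] <- b[[i]] - w * x[[ch]]
  }
  theta <- qr.coef(qr(A), b)
  unname(c(x, theta))
}

# --- independent oracle: species-overlap event labels ---------------------
# exhaustive per-node species sets via phangorn::Descendants
overlap_events_oracle <- function(gt) {
  phy <- gt$phylo
  nt <- length(phy$tip.label)
  sp_of_tip <- gt$tip_species
  out <- character(phy$Nnode)
  for (node in (nt + 1):(nt + phy$Nnode)) {
    kids <- phangorn::Children(phy, node)
    sets <- lapply(kids, function(k) {
      tips <- unlist(phangorn::Descendants(phy, k, type = "tips"))
      unique(sp_of_tip[tips])
    })
    overlap <- FALSE
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (a < b && length(intersect(sets[[a]], sets[[b]]))) overlap <- TRUE
      }
    }
    out[[node - nt]] <- if (overlap) "duplication" else "speciation"
  }
  out
}

# small count fixture builder: counts as a gene x library matrix
counts_from_matrix <- function(m, eff_length = 500) {
  tibble::tibble(
    gene = rep(rownames(m), times = ncol(m)),
    library = rep(colnames(m), each = nrow(m)),
    count = as.vector(m),
    eff_length = eff_length
  )
}

# expected per-library values for a (gene, species, tissue) truth table
expr_key <- function(expr, meta) {
  dplyr::inner_join(expr, meta, by = c("species", "tissue")) |>
    dplyr::select("gene", "library", "value")
}

descendants_of <- function(phy, node) {
  unlist(phangorn::Descendants(phy, node, type = "all"))
}

internal_st_nodes <- function(st) {
  nt <- length(st$phylo$tip.label)
  (nt + 1):(nt + st$phylo$Nnode)
}

# treat a count fixture's values directly as an expression table of a
# given unit (bypassing normalization where a test targets later stages)
expr_set_unit_for_test <- function(counts_tbl, unit = "TPM10K") {
  out <- tibble::tibble(gene = counts_tbl$gene, library = counts_tbl$library,
                        value = counts_tbl$count)
  attr(out, "unit") <- unit
  out
}

all_true_flags <- function(genes) {
  tibble::tibble(gene = genes, is_rRNA = FALSE, is_protein_coding = TRUE)
}

# the ten-tree filter fixture with one planted violation per rule; returns
# a list of (gene_tree, tip value vector) pairs plus the hand-enumerated
# verdicts (see the filter tests)
filter_fixture <- function() {
  st <- tiny_species_tree()
  mk <- function(text) read_gene_tree(text = text)
  full_values <- function(gt) {
    setNames(rep(1, length(gt$phylo$tip.label)), gt$phylo$tip.label)
  }
  trees <- list()
  values <- list()
  # t1: clean congruent single-copy tree -> keep
  trees$t1 <- congruent_gene_tree(st)
  # t2: one branch of length 3 -> long-branch
  trees$t2 <- mk("(((A@g:0.3,B@g:3):0.3,C@g:0.6):0.4,D@g:1);")
  # t3: 3 of 6 branches at the default length (0.5 > 0.25) -> default fraction
  trees$t3 <- mk(paste0("(((A@g:0.000001,B@g:0.000001):0.000001,",
                        "C@g:0.6):0.4,D@g:1);"))
  # t4: 2 of 8 branches default (exactly 0.25, strict rule) -> keep
  trees$t4 <- mk(paste0("((((A@g1:0.000001,A@g2:0.000001):0.3,B@g:0.3):0.3,",
                        "C@g:0.6):0.4,D@g:1);"))
  # t5: topology conflicting with the species tree -> 1 null of 3 internal
  # nodes (0.33 > 0.3) -> null density
  trees$t5 <- mk("(((A@g:0.3,C@g:0.3):0.3,B@g:0.6):0.4,D@g:1);")
  # t6: single-species family, no speciation nodes -> no-speciation
  trees$t6 <- mk("((A@g1:0.1,A@g2:0.1):0.2,A@g3:0.3);")
  # t7: two congruent copies under a root duplication with stems of 5
  # substitutions -> extrapolated root age 6 -> deep-root
  copy <- "(((A@gX:0.3,B@gX:0.3):0.3,C@gX:0.6):0.4,D@gX:1)"
  trees$t7 <- mk(paste0("(", sub("gX", "g1", copy, fixed = TRUE), ":5,",
                        sub("gX", "g2", copy, fixed = TRUE), ":5);"))
  # t8: congruent but only two tips carry expression values
  trees$t8 <- congruent_gene_tree(st)
  # t9: root duplication with short stems (root age 1.2) -> keep
  trees$t9 <- mk(paste0("(", sub("gX", "g1", copy, fixed = TRUE), ":0.2,",
                        sub("gX", "g2", copy, fixed = TRUE), ":0.2);"))
  # t10: long branch AND only two valued tips -> two reasons
  trees$t10 <- mk("(((A@g:0.3,B@g:3):0.3,C@g:0.6):0.4,D@g:1);")
  for (nm in names(trees)) values[[nm]] <- full_values(trees[[nm]])
  values$t8 <- values$t8[1:2]
  values$t10 <- values$t10[1:2]
  expected <- c(t1 = "keep", t2 = "discard", t3 = "discard", t4 = "keep",
                t5 = "discard", t6 = "discard", t7 = "discard",
                t8 = "discard", t9 = "keep", t10 = "discard")
  list(st = st, trees = trees, values = values, expected = expected)
}

# run the filter fixture through annotation, calibration and staging,
# producing the full report the rules consult
filter_fixture_report <- function(fx) {
  rows <- lapply(names(fx$trees), function(nm) {
    gt <- annotate_gene_tree(fx$trees[[nm]], fx$st)
    ct <- calibrate_gene_tree(gt, fx$st)
    stopifnot(!is_calibration_failure(ct))
    tree_filter_stats(ct, tip_values = fx$values[[nm]], tree_id = nm)
  })
  dplyr::bind_rows(rows)
}
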