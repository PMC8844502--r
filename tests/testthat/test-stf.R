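test_that("strict orthologs require one gene per species and no duplications", {
  st <- tiny_species_tree()
  spp <- st$phylo$tip.label
  clean <- annotate_gene_tree(congruent_gene_tree(st), st)
  groups <- extract_strict_orthologs(list(fam1 = clean), spp)
  expect_equal(nrow(groups), 4)
  expect_setequal(groups$species, spp)

  # a duplication ancestral to two species-complete copies: no group (two
  # genes per species)
  nwk <- write_species_tree(st)
  dup_txt <- paste0("(", sub(";$", "", gsub("(\\w+):", "\\1@g1:", nwk)),
                    ":0.2,", sub(";$", "", gsub("(\\w+):", "\\1@g2:", nwk)),
                    ":0.2);")
  dup <- annotate_gene_tree(read_gene_tree(text = dup_txt), st)
  expect_equal(nrow(extract_strict_orthologs(list(fam = dup), spp)), 0)

  # a within-species duplication on the path also disqualifies
  part <- annotate_gene_tree(read_gene_tree(
    text = "((((A@g1:0.1,A@g2:0.1):0.2,B@g1:0.3):0.3,C@g1:0.6):0.4,D@g1:1);"),
    st)
  expect_equal(nrow(extract_strict_orthologs(
    list(fam = part), spp)), 0)

  # simulated single-copy forest: every planted family is recovered
  st7 <- example_species_tree()
  forest <- simulate_gene_trees(st7, 0, 0, n_trees = 8, seed = 81)
  ann <- lapply(forest, annotate_gene_tree, st = st7)
  got <- extract_strict_orthologs(ann, st7$phylo$tip.label)
  expect_setequal(unique(got$group), names(forest))
  expect_equal(nrow(got), 8 * 7)
})

test_that("external ortholog tables are validated row-wise", {
  tbl <- tibble::tibble(
    group = c("o1", "o1", "o2", "o2", "o2"),
    species = c("A", "B", "A", "A", "B"),
    gene = paste0("g", 1:5))
  expect_warning(out <- extract_strict_orthologs(
    species_list = c("A", "B"), ortholog_table = tbl), "rejected")
  expect_setequal(unique(out$group), "o1")
})

test_that("variance partition attributes pure effects to the right factor", {
  grid <- tidyr::crossing(species = paste0("s", 1:4),
                          tissue = paste0("t", 1:4))
  sp_only <- dplyr::mutate(grid, ortholog = "o1",
                           value = as.numeric(factor(species)) * 10)
  fit <- variance_partition(sp_only)
  rec <- tidy(fit)
  expect_equal(rec$species_prop, 1)
  expect_equal(rec$tissue_prop, 0)
  expect_identical(rec$label, "SVG")

  ti_only <- dplyr::mutate(grid, ortholog = "o1",
                           value = as.numeric(factor(tissue)) * 3)
  rec2 <- tidy(variance_partition(ti_only))
  expect_equal(rec2$tissue_prop, 1)
  expect_identical(rec2$label, "TVG")

  # constant values: all proportions zero, label other
  const <- dplyr::mutate(grid, ortholog = "o1", value = 7)
  rec3 <- tidy(variance_partition(const))
  expect_equal(rec3$species_prop + rec3$tissue_prop + rec3$residual_prop, 0)
  expect_identical(rec3$label, "other")

  # swapping the factor labels swaps SVG and TVG exactly
  mixed <- dplyr::bind_rows(
    dplyr::mutate(sp_only, ortholog = "a"),
    dplyr::mutate(ti_only, ortholog = "b"))
  fwd <- tidy(variance_partition(mixed))
  swapped <- dplyr::rename(mixed, species = "tissue", tissue = "species")
  bwd <- tidy(variance_partition(swapped))
  expect_identical(fwd$label[fwd$ortholog == "a"],
                   bwd$label[bwd$ortholog == "b"])
  expect_equal(fwd$species_prop, bwd$tissue_prop)

  # incomplete orthologs are dropped, replicates averaged first
  with_rep <- dplyr::bind_rows(sp_only, sp_only[1, ])
  incomplete <- dplyr::mutate(grid[-1, ], ortholog = "o2", value = 1)
  fit4 <- variance_partition(dplyr::bind_rows(with_rep, incomplete))
  expect_equal(nrow(tidy(fit4)), 1)
  expect_equal(glance(fit4)$n_dropped_incomplete, 1)
})

test_that("proportions are valid and noisy planted effects are recovered", {
  set.seed(82)
  grid <- tidyr::crossing(species = paste0("s", 1:4),
                          tissue = paste0("t", 1:4))
  genes <- lapply(1:60, function(i) {
    kind <- if (i %% 2 == 0) "species" else "tissue"
    eff <- rnorm(4)
    idx <- as.numeric(factor(if (kind == "species") grid$species
                             else grid$tissue))
    dplyr::mutate(grid, ortholog = sprintf("o%02d_%s", i, kind),
                  value = eff[idx] + rnorm(16, 0, 0.1))
  })
  fit <- variance_partition(dplyr::bind_rows(genes))
  rec <- tidy(fit)
  expect_true(all(rec$species_prop >= 0 & rec$species_prop <= 1))
  expect_true(all(abs(rec$species_prop + rec$tissue_prop +
                        rec$residual_prop - 1) < 1e-9))
  sp_genes <- grepl("species", rec$ortholog)
  expect_gt(mean(rec$label[sp_genes] == "SVG"), 0.9)
  expect_gt(mean(rec$label[!sp_genes] == "TVG"), 0.9)
})

test_that("SVG/TVG rules apply the 75% and two-fold thresholds", {
  rec <- tibble::tibble(species_prop = c(0.8, 0.3, 0.2),
                        tissue_prop = c(0.1, 0.5, 0.7))
  expect_identical(classify_svg_tvg(rec), c("SVG", "other", "TVG"))
})

test_that("ratio transformation strips efficiency-driven species signal", {
  # genes whose only species signal is a gene-by-species efficiency factor:
  # on raw values species dominates; on within-species tissue ratios the
  # species proportion collapses
  set.seed(83)
  n_rep <- 40
  drop_count <- 0
  for (r in seq_len(n_rep)) {
    grid <- tidyr::crossing(species = paste0("s", 1:4),
                            tissue = paste0("t", 1:4))
    tissue_effect <- rnorm(4, 0, 0.3)
    eff <- exp(rnorm(4, 0, 1)) # per-species efficiency
    d <- dplyr::mutate(grid, ortholog = "o",
                       value = eff[as.numeric(factor(species))] *
                         exp(tissue_effect[as.numeric(factor(tissue))] +
                               rnorm(16, 0, 0.05)))
    raw <- tidy(variance_partition(d))
    ratio_d <- d |>
      dplyr::group_by(species) |>
      dplyr::mutate(value = value / value[tissue == "t1"]) |>
      dplyr::ungroup() |>
      dplyr::filter(tissue != "t1")
    ratio <- tidy(variance_partition(ratio_d))
    if (ratio$species_prop < raw$species_prop) drop_count <- drop_count + 1
  }
  expect_gt(drop_count / n_rep, 0.9)
})
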