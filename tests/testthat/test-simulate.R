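test_that("BM simulation is degenerate at zero rate and seed-reproducible", {
  st <- example_species_tree()
  sim0 <- simulate_bm(st, root_value = 3, sigma2 = 0)
  expect_identical(sim0$value, rep(3, 13))

  a <- simulate_bm(st, 0, 1, seed = 91)
  b <- simulate_bm(st, 0, 1, seed = 91)
  expect_identical(a, b)
  c <- simulate_bm(st, 0, 1, seed = 92)
  expect_false(identical(a$value, c$value))

  expect_error(simulate_bm(st, 0, -1), "sigma2")
})

test_that("tip variance and covariance follow the BM expectations", {
  phy <- ape::read.tree(text = "((t1:0.3,t2:0.3):0.7,(t3:0.5,t4:0.5):0.5);")
  sigma2 <- 2
  n <- 2000
  set.seed(93)
  tips <- t(replicate(n, simulate_bm(phy, 0, sigma2)$value[1:4]))
  expect_equal(var(tips[, 1]), sigma2 * 1, tolerance = 0.1)
  # shared path of t1, t2 is 0.7; of t1, t3 is 0
  expect_equal(cov(tips[, 1], tips[, 2]), sigma2 * 0.7, tolerance = 0.12)
  expect_equal(cov(tips[, 1], tips[, 3]), 0, tolerance = 0.12)
})

test_that("empirical BM parameters follow the moment conventions", {
  cherry <- ape::read.tree(text = "(a:1,b:1);")
  # need >= 3 tips
  expect_error(empirical_bm_params(cherry, c(1, 2)), ">= 3")
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  const <- empirical_bm_params(star, c(2, 2, 2))
  expect_equal(const$sigma2, 0)
  expect_equal(const$root_value, 2)
  p <- empirical_bm_params(star, c(0, 2, 1))
  expect_equal(p$root_value, 1)
  expect_equal(p$sigma2, var(c(0, 2, 1)) / 1)

  # rough calibration of the estimator on simulated data
  set.seed(94)
  phy <- ape::rtree(50)
  phy$edge.length <- phy$edge.length / max(sbftools:::node_depths(phy))
  sig_hat <- replicate(100, {
    sim <- simulate_bm(phy, 0, sigma2 = 3)
    empirical_bm_params(phy, sim$value[1:50])$sigma2
  })
  expect_equal(mean(sig_hat), 3, tolerance = 0.3)
})

test_that("duplication-loss gene trees carry faithful histories", {
  st <- example_species_tree()
  # no events: every tree congruent, all speciations at species ages
  pure <- simulate_gene_trees(st, 0, 0, n_trees = 5, seed = 95)
  for (gt in pure) {
    truth <- attr(gt, "truth")
    expect_identical(unique(truth$event), "speciation")
    expect_equal(length(gt$phylo$tip.label), 7)
    expect_setequal(gt$tip_species, st$phylo$tip.label)
    # true node ages reproduce the species-tree ages
    expect_equal(sort(truth$age[truth$age > 0]),
                 sort(st$age[st$age > 0]))
    # annotation recovers the true history exactly on loss-free trees
    ann <- annotate_gene_tree(gt, st)
    expect_identical(ann$event, truth$event)
  }

  # duplications without loss can only add tips
  dup_only <- simulate_gene_trees(st, 0.8, 0, n_trees = 20, seed = 96)
  expect_true(all(vapply(dup_only, function(g)
    length(g$phylo$tip.label), 1L) >= 7))

  # mean tip count grows with the duplication rate
  mean_tips <- vapply(c(0, 0.5, 1.5), function(r) {
    trees <- simulate_gene_trees(st, r, 0, n_trees = 40, seed = 97)
    mean(vapply(trees, function(g) length(g$phylo$tip.label), 1L))
  }, 1.0)
  expect_true(all(diff(mean_tips) > 0))

  # reproducibility
  expect_identical(
    write_gene_tree(simulate_gene_trees(st, 0.5, 0.3, 3, seed = 98)[[2]]),
    write_gene_tree(simulate_gene_trees(st, 0.5, 0.3, 3, seed = 98)[[2]]))
})

test_that("simulated counts respect expectations and library size", {
  expr <- tidyr::crossing(gene = paste0("g", 1:5), species = "s",
                          tissue = c("a", "b")) |>
    dplyr::mutate(value = rep(c(10, 20, 5, 1, 40), each = 2))
  # expected counts at equal lengths and unit efficiency recover the truth
  out <- simulate_counts(expr, library_size = NULL)
  tpm <- compute_tpm(out$counts)
  joined <- dplyr::inner_join(tpm,
                              dplyr::inner_join(expr, out$meta,
                                                by = c("species", "tissue")),
                              by = c("gene", "library"))
  expect_equal(cor(joined$value.x, joined$value.y), 1)

  # multinomial library size is conserved exactly
  out2 <- simulate_counts(expr, library_size = 10000, seed = 99)
  sums <- tapply(out2$counts$count, out2$counts$library, sum)
  expect_true(all(sums == 10000))

  # counts converge on the truth as depth grows
  cors <- vapply(c(1e3, 1e5), function(ls) {
    o <- simulate_counts(expr, library_size = ls, seed = 100)
    j <- dplyr::inner_join(compute_tpm(o$counts), expr_key(expr, o$meta),
                           by = c("gene", "library"))
    cor(j$value.x, j$value.y)
  }, 1.0)
  expect_gt(cors[[2]], cors[[1]] - 1e-12)
  expect_gt(cors[[2]], 0.999)

  expect_error(simulate_counts(dplyr::mutate(expr, value = 0)), "zero total")
  expect_error(
    simulate_counts(expr, efficiencies = tibble::tibble(
      gene = "g1", species = "s", efficiency = -1)), "> 0")
})

test_that("scenario generation wires trees, counts and metadata together", {
  sim <- simulate_sbf_scenario(n_families = 3, n_background = 30,
                               sigma2 = 0.5, seed = 101)
  expect_equal(length(sim$gene_trees), 3)
  expect_setequal(sim$meta$species[match(unique(sim$counts$library),
                                         sim$meta$library)],
                  sim$species_tree$phylo$tip.label)
  # every gene-tree tip has expression rows in its species' libraries
  gt <- sim$gene_trees[[1]]
  tip_genes <- gt$phylo$tip.label
  expect_true(all(tip_genes %in% sim$counts$gene))
  # references differ across species only through family gene content
  expect_true(all(sim$n_reference$n_genes >= 30))
  # deterministic under the seed
  sim2 <- simulate_sbf_scenario(n_families = 3, n_background = 30,
                                sigma2 = 0.5, seed = 101)
  expect_identical(sim$counts, sim2$counts)
})
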