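test_that("gene filtering enforces flags and library support", {
  m <- rbind(
    g1 = c(5, 0, 0),    # one positive library: removed
    g2 = c(1, 1, 0),    # exactly two: retained
    g3 = c(2, 3, 4)
  )
  colnames(m) <- paste0("L", 1:3)
  counts <- counts_from_matrix(m)
  flags <- all_true_flags(rownames(m))
  kept <- filter_genes(counts, flags)
  expect_setequal(unique(kept$gene), c("g2", "g3"))

  # 10-gene fixture with 3 planted violations: rRNA, non-coding, 1-library
  m10 <- matrix(1, nrow = 10, ncol = 3,
                dimnames = list(paste0("g", 1:10), paste0("L", 1:3)))
  m10["g4", ] <- c(9, 0, 0)
  counts10 <- counts_from_matrix(m10)
  flags10 <- all_true_flags(rownames(m10))
  flags10$is_rRNA[flags10$gene == "g2"] <- TRUE
  flags10$is_protein_coding[flags10$gene == "g7"] <- FALSE
  kept10 <- filter_genes(counts10, flags10)
  expect_setequal(unique(kept10$gene),
                  setdiff(paste0("g", 1:10), c("g2", "g4", "g7")))
  # order preserved
  expect_identical(unique(kept10$gene),
                   intersect(paste0("g", 1:10), unique(kept10$gene)))

  expect_error(filter_genes(counts, all_true_flags(c("g1", "g2"))),
               "g3")
})

test_that("TPM normalizes length-scaled counts to a fixed library sum", {
  m <- rbind(a = c(10, 10), b = c(10, 20))
  colnames(m) <- c("L1", "L2")
  counts <- counts_from_matrix(m)
  counts$eff_length <- rep(c(1, 1, 1, 2), 1) # L2: equal per-length rates
  tpm <- compute_tpm(counts)
  expect_identical(expr_unit(tpm), "TPM")
  expect_equal(tpm$value[tpm$library == "L1"], c(5e5, 5e5))
  expect_equal(tpm$value[tpm$library == "L2"], c(5e5, 5e5))

  mz <- rbind(a = c(1, 0), b = c(1, 0))
  colnames(mz) <- c("L1", "L2")
  expect_error(compute_tpm(counts_from_matrix(mz)), "L2")
})

test_that("TPM column sums and TPM10K column means hold on random libraries", {
  set.seed(11)
  for (rep in 1:20) {
    n_genes <- sample(5:80, 1)
    m <- matrix(rpois(n_genes * 3, lambda = 50) * runif(n_genes * 3, 0, 2),
                nrow = n_genes,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("L", 1:3)))
    counts <- counts_from_matrix(m, eff_length = runif(n_genes * 3, 100, 5000))
    tpm <- compute_tpm(counts)
    sums <- as.numeric(tapply(tpm$value, tpm$library, sum))
    expect_equal(sums, rep(1e6, 3), tolerance = 1e-6)
    t10 <- compute_tpm10k(tpm, n_genes)
    means <- as.numeric(tapply(t10$value, t10$library, mean))
    expect_equal(means, rep(100, 3), tolerance = 1e-9)
  }
})

test_that("TPM10K rescales by reference size, per species when needed", {
  m <- rbind(a = 1e6, b = 0)
  colnames(m) <- "L1"
  tpm <- compute_tpm(counts_from_matrix(m))
  t10 <- compute_tpm10k(tpm, 2)
  expect_equal(t10$value, c(200, 0))
  expect_identical(expr_unit(t10), "TPM10K")
  expect_error(compute_tpm10k(tpm, -1), "> 0")
  expect_error(compute_tpm10k(t10, 2), "TPM")

  # per-species n via metadata
  m2 <- rbind(a = c(2.5e5, 2.5e5), b = c(7.5e5, 7.5e5))
  colnames(m2) <- c("L1", "L2")
  tpm2 <- compute_tpm(counts_from_matrix(m2))
  meta <- tibble::tibble(library = c("L1", "L2"), species = c("s1", "s2"))
  nref <- tibble::tibble(species = c("s1", "s2"), n_genes = c(10000, 20000))
  t102 <- compute_tpm10k(tpm2, nref, meta)
  expect_equal(t102$value[t102$library == "L2"] /
                 t102$value[t102$library == "L1"], c(2, 2))
})

test_that("replicate summarization takes the mean then the log", {
  m <- rbind(g = c(10, 30))
  colnames(m) <- c("L1", "L2")
  t10 <- expr_set_unit_for_test(counts_from_matrix(m))
  meta <- tibble::tibble(library = c("L1", "L2"), species = "s",
                         tissue = "palpon")
  out <- summarize_and_log(t10, meta)
  expect_equal(out$value, log(21))

  # single replicate
  out1 <- summarize_and_log(t10[t10$library == "L1", ], meta[1, ])
  expect_equal(out1$value, log(11))

  # permutation invariance over replicate order
  shuffled <- t10[c(2, 1), ]
  expect_equal(summarize_and_log(shuffled, meta)$value, out$value)

  # 3 tissues x 2 replicates against hand-computed means
  vals <- matrix(c(1, 3, 10, 30, 100, 300), nrow = 1)
  colnames(vals) <- paste0("L", 1:6)
  rownames(vals) <- "g"
  meta6 <- tibble::tibble(library = paste0("L", 1:6), species = "s",
                          tissue = rep(c("a", "b", "c"), each = 2))
  out6 <- summarize_and_log(expr_set_unit_for_test(counts_from_matrix(vals)),
                            meta6)
  expect_equal(sort(out6$value), sort(log(c(3, 21, 201))))

  # zero means dropped with a warning when the pseudocount is 0
  mzz <- rbind(g = c(0, 5))
  colnames(mzz) <- c("L1", "L2")
  z <- expr_set_unit_for_test(counts_from_matrix(mzz, eff_length = 1))
  metaz <- tibble::tibble(library = c("L1", "L2"), species = "s",
                          tissue = c("a", "b"))
  expect_warning(outz <- summarize_and_log(z, metaz, pseudocount = 0),
                 "dropped")
  expect_equal(nrow(outz), 1)
})

test_that("tissue log-ratios subtract the denominator and cancel efficiencies", {
  le <- tibble::tibble(
    gene = "g", species = "s",
    tissue = c("palpon", "gastrozooid"),
    value = c(5, 3))
  attr(le, "unit") <- "logTPM10K"
  r <- expression_ratio(le, "gastrozooid")
  expect_equal(r$ratio, 2)
  expect_identical(r$tissue, "palpon")

  # identical values -> zero ratio
  le0 <- le; le0$value <- c(3, 3)
  expect_equal(expression_ratio(le0, "gastrozooid")$ratio, 0)

  expect_error(expression_ratio(le, "pneumatophore"), "absent")

  # species without the denominator contribute no rows
  le2 <- dplyr::bind_rows(le, tibble::tibble(gene = "g", species = "s2",
                                             tissue = "palpon", value = 4))
  attr(le2, "unit") <- "logTPM10K"
  r2 <- expression_ratio(le2, "gastrozooid")
  expect_identical(unique(r2$species), "s")

  # counting-efficiency cancellation, exact: scaling one gene's TPM10K by a
  # constant in every tissue of one species leaves its log-ratios unchanged
  # (pseudocount 0)
  set.seed(3)
  m <- matrix(rlnorm(40, 2, 1), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("L", 1:4)))
  meta <- tibble::tibble(library = paste0("L", 1:4), species = "s",
                         tissue = c("gas", "gas", "pal", "pne"))
  t10 <- compute_tpm10k(compute_tpm(counts_from_matrix(m)), 10)
  base <- expression_ratio(summarize_and_log(t10, meta, pseudocount = 0),
                           "gas")
  scaled <- t10
  scaled$value[scaled$gene == "g3"] <- scaled$value[scaled$gene == "g3"] * exp(1)
  attr(scaled, "unit") <- "TPM10K"
  after <- expression_ratio(summarize_and_log(scaled, meta, pseudocount = 0),
                            "gas")
  expect_equal(after$ratio[after$gene == "g3"],
               base$ratio[base$gene == "g3"], tolerance = 1e-12)
})
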