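# Synthetic-data generators: Brownian traits, duplication-loss gene trees
# with known histories, counting-efficiency factors and multinomial read
# counts. These generators define the study conditions used throughout the
# test surface; their histories are exposed so simulated truth can serve as
# an oracle.

#' A synthetic seven-species ultrametric species tree
#'
#' A fixed, synthetic tree shaped like a small siphonophore phylogeny
#' (seven species, root age 1, twelve labeled branches, shortest branch
#' 0.15). It is generated in code and is not an estimate from data.
#'
#' @return a `species_tree`.
#' @export
example_species_tree <- function() {
  txt <- paste0(
    "(Apolemia:1.0,((Bargmannia:0.55,(Physalia:0.35,Diphyes:0.35):0.2):0.3,",
    "(Frillagalma:0.6,(Agalma:0.3,Nanomia:0.3):0.3):0.25):0.15);")
  read_species_tree(text = txt)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) tree
  else if (!is.null(tree$phylo)) tree$phylo
  else abort("expected a phylo, species_tree or gene_tree")
}

#' Simulate a trait under Brownian motion on a tree
#'
#' Values evolve from `root_value` with independent Gaussian increments of
#' variance `sigma2 * t` along each branch of length `t`. The full internal
#' node history is returned so the simulation can act as an oracle for
#' reconstruction.
#'
#' @param tree a `phylo` (branch lengths = time), or a `species_tree` /
#'   `calibrated_gene_tree`.
#' @param root_value trait value at the root.
#' @param sigma2 Brownian rate (variance per unit time), `>= 0`.
#' @param seed optional integer seed (the caller's RNG stream is restored).
#' @return tibble `node`, `value` over all nodes (tips first).
#' @export
simulate_bm <- function(tree, root_value = 0, sigma2 = 1, seed = NULL) {
  if (sigma2 < 0) abort("sigma2 must be >= 0")
  phy <- as_phylo_tree(tree)
  with_seed(seed, {
    N <- n_tips(phy) + phy$Nnode
    value <- numeric(N)
    value[[root_node(phy)]] <- root_value
    e <- ape::reorder.phylo(phy, "cladewise")
    for (i in seq_len(nrow(e$edge))) {
      a <- e$edge[i, 1]; b <- e$edge[i, 2]
      value[[b]] <- value[[a]] +
        if (sigma2 > 0) rnorm(1, 0, sqrt(sigma2 * e$edge.length[[i]])) else 0
    }
    tibble(node = seq_len(N), value = value)
  })
}

#' Empirical Brownian-motion parameters from tip values
#'
#' A moment-based convention: the root value is estimated by the tip mean
#' and the rate by the tip variance divided by the mean root-to-tip time.
#'
#' @param tree a tree (see [simulate_bm()]).
#' @param tip_values numeric vector of tip values (tree order, or named by
#'   tip label).
#' @return list with `root_value` and `sigma2`.
#' @export
empirical_bm_params <- function(tree, tip_values) {
  phy <- as_phylo_tree(tree)
  if (!is.null(names(tip_values))) tip_values <- tip_values[phy$tip.label]
  if (length(tip_values) < 3) abort("need >= 3 tip values")
  depth <- node_depths(phy)[seq_len(n_tips(phy))]
  if (mean(depth) <= 0) abort("tree has zero tip depth")
  list(root_value = mean(tip_values),
       sigma2 = var(tip_values) / mean(depth))
}

# --- duplication-loss gene-tree simulation -------------------------------

# nested-list lineage simulation inside one species-tree branch, from age
# t_top down to species node `sp`; returns NULL on extinction
sim_lineage <- function(sp, t_top, st, st_children, dup_rate, loss_rate) {
  t_bottom <- st$age[[sp]]
  t <- t_top
  total <- dup_rate + loss_rate
  repeat {
    wait <- if (total > 0) stats::rexp(1, total) else Inf
    if (t - wait <= t_bottom) break
    t <- t - wait
    if (runif(1) < dup_rate / total) {
      left <- sim_lineage(sp, t, st, st_children, dup_rate, loss_rate)
      right <- sim_lineage(sp, t, st, st_children, dup_rate, loss_rate)
      if (is.null(left)) return(right)
      if (is.null(right)) return(left)
      return(list(type = "duplication", age = t, species_node = sp,
                  children = list(left, right)))
    }
    return(NULL) # loss
  }
  kids <- st_children[[sp]]
  if (is.null(kids)) {
    return(list(type = "tip", age = 0,
                species = st$phylo$tip.label[[sp]], species_node = sp))
  }
  left <- sim_lineage(kids[[1]], t_bottom, st, st_children, dup_rate, loss_rate)
  right <- sim_lineage(kids[[2]], t_bottom, st, st_children, dup_rate, loss_rate)
  if (is.null(left)) return(right)
  if (is.null(right)) return(left)
  list(type = "speciation", age = t_bottom, species_node = sp,
       children = list(left, right))
}

# convert a nested lineage structure into a gene_tree with truth attributes
lineage_to_gene_tree <- function(lin, family_id, separator, gamma_shape) {
  tips <- list(); internals <- list()
  walk_count <- function(x) {
    if (x$type == "tip") tips[[length(tips) + 1]] <<- x
    else {
      internals[[length(internals) + 1]] <<- x
      for (k in x$children) walk_count(k)
    }
  }
  walk_count(lin)
  nt <- length(tips); nn <- length(internals)
  if (nt < 2) return(NULL)
  edges <- matrix(0L, nrow = nt + nn - 1, ncol = 2)
  time_len <- numeric(nt + nn - 1)
  tip_label <- character(nt)
  ev <- character(nn); sn <- integer(nn); age <- numeric(nt + nn)
  tip_i <- 0L; int_i <- 0L; edge_i <- 0L; gene_i <- 0L
  assign_node <- function(x) {
    if (x$type == "tip") {
      tip_i <<- tip_i + 1L
      gene_i <<- gene_i + 1L
      tip_label[[tip_i]] <<- paste0(x$species, separator, family_id,
                                    "_g", gene_i)
      age[[tip_i]] <<- 0
      return(tip_i)
    }
    int_i <<- int_i + 1L
    me <- nt + int_i
    ev[[int_i]] <<- x$type
    sn[[int_i]] <<- x$species_node
    age[[me]] <<- x$age
    for (k in x$children) {
      child <- assign_node(k)
      edge_i <<- edge_i + 1L
      edges[edge_i, ] <<- c(me, child)
      time_len[[edge_i]] <<- x$age - k$age
    }
    me
  }
  assign_node(lin)
  subst <- time_len * rgamma(length(time_len), shape = gamma_shape,
                             rate = gamma_shape)
  # edges come out of the DFS in arbitrary row order; have ape put them in
  # canonical cladewise order and carry the per-edge vectors along
  phy <- structure(list(edge = edges, edge.length = seq_along(time_len),
                        tip.label = tip_label, Nnode = nn),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  perm <- phy$edge.length
  phy$edge.length <- subst[perm]
  time_len <- time_len[perm]
  gt <- gene_tree(phy, separator = separator)
  attr(gt, "truth") <- list(event = ev, species_node = sn, age = age,
                            time_length = time_len)
  gt
}

#' Time tree of a simulated gene tree's true history
#'
#' @param gt a gene tree from [simulate_gene_trees()].
#' @return a `phylo` with true time branch lengths.
#' @export
true_time_tree <- function(gt) {
  truth <- attr(gt, "truth")
  if (is.null(truth)) abort("gene tree carries no simulation truth")
  phy <- gt$phylo
  phy$edge.length <- truth$time_length
  phy
}

#' Simulate duplication-loss gene trees inside a species tree
#'
#' A single gene lineage enters the species tree at its root and follows
#' the species phylogeny; along every species-tree branch it duplicates at
#' rate `dup_rate` and is lost at rate `loss_rate` (per unit time). Each
#' surviving internal node carries its true event and species node in
#' `attr(, "truth")` (speciation or duplication nodes whose other copy was
#' entirely lost leave no node). Substitution branch lengths are the true
#' time lengths multiplied by independent Gamma(shape, shape) factors
#' (mean 1), emulating rate variation across branches.
#'
#' @param st a `species_tree`.
#' @param dup_rate,loss_rate event rates per unit time (root age = 1).
#' @param n_trees number of trees to return.
#' @param seed optional integer seed.
#' @param separator species/gene separator for tip labels.
#' @param gamma_shape shape of the rate-variation Gamma (default 10;
#'   larger = more clock-like).
#' @param family_prefix prefix for tree/gene family identifiers.
#' @return a named list of `gene_tree` objects (trees whose lineages all
#'   died, or with fewer than two surviving tips, are re-drawn; the names
#'   are family ids).
#' @export
simulate_gene_trees <- function(st, dup_rate = 0.5, loss_rate = 0.3,
                                n_trees = 10, seed = NULL, separator = "@",
                                gamma_shape = 10, family_prefix = "fam") {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  st_children <- children_list(st$phylo)
  with_seed(seed, {
    out <- vector("list", n_trees)
    nm <- character(n_trees)
    for (i in seq_len(n_trees)) {
      fam <- paste0(family_prefix, i)
      gt <- NULL
      attempts <- 0L
      while (is.null(gt)) {
        attempts <- attempts + 1L
        if (attempts > 1000L) abort("all simulated lineages died; lower loss_rate")
        lin <- sim_lineage(root_node(st$phylo), st$age[[root_node(st$phylo)]],
                           st, st_children, dup_rate, loss_rate)
        if (!is.null(lin) && lin$type != "tip") {
          gt <- lineage_to_gene_tree(lin, fam, separator, gamma_shape)
        }
      }
      out[[i]] <- gt
      nm[[i]] <- fam
    }
    setNames(out, nm)
  })
}

#' Simulate read counts with counting-efficiency factors
#'
#' Expected counts are proportional to `efficiency * expression * length`;
#' reads are drawn multinomially per library so the library size is
#' conserved exactly. With `library_size = NULL` the expected counts
#' themselves are returned (the infinite-depth limit).
#'
#' @param true_expression tibble `gene`, `species`, `tissue`, `value`
#'   (natural-scale expression). Genes absent from a species are simply
#'   missing rows for that species' libraries.
#' @param efficiencies tibble `gene`, `species`, `efficiency` (> 0);
#'   missing pairs default to 1.
#' @param library_size reads per library (`NULL` = expected counts).
#' @param gene_lengths tibble `gene`, `length` or a single number
#'   (default 500 nt) used as effective length.
#' @param replicates libraries per (species, tissue).
#' @param seed optional integer seed.
#' @return list with `counts` (long count table: `gene`, `library`,
#'   `count`, `eff_length`) and `meta` (`library`, `species`, `tissue`,
#'   `replicate`).
#' @export
simulate_counts <- function(true_expression, efficiencies = NULL,
                            library_size = NULL, gene_lengths = 500,
                            replicates = 1, seed = NULL) {
  if (is.null(efficiencies)) {
    efficiencies <- tibble(gene = character(), species = character(),
                           efficiency = numeric())
  }
  if (any(efficiencies$efficiency <= 0)) abort("efficiencies must be > 0")
  tbl <- true_expression |>
    left_join(efficiencies, by = c("gene", "species")) |>
    mutate(efficiency = ifelse(is.na(.data$efficiency), 1, .data$efficiency))
  if (is.numeric(gene_lengths) && length(gene_lengths) == 1) {
    tbl$length <- gene_lengths
  } else {
    tbl <- left_join(tbl, gene_lengths, by = "gene")
    if (anyNA(tbl$length)) abort("gene_lengths missing for some genes")
  }
  with_seed(seed, {
    libs <- tbl |>
      distinct(.data$species, .data$tissue) |>
      tidyr::crossing(replicate = seq_len(replicates)) |>
      mutate(library = paste0(.data$species, "_", .data$tissue, "_r",
                              .data$replicate))
    rows <- map(seq_len(nrow(libs)), function(i) {
      lib <- libs[i, ]
      sub <- tbl |>
        filter(.data$species == lib$species, .data$tissue == lib$tissue)
      w <- sub$efficiency * sub$value * sub$length
      if (sum(w) <= 0) abort(paste0("library '", lib$library,
                                    "' has zero total expectation"))
      cnt <- if (is.null(library_size)) w
             else as.numeric(rmultinom(1, library_size, w))
      tibble(gene = sub$gene, library = lib$library, count = cnt,
             eff_length = sub$length)
    })
    list(counts = bind_rows(rows),
         meta = select(libs, "library", "species", "tissue", "replicate"))
  })
}

#' Simulate a full cross-species expression scenario
#'
#' Generates everything the pipeline consumes: duplication-loss gene
#' families with Brownian log-expression evolving on their true time
#' trees (one independent trait per tissue), a background of single-copy
#' genes with species-invariant expression filling out each reference,
#' lognormal gene-by-species counting-efficiency factors, and read counts.
#'
#' @param st a `species_tree` (default [example_species_tree()]).
#' @param n_families number of gene families (trees).
#' @param dup_rate,loss_rate duplication-loss rates per unit time.
#' @param n_background additional single-copy background genes per
#'   reference (shared across species).
#' @param tissues tissue names; the first is used as the ratio denominator
#'   downstream unless stated otherwise.
#' @param sigma2 Brownian rate of log-expression per tissue trait.
#' @param root_mean,root_sd distribution of family/tissue root
#'   log-expression values.
#' @param background_sdlog spread of background gene log-expression.
#' @param efficiency_sdlog lognormal sd of counting-efficiency factors
#'   (0 disables them).
#' @param library_size reads per library (`NULL` = expected counts).
#' @param replicates libraries per (species, tissue).
#' @param seed optional integer seed.
#' @return list: `species_tree`, `gene_trees`, `counts`, `meta`, `flags`,
#'   `n_reference` (tibble `species`, `n_genes`), `true_expression`
#'   (natural scale), `true_log_expression`, `efficiencies`, `tissues`.
#' @export
simulate_sbf_scenario <- function(st = example_species_tree(),
                                  n_families = 30,
                                  dup_rate = 0.5, loss_rate = 0.3,
                                  n_background = 2000,
                                  tissues = c("gastrozooid_mature",
                                              "gastrozooid_dev",
                                              "nectophore_dev",
                                              "palpon_mature",
                                              "pneumatophore"),
                                  sigma2 = 1,
                                  root_mean = 1.5, root_sd = 1,
                                  background_sdlog = 1.25,
                                  efficiency_sdlog = 0.5,
                                  library_size = NULL,
                                  replicates = 1,
                                  seed = NULL) {
  with_seed(seed, {
    trees <- simulate_gene_trees(st, dup_rate, loss_rate, n_families,
                                 seed = NULL)
    species <- st$phylo$tip.label
    # per-tissue BM traits on the true time tree of each family
    trait_rows <- list()
    for (fam in names(trees)) {
      gt <- trees[[fam]]
      tphy <- true_time_tree(gt)
      for (ti in tissues) {
        root <- rnorm(1, root_mean, root_sd)
        sim <- simulate_bm(tphy, root_value = root, sigma2 = sigma2)
        tip_vals <- sim$value[seq_len(n_tips(tphy))]
        trait_rows[[length(trait_rows) + 1]] <- tibble(
          gene = tphy$tip.label,
          species = trees[[fam]]$tip_species,
          tissue = ti,
          log_value = tip_vals)
      }
    }
    fam_expr <- bind_rows(trait_rows)
    # background single-copy genes, expression shared across species
    if (n_background > 0) {
      bg <- tidyr::crossing(
        gene = paste0("bg", seq_len(n_background)),
        tissue = tissues) |>
        mutate(log_value = rnorm(n(), root_mean, background_sdlog))
      bg <- tidyr::crossing(bg, species = species)
      fam_expr <- bind_rows(fam_expr, select(bg, "gene", "species",
                                             "tissue", "log_value"))
    }
    true_log <- fam_expr
    true_expr <- true_log |>
      mutate(value = exp(.data$log_value)) |>
      select("gene", "species", "tissue", "value")
    genes_by_species <- true_expr |> distinct(.data$gene, .data$species)
    eff <- genes_by_species |>
      mutate(efficiency = if (efficiency_sdlog > 0)
        rlnorm(n(), 0, efficiency_sdlog) else 1)
    sim <- simulate_counts(true_expr, eff, library_size = library_size,
                           replicates = replicates)
    flags <- tibble(gene = unique(true_expr$gene),
                    is_rRNA = FALSE, is_protein_coding = TRUE)
    n_ref <- genes_by_species |> count(.data$species, name = "n_genes")
    list(species_tree = st, gene_trees = trees, counts = sim$counts,
         meta = sim$meta, flags = flags, n_reference = n_ref,
         true_expression = true_expr, true_log_expression = true_log,
         efficiencies = eff, tissues = tissues)
  })
}
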