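#' Build a species tree object
#'
#' Wraps a rooted, binary, ultrametric `phylo` tree into a `species_tree`.
#' Branch lengths are rescaled so the root age equals 1 (the time unit used
#' throughout: gene-tree calibration, root-depth filters, and scaled branch
#' changes are all expressed on this scale). Non-root branches receive
#' deterministic preorder letter identifiers (A, B, C, ...).
#'
#' @param phy an ape `phylo` object, or a Newick string/file (see
#'   [read_species_tree()]). Must be rooted, binary and ultrametric.
#' @param tol relative tolerance on tip-depth equality for the
#'   ultrametricity check, as a fraction of root age.
#' @return an object of class `species_tree`: a list with elements `phylo`
#'   (rescaled), `age` (node ages, root = 1, tips = 0), and `branch_id`
#'   (letter per non-root node, indexing the branch above that node).
#' @seealso [label_species_branches()], [read_species_tree()]
#' @export
#' @examples
#' st <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' st$age[4]           # root age is rescaled to 1
#' st$branch_id        # preorder letters on the 4 non-root branches
species_tree <- function(phy, tol = 1e-8) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) {
    abort("species tree must have branch lengths")
  }
  if (!ape::is.rooted(phy)) {
    abort("species tree must be rooted")
  }
  if (!ape::is.binary(phy)) {
    abort("species tree must be binary")
  }
  if (anyDuplicated(phy$tip.label)) {
    abort("species tip labels must be unique")
  }
  depth <- node_depths(phy)
  tipd <- depth[seq_len(n_tips(phy))]
  root_age <- max(tipd)
  if (root_age <= 0) abort("species tree has zero depth")
  if (any(abs(tipd - root_age) > tol * root_age)) {
    bad <- phy$tip.label[which.max(abs(tipd - root_age))]
    abort(paste0("species tree is not ultrametric (tip '", bad,
                 "' depth deviates by more than ", format(tol),
                 " x root age)"))
  }
  phy$edge.length <- phy$edge.length / root_age
  age <- node_ages_from_depths(phy)
  age[seq_len(n_tips(phy))] <- 0
  st <- structure(
    list(phylo = phy, age = age, branch_id = NULL),
    class = "species_tree"
  )
  label_species_branches(st)
}

#' Assign letter identifiers to species-tree branches
#'
#' Every non-root branch gets a single letter id (A, B, ... then AA, AB, ...)
#' in deterministic preorder (cladewise) traversal of the tree. Relabeling is
#' idempotent. These ids are the units reported by the species-branch
#' filtering tallies: gene-tree branches equivalent to a given species-tree
#' branch inherit its id.
#'
#' @param st a `species_tree`
#' @return the `species_tree` with `branch_id` filled in: a character vector
#'   indexed by child node of each branch (`NA` at the root).
#' @export
label_species_branches <- function(st) {
  stopifnot(inherits(st, "species_tree"))
  phy <- st$phylo
  e <- ape::reorder.phylo(phy, "cladewise")$edge
  ids <- rep(NA_character_, n_tips(phy) + phy$Nnode)
  ids[e[, 2]] <- letter_ids(nrow(e))
  st$branch_id <- ids
  st
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree:", n_tips(x$phylo), "species,",
      sum(!is.na(x$branch_id)), "labeled branches, root age",
      format(x$age[root_node(x$phylo)]), "\n")
  invisible(x)
}

#' Build a gene tree object
#'
#' Wraps a rooted `phylo` gene tree whose tip labels carry species identity
#' (`"species<sep>gene"`, e.g. `"Nbijuga@g17"`), or for which an explicit
#' tip-to-species mapping is supplied. Branch lengths are interpreted as
#' substitutions per site until the tree is calibrated.
#'
#' @param phy an ape `phylo`, rooted, with branch lengths >= 0.
#' @param separator separator between species and gene in tip labels.
#' @param tip_species optional named character vector (names = tip labels,
#'   values = species); overrides label parsing.
#' @param event optional per-internal-node event vector (`"speciation"`,
#'   `"duplication"`, `"null"`, or `NA` for unassigned), e.g. recovered from
#'   NHX annotations.
#' @param species_node optional per-internal-node species-tree node ids.
#' @return an object of class `gene_tree` with elements `phylo`,
#'   `tip_species`, `gene` (per tip), `event` and `species_node` (per
#'   internal node, index 1 = root), `separator`.
#' @export
gene_tree <- function(phy, separator = "@", tip_species = NULL,
                      event = NULL, species_node = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) abort("gene tree must be rooted")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  if (any(phy$edge.length < 0)) abort("gene tree branch lengths must be >= 0")
  labs <- phy$tip.label
  if (is.null(labs) || any(!nzchar(labs))) abort("gene tree tips must be labeled")
  if (is.null(tip_species)) {
    parts <- strsplit(labs, separator, fixed = TRUE)
    sp <- map_chr(parts, 1)
    gid <- map_chr(parts, function(p) {
      if (length(p) >= 2) paste(p[-1], collapse = separator) else p[[1]]
    })
  } else {
    if (!all(labs %in% names(tip_species))) {
      missing_tip <- setdiff(labs, names(tip_species))[1]
      abort(paste0("no species mapping for tip '", missing_tip, "'"))
    }
    sp <- unname(tip_species[labs])
    gid <- labs
  }
  nn <- phy$Nnode
  ev <- event %||% rep(NA_character_, nn)
  sn <- species_node %||% rep(NA_integer_, nn)
  stopifnot(length(ev) == nn, length(sn) == nn)
  structure(
    list(phylo = phy, tip_species = sp, gene = gid,
         event = ev, species_node = as.integer(sn),
         separator = separator),
    class = "gene_tree"
  )
}

#' @export
print.gene_tree <- function(x, ...) {
  nn <- x$phylo$Nnode
  cat(if (inherits(x, "calibrated_gene_tree")) "Calibrated gene" else "Gene",
      "tree:", n_tips(x$phylo), "tips,",
      length(unique(x$tip_species)), "species;",
      sum(x$event %in% "speciation"), "speciation /",
      sum(x$event %in% "duplication"), "duplication /",
      sum(x$event %in% "null"), "null of", nn, "internal nodes\n")
  invisible(x)
}

# event vector indexed by *node number* (NA over tips) for internal use
node_events <- function(gt) {
  c(rep(NA_character_, n_tips(gt$phylo)), gt$event)
}

node_species_nodes <- function(gt) {
  c(rep(NA_integer_, n_tips(gt$phylo)), gt$species_node)
}

internal_index <- function(gt, node) node - n_tips(gt$phylo)

#' Per-node annotation table of a gene tree
#'
#' @param gt a `gene_tree`
#' @param st optional `species_tree`; when given, `species_node` ids are also
#'   reported as clade labels of the species tree.
#' @return a tibble with one row per gene-tree node: `node`, `type`
#'   (tip/internal), `label`, `species`, `event`, `species_node`.
#' @export
node_table <- function(gt, st = NULL) {
  phy <- gt$phylo
  nt <- n_tips(phy)
  nodes <- all_nodes(phy)
  tbl <- tibble(
    node = nodes,
    type = ifelse(nodes <= nt, "tip", "internal"),
    label = c(phy$tip.label,
              phy$node.label %||% rep(NA_character_, phy$Nnode)),
    species = c(gt$tip_species, rep(NA_character_, phy$Nnode)),
    event = node_events(gt),
    species_node = node_species_nodes(gt)
  )
  if (!is.null(st)) {
    tbl$species_branch <- ifelse(
      is.na(tbl$species_node), NA_character_, st$branch_id[tbl$species_node])
  }
  tbl
}
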