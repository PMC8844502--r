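# Low-level helpers shared by the tree-facing modules. All node indices follow
# the ape convention: tips 1..Ntip, internal nodes Ntip+1..Ntip+Nnode, with the
# root at Ntip+1 on a rooted tree.

n_tips <- function(phy) length(phy$tip.label)

all_nodes <- function(phy) seq_len(n_tips(phy) + phy$Nnode)

internal_nodes <- function(phy) n_tips(phy) + seq_len(phy$Nnode)

root_node <- function(phy) n_tips(phy) + 1L

is_tip <- function(phy, node) node <= n_tips(phy)

# parent[node] for every node; 0 for the root
parent_vector <- function(phy) {
  p <- integer(n_tips(phy) + phy$Nnode)
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

# list of child node vectors indexed by node
children_list <- function(phy) {
  ch <- vector("list", n_tips(phy) + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]
    ch[[a]] <- c(ch[[a]], phy$edge[i, 2])
  }
  ch
}

# edge index (row of phy$edge) keyed by child node; 0 for the root
edge_index_by_child <- function(phy) {
  idx <- integer(n_tips(phy) + phy$Nnode)
  idx[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  idx
}

# nodes in postorder (children before parents)
postorder_nodes <- function(phy) {
  e <- ape::reorder.phylo(phy, "postorder")$edge
  unique(c(e[, 2], e[nrow(e), 1]))
}

# nodes in preorder (parents before children)
preorder_nodes <- function(phy) rev(postorder_nodes(phy))

# distance from the root to every node, in edge-length units
node_depths <- function(phy) {
  depth <- numeric(n_tips(phy) + phy$Nnode)
  e <- ape::reorder.phylo(phy, "cladewise")$edge
  len <- ape::reorder.phylo(phy, "cladewise")$edge.length
  for (i in seq_len(nrow(e))) depth[e[i, 2]] <- depth[e[i, 1]] + len[i]
  depth
}

# ages (time above the present) assuming the deepest tip sits at the present
node_ages_from_depths <- function(phy) {
  depth <- node_depths(phy)
  age <- max(depth[seq_len(n_tips(phy))]) - depth
  age[abs(age) < 1e-12] <- 0
  age
}

# species set below every node, as a list of character vectors
species_sets <- function(phy, tip_species) {
  sets <- vector("list", n_tips(phy) + phy$Nnode)
  for (i in seq_len(n_tips(phy))) sets[[i]] <- tip_species[[i]]
  e <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(e))) {
    a <- e[i, 1]; b <- e[i, 2]
    sets[[a]] <- union(sets[[a]], sets[[b]])
  }
  sets
}

# A, B, ..., Z, AA, AB, ... — deterministic branch identifiers
letter_ids <- function(n) {
  out <- character(n)
  for (i in seq_len(n)) {
    k <- i
    s <- ""
    while (k > 0) {
      r <- (k - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      k <- (k - 1L) %/% 26L
    }
    out[i] <- s
  }
  out
}

# run code under a temporary RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
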