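# Pruning to observed tips and joint maximum-likelihood ancestral state
# reconstruction under Brownian motion.
#
# The joint ML ancestral states under BM are the minimizers of
# sum over branches of (value_child - value_parent)^2 / t, a weighted
# least-squares problem solved exactly by a two-pass (post-order then
# pre-order) message-passing scheme in linear time.

MIN_BRANCH_TIME <- 1e-9

floor_branch_times <- function(t) {
  if (any(t < MIN_BRANCH_TIME)) {
    warn(paste0(sum(t < MIN_BRANCH_TIME), " calibrated branch(es) shorter ",
                "than ", format(MIN_BRANCH_TIME), " floored"))
    t[t < MIN_BRANCH_TIME] <- MIN_BRANCH_TIME
  }
  t
}

# joint ML BM values for every node of `phy` given named tip values
bm_joint_ml <- function(phy, tip_values) {
  nt <- n_tips(phy)
  N <- nt + phy$Nnode
  x <- tip_values[phy$tip.label]
  stopifnot(!anyNA(x))
  eidx <- edge_index_by_child(phy)
  tlen <- floor_branch_times(phy$edge.length)
  ch <- children_list(phy)
  mu <- numeric(N); lef <- numeric(N) # message mean and effective length
  value <- numeric(N)
  value[seq_len(nt)] <- x
  post <- postorder_nodes(phy)
  rt <- root_node(phy)
  condvar <- numeric(N)
  for (v in post) {
    if (is_tip(phy, v)) {
      mu[[v]] <- value[[v]]
      lef[[v]] <- tlen[[eidx[[v]]]]
      next
    }
    w <- 1 / lef[ch[[v]]]
    mu[[v]] <- sum(w * mu[ch[[v]]]) / sum(w)
    condvar[[v]] <- 1 / sum(w)
    if (v != rt) lef[[v]] <- tlen[[eidx[[v]]]] + condvar[[v]]
  }
  value[[rt]] <- mu[[rt]]
  par <- parent_vector(phy)
  for (v in preorder_nodes(phy)) {
    if (v == rt || is_tip(phy, v)) next
    p <- value[[par[[v]]]]
    t_up <- tlen[[eidx[[v]]]]
    value[[v]] <- (mu[[v]] / condvar[[v]] + p / t_up) /
      (1 / condvar[[v]] + 1 / t_up)
  }
  value
}

#' Prune a calibrated gene tree to tips with observed values
#'
#' Tips without (finite) values are removed; resulting degree-2 nodes are
#' suppressed with their incident time lengths summed, so path lengths
#' among surviving tips are conserved. Original node identities are
#' retained in `$orig_node`.
#'
#' @param ct a `calibrated_gene_tree`.
#' @param tip_values named numeric vector (names = tip labels).
#' @return a pruned `calibrated_gene_tree` (events/ages subset to surviving
#'   nodes, `orig_node` mapping new to original node numbers), or `NULL`
#'   with a warning when fewer than two tips carry values.
#' @export
prune_to_observed <- function(ct, tip_values) {
  stopifnot(inherits(ct, "calibrated_gene_tree"))
  phy <- ct$phylo
  nt <- n_tips(phy)
  valued <- names(tip_values)[is.finite(tip_values)]
  keep <- phy$tip.label %in% valued
  if (sum(keep) < 2) {
    warn("fewer than two tips carry values; nothing to prune to")
    return(NULL)
  }
  if (all(keep)) {
    ct$orig_node <- all_nodes(phy)
    return(ct)
  }
  tagged <- phy
  tagged$node.label <- paste0(".n", internal_nodes(phy))
  pruned <- ape::drop.tip(tagged, phy$tip.label[!keep], collapse.singles = TRUE)
  ntp <- length(pruned$tip.label)
  orig_internal <- as.integer(sub("^\\.n", "", pruned$node.label))
  orig_tip <- match(pruned$tip.label, phy$tip.label)
  orig_node <- c(orig_tip, orig_internal)
  out <- ct
  out$phylo <- pruned
  out$phylo$node.label <- NULL
  out$tip_species <- ct$tip_species[orig_tip]
  out$gene <- ct$gene[orig_tip]
  out$event <- ct$event[orig_internal - nt]
  out$species_node <- ct$species_node[orig_internal - nt]
  out$age <- ct$age[orig_node]
  out$subst_length <- NULL
  out$orig_node <- orig_node
  out
}

#' Reconstruct ancestral log-expression under Brownian motion
#'
#' Prunes the tree to tips with observed values, computes joint
#' maximum-likelihood ancestral states under a Brownian-motion model (the
#' weighted-least-squares optimum minimizing the sum of squared changes per
#' unit time), and maps node values back onto the unpruned tree. Nodes
#' suppressed during pruning receive no value (`provenance = "absent"`):
#' a branch change is only computed where both endpoints carry values.
#'
#' @param ct a `calibrated_gene_tree` (unpruned).
#' @param tip_values named numeric vector of observed tip values
#'   (log-scale expression, or log-ratios).
#' @param min_tips minimum number of valued tips required (default 3).
#' @return a trait map tibble over the unpruned tree's nodes: `node`,
#'   `value`, `provenance` (`observed` / `reconstructed` / `absent`).
#' @export
reconstruct_ancestral_bm <- function(ct, tip_values, min_tips = 3) {
  stopifnot(inherits(ct, "calibrated_gene_tree"))
  n_val <- sum(ct$phylo$tip.label %in% names(tip_values)[is.finite(tip_values)])
  if (n_val < min_tips) {
    abort(paste0("only ", n_val, " tips carry values; >= ", min_tips,
                 " required for reconstruction"))
  }
  pruned <- prune_to_observed(ct, tip_values)
  vals <- bm_joint_ml(pruned$phylo, tip_values)
  N <- n_tips(ct$phylo) + ct$phylo$Nnode
  out <- tibble(node = seq_len(N), value = NA_real_, provenance = "absent")
  out$value[pruned$orig_node] <- vals
  ntp <- n_tips(pruned$phylo)
  out$provenance[pruned$orig_node[seq_len(ntp)]] <- "observed"
  out$provenance[pruned$orig_node[-seq_len(ntp)]] <- "reconstructed"
  out
}
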