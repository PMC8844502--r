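# Event annotation of gene-tree nodes (species overlap), mapping of
# speciation nodes onto the species tree, and null-node marking.

#' Label gene-tree nodes as speciation or duplication (species overlap)
#'
#' An internal node is a duplication if the species sets of its child
#' subtrees intersect, a speciation otherwise. Nodes that already carry an
#' event annotation (e.g. from NHX input produced by an upstream
#' reconciliation) are left untouched unless `overwrite = TRUE`. A
#' non-binary node is treated as a single event over all pairs of its
#' children's species sets, with a warning.
#'
#' @param gt a `gene_tree`
#' @param overwrite relabel nodes that already have an event (default FALSE).
#' @return the `gene_tree` with `event` filled in.
#' @export
label_events <- function(gt, overwrite = FALSE) {
  phy <- gt$phylo
  nt <- n_tips(phy)
  sets <- species_sets(phy, gt$tip_species)
  ch <- children_list(phy)
  warned <- FALSE
  for (node in internal_nodes(phy)) {
    j <- node - nt
    if (!overwrite && !is.na(gt$event[[j]])) next
    kids <- ch[[node]]
    if (length(kids) > 2 && !warned) {
      warn("non-binary gene-tree node: treating as a single event over all children")
      warned <- TRUE
    }
    overlap <- FALSE
    for (a in seq_along(kids)) {
      for (b in seq_along(kids)) {
        if (a < b && length(intersect(sets[[kids[[a]]]], sets[[kids[[b]]]]))) {
          overlap <- TRUE
        }
      }
    }
    gt$event[[j]] <- if (overlap) "duplication" else "speciation"
  }
  gt
}

#' Map speciation nodes onto species-tree nodes
#'
#' Every speciation node is assigned the most recent common ancestor, in the
#' species tree, of the species found at its descendant tips. Duplication
#' nodes carry no mapping. A single-species clade maps to that species' tip
#' node.
#'
#' @param gt a `gene_tree` with events labeled (see [label_events()]).
#' @param st a `species_tree`.
#' @return the `gene_tree` with `species_node` filled in (species-tree node
#'   numbers).
#' @export
map_speciation_nodes <- function(gt, st) {
  phy <- gt$phylo
  nt <- n_tips(phy)
  sp_tips <- st$phylo$tip.label
  unknown <- setdiff(unique(gt$tip_species), sp_tips)
  if (length(unknown)) {
    abort(paste0("species '", unknown[[1]], "' is not in the species tree"))
  }
  sets <- species_sets(phy, gt$tip_species)
  for (node in internal_nodes(phy)) {
    j <- node - nt
    if (is.na(gt$event[[j]]) || gt$event[[j]] == "duplication") {
      gt$species_node[[j]] <- NA_integer_
      next
    }
    spp <- sets[[node]]
    tipn <- match(spp, sp_tips)
    gt$species_node[[j]] <- if (length(tipn) == 1) tipn else
      as.integer(ape::getMRCA(st$phylo, tipn))
  }
  gt
}

#' Mark nested same-mapping speciation nodes as null
#'
#' Traversing from the root toward the tips, a speciation node whose mapped
#' species-tree node has already been claimed by a non-null speciation
#' ancestor on the same root-to-node path is demoted to `event = "null"`
#' (its `species_node` is retained for diagnostics). Such nodes arise when
#' the species-overlap method labels a node speciation although the local
#' topology conflicts with the species tree; without demotion they would
#' impose equal-age calibration constraints on nested nodes. Intervening
#' duplication nodes do not reset the scan.
#'
#' @param gt a `gene_tree` with `species_node` assigned.
#' @return the `gene_tree` with null nodes marked; the number of demoted
#'   nodes is available as `attr(, "n_nulled")`.
#' @export
mark_null_nodes <- function(gt) {
  phy <- gt$phylo
  nt <- n_tips(phy)
  ch <- children_list(phy)
  n_nulled <- 0L
  recurse <- function(node, claimed) {
    if (node <= nt) return(invisible(NULL))
    j <- node - nt
    ev <- gt$event[[j]]
    sn <- gt$species_node[[j]]
    if (!is.na(ev) && ev == "speciation" && !is.na(sn)) {
      if (sn %in% claimed) {
        gt$event[[j]] <<- "null"
        n_nulled <<- n_nulled + 1L
      } else {
        claimed <- c(claimed, sn)
      }
    }
    for (k in ch[[node]]) recurse(k, claimed)
    invisible(NULL)
  }
  recurse(root_node(phy), integer(0))
  attr(gt, "n_nulled") <- n_nulled
  gt
}

#' Fully annotate a gene tree against a species tree
#'
#' Convenience wrapper: [label_events()] (honoring pre-existing NHX events),
#' then [map_speciation_nodes()], then [mark_null_nodes()].
#'
#' @inheritParams map_speciation_nodes
#' @return an annotated `gene_tree`.
#' @export
annotate_gene_tree <- function(gt, st) {
  mark_null_nodes(map_speciation_nodes(label_events(gt), st))
}
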