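# Time calibration of annotated gene trees against the species tree.
#
# Non-null speciation nodes are pinned exactly to the age of their mapped
# species-tree node (tips to age 0); every other node is placed by
# deterministic interpolation between its nearest constrained ancestor and
# its oldest constrained descendant, proportional to the original
# substitution branch lengths. When all original lengths on the path carry
# the default (effectively zero) value, ages are spread evenly by hop count
# instead. The contract any chronos-like dating method must satisfy —
# constrained ages exact, parent strictly older than child — holds by
# construction; a penalized-likelihood optimizer can be substituted as long
# as it honors the same constraints.

#' Test for a calibration failure object
#'
#' @param x result of [calibrate_gene_tree()]
#' @return TRUE if calibration failed (infeasible constraints).
#' @export
is_calibration_failure <- function(x) inherits(x, "calibration_failure")

#' @export
print.calibration_failure <- function(x, ...) {
  cat("Calibration failure:", x$message, "\n")
  invisible(x)
}

calibration_failure <- function(parent, child, parent_age, child_age) {
  structure(
    list(parent = parent, child = child,
         parent_age = parent_age, child_age = child_age,
         message = paste0("constrained node ", child, " (age ",
                          format(child_age), ") is not younger than its ",
                          "constrained ancestor ", parent, " (age ",
                          format(parent_age), ")")),
    class = "calibration_failure"
  )
}

#' Time-calibrate a gene tree against the species tree
#'
#' Produces a `calibrated_gene_tree` whose branch lengths are in
#' species-tree time units (root of the species tree = 1). Tips sit at age
#' 0 and every non-null speciation node at the age of its species-tree
#' node, exactly. Duplication and null nodes are interpolated (see the
#' package vignette for the placement rules, including the unconstrained
#' root). Returns a `calibration_failure` carrying the violating node pair
#' when a constrained descendant is at least as old as a constrained
#' ancestor.
#'
#' @param gt an annotated `gene_tree` (events, species nodes and nulls
#'   assigned; see [annotate_gene_tree()]).
#' @param st the `species_tree` used for annotation.
#' @return a `calibrated_gene_tree` (with `age` per node and original
#'   substitution lengths kept in `subst_length`), or a
#'   `calibration_failure`.
#' @export
calibrate_gene_tree <- function(gt, st) {
  phy <- gt$phylo
  nt <- n_tips(phy)
  nn <- phy$Nnode
  N <- nt + nn
  par <- parent_vector(phy)
  ch <- children_list(phy)
  eidx <- edge_index_by_child(phy)
  elen <- phy$edge.length

  # constrained ages: tips at 0, non-null speciation nodes at species age
  cage <- rep(NA_real_, N)
  cage[seq_len(nt)] <- 0
  for (j in seq_len(nn)) {
    if (!is.na(gt$event[[j]]) && gt$event[[j]] == "speciation" &&
        !is.na(gt$species_node[[j]])) {
      cage[nt + j] <- st$age[[gt$species_node[[j]]]]
    }
  }
  constrained <- !is.na(cage)

  post <- postorder_nodes(phy)
  # per node: oldest constrained strict descendant (age, id, path length in
  # original units, path hops, all-default flag), plus max original depth
  # and hop depth below the node
  m_age <- rep(-Inf, N); m_node <- rep(NA_integer_, N)
  m_len <- numeric(N); m_hops <- integer(N); m_def <- rep(TRUE, N)
  depth_len <- numeric(N); depth_hops <- integer(N)
  for (v in post) {
    if (is_tip(phy, v)) next
    best <- -Inf
    for (c_ in ch[[v]]) {
      b <- elen[[eidx[[c_]]]]
      depth_len[[v]] <- max(depth_len[[v]], b + depth_len[[c_]])
      depth_hops[[v]] <- max(depth_hops[[v]], 1L + depth_hops[[c_]])
      cand_age <- if (constrained[[c_]]) cage[[c_]] else m_age[[c_]]
      if (cand_age > best) {
        best <- cand_age
        if (constrained[[c_]]) {
          m_node[[v]] <- c_
          m_len[[v]] <- b
          m_hops[[v]] <- 1L
          m_def[[v]] <- b <= DEFAULT_BRANCH_LENGTH
        } else {
          m_node[[v]] <- m_node[[c_]]
          m_len[[v]] <- b + m_len[[c_]]
          m_hops[[v]] <- 1L + m_hops[[c_]]
          m_def[[v]] <- m_def[[c_]] && b <= DEFAULT_BRANCH_LENGTH
        }
      }
    }
    m_age[[v]] <- best
    # feasibility: a constrained node must be strictly older than every
    # constrained node below it
    if (constrained[[v]] && cage[[v]] <= m_age[[v]]) {
      return(calibration_failure(v, m_node[[v]], cage[[v]], m_age[[v]]))
    }
  }

  age <- rep(NA_real_, N)
  pre <- preorder_nodes(phy)
  rt <- root_node(phy)
  no_positive_constraint <- !any(cage > 0, na.rm = TRUE)
  for (v in pre) {
    if (constrained[[v]]) {
      age[[v]] <- cage[[v]]
      next
    }
    if (no_positive_constraint) {
      # no speciation constraints anywhere (such trees are filtered out
      # downstream): fall back to original heights so output is well formed
      age[[v]] <- depth_len[[v]]
      next
    }
    m <- m_age[[v]]
    if (v == rt) {
      # unconstrained root: extrapolate above the oldest constrained
      # descendant at that subtree's implied substitution rate
      d <- m_node[[v]]
      D <- depth_len[[d]]
      if (!m_def[[v]] && D > DEFAULT_BRANCH_LENGTH) {
        age[[v]] <- m + m_len[[v]] * (m / D)
      } else {
        h_d <- max(1L, depth_hops[[d]])
        age[[v]] <- m * (h_d + m_hops[[v]]) / h_d
      }
      next
    }
    P <- age[[par[[v]]]]
    b <- elen[[eidx[[v]]]]
    if (!m_def[[v]] || b > DEFAULT_BRANCH_LENGTH) {
      s <- m_len[[v]]
      age[[v]] <- m + (P - m) * s / (s + b)
    } else {
      # all original lengths on the path are default: spread evenly
      k <- m_hops[[v]]
      age[[v]] <- m + (P - m) * k / (k + 1L)
    }
  }

  newlen <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  newlen[newlen < 0 & newlen > -1e-12] <- 0
  ct <- gt
  ct$subst_length <- elen
  ct$phylo$edge.length <- newlen
  ct$age <- age
  class(ct) <- c("calibrated_gene_tree", "gene_tree")
  ct
}

#' Root age of a calibrated gene tree
#'
#' The maximum node age; values above the root-depth threshold (default 5
#' in [sbf_filter_thresholds()], with the species-tree root at 1) indicate
#' calibration problems.
#'
#' @param ct a `calibrated_gene_tree`
#' @return the root age (a scalar).
#' @export
root_depth <- function(ct) {
  stopifnot(inherits(ct, "calibrated_gene_tree"))
  ct$age[[root_node(ct$phylo)]]
}
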