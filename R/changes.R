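# The SBF core: scaled per-branch expression changes, species-equivalent
# branch identification, change classification and per-branch tallies.

#' Thresholds for classifying scaled expression changes
#'
#' A scaled change in `[neutral_lo, neutral_hi]` (boundaries included) is
#' neutral; below `neutral_lo` negative; above `neutral_hi` positive.
#' `large` is the absolute cutoff used to flag very large changes
#' (putative lineage-specific expression shifts).
#'
#' @param neutral_lo,neutral_hi bounds of the neutral band (default -2, 2).
#' @param large absolute threshold for very large changes (default 5).
#' @export
sbf_change_thresholds <- function(neutral_lo = -2, neutral_hi = 2, large = 5) {
  stopifnot(neutral_lo < 0, 0 < neutral_hi, neutral_hi < large)
  list(neutral_lo = neutral_lo, neutral_hi = neutral_hi, large = large)
}

#' Classify scaled changes
#'
#' @param delta numeric vector of scaled changes.
#' @param thresholds see [sbf_change_thresholds()].
#' @return character vector: `"negative"`, `"neutral"` or `"positive"`.
#' @export
classify_change <- function(delta, thresholds = sbf_change_thresholds()) {
  if (any(is.nan(delta) | is.na(delta))) {
    abort("scaled changes must be finite; found NaN/NA")
  }
  ifelse(delta < thresholds$neutral_lo, "negative",
         ifelse(delta > thresholds$neutral_hi, "positive", "neutral"))
}

#' Identify species-equivalent branches of a gene tree
#'
#' A gene-tree branch (u -> v) is equivalent to a species-tree branch when u
#' is a non-null speciation node and either (a) v is a non-null speciation
#' node whose species node is a child, in the species tree, of u's species
#' node, or (b) v is a tip whose species' tip node is a child of u's species
#' node. The branch inherits the species-tree branch id of the child
#' species node. Due to duplications, several gene-tree branches may map to
#' the same species-tree branch; branches spanning more than one
#' species-tree branch remain unlabeled.
#'
#' @param gt an annotated `gene_tree` (or `calibrated_gene_tree`).
#' @param st the `species_tree`.
#' @return tibble `parent_node`, `child_node`, `species_branch` (`NA` for
#'   unlabeled branches), one row per gene-tree branch.
#' @export
find_species_equivalent_branches <- function(gt, st) {
  phy <- gt$phylo
  nt <- n_tips(phy)
  ev <- node_events(gt)
  sn <- node_species_nodes(gt)
  st_parent <- parent_vector(st$phylo)
  sp_tip_node <- setNames(seq_along(st$phylo$tip.label), st$phylo$tip.label)
  label <- rep(NA_character_, nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    u <- phy$edge[i, 1]; v <- phy$edge[i, 2]
    if (is.na(ev[[u]]) || ev[[u]] != "speciation") next
    if (v <= nt) {
      child_sn <- sp_tip_node[[gt$tip_species[[v]]]]
    } else {
      if (is.na(ev[[v]]) || ev[[v]] != "speciation") next
      child_sn <- sn[[v]]
      if (is.na(child_sn)) next
    }
    if (!is.na(sn[[u]]) && st_parent[[child_sn]] == sn[[u]]) {
      label[[i]] <- st$branch_id[[child_sn]]
    }
  }
  tibble(parent_node = phy$edge[, 1], child_node = phy$edge[, 2],
         species_branch = label)
}

#' Scaled expression changes along gene-tree branches
#'
#' For every branch whose two endpoints carry trait values, the change is
#' `(child value - parent value) / time length`. Calibrated branch times
#' shorter than 1e-9 are floored at that value and the record flagged. When a species tree is supplied, records carry the
#' species-equivalent branch id (`NA` where the branch is not
#' species-equivalent).
#'
#' @param ct a `calibrated_gene_tree`.
#' @param traits trait map from [reconstruct_ancestral_bm()] (or
#'   [ratio_trait_map()]).
#' @param tissue label recorded in the records (a tissue, or a tissue-ratio
#'   label such as `"palpon/gastrozooid"`).
#' @param st optional `species_tree` for species-equivalent labeling.
#' @param tree_id identifier recorded in the records.
#' @param thresholds see [sbf_change_thresholds()].
#' @return tibble of branch-change records: `tree_id`, `parent_node`,
#'   `child_node`, `tissue`, `parent_value`, `child_value`, `time_length`,
#'   `scaled_change`, `class`, `flagged`, and `species_branch` when `st`
#'   is given.
#' @export
scaled_branch_changes <- function(ct, traits, tissue = "tissue", st = NULL,
                                  tree_id = "tree",
                                  thresholds = sbf_change_thresholds()) {
  stopifnot(inherits(ct, "calibrated_gene_tree"))
  phy <- ct$phylo
  val <- rep(NA_real_, n_tips(phy) + phy$Nnode)
  val[traits$node] <- traits$value
  u <- phy$edge[, 1]; v <- phy$edge[, 2]
  ok <- is.finite(val[u]) & is.finite(val[v])
  tlen <- phy$edge.length
  flagged <- tlen < MIN_BRANCH_TIME
  tlen <- pmax(tlen, MIN_BRANCH_TIME)
  rec <- tibble(
    tree_id = tree_id,
    parent_node = u[ok],
    child_node = v[ok],
    tissue = tissue,
    parent_value = val[u][ok],
    child_value = val[v][ok],
    time_length = tlen[ok],
    scaled_change = (val[v][ok] - val[u][ok]) / tlen[ok],
    flagged = flagged[ok]
  )
  rec$class <- classify_change(rec$scaled_change, thresholds)
  if (!is.null(st)) {
    seb <- find_species_equivalent_branches(ct, st)
    rec <- left_join(rec, seb, by = c("parent_node", "child_node"))
  }
  rec
}

#' Node-wise ratio of two tissues' trait maps
#'
#' The log-ratio trait at a node is the difference of the two tissues'
#' values there; only nodes valued for both tissues carry a ratio (tissue
#' sampling differs, so the pruned trees behind the two maps may differ).
#'
#' @param numerator,denominator trait maps from
#'   [reconstruct_ancestral_bm()] over the same (unpruned) tree.
#' @return a trait map tibble (`node`, `value`, `provenance`).
#' @export
ratio_trait_map <- function(numerator, denominator) {
  stopifnot(nrow(numerator) == nrow(denominator))
  both <- !is.na(numerator$value) & !is.na(denominator$value)
  prov <- ifelse(!both, "absent",
                 ifelse(numerator$provenance == "observed" &
                          denominator$provenance == "observed",
                        "observed", "reconstructed"))
  tibble(node = numerator$node,
         value = ifelse(both, numerator$value - denominator$value, NA_real_),
         provenance = prov)
}

#' Tally classified changes per species-equivalent branch
#'
#' Counts records by (species branch, tissue, class). Only records on
#' species-equivalent branches enter the tally; a (branch, tissue) pair
#' with no records (e.g. ratio analyses in species lacking the denominator
#' tissue) is simply absent.
#'
#' @param records branch-change records from [scaled_branch_changes()]
#'   (rows from several trees may be bound together).
#' @return an `sbf_tally` tibble: `species_branch`, `tissue`,
#'   `n_negative`, `n_neutral`, `n_positive`, `n_total`.
#' @export
tally_changes <- function(records) {
  if (!"species_branch" %in% names(records)) {
    abort("records carry no species_branch column; pass `st` to scaled_branch_changes()")
  }
  out <- records |>
    filter(!is.na(.data$species_branch)) |>
    count(.data$species_branch, .data$tissue, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  for (col in c("n_negative", "n_neutral", "n_positive")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out <- out |>
    mutate(n_total = .data$n_negative + .data$n_neutral + .data$n_positive) |>
    select("species_branch", "tissue", "n_negative", "n_neutral",
           "n_positive", "n_total") |>
    arrange(.data$species_branch, .data$tissue)
  class(out) <- c("sbf_tally", class(out))
  out
}

#' Mean number of species-equivalent branches per species branch
#'
#' The mean, over tissues (or tissue ratios), of the number of classified
#' branches mapping to each species-tree branch.
#'
#' @param tally an `sbf_tally` from [tally_changes()].
#' @return tibble `species_branch`, `mean_branches`.
#' @export
mean_branch_counts <- function(tally) {
  tally |>
    as_tibble() |>
    group_by(.data$species_branch) |>
    summarise(mean_branches = mean(.data$n_total), .groups = "drop")
}

#' Records with very large scaled changes
#'
#' @param records branch-change records.
#' @param threshold absolute cutoff (default the `large` threshold, 5).
#' @return the subset of records with `|scaled_change| > threshold`.
#' @export
large_changes <- function(records, threshold = sbf_change_thresholds()$large) {
  records |> filter(abs(.data$scaled_change) > threshold)
}

#' @describeIn tally_changes stacked-bar plot of change classes per species
#'   branch and tissue (negative/neutral/positive).
#' @param object an `sbf_tally`.
#' @param ... ignored.
#' @method autoplot sbf_tally
#' @export
autoplot.sbf_tally <- function(object, ...) {
  long <- object |>
    as_tibble() |>
    tidyr::pivot_longer(cols = c("n_negative", "n_neutral", "n_positive"),
                        names_to = "class", values_to = "n") |>
    mutate(class = sub("^n_", "", .data$class))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tissue, y = .data$n,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$species_branch)) +
    ggplot2::scale_fill_manual(values = c(negative = "#c0392b",
                                          neutral = "#27ae60",
                                          positive = "#2980b9")) +
    ggplot2::labs(x = NULL, y = "branches", fill = "change") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
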