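# Classical between-species analysis (species tree filtering, STF):
# strict-ortholog extraction and two-factor variance partitioning into
# species-variable (SVG) and tissue-variable (TVG) genes.

#' Extract strict orthologs from annotated gene trees
#'
#' A gene tree yields a strict-ortholog group when, restricted to the
#' listed species, it contains exactly one gene per species and the
#' subtree connecting those genes contains no duplication and no null
#' nodes (gene lineages related only by speciation events). Alternatively
#' an external single-copy table is validated and passed through.
#'
#' @param gene_trees a (named) list of annotated `gene_tree`s, or `NULL`
#'   when `ortholog_table` is supplied.
#' @param species_list species that must each contribute exactly one gene.
#' @param ortholog_table optional external table (`group`, `species`,
#'   `gene`); groups with a duplicated or missing species are dropped with
#'   a warning.
#' @return tibble `group`, `species`, `gene` (and `tree_id` when derived
#'   from trees).
#' @export
extract_strict_orthologs <- function(gene_trees = NULL, species_list,
                                     ortholog_table = NULL) {
  if (!is.null(ortholog_table)) {
    bad <- ortholog_table |>
      group_by(.data$group) |>
      summarise(ok = all(sort(unique(.data$species)) == sort(species_list)) &&
                  !anyDuplicated(.data$species), .groups = "drop") |>
      filter(!.data$ok)
    if (nrow(bad)) {
      warn(paste0(nrow(bad), " ortholog group(s) rejected (duplicate or ",
                  "missing species): ", paste(head(bad$group, 5),
                                              collapse = ", ")))
    }
    return(ortholog_table |> filter(!.data$group %in% bad$group))
  }
  nm <- names(gene_trees) %||% paste0("tree_", seq_along(gene_trees))
  rows <- imap(gene_trees, function(gt, id) {
    phy <- gt$phylo
    sel <- which(gt$tip_species %in% species_list)
    spp <- gt$tip_species[sel]
    if (length(sel) != length(species_list) ||
        !setequal(spp, species_list) || anyDuplicated(spp)) {
      return(NULL)
    }
    # internal nodes of the subtree connecting the selected tips: the MRCA
    # and every node on a path between it and a selected tip
    if (length(sel) == 1) return(NULL)
    mrca <- ape::getMRCA(phy, sel)
    par <- parent_vector(phy)
    on_path <- integer(0)
    for (tip in sel) {
      v <- tip
      while (v != mrca) {
        v <- par[[v]]
        on_path <- c(on_path, v)
      }
    }
    ev <- node_events(gt)[unique(on_path)]
    if (any(ev %in% c("duplication", "null")) || any(is.na(ev))) return(NULL)
    tibble(group = id, tree_id = id,
           species = gt$tip_species[sel], gene = phy$tip.label[sel])
  })
  out <- bind_rows(compact(rows))
  if (nrow(out) == 0) {
    return(tibble(group = character(), tree_id = character(),
                  species = character(), gene = character()))
  }
  out
}

partition_one <- function(d) {
  # order-invariant (type II) sums of squares for the additive model
  # value ~ species + tissue; proportions of total sum of squares
  tss <- sum((d$value - mean(d$value))^2)
  if (tss <= 0) {
    return(c(species_prop = 0, tissue_prop = 0, residual_prop = 0))
  }
  rss_full <- sum(lm(value ~ species + tissue, data = d)$residuals^2)
  rss_no_sp <- sum(lm(value ~ tissue, data = d)$residuals^2)
  rss_no_ti <- sum(lm(value ~ species, data = d)$residuals^2)
  sp <- (rss_no_sp - rss_full) / tss
  ti <- (rss_no_ti - rss_full) / tss
  c(species_prop = sp, tissue_prop = ti, residual_prop = 1 - sp - ti)
}

#' Two-factor variance partition per ortholog
#'
#' Fits the additive model `value ~ species + tissue` per ortholog and
#' reports the proportion of total variance explained by each factor
#' (sum of squares adjusted for the other factor — order-invariant,
#' type-II style — divided by the total sum of squares; for balanced
#' designs this coincides with sequential sums of squares). Orthologs
#' missing any (species, tissue) cell are dropped (complete-case
#' analysis); replicate values within a cell are averaged first.
#'
#' @param data tibble with columns `ortholog`, `species`, `tissue`,
#'   `value` (TPM10K values or TPM10K ratios, used directly).
#' @param thresholds see [svg_tvg_thresholds()].
#' @return an `stf_partition` object; `tidy()` returns the per-ortholog
#'   tibble (`ortholog`, `species_prop`, `tissue_prop`, `residual_prop`,
#'   `label`), `glance()` a one-row summary.
#' @export
variance_partition <- function(data, thresholds = svg_tvg_thresholds()) {
  need <- c("ortholog", "species", "tissue", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  cells <- data |>
    group_by(.data$ortholog, .data$species, .data$tissue) |>
    summarise(value = mean(.data$value), .groups = "drop")
  n_sp <- length(unique(cells$species))
  n_ti <- length(unique(cells$tissue))
  if (n_sp < 2 || n_ti < 2) {
    abort("variance partition needs >= 2 species and >= 2 tissues")
  }
  complete <- cells |>
    count(.data$ortholog) |>
    filter(.data$n == n_sp * n_ti)
  n_dropped <- length(unique(cells$ortholog)) - nrow(complete)
  res <- cells |>
    filter(.data$ortholog %in% complete$ortholog) |>
    tidyr::nest(cell_data = c("species", "tissue", "value")) |>
    mutate(props = map(.data$cell_data, partition_one)) |>
    select(-"cell_data")
  rec <- bind_rows(map(res$props, function(p) as_tibble(as.list(p))))
  rec <- bind_cols(tibble(ortholog = res$ortholog), rec)
  rec$label <- classify_svg_tvg(rec, thresholds)
  structure(
    list(records = rec, n_dropped = n_dropped, thresholds = thresholds,
         n_species = n_sp, n_tissues = n_ti),
    class = "stf_partition"
  )
}

#' Thresholds for SVG/TVG classification
#'
#' A gene is species-variable (SVG) or tissue-variable (TVG) when species
#' and tissue together explain more than `combined` of the variance and
#' the dominant factor explains more than `fold` times the other.
#'
#' @param combined combined-variance threshold (default 0.75).
#' @param fold dominance fold (default 2).
#' @export
svg_tvg_thresholds <- function(combined = 0.75, fold = 2) {
  list(combined = combined, fold = fold)
}

#' Classify orthologs as SVG, TVG or other
#'
#' @param records tibble with `species_prop` and `tissue_prop` columns.
#' @param thresholds see [svg_tvg_thresholds()].
#' @return character vector of labels (`"SVG"`, `"TVG"`, `"other"`).
#' @export
classify_svg_tvg <- function(records, thresholds = svg_tvg_thresholds()) {
  combined <- records$species_prop + records$tissue_prop
  ifelse(combined > thresholds$combined &
           records$species_prop > thresholds$fold * records$tissue_prop,
         "SVG",
         ifelse(combined > thresholds$combined &
                  records$tissue_prop > thresholds$fold * records$species_prop,
                "TVG", "other"))
}

#' @export
print.stf_partition <- function(x, ...) {
  g <- glance(x)
  cat("STF variance partition:", g$n_orthologs, "orthologs (",
      g$n_svg, "SVG,", g$n_tvg, "TVG,", g$n_other, "other );",
      x$n_dropped, "dropped as incomplete\n")
  invisible(x)
}

#' @method tidy stf_partition
#' @export
tidy.stf_partition <- function(x, ...) x$records

#' @method glance stf_partition
#' @export
glance.stf_partition <- function(x, ...) {
  tibble(
    n_orthologs = nrow(x$records),
    n_svg = sum(x$records$label == "SVG"),
    n_tvg = sum(x$records$label == "TVG"),
    n_other = sum(x$records$label == "other"),
    n_dropped_incomplete = x$n_dropped,
    n_species = x$n_species,
    n_tissues = x$n_tissues
  )
}

#' @method autoplot stf_partition
#' @export
autoplot.stf_partition <- function(object, ...) {
  rec <- object$records
  ord <- rec |>
    mutate(rank = .data$species_prop - .data$tissue_prop) |>
    arrange(.data$rank)
  ord$idx <- seq_len(nrow(ord))
  long <- ord |>
    tidyr::pivot_longer(cols = c("species_prop", "tissue_prop",
                                 "residual_prop"),
                        names_to = "component", values_to = "prop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$idx, y = .data$prop,
                                     fill = .data$component)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(
      values = c(species_prop = "#c0392b", tissue_prop = "#2980b9",
                 residual_prop = "grey70"),
      labels = c(species_prop = "species", tissue_prop = "tissue",
                 residual_prop = "residual")) +
    ggplot2::labs(x = "ortholog (sorted)", y = "proportion of variance",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
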