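# Gene-tree quality filters: branch-length summaries and exclusion rules,
# with per-tree reasons.

#' Default branch length marking an effectively zero branch
#'
#' Upstream tree inference assigns 1e-6 to branches of estimated length 0;
#' the default-fraction filter counts branches carrying exactly this value.
#' @export
DEFAULT_BRANCH_LENGTH <- 1e-6

#' Filter thresholds for gene-tree exclusion
#'
#' All thresholds are strict in the direction stated: a tree is discarded
#' when `max_len > 2`, `default_fraction > 0.25`, `null_per_internal > 0.3`,
#' `n_speciation < 1`, `root_depth > 5` (species-tree root = 1), or
#' `n_expression_tips < 3`. The long-branch and default-fraction rules are
#' combined with OR by default (`combine_length_rules = "or"`): either
#' pathology alone discards the tree; set `"and"` to require both.
#'
#' @param max_len longest allowed branch (substitutions/site).
#' @param default_fraction allowed fraction of default-length branches.
#' @param combine_length_rules `"or"` or `"and"` for the two rules above.
#' @param null_per_internal allowed null nodes per internal node.
#' @param min_speciation minimum number of (non-null) speciation nodes.
#' @param max_root_depth maximum calibrated root age.
#' @param min_expression_tips minimum tips with expression values.
#' @return a named list of thresholds.
#' @export
sbf_filter_thresholds <- function(max_len = 2,
                                  default_fraction = 0.25,
                                  combine_length_rules = c("or", "and"),
                                  null_per_internal = 0.3,
                                  min_speciation = 1,
                                  max_root_depth = 5,
                                  min_expression_tips = 3) {
  list(max_len = max_len,
       default_fraction = default_fraction,
       combine_length_rules = match.arg(combine_length_rules),
       null_per_internal = null_per_internal,
       min_speciation = min_speciation,
       max_root_depth = max_root_depth,
       min_expression_tips = min_expression_tips)
}

#' Branch-length summary statistics of a gene tree
#'
#' Statistics over all branches of the rooted tree (a root edge, if any,
#' is excluded); `default_fraction` is the fraction of branches whose
#' length equals [DEFAULT_BRANCH_LENGTH] exactly. On a calibrated tree the
#' original substitution lengths (`subst_length`) are summarized, not the
#' time lengths.
#'
#' @param gt a `gene_tree`.
#' @return one-row tibble: `n_branches`, `max_len`, `min_len`, `sd_len`,
#'   `default_fraction`.
#' @export
branch_length_summary <- function(gt) {
  len <- gt$subst_length %||% gt$phylo$edge.length
  tibble(
    n_branches = length(len),
    max_len = max(len),
    min_len = min(len),
    sd_len = if (length(len) > 1) sd(len) else 0,
    default_fraction = mean(len == DEFAULT_BRANCH_LENGTH)
  )
}

#' Full filter-statistics row for a gene tree
#'
#' Collects every statistic the exclusion rules consult. Annotation-derived
#' fields are `NA` until events are labeled; `root_depth` is `NA` until the
#' tree is calibrated; `n_expression_tips` is `NA` unless `tip_values` is
#' given.
#'
#' @param gt a `gene_tree` (possibly annotated and/or calibrated).
#' @param tip_values optional named numeric vector of expression values
#'   (names = tip labels) used to count valued tips.
#' @param tree_id identifier recorded in the row.
#' @return a one-row tibble.
#' @export
tree_filter_stats <- function(gt, tip_values = NULL, tree_id = "tree") {
  stats <- branch_length_summary(gt)
  nn <- gt$phylo$Nnode
  annotated <- any(!is.na(gt$event))
  n_spec <- if (annotated) sum(gt$event %in% "speciation") else NA_integer_
  n_null <- if (annotated) sum(gt$event %in% "null") else NA_integer_
  tibble(
    tree_id = tree_id,
    stats,
    n_internal = nn,
    n_speciation = n_spec,
    n_null = n_null,
    null_per_internal = if (annotated) n_null / nn else NA_real_,
    root_depth = if (inherits(gt, "calibrated_gene_tree"))
      root_depth(gt) else NA_real_,
    n_expression_tips = if (!is.null(tip_values))
      sum(gt$phylo$tip.label %in% names(tip_values)[is.finite(tip_values)])
    else NA_integer_
  )
}

stage_fields <- list(
  "pre-calibration" = c("max_len", "default_fraction", "null_per_internal",
                        "n_speciation"),
  "post-calibration" = "root_depth",
  "post-pruning" = "n_expression_tips"
)

#' Apply the gene-tree exclusion rules
#'
#' Evaluates the thresholds relevant to a pipeline stage on a report of
#' [tree_filter_stats()] rows and records a verdict with reasons. A tree is
#' discarded iff at least one reason fires; filters are monotone in every
#' threshold.
#'
#' @param report tibble of filter-statistics rows (one per tree).
#' @param stage `"pre-calibration"` (branch lengths, null density,
#'   speciation count), `"post-calibration"` (root depth), `"post-pruning"`
#'   (valued tips) or `"all"`.
#' @param thresholds see [sbf_filter_thresholds()].
#' @return the report with `verdict` (`"keep"`/`"discard"`) and `reasons`
#'   (semicolon-joined) columns.
#' @export
apply_tree_filters <- function(report,
                               stage = c("pre-calibration", "post-calibration",
                                         "post-pruning", "all"),
                               thresholds = sbf_filter_thresholds()) {
  stage <- match.arg(stage)
  fields <- if (stage == "all") unlist(stage_fields, use.names = FALSE)
            else stage_fields[[stage]]
  missing_f <- fields[map_lgl(fields, function(f)
    !f %in% names(report) || all(is.na(report[[f]])))]
  if (length(missing_f)) {
    abort(paste0("stage '", stage, "' needs field(s) not computed yet: ",
                 paste(missing_f, collapse = ", ")))
  }
  th <- thresholds
  n <- nrow(report)
  reasons <- rep(list(character(0)), n)
  add_reason <- function(hit, label) {
    hit <- !is.na(hit) & hit
    for (i in which(hit)) reasons[[i]] <<- c(reasons[[i]], label)
  }
  if (any(c("max_len", "default_fraction") %in% fields)) {
    long_branch <- report$max_len > th$max_len
    many_default <- report$default_fraction > th$default_fraction
    if (th$combine_length_rules == "or") {
      add_reason(long_branch, "long-branch")
      add_reason(many_default, "default-length-fraction")
    } else {
      add_reason(long_branch & many_default, "long-branch-and-default-fraction")
    }
  }
  if ("null_per_internal" %in% fields) {
    add_reason(report$null_per_internal > th$null_per_internal, "null-density")
  }
  if ("n_speciation" %in% fields) {
    add_reason(report$n_speciation < th$min_speciation, "no-speciation")
  }
  if ("root_depth" %in% fields) {
    add_reason(report$root_depth > th$max_root_depth, "deep-root")
  }
  if ("n_expression_tips" %in% fields) {
    add_reason(report$n_expression_tips < th$min_expression_tips,
               "few-expression-tips")
  }
  report$verdict <- ifelse(lengths(reasons) > 0, "discard", "keep")
  report$reasons <- map_chr(reasons, paste, collapse = ";")
  report
}
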