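# Gene-level filtering, TPM / TPM10K normalization, replicate summarization
# and denominator-tissue expression ratios.
#
# All tables are long-format tibbles. A count table has one row per
# (gene, library) with columns `gene`, `library`, `count`, `eff_length`;
# expression tables carry a `unit` attribute ("TPM", "TPM10K" or
# "logTPM10K") retrievable with expr_unit().

expr_set_unit <- function(x, unit) {
  attr(x, "unit") <- unit
  x
}

#' Unit of an expression table
#'
#' @param x a tibble produced by [compute_tpm()], [compute_tpm10k()] or
#'   [summarize_and_log()]
#' @return `"TPM"`, `"TPM10K"` or `"logTPM10K"` (or `NULL`).
#' @export
expr_unit <- function(x) attr(x, "unit", exact = TRUE)

check_counts <- function(counts) {
  need <- c("gene", "library", "count", "eff_length")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    abort(paste0("count table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(counts$count)) || any(counts$count < 0)) {
    abort("counts must be finite and >= 0")
  }
  bad <- counts$count > 0 & !(is.finite(counts$eff_length) & counts$eff_length > 0)
  if (any(bad)) {
    abort(paste0("effective length must be > 0 where counts are > 0 (gene '",
                 counts$gene[which(bad)[1]], "')"))
  }
  invisible(counts)
}

#' Filter genes on annotation flags and library support
#'
#' Retains protein-coding, non-rRNA genes observed (count > 0) in at least
#' `min_libraries` libraries. Gene order is preserved.
#'
#' @param counts long count table (`gene`, `library`, `count`, `eff_length`).
#' @param flags tibble with columns `gene`, `is_rRNA`, `is_protein_coding`;
#'   every gene in `counts` must be flagged.
#' @param min_libraries minimum number of libraries with a positive count
#'   (default 2).
#' @return the filtered count table.
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   gene = rep(c("g1", "g2"), each = 3),
#'   library = rep(c("L1", "L2", "L3"), 2),
#'   count = c(5, 0, 0, 1, 1, 0), eff_length = 500)
#' flags <- tibble::tibble(gene = c("g1", "g2"),
#'                         is_rRNA = FALSE, is_protein_coding = TRUE)
#' filter_genes(counts, flags)  # g1 seen in only one library: removed
filter_genes <- function(counts, flags, min_libraries = 2) {
  check_counts(counts)
  genes <- unique(counts$gene)
  unflagged <- setdiff(genes, flags$gene)
  if (length(unflagged)) {
    abort(paste0("missing annotation flags for gene '", unflagged[[1]], "'",
                 if (length(unflagged) > 1)
                   paste0(" (and ", length(unflagged) - 1, " more)")))
  }
  support <- counts |>
    group_by(.data$gene) |>
    summarise(n_pos = sum(.data$count > 0), .groups = "drop")
  keep <- flags |>
    inner_join(support, by = "gene") |>
    filter(!.data$is_rRNA, .data$is_protein_coding,
           .data$n_pos >= min_libraries)
  counts |> filter(.data$gene %in% keep$gene)
}

#' Transcripts per million
#'
#' Per library, `TPM_i = 1e6 * (count_i / eff_length_i) / sum_j(count_j /
#' eff_length_j)`. Every library column sums to 1e6.
#'
#' @param counts long count table (`gene`, `library`, `count`, `eff_length`).
#' @return tibble `gene`, `library`, `value` with unit `"TPM"`.
#' @export
compute_tpm <- function(counts) {
  check_counts(counts)
  rate <- ifelse(counts$count > 0, counts$count / counts$eff_length, 0)
  out <- counts |>
    mutate(.rate = rate) |>
    group_by(.data$library) |>
    mutate(.total = sum(.data$.rate)) |>
    ungroup()
  if (any(out$.total <= 0)) {
    bad <- unique(out$library[out$.total <= 0])[[1]]
    abort(paste0("library '", bad, "' has no mapped reads; TPM is undefined"))
  }
  out <- out |>
    mutate(value = 1e6 * .data$.rate / .data$.total) |>
    select("gene", "library", "value")
  expr_set_unit(out, "TPM")
}

#' TPM10K: TPM rescaled by reference size
#'
#' `TPM10K_i = TPM_i * n / 1e4`, where `n` is the number of genes in the
#' species' reference (the full, pre-filtering reference: `n` is a property
#' of the reference transcriptome, not of the analyzed subset). With all `n`
#' genes present, every library then has mean 100 and sum `100 * n`, making
#' values comparable across species whose references differ in size.
#'
#' @param tpm output of [compute_tpm()].
#' @param n_reference either a single positive integer (one reference for
#'   all libraries) or a tibble `species`, `n_genes`; in the latter case
#'   `meta` must map libraries to species.
#' @param meta optional sample metadata (`library`, `species`).
#' @return tibble `gene`, `library`, `value` with unit `"TPM10K"`.
#' @export
compute_tpm10k <- function(tpm, n_reference, meta = NULL) {
  if (!identical(expr_unit(tpm), "TPM")) {
    abort("compute_tpm10k() expects a table with unit 'TPM'")
  }
  if (is.numeric(n_reference) && length(n_reference) == 1) {
    if (n_reference <= 0) abort("n_reference must be > 0")
    out <- tpm |> mutate(value = .data$value * n_reference / 1e4)
  } else {
    if (is.null(meta)) {
      abort("per-species n_reference requires `meta` (library -> species)")
    }
    if (any(n_reference$n_genes <= 0)) abort("n_reference must be > 0")
    out <- tpm |>
      left_join(select(meta, "library", "species"), by = "library") |>
      left_join(select(n_reference, "species", "n_genes"), by = "species")
    if (any(is.na(out$n_genes))) {
      bad <- unique(out$library[is.na(out$n_genes)])[[1]]
      abort(paste0("no reference gene count for library '", bad, "'"))
    }
    out <- out |>
      mutate(value = .data$value * .data$n_genes / 1e4) |>
      select("gene", "library", "value")
  }
  expr_set_unit(out, "TPM10K")
}

#' Average replicates within (species, tissue) and log-transform
#'
#' Takes the mean TPM10K over replicate libraries of the same tissue within
#' a species, then `log(mean + pseudocount)`. With `pseudocount = 0`, zero
#' means would map to `-Inf`; those values are dropped with a warning.
#'
#' @param expr TPM10K table from [compute_tpm10k()].
#' @param meta sample metadata (`library`, `species`, `tissue`).
#' @param pseudocount added before the log (default 1).
#' @param log_base base of the logarithm (default natural log).
#' @return tibble `gene`, `species`, `tissue`, `value` with unit
#'   `"logTPM10K"`.
#' @export
summarize_and_log <- function(expr, meta, pseudocount = 1, log_base = exp(1)) {
  if (!identical(expr_unit(expr), "TPM10K")) {
    abort("summarize_and_log() expects a table with unit 'TPM10K'")
  }
  orphan <- setdiff(unique(expr$library), meta$library)
  if (length(orphan)) {
    abort(paste0("library '", orphan[[1]], "' has no metadata row"))
  }
  out <- expr |>
    inner_join(select(meta, "library", "species", "tissue"), by = "library") |>
    group_by(.data$gene, .data$species, .data$tissue) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    mutate(value = log(.data$value + pseudocount, base = log_base))
  if (any(!is.finite(out$value))) {
    n_bad <- sum(!is.finite(out$value))
    warn(paste0(n_bad, " zero-mean value(s) dropped under pseudocount ",
                pseudocount, " (log not finite)"))
    out <- out |> filter(is.finite(.data$value))
  }
  expr_set_unit(out, "logTPM10K")
}

#' Within-species tissue expression ratios (log scale)
#'
#' For each species having the denominator tissue, returns the difference of
#' log values, `log(tissue) - log(denominator)`, for every other tissue.
#' Because a gene-by-species counting-efficiency factor multiplies the
#' expression of a gene identically in every library of a species, it cancels
#' from these ratios. Species lacking the denominator tissue yield no ratio
#' rows.
#'
#' @param log_expr logTPM10K table from [summarize_and_log()].
#' @param denominator_tissue tissue used as denominator (the most commonly
#'   sampled tissue; in the siphonophore setting, the mature gastrozooid).
#' @return tibble `gene`, `species`, `tissue` (numerator), `ratio`.
#' @export
expression_ratio <- function(log_expr, denominator_tissue) {
  if (!identical(expr_unit(log_expr), "logTPM10K")) {
    abort("expression_ratio() expects a table with unit 'logTPM10K'")
  }
  denom <- log_expr |>
    filter(.data$tissue == denominator_tissue) |>
    select("gene", "species", denom_value = "value")
  if (nrow(denom) == 0) {
    abort(paste0("denominator tissue '", denominator_tissue,
                 "' is absent from every species"))
  }
  log_expr |>
    filter(.data$tissue != denominator_tissue) |>
    inner_join(denom, by = c("gene", "species")) |>
    mutate(ratio = .data$value - .data$denom_value) |>
    select("gene", "species", "tissue", "ratio")
}
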