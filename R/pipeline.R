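# Subcommand pipeline driver: each stage reads and writes plain TSV/Newick
# artifacts in an output directory, so runs are inspectable and reruns with
# the same seed and config are byte-identical. A manifest records inputs,
# config hash, seed and versions.

#' Default pipeline configuration
#'
#' All analysis thresholds live here with their standard values: the
#' neutral band (-2, 2), the gene-tree filter cutoffs, the pseudocount,
#' the tip-label separator, and the simulation scenario parameters.
#'
#' @param ... named overrides of any default (nested lists are merged
#'   shallowly, e.g. `simulate = list(n_families = 5)`).
#' @return a named list.
#' @export
sbf_config <- function(...) {
  base <- list(
    separator = "@",
    pseudocount = 1,
    log_base = exp(1),
    denominator_tissue = "gastrozooid_mature",
    min_libraries = 2,
    thresholds = list(max_len = 2, default_fraction = 0.25,
                      combine_length_rules = "or", null_per_internal = 0.3,
                      min_speciation = 1, max_root_depth = 5,
                      min_expression_tips = 3),
    change_thresholds = list(neutral_lo = -2, neutral_hi = 2, large = 5),
    svg_tvg = list(combined = 0.75, fold = 2),
    simulate = list(n_families = 20, dup_rate = 0.5, loss_rate = 0.3,
                    n_background = 1000, sigma2 = 1, root_mean = 1.5,
                    root_sd = 1, background_sdlog = 1.25,
                    efficiency_sdlog = 0.5, library_size = NULL,
                    replicates = 2)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- modifyList(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [sbf_config()].
#'
#' @param path YAML file.
#' @return a config list.
#' @export
read_sbf_config <- function(path) {
  do.call(sbf_config, yaml::read_yaml(path))
}

write_tsv_file <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  as_tibble(read.delim(path, sep = "\t", comment.char = "#",
                       stringsAsFactors = FALSE))
}

stage_path <- function(outdir, name) file.path(outdir, name)

require_inputs <- function(outdir, files) {
  paths <- file.path(outdir, files)
  missing_f <- files[!file.exists(paths)]
  if (length(missing_f)) {
    abort(paste0("missing input file(s): ",
                 paste(missing_f, collapse = ", ")),
          class = "sbf_missing_input")
  }
  invisible(paths)
}

#' Run one pipeline stage
#'
#' Stages communicate through files in `outdir`:
#' \describe{
#'   \item{simulate}{writes `counts.tsv`, `meta.tsv`, `flags.tsv`,
#'     `n_reference.tsv`, `species_tree.nwk`, `gene_trees.nwk`}
#'   \item{normalize}{counts -> `expression_tpm10k.tsv` (per-library
#'     TPM10K) and `expression_log.tsv` (per species x tissue logTPM10K)}
#'   \item{ratio}{`ratios.tsv` (log-ratios against the denominator tissue)}
#'   \item{annotate}{`gene_trees_annotated.nhx`, `node_table.tsv`}
#'   \item{filter}{`filter_report.tsv` (pre-calibration verdicts)}
#'   \item{calibrate}{`gene_trees_calibrated.nhx`,
#'     `calibration_failures.tsv`, root-depth verdicts appended to the
#'     report}
#'   \item{reconstruct}{`traits.tsv` (per tree x node x tissue values)}
#'   \item{changes}{`records.tsv`, `tally.tsv`, `tally_ratio.tsv`}
#'   \item{stf}{`stf_partition.tsv`}
#' }
#'
#' @param stage one of simulate, normalize, ratio, annotate, filter,
#'   calibrate, reconstruct, changes, stf.
#' @param outdir working directory for stage artifacts.
#' @param config see [sbf_config()].
#' @param seed integer seed used by stochastic stages.
#' @return (invisibly) the character vector of files the stage wrote.
#' @export
sbf_run_stage <- function(stage, outdir, config = sbf_config(), seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sep <- config$separator
  th <- do.call(sbf_filter_thresholds, config$thresholds)
  cth <- do.call(sbf_change_thresholds, config$change_thresholds)
  wrote <- character(0)
  emit <- function(...) wrote <<- c(wrote, ...)

  if (stage == "simulate") {
    sim <- do.call(simulate_sbf_scenario,
                   c(config$simulate, list(seed = seed)))
    write_tsv_file(sim$counts, stage_path(outdir, "counts.tsv"))
    write_tsv_file(sim$meta, stage_path(outdir, "meta.tsv"))
    write_tsv_file(sim$flags, stage_path(outdir, "flags.tsv"))
    write_tsv_file(sim$n_reference, stage_path(outdir, "n_reference.tsv"))
    write_species_tree(sim$species_tree,
                       stage_path(outdir, "species_tree.nwk"))
    lines <- map_chr(names(sim$gene_trees), function(nm)
      paste0(nm, "\t", write_gene_tree(sim$gene_trees[[nm]])))
    writeLines(lines, stage_path(outdir, "gene_trees.nwk"))
    emit("counts.tsv", "meta.tsv", "flags.tsv", "n_reference.tsv",
         "species_tree.nwk", "gene_trees.nwk")
  } else if (stage == "normalize") {
    require_inputs(outdir, c("counts.tsv", "meta.tsv", "flags.tsv",
                             "n_reference.tsv"))
    counts <- read_tsv_file(stage_path(outdir, "counts.tsv"))
    meta <- read_tsv_file(stage_path(outdir, "meta.tsv"))
    flags <- read_tsv_file(stage_path(outdir, "flags.tsv"))
    n_ref <- read_tsv_file(stage_path(outdir, "n_reference.tsv"))
    kept <- filter_genes(counts, flags, min_libraries = config$min_libraries)
    tpm10k <- compute_tpm10k(compute_tpm(kept), n_ref, meta)
    logexp <- summarize_and_log(tpm10k, meta,
                                pseudocount = config$pseudocount,
                                log_base = config$log_base)
    write_tsv_file(tpm10k, stage_path(outdir, "expression_tpm10k.tsv"),
                   comment = "unit=TPM10K")
    write_tsv_file(logexp, stage_path(outdir, "expression_log.tsv"),
                   comment = paste0("unit=logTPM10K pseudocount=",
                                    config$pseudocount))
    emit("expression_tpm10k.tsv", "expression_log.tsv")
  } else if (stage == "ratio") {
    require_inputs(outdir, "expression_log.tsv")
    logexp <- expr_set_unit(read_tsv_file(
      stage_path(outdir, "expression_log.tsv")), "logTPM10K")
    ratios <- expression_ratio(logexp, config$denominator_tissue)
    write_tsv_file(ratios, stage_path(outdir, "ratios.tsv"),
                   comment = paste0("denominator=", config$denominator_tissue))
    emit("ratios.tsv")
  } else if (stage == "annotate") {
    require_inputs(outdir, c("species_tree.nwk", "gene_trees.nwk"))
    st <- read_species_tree(stage_path(outdir, "species_tree.nwk"))
    trees <- read_gene_trees(stage_path(outdir, "gene_trees.nwk"),
                             separator = sep)
    ann <- map(trees, annotate_gene_tree, st = st)
    writeLines(map_chr(names(ann), function(nm)
      paste0(nm, "\t", write_gene_tree(ann[[nm]]))),
      stage_path(outdir, "gene_trees_annotated.nhx"))
    tbl <- bind_rows(imap(ann, function(gt, nm)
      mutate(node_table(gt, st), tree_id = nm, .before = 1)))
    write_tsv_file(tbl, stage_path(outdir, "node_table.tsv"))
    emit("gene_trees_annotated.nhx", "node_table.tsv")
  } else if (stage == "filter") {
    require_inputs(outdir, "gene_trees_annotated.nhx")
    ann <- read_gene_trees(stage_path(outdir, "gene_trees_annotated.nhx"),
                           separator = sep)
    report <- bind_rows(imap(ann, function(gt, nm)
      tree_filter_stats(gt, tree_id = nm)))
    report <- apply_tree_filters(report, "pre-calibration", th)
    write_tsv_file(report, stage_path(outdir, "filter_report.tsv"))
    emit("filter_report.tsv")
  } else if (stage == "calibrate") {
    require_inputs(outdir, c("gene_trees_annotated.nhx", "species_tree.nwk",
                             "filter_report.tsv"))
    st <- read_species_tree(stage_path(outdir, "species_tree.nwk"))
    ann <- read_gene_trees(stage_path(outdir, "gene_trees_annotated.nhx"),
                           separator = sep)
    report <- read_tsv_file(stage_path(outdir, "filter_report.tsv"))
    keep_ids <- report$tree_id[report$verdict == "keep"]
    failures <- list()
    lines <- character(0)
    depth_rows <- list()
    for (nm in intersect(names(ann), keep_ids)) {
      ct <- calibrate_gene_tree(ann[[nm]], st)
      if (is_calibration_failure(ct)) {
        failures[[nm]] <- tibble(tree_id = nm, reason = "infeasible",
                                 parent = ct$parent, child = ct$child)
        next
      }
      depth_rows[[nm]] <- tibble(tree_id = nm, root_depth = root_depth(ct))
      lines <- c(lines, paste0(nm, "\t", write_gene_tree(ct)))
    }
    writeLines(lines, stage_path(outdir, "gene_trees_calibrated.nhx"))
    fail_tbl <- if (length(failures)) bind_rows(failures)
                else tibble(tree_id = character(), reason = character(),
                            parent = integer(), child = integer())
    write_tsv_file(fail_tbl, stage_path(outdir, "calibration_failures.tsv"))
    depth_tbl <- bind_rows(depth_rows) |>
      apply_tree_filters("post-calibration", th)
    write_tsv_file(depth_tbl, stage_path(outdir, "root_depth_report.tsv"))
    emit("gene_trees_calibrated.nhx", "calibration_failures.tsv",
         "root_depth_report.tsv")
  } else if (stage %in% c("reconstruct", "changes")) {
    require_inputs(outdir, c("gene_trees_calibrated.nhx", "species_tree.nwk",
                             "expression_log.tsv", "root_depth_report.tsv"))
    st <- read_species_tree(stage_path(outdir, "species_tree.nwk"))
    cal <- read_gene_trees(stage_path(outdir, "gene_trees_calibrated.nhx"),
                           separator = sep)
    depth_tbl <- read_tsv_file(stage_path(outdir, "root_depth_report.tsv"))
    keep_ids <- depth_tbl$tree_id[depth_tbl$verdict == "keep"]
    logexp <- read_tsv_file(stage_path(outdir, "expression_log.tsv"))
    ratios_path <- stage_path(outdir, "ratios.tsv")
    tissues <- unique(logexp$tissue)
    trait_rows <- list()
    records <- list()
    for (nm in intersect(names(cal), keep_ids)) {
      ct <- as_calibrated(cal[[nm]], st)
      maps <- list()
      for (ti in tissues) {
        tv <- tip_values_for(ct, logexp[logexp$tissue == ti, ], sep)
        if (sum(is.finite(tv)) < th$min_expression_tips) next
        tm <- reconstruct_ancestral_bm(ct, tv,
                                       min_tips = th$min_expression_tips)
        maps[[ti]] <- tm
        trait_rows[[paste(nm, ti)]] <- mutate(tm, tree_id = nm, tissue = ti,
                                              .before = 1)
        records[[paste(nm, ti)]] <- scaled_branch_changes(
          ct, tm, tissue = ti, st = st, tree_id = nm, thresholds = cth)
      }
      denom <- config$denominator_tissue
      if (!is.null(maps[[denom]])) {
        for (ti in setdiff(names(maps), denom)) {
          rtm <- ratio_trait_map(maps[[ti]], maps[[denom]])
          lab <- paste0(ti, "/", denom)
          records[[paste(nm, lab)]] <- scaled_branch_changes(
            ct, rtm, tissue = lab, st = st, tree_id = nm, thresholds = cth)
        }
      }
    }
    traits <- bind_rows(trait_rows)
    write_tsv_file(traits, stage_path(outdir, "traits.tsv"))
    emit("traits.tsv")
    if (stage == "changes") {
      rec <- bind_rows(records)
      write_tsv_file(rec, stage_path(outdir, "records.tsv"))
      is_ratio <- grepl("/", rec$tissue, fixed = TRUE)
      write_tsv_file(tally_changes(rec[!is_ratio, ]),
                     stage_path(outdir, "tally.tsv"))
      if (any(is_ratio)) {
        write_tsv_file(tally_changes(rec[is_ratio, ]),
                       stage_path(outdir, "tally_ratio.tsv"))
        emit("tally_ratio.tsv")
      }
      emit("records.tsv", "tally.tsv")
    }
  } else if (stage == "stf") {
    require_inputs(outdir, c("gene_trees_annotated.nhx", "species_tree.nwk",
                             "expression_tpm10k.tsv", "meta.tsv"))
    st <- read_species_tree(stage_path(outdir, "species_tree.nwk"))
    ann <- read_gene_trees(stage_path(outdir, "gene_trees_annotated.nhx"),
                           separator = sep)
    meta <- read_tsv_file(stage_path(outdir, "meta.tsv"))
    tpm10k <- read_tsv_file(stage_path(outdir, "expression_tpm10k.tsv"))
    groups <- extract_strict_orthologs(ann, st$phylo$tip.label)
    if (nrow(groups) == 0) {
      write_tsv_file(tibble(ortholog = character()),
                     stage_path(outdir, "stf_partition.tsv"))
      return(invisible(stage_path(outdir, "stf_partition.tsv")))
    }
    values <- tpm10k |>
      inner_join(select(meta, "library", "species", "tissue"),
                 by = "library") |>
      group_by(.data$gene, .data$species, .data$tissue) |>
      summarise(value = mean(.data$value), .groups = "drop") |>
      inner_join(groups, by = c("gene" = "gene", "species" = "species")) |>
      rename(ortholog = "group")
    fit <- variance_partition(values, do.call(svg_tvg_thresholds,
                                              config$svg_tvg))
    write_tsv_file(tidy(fit), stage_path(outdir, "stf_partition.tsv"))
    emit("stf_partition.tsv")
  } else {
    abort(paste0("unknown stage '", stage, "'"))
  }
  invisible(file.path(outdir, wrote))
}

# restore calibrated class/ages on a tree read back from a calibrated NHX
# file (branch lengths are time there)
as_calibrated <- function(gt, st) {
  if (inherits(gt, "calibrated_gene_tree")) return(gt)
  ct <- gt
  ct$age <- node_ages_from_depths(gt$phylo)
  class(ct) <- c("calibrated_gene_tree", "gene_tree")
  ct
}

# named tip-value vector for one tissue's expression rows; matches the
# full tip label first, then the species/gene decomposition
tip_values_for <- function(gt, expr_rows, sep) {
  labs <- gt$phylo$tip.label
  v <- expr_rows$value[match(labs, expr_rows$gene)]
  need <- is.na(v)
  if (any(need)) {
    key <- paste(expr_rows$species, expr_rows$gene, sep = sep)
    v[need] <- expr_rows$value[match(labs[need], key)]
  }
  setNames(v, labs)
}

#' Run the full pipeline on one directory
#'
#' Chains simulate (optional), normalize, ratio, annotate, filter,
#' calibrate, reconstruct, changes and stf, then writes `manifest.json`
#' recording the seed, the config hash, package and R versions and the
#' files each stage produced. Reruns with the same seed and config are
#' byte-identical; no stage mutates its inputs.
#'
#' @param outdir working directory.
#' @param config see [sbf_config()].
#' @param seed integer seed.
#' @param simulate generate inputs first (default TRUE; set FALSE when
#'   `outdir` already contains counts and trees).
#' @return (invisibly) the manifest as a list.
#' @export
sbf_run_all <- function(outdir, config = sbf_config(), seed = 1,
                        simulate = TRUE) {
  stages <- c(if (simulate) "simulate",
              "normalize", "ratio", "annotate", "filter", "calibrate",
              "reconstruct", "changes", "stf")
  outputs <- list()
  for (s in stages) {
    outputs[[s]] <- basename(sbf_run_stage(s, outdir, config, seed))
  }
  cfg_path <- stage_path(outdir, "config_used.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    inputs = if (simulate) "simulated" else "user-supplied",
    stages = outputs,
    versions = list(
      package = as.character(utils::packageVersion("sbftools")),
      r = paste(R.version$major, R.version$minor, sep = "."))
  )
  jsonlite::write_json(manifest, stage_path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Thin argument parser behind the `inst/exec/sbftools` script:
#' `sbftools <stage|all> --outdir DIR [--config FILE] [--seed N]`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
sbf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: sbftools <stage|all> --outdir DIR [--config FILE] [--seed N]\n")
    cat("stages: simulate normalize ratio annotate filter calibrate",
        "reconstruct changes stf\n")
    return(invisible(1L))
  }
  stage <- args[[1]]
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[[1]] < length(args)) args[[i[[1]] + 1L]] else default
  }
  outdir <- get_opt("--outdir", ".")
  seed <- as.integer(get_opt("--seed", "1"))
  cfg_file <- get_opt("--config")
  config <- if (is.null(cfg_file)) sbf_config() else read_sbf_config(cfg_file)
  status <- tryCatch({
    if (stage == "all") {
      sbf_run_all(outdir, config, seed)
    } else {
      sbf_run_stage(stage, outdir, config, seed)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
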