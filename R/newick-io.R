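# Newick / NHX input and output. Parsing proper is delegated to ape; NHX
# comments ([&&NHX:key=value:...]) are folded into node labels before parsing
# and unfolded afterwards, because ape discards bracketed comments. Supported
# keys: Ev (S|D), Snode (species-tree node id), NULLED (1). Annotation values
# must not contain '.', ':' or '='.

NHX_MARK <- "__NHX__"

# named character vector -> label-safe token (':' -> '--', '=' -> '.')
nhx_encode_pairs <- function(pairs) {
  paste0(NHX_MARK, paste(paste0(names(pairs), ".", pairs), collapse = "--"))
}

# label-safe token payload -> named character vector
nhx_decode_token <- function(token) {
  items <- strsplit(token, "--", fixed = TRUE)[[1]]
  kv <- strsplit(items, ".", fixed = TRUE)
  setNames(map_chr(kv, function(x) paste(x[-1], collapse = ".")),
           map_chr(kv, 1))
}

# token payload -> NHX comment body ("Ev=S:Snode=3")
nhx_payload_to_comment <- function(payload) {
  items <- strsplit(payload, "--", fixed = TRUE)[[1]]
  paste(map_chr(items, function(it) sub(".", "=", it, fixed = TRUE)),
        collapse = ":")
}

# Fold every [&&NHX:...] comment into the label of the node it follows. A
# comment after "label:length" is moved in front of the colon so it becomes
# part of the label.
fold_nhx_comments <- function(text) {
  out <- character(0)
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    hit <- regexpr("\\[&&NHX:[^\\]]*\\]", rest, perl = TRUE)
    if (hit == -1L) {
      out <- c(out, rest)
      break
    }
    start <- i + as.integer(hit) - 1L
    len <- attr(hit, "match.length")
    comment <- substr(text, start + 7L, start + len - 2L)
    payload <- gsub("=", ".", gsub(":", "--", comment, fixed = TRUE), fixed = TRUE)
    before <- substr(text, i, start - 1L)
    token <- paste0(NHX_MARK, payload)
    m <- regexpr(":[0-9eE.+-]+$", before, perl = TRUE)
    if (m != -1L) {
      out <- c(out, substr(before, 1L, as.integer(m) - 1L), token,
               substr(before, as.integer(m), nchar(before)))
    } else {
      out <- c(out, before, token)
    }
    i <- start + len
  }
  paste(out, collapse = "")
}

# split folded labels back into (label, annotation) pairs
unfold_labels <- function(labs) {
  labs <- labs %||% character(0)
  ann <- vector("list", length(labs))
  clean <- labs
  for (j in which(grepl(NHX_MARK, labs, fixed = TRUE))) {
    parts <- strsplit(labs[[j]], NHX_MARK, fixed = TRUE)[[1]]
    clean[[j]] <- parts[[1]]
    if (length(parts) > 1 && nzchar(parts[[2]])) {
      ann[[j]] <- nhx_decode_token(parts[[2]])
    }
  }
  list(label = clean, ann = ann)
}

# structural validation so malformed input gets a position, not an opaque
# parser failure
validate_newick <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (k in seq_along(chars)) {
    if (chars[[k]] == "(") depth <- depth + 1L
    if (chars[[k]] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(paste0("malformed Newick: unmatched ')' at character ", k))
      }
    }
  }
  if (depth != 0L) {
    abort(paste0("malformed Newick: ", depth, " unclosed '(' at end of string"))
  }
  if (!grepl(";\\s*$", text)) {
    abort("malformed Newick: missing terminal ';'")
  }
  invisible(text)
}

read_one_newick <- function(text) {
  validate_newick(text)
  phy <- ape::read.tree(text = fold_nhx_comments(text))
  if (is.null(phy)) abort("malformed Newick: the string could not be parsed")
  tips <- unfold_labels(phy$tip.label)
  nodes <- unfold_labels(phy$node.label)
  phy$tip.label <- tips$label
  if (!is.null(phy$node.label)) phy$node.label <- nodes$label
  list(phylo = phy, tip_ann = tips$ann, node_ann = nodes$ann)
}

#' Read a species tree from Newick
#'
#' The tree must be rooted, binary and ultrametric; it is rescaled to root
#' age 1 and branch-labeled (see [species_tree()]).
#'
#' @param file path to a Newick file (one tree).
#' @param text Newick string (alternative to `file`).
#' @param tol ultrametricity tolerance passed to [species_tree()].
#' @return a `species_tree`
#' @export
read_species_tree <- function(file = NULL, text = NULL, tol = 1e-8) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  species_tree(read_one_newick(text)$phylo, tol = tol)
}

#' Read a gene tree from Newick/NHX
#'
#' Tip labels carry species identity as `"species<sep>gene"`. NHX comments
#' with keys `Ev` (`S`/`D`), `Snode` and `NULLED` are recovered into the
#' per-node event annotations; they take precedence over any later
#' species-overlap labeling (see [label_events()]).
#'
#' @inheritParams read_species_tree
#' @param separator species/gene separator in tip labels.
#' @param tip_species optional named species mapping (names = tip labels).
#' @return a `gene_tree`
#' @export
read_gene_tree <- function(file = NULL, text = NULL, separator = "@",
                           tip_species = NULL) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  parsed <- read_one_newick(text)
  phy <- parsed$phylo
  nn <- phy$Nnode
  ev <- rep(NA_character_, nn)
  sn <- rep(NA_integer_, nn)
  for (j in seq_len(nn)) {
    a <- if (j <= length(parsed$node_ann)) parsed$node_ann[[j]] else NULL
    if (is.null(a)) next
    if ("Ev" %in% names(a)) {
      ev[[j]] <- switch(unname(a[["Ev"]]), S = "speciation",
                        D = "duplication", NA_character_)
    }
    if ("NULLED" %in% names(a) && a[["NULLED"]] == "1") ev[[j]] <- "null"
    if ("Snode" %in% names(a)) sn[[j]] <- as.integer(a[["Snode"]])
  }
  gene_tree(phy, separator = separator, tip_species = tip_species,
            event = ev, species_node = sn)
}

#' Read a file of gene trees (one Newick per line)
#'
#' Lines may optionally be prefixed `name<TAB>newick`.
#'
#' @inheritParams read_gene_tree
#' @param file path to the file.
#' @return a named list of `gene_tree` objects.
#' @export
read_gene_trees <- function(file, separator = "@") {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) >= 2) {
      nm[[i]] <- fields[[1]]
      txt <- fields[[2]]
    } else {
      nm[[i]] <- paste0("tree_", i)
      txt <- fields[[1]]
    }
    out[[i]] <- read_gene_tree(text = txt, separator = separator)
  }
  setNames(out, nm)
}

#' Write a gene tree to Newick/NHX
#'
#' Event annotations (`Ev`, `Snode`, `NULLED`) are written as NHX comments
#' after the branch length; calibrated trees carry time branch lengths.
#'
#' @param gt a `gene_tree` or `calibrated_gene_tree`
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when writing to a file).
#' @export
write_gene_tree <- function(gt, file = NULL, digits = 10) {
  phy <- gt$phylo
  nn <- phy$Nnode
  labs <- phy$node.label %||% rep("", nn)
  for (j in seq_len(nn)) {
    pairs <- character(0)
    ev <- gt$event[[j]]
    if (!is.na(ev)) {
      pairs <- c(pairs,
                 Ev = switch(ev, speciation = "S", duplication = "D", null = "S"))
      if (ev == "null") pairs <- c(pairs, NULLED = "1")
    }
    if (!is.na(gt$species_node[[j]])) {
      pairs <- c(pairs, Snode = as.character(gt$species_node[[j]]))
    }
    if (length(pairs)) {
      labs[[j]] <- paste0(labs[[j]], nhx_encode_pairs(pairs))
    }
  }
  phy$node.label <- labs
  txt <- ape::write.tree(phy, digits = digits)
  # unfold __NHX__ tokens back into [&&NHX:...] comments, after any length
  repeat {
    m <- regexpr(paste0(NHX_MARK, "[A-Za-z0-9_.-]*(:[0-9eE.+-]+)?"),
                 txt, perl = TRUE)
    if (m == -1L) break
    s <- as.integer(m)
    e <- s + attr(m, "match.length") - 1L
    piece <- substr(txt, s, e)
    body <- substr(piece, nchar(NHX_MARK) + 1L, nchar(piece))
    colon <- regexpr(":", body, fixed = TRUE)
    if (colon == -1L) {
      payload <- body
      lenpart <- ""
    } else {
      payload <- substr(body, 1L, as.integer(colon) - 1L)
      lenpart <- substr(body, as.integer(colon), nchar(body))
    }
    replacement <- paste0(lenpart, "[&&NHX:", nhx_payload_to_comment(payload), "]")
    txt <- paste0(substr(txt, 1L, s - 1L), replacement,
                  substr(txt, e + 1L, nchar(txt)))
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Write a species tree to Newick
#'
#' @param st a `species_tree`
#' @param file optional path; when `NULL` the Newick string is returned.
#' @export
write_species_tree <- function(st, file = NULL) {
  txt <- ape::write.tree(st$phylo)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
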