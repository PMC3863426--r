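#' @importFrom rlang %||% .data
NULL

new_gene_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  class(nodes) <- c("gene_tree", class(nodes))
  nodes
}

#' @export
print.gene_tree <- function(x, ...) {
  n_dup <- sum(x$event == "duplication", na.rm = TRUE)
  cat("<gene_tree> ", sum(x$is_leaf), " leaves, ", n_dup,
      " duplication node(s)\n", sep = "")
  NextMethod()
}

#' Parse a gene-family tree in NHX format
#'
#' Reads one rooted Newick tree whose bracketed `[&&NHX:...]` comments carry
#' the reconciliation annotations used for duplication dating:
#' `D=Y|N` (duplication flag), `S=<taxon>` (the taxonomic level assigned to
#' the node), and `DCS=<float>` (duplication-consistency score in \[0, 1\]).
#' Unknown NHX tags are ignored with a warning. Leaves may carry an `S=` tag
#' giving their species.
#'
#' @param nhx_text A single string: one tree ending in `;`.
#' @return A `gene_tree`: a tibble with one row per node and columns
#'   `node` (integer id, root = 1), `parent` (`NA` for the root), `is_leaf`,
#'   `label` (gene id for leaves), `species` (leaf `S` tag), `event`
#'   (`"duplication"`, `"speciation"`, or `NA` for unannotated internals),
#'   `taxon` (internal `S` tag), `score` (`DCS`), and `branch_length`.
#' @export
#' @examples
#' tr <- parse_gene_tree(
#'   "((gA:1,gB:1)[&&NHX:D=Y:S=Hominidae:DCS=0.9]:1,gC:1)[&&NHX:D=N:S=Catarrhini];")
#' tr
parse_gene_tree <- function(nhx_text) {
  stopifnot(is.character(nhx_text), length(nhx_text) == 1L)
  txt <- trimws(nhx_text)
  if (!nzchar(txt)) stop("empty tree text", call. = FALSE)
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (depth[length(depth)] != 0L || any(depth < 0L)) {
    stop("unbalanced parentheses in tree text", call. = FALSE)
  }

  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$chars <- chars
  env$n <- length(chars)
  env$rows <- list()
  env$next_id <- 0L
  env$unknown_tags <- character()

  peek <- function() if (env$pos <= env$n) env$chars[env$pos] else ""
  advance <- function() env$pos <- env$pos + 1L

  read_until <- function(stop_chars) {
    start <- env$pos
    while (env$pos <= env$n && !(env$chars[env$pos] %in% stop_chars)) {
      if (env$chars[env$pos] == "[") { # comments handled separately
        break
      }
      advance()
    }
    if (env$pos > start) {
      paste(env$chars[start:(env$pos - 1L)], collapse = "")
    } else ""
  }

  read_comment <- function() {
    # positioned at '['; returns comment body without brackets
    start <- env$pos
    while (env$pos <= env$n && env$chars[env$pos] != "]") advance()
    if (env$pos > env$n) stop("unterminated NHX comment", call. = FALSE)
    body <- paste(env$chars[(start + 1L):(env$pos - 1L)], collapse = "")
    advance()
    body
  }

  parse_nhx_tags <- function(comment, node_desc) {
    out <- list(event = NA_character_, taxon = NA_character_,
                score = NA_real_, species = NA_character_, has_nhx = FALSE)
    if (!startsWith(comment, "&&NHX")) return(out)
    out$has_nhx <- TRUE
    body <- sub("^&&NHX:?", "", comment)
    if (!nzchar(body)) return(out)
    for (tag in strsplit(body, ":", fixed = TRUE)[[1]]) {
      kv <- strsplit(tag, "=", fixed = TRUE)[[1]]
      key <- kv[1]
      val <- if (length(kv) > 1L) paste(kv[-1], collapse = "=") else ""
      if (key == "D") {
        out$event <- if (toupper(val) == "Y") "duplication" else "speciation"
      } else if (key == "S") {
        out$taxon <- val
      } else if (key == "DCS") {
        sc <- suppressWarnings(as.numeric(val))
        if (is.na(sc) || sc < 0 || sc > 1) {
          stop("DCS outside [0,1] at node ", node_desc, ": '", val, "'",
               call. = FALSE)
        }
        out$score <- sc
      } else {
        env$unknown_tags <- union(env$unknown_tags, key)
      }
    }
    out
  }

  # name/comment/branch-length suffix shared by leaves and internal nodes;
  # the NHX comment may come before or after ':length'
  read_suffix <- function(node_desc) {
    label <- read_until(c(":", ",", ")", ";", "["))
    comment <- NULL
    bl <- NA_real_
    repeat {
      ch <- peek()
      if (ch == "[") {
        comment <- read_comment()
      } else if (ch == ":") {
        advance()
        bl_txt <- read_until(c(",", ")", ";", "["))
        bl <- suppressWarnings(as.numeric(bl_txt))
      } else break
    }
    tags <- if (is.null(comment)) {
      list(event = NA_character_, taxon = NA_character_, score = NA_real_,
           has_nhx = FALSE)
    } else {
      parse_nhx_tags(comment, node_desc)
    }
    list(label = label, branch_length = bl, tags = tags)
  }

  parse_clade <- function(parent_id) {
    env$next_id <- env$next_id + 1L
    id <- env$next_id
    if (peek() == "(") {
      advance()
      repeat {
        parse_clade(id)
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed tree near position ", env$pos, call. = FALSE)
      }
      sfx <- read_suffix(paste0("#", id))
      tags <- sfx$tags
      if (tags$has_nhx && is.na(tags$taxon)) {
        stop("internal node #", id, " has an NHX comment without an S tag",
             call. = FALSE)
      }
      env$rows[[id]] <- list(
        node = id, parent = parent_id, is_leaf = FALSE,
        label = sfx$label, species = NA_character_,
        event = tags$event, taxon = tags$taxon, score = tags$score,
        branch_length = sfx$branch_length)
    } else {
      sfx <- read_suffix(paste0("#", id))
      if (!nzchar(sfx$label)) {
        stop("unnamed leaf at node #", id, call. = FALSE)
      }
      env$rows[[id]] <- list(
        node = id, parent = parent_id, is_leaf = TRUE,
        label = sfx$label, species = sfx$tags$taxon,
        event = NA_character_, taxon = NA_character_, score = NA_real_,
        branch_length = sfx$branch_length)
    }
    id
  }

  parse_clade(NA_integer_)
  if (peek() != ";") {
    stop("tree text must end with ';'", call. = FALSE)
  }
  if (length(env$unknown_tags) > 0L) {
    warning("ignoring unknown NHX tag(s): ",
            paste(env$unknown_tags, collapse = ", "), call. = FALSE)
  }
  new_gene_tree(dplyr::bind_rows(env$rows))
}

#' Serialize a gene tree back to NHX text
#'
#' Inverse of [parse_gene_tree()]: `parse_gene_tree(write_gene_tree(x))`
#' reproduces `x` node for node.
#'
#' @param tree A `gene_tree` tibble.
#' @return A single NHX string terminated by `;`.
#' @export
write_gene_tree <- function(tree) {
  stopifnot(is.data.frame(tree))
  kids <- split(tree$node, factor(tree$parent, levels = tree$node))

  fmt_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

  node_text <- function(id) {
    row <- tree[tree$node == id, ]
    nhx <- character()
    if (row$is_leaf) {
      if (!is.na(row$species)) nhx <- c(nhx, paste0("S=", row$species))
      core <- row$label
    } else {
      if (!is.na(row$event)) {
        nhx <- c(nhx, paste0("D=", if (row$event == "duplication") "Y" else "N"))
      }
      if (!is.na(row$taxon)) nhx <- c(nhx, paste0("S=", row$taxon))
      if (!is.na(row$score)) nhx <- c(nhx, paste0("DCS=", fmt_num(row$score)))
      core <- paste0(
        "(", paste(vapply(kids[[as.character(id)]], node_text, character(1)),
                   collapse = ","), ")",
        if (nzchar(row$label)) row$label else "")
    }
    if (length(nhx) > 0L) {
      core <- paste0(core, "[&&NHX:", paste(nhx, collapse = ":"), "]")
    }
    if (!is.na(row$branch_length)) {
      core <- paste0(core, ":", fmt_num(row$branch_length))
    }
    core
  }

  root <- tree$node[is.na(tree$parent)]
  paste0(node_text(root), ";")
}

#' Read a directory of NHX tree files
#'
#' @param dir Directory containing `*.nhx` files, one tree per file.
#' @return Named list of `gene_tree` tibbles (names = file names without
#'   extension).
#' @export
read_tree_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.nhx$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no .nhx files found in ", dir, call. = FALSE)
  }
  trees <- lapply(files, function(f) parse_gene_tree(readr::read_file(f)))
  names(trees) <- sub("\\.nhx$", "", basename(files))
  trees
}
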