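#' Combine gene trees into one node table
#'
#' Stacks a list of `gene_tree` tibbles into a single tibble with a `family`
#' column, the form consumed by [assign_duplication_age()].
#'
#' @param trees A `gene_tree`, or a (optionally named) list of them.
#' @return A tibble of nodes with a `family` identifier column.
#' @export
bind_gene_trees <- function(trees) {
  if (is.data.frame(trees)) {
    if (!"family" %in% names(trees)) trees$family <- "fam_1"
    return(tibble::as_tibble(trees))
  }
  stopifnot(is.list(trees), length(trees) > 0L)
  nm <- names(trees) %||% paste0("fam_", seq_along(trees))
  if (is.null(names(trees))) names(trees) <- nm
  dplyr::bind_rows(trees, .id = "family")
}

#' Assign a duplication age class to every focal-species gene
#'
#' For each focal-species leaf the walk goes leaf to root and inspects
#' duplication nodes in order. At each duplication node with
#' duplication-consistency score `s`:
#' * `s >` `score_threshold`: the gene is a duplicated gene (`PDG`) and its
#'   age class is the node's taxonomic level (via [map_taxon_to_class()]);
#' * `s == 0`: the duplication is treated as a reconstruction artifact and
#'   the walk continues to the next duplication node toward the root;
#' * `0 < s <=` `score_threshold`: the age is considered unclear and the gene
#'   is left `UNASSIGNED`.
#'
#' A gene whose walk exhausts all duplication nodes (none present, or all
#' skipped as artifacts) is a `SINGLETON`. A would-be PDG whose evidence node
#' maps to a level older than the timeline (out-of-timeline) is also a
#' `SINGLETON`: it was not duplicated within the analyzed era.
#'
#' @param trees A `gene_tree`, a list of them, or a bound node table from
#'   [bind_gene_trees()] (a `family` column distinguishes trees).
#' @param timeline A [phylo_timeline()]; focal leaves are those whose species
#'   label equals `timeline$focal_species`.
#' @param score_threshold Acceptance threshold on the consistency score;
#'   a node is age evidence only when its score is strictly greater
#'   (default 0.3).
#' @return A tibble with one row per focal-species gene: `gene_id`, `status`
#'   (`PDG` / `SINGLETON` / `UNASSIGNED`), `age_class` (integer index,
#'   1 = oldest; `NA` unless PDG), `age_class_label`, and `evidence_node`
#'   (`family:node`, `NA` unless PDG).
#' @export
#' @examples
#' tl <- load_timeline("human")
#' tr <- parse_gene_tree(paste0(
#'   "((g1[&&NHX:S=Homo_sapiens]:1,g2[&&NHX:S=Homo_sapiens]:1)",
#'   "[&&NHX:D=Y:S=Hominidae:DCS=0.9]:1,g3[&&NHX:S=Pan_troglodytes]:1)",
#'   "[&&NHX:D=N:S=Catarrhini];"))
#' assign_duplication_age(tr, tl)
assign_duplication_age <- function(trees, timeline, score_threshold = 0.3) {
  stopifnot(inherits(timeline, "phylo_timeline"))
  nodes <- bind_gene_trees(trees)

  key <- paste(nodes$family, nodes$node)
  pidx <- match(paste(nodes$family, nodes$parent), key)

  species_norm <- gsub("_", " ", nodes$species, fixed = TRUE)
  focal <- which(nodes$is_leaf &
                   !is.na(species_norm) &
                   species_norm == timeline$focal_species)
  gene_id <- nodes$label[focal]
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("gene(s) present in multiple trees: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }

  is_dup <- !nodes$is_leaf & !is.na(nodes$event) & nodes$event == "duplication"
  cls <- map_taxon_to_class(nodes$taxon, timeline)

  n <- length(focal)
  status <- rep("undecided", n)
  evidence <- rep(NA_integer_, n)
  cur <- pidx[focal]
  while (any(status == "undecided" & !is.na(cur))) {
    active <- which(status == "undecided" & !is.na(cur))
    at_dup <- active[is_dup[cur[active]]]
    if (length(at_dup) > 0L) {
      s <- nodes$score[cur[at_dup]]
      if (anyNA(s)) {
        bad <- cur[at_dup][is.na(s)][1]
        stop("duplication node missing a consistency score: ",
             nodes$family[bad], ":", nodes$node[bad], call. = FALSE)
      }
      accept <- at_dup[s > score_threshold]
      unclear <- at_dup[s > 0 & s <= score_threshold]
      status[accept] <- "PDG"
      evidence[accept] <- cur[accept]
      status[unclear] <- "UNASSIGNED"
      # s == 0: artifact; keep walking toward the root
    }
    cur <- pidx[cur]
  }
  status[status == "undecided"] <- "SINGLETON"

  age_class <- ifelse(status == "PDG", cls[evidence], NA_integer_)
  # accepted node older than the timeline: not duplicated in the analyzed era
  oot <- status == "PDG" & is.na(age_class)
  status[oot] <- "SINGLETON"
  evidence[oot] <- NA_integer_
  age_class[oot] <- NA_integer_

  tibble::tibble(
    gene_id = gene_id,
    status = status,
    age_class = as.integer(age_class),
    age_class_label = ifelse(is.na(age_class), NA_character_,
                             timeline$classes[age_class]),
    evidence_node = ifelse(is.na(evidence), NA_character_,
                           paste0(nodes$family[evidence], ":",
                                  nodes$node[evidence]))
  )
}

#' Split duplicated genes into young and old age groups
#'
#' Genes at or younger than the split class are `young`; strictly older are
#' `old`. For the human timeline the default split at Simiiformes labels the
#' primate-era phylostrata as young. Singleton and unassigned genes get `NA`.
#'
#' @param ages Assignment tibble from [assign_duplication_age()].
#' @param timeline The [phylo_timeline()] used for the assignment.
#' @param split_class Label of the oldest class counted as young.
#' @return `ages` with an added `age_group` column (`"young"` / `"old"` /
#'   `NA`).
#' @export
young_old_split <- function(ages, timeline, split_class = "Simiiformes") {
  split_idx <- match(split_class, timeline$classes)
  if (is.na(split_idx)) {
    stop("split class '", split_class, "' is not a timeline class",
         call. = FALSE)
  }
  dplyr::mutate(
    ages,
    age_group = dplyr::case_when(
      .data$status != "PDG" ~ NA_character_,
      .data$age_class >= split_idx ~ "young",
      TRUE ~ "old"
    )
  )
}
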