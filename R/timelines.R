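#' Construct a phylostratum timeline
#'
#' A timeline is the ordered list of ancestral taxa (oldest to youngest) that
#' defines the discrete duplication-age classes for a focal species, together
#' with collapse aliases that fold unstable taxonomic levels into a retained
#' class (e.g. Euarchontoglires into Eutheria).
#'
#' @param classes Character vector of class labels, ordered oldest to
#'   youngest. The last class must equal `focal_species`.
#' @param focal_species Label of the focal species (youngest class).
#' @param name Short identifier for the timeline.
#' @param collapse_aliases Named character vector mapping a taxon label to the
#'   class it collapses into. May be empty.
#'
#' @return An object of class `phylo_timeline`: a list with elements `name`,
#'   `classes`, `focal_species` and `collapse_aliases`.
#' @export
#' @examples
#' tl <- phylo_timeline(c("Bilateria", "Mammalia", "Homo sapiens"),
#'                      focal_species = "Homo sapiens")
#' n_age_classes(tl)
phylo_timeline <- function(classes, focal_species, name = "custom",
                           collapse_aliases = character()) {
  classes <- as.character(classes)
  if (length(classes) < 1L) {
    stop("a timeline needs at least one age class", call. = FALSE)
  }
  if (anyDuplicated(classes)) {
    stop("timeline class labels must be unique", call. = FALSE)
  }
  if (!identical(classes[length(classes)], focal_species)) {
    stop("`focal_species` must equal the youngest (last) timeline class",
         call. = FALSE)
  }
  collapse_aliases <- vapply(collapse_aliases, as.character, character(1))
  if (length(collapse_aliases) > 0L) {
    bad <- setdiff(unname(collapse_aliases), classes)
    if (length(bad) > 0L) {
      stop("collapse alias target(s) not in timeline: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    clash <- intersect(names(collapse_aliases), classes)
    if (length(clash) > 0L) {
      stop("alias source(s) are themselves timeline classes: ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(name = name, classes = classes, focal_species = focal_species,
         collapse_aliases = collapse_aliases),
    class = "phylo_timeline"
  )
}

#' @export
print.phylo_timeline <- function(x, ...) {
  cat("<phylo_timeline> ", x$name, ": ", length(x$classes),
      " age classes (oldest -> youngest)\n", sep = "")
  cat("  ", paste(x$classes, collapse = " > "), "\n", sep = "")
  if (length(x$collapse_aliases) > 0L) {
    cat("  aliases: ",
        paste(names(x$collapse_aliases), "->", x$collapse_aliases,
              collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of age classes in a timeline
#' @param timeline A [phylo_timeline()] object.
#' @return Integer count of classes.
#' @export
n_age_classes <- function(timeline) {
  stopifnot(inherits(timeline, "phylo_timeline"))
  length(timeline$classes)
}

#' Load a timeline shipped with the package or from a YAML file
#'
#' Two timelines are built in: `"human"` (14 classes, Bilateria through
#' *Homo sapiens*, with Euarchontoglires collapsed into Eutheria) and
#' `"mouse"` (13 classes, Bilateria through *Mus musculus*). Any other value
#' is treated as a path to a YAML file with fields `name`, `focal_species`,
#' `classes` and optional `collapse_aliases`.
#'
#' @param which `"human"`, `"mouse"`, or a path to a timeline YAML file.
#' @return A [phylo_timeline()] object.
#' @export
#' @examples
#' load_timeline("human")
load_timeline <- function(which = c("human", "mouse")) {
  path <- if (which[1] %in% c("human", "mouse")) {
    system.file("extdata", "timelines", paste0(which[1], ".yaml"),
                package = "duplirep", mustWork = TRUE)
  } else {
    which[1]
  }
  spec <- yaml::read_yaml(path)
  aliases <- unlist(spec$collapse_aliases %||% list())
  if (is.null(aliases)) aliases <- character()
  phylo_timeline(classes = unlist(spec$classes),
                 focal_species = spec$focal_species,
                 name = spec$name %||% basename(path),
                 collapse_aliases = aliases)
}

#' Map a taxon label to its phylostratum index
#'
#' Collapse aliases are resolved before lookup. Taxa that are neither a
#' timeline class nor an alias (typically levels older than the oldest class,
#' such as Opisthokonta for the human timeline) return `NA`, meaning
#' out-of-timeline. Underscores in labels are treated as spaces so NHX-safe
#' labels like `Homo_sapiens` resolve.
#'
#' @param taxon Character vector of taxon labels.
#' @param timeline A [phylo_timeline()] object.
#' @return Integer vector of class indices (1 = oldest); `NA` for
#'   out-of-timeline taxa. Total function: never errors on unknown labels.
#' @export
#' @examples
#' tl <- load_timeline("human")
#' map_taxon_to_class(c("Hominidae", "Euarchontoglires", "Opisthokonta"), tl)
map_taxon_to_class <- function(taxon, timeline) {
  stopifnot(inherits(timeline, "phylo_timeline"))
  taxon <- gsub("_", " ", as.character(taxon), fixed = TRUE)
  aliased <- unname(timeline$collapse_aliases[taxon])
  taxon <- ifelse(is.na(aliased), taxon, aliased)
  match(taxon, timeline$classes)
}
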