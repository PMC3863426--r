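#' Is a chromosome an autosome?
#'
#' Autosomes are recognised as purely numeric names, with or without a
#' `chr` prefix (`"7"`, `"chr12"`). Everything else (`chrX`, `Y`, `MT`,
#' scaffolds) is non-autosomal.
#'
#' @param chrom Character vector of chromosome names.
#' @return Logical vector.
#' @export
is_autosome <- function(chrom) {
  grepl("^(chr)?[0-9]+$", chrom, ignore.case = TRUE)
}

#' Call copy-number-variable genes
#'
#' A gene is copy-number variable (CNV) when at least `min_individuals`
#' individuals carry `gain_threshold` or more copies, or at least
#' `min_individuals` individuals carry fewer than `loss_threshold` copies
#' (defaults: >= 4 copies or < 2 copies in >= 2 individuals). The two
#' criteria are evaluated independently and either suffices. Before calling,
#' genes shorter than `min_gene_length` (copy-number estimates are unreliable
#' there) and, by default, non-autosomal genes are excluded. Gene length is
#' `end - start` on 0-based half-open coordinates; a gene of exactly
#' `min_gene_length` is kept.
#'
#' Setting `loss_threshold = 0` disables the loss criterion (no copy number
#' is below zero), giving the gains-only mode.
#'
#' @param copies Tibble with a `gene_id` column and one integer column per
#'   individual.
#' @param genes Gene table with `gene_id`, `chrom`, `start`, `end`.
#' @param min_gene_length Minimum gene length in bp to keep (default 1000).
#' @param gain_threshold Copies at or above which an individual counts as a
#'   gain carrier (default 4, inclusive).
#' @param loss_threshold Copies strictly below which an individual counts as
#'   a loss carrier (default 2).
#' @param min_individuals Carriers required to call a CNV (default 2).
#' @param autosomes_only Exclude non-autosomal genes (default `TRUE`).
#' @return Tibble: `gene_id`, `status` (`CNV` / `NON_CNV` / `EXCLUDED`),
#'   `exclusion_reason` (`too_short` / `non_autosomal` / `NA`), `n_gain`,
#'   `n_loss`.
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "1", start = 0, end = 2000)
#' cn <- tibble::tibble(gene_id = "g1", i1 = 2L, i2 = 2L, i3 = 4L, i4 = 4L)
#' call_cnv_genes(cn, genes)
call_cnv_genes <- function(copies, genes,
                           min_gene_length = 1000,
                           gain_threshold = 4,
                           loss_threshold = 2,
                           min_individuals = 2,
                           autosomes_only = TRUE) {
  stopifnot(is.data.frame(copies), is.data.frame(genes),
            "gene_id" %in% names(copies),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            min_individuals >= 1, gain_threshold > loss_threshold)

  ind_cols <- setdiff(names(copies), "gene_id")
  if (length(ind_cols) == 0L) {
    stop("copy-number table has no individual columns", call. = FALSE)
  }
  cn <- as.matrix(copies[ind_cols])
  if (anyNA(cn) || any(cn != round(cn)) || any(cn < 0)) {
    stop("copy numbers must be non-negative integers", call. = FALSE)
  }

  meta <- dplyr::left_join(copies["gene_id"], genes, by = "gene_id")
  if (anyNA(meta$start)) {
    stop("gene(s) in the copy-number table missing from the gene table: ",
         paste(utils::head(meta$gene_id[is.na(meta$start)], 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(meta$end <= meta$start)) {
    stop("gene coordinates must satisfy end > start", call. = FALSE)
  }

  len <- meta$end - meta$start
  excl <- dplyr::case_when(
    len < min_gene_length ~ "too_short",
    autosomes_only & !is_autosome(meta$chrom) ~ "non_autosomal",
    TRUE ~ NA_character_
  )

  n_gain <- rowSums(cn >= gain_threshold)
  n_loss <- rowSums(cn < loss_threshold)
  cnv <- n_gain >= min_individuals | n_loss >= min_individuals

  tibble::tibble(
    gene_id = copies$gene_id,
    status = dplyr::case_when(
      !is.na(excl) ~ "EXCLUDED",
      cnv ~ "CNV",
      TRUE ~ "NON_CNV"
    ),
    exclusion_reason = excl,
    n_gain = as.integer(n_gain),
    n_loss = as.integer(n_loss)
  )
}

#' Cross-tabulate CNV status by duplication age class
#'
#' Joins CNV calls to age assignments and counts CNV and non-CNV duplicated
#' genes per phylostratum. Excluded genes, unassigned genes and singletons
#' (which carry no age class) are dropped, with a message reporting how many.
#'
#' @param calls Output of [call_cnv_genes()].
#' @param ages Output of [assign_duplication_age()].
#' @return Tibble ordered oldest to youngest: `age_class`,
#'   `age_class_label`, `n_cnv`, `n_non_cnv`, `cnv_fraction`. The cell total
#'   equals the number of joined, retained genes.
#' @export
cnv_by_age_table <- function(calls, ages) {
  joined <- dplyr::inner_join(calls, ages, by = "gene_id")
  if (nrow(joined) == 0L) {
    stop("no genes shared between CNV calls and age assignments",
         call. = FALSE)
  }
  n_excl <- sum(joined$status.x == "EXCLUDED")
  n_drop_age <- sum(joined$status.y != "PDG")
  kept <- dplyr::filter(joined, .data$status.x != "EXCLUDED",
                        .data$status.y == "PDG")
  message("cnv_by_age_table: dropped ", n_excl, " excluded and ",
          n_drop_age, " non-PDG genes; ", nrow(kept), " genes retained")
  if (nrow(kept) == 0L) {
    stop("no PDG genes with a CNV call remain after exclusions",
         call. = FALSE)
  }
  kept |>
    dplyr::count(.data$age_class, .data$age_class_label,
                 cnv = .data$status.x == "CNV") |>
    tidyr::pivot_wider(names_from = "cnv", values_from = "n",
                       values_fill = 0L,
                       names_sort = TRUE) |>
    dplyr::rename(n_cnv = dplyr::any_of("TRUE"),
                  n_non_cnv = dplyr::any_of("FALSE")) |>
    (\(d) {
      if (!"n_cnv" %in% names(d)) d$n_cnv <- 0L
      if (!"n_non_cnv" %in% names(d)) d$n_non_cnv <- 0L
      d
    })() |>
    dplyr::mutate(cnv_fraction = .data$n_cnv / (.data$n_cnv + .data$n_non_cnv)) |>
    dplyr::select("age_class", "age_class_label", "n_cnv", "n_non_cnv",
                  "cnv_fraction") |>
    dplyr::arrange(.data$age_class)
  }
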