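safe_test <- function(expr, label) {
  tryCatch(expr, error = function(e) {
    test_result(label, p_value = NA_real_, n = 0L,
                note = paste("not computed:", conditionMessage(e)))
  })
}

#' Run the full duplication-age / CNV / replication-timing analysis
#'
#' Orchestrates every stage: duplication-age assignment from the gene trees,
#' CNV calling from the copy-number matrix, per-gene replication-timing
#' ranks from the probe tracks, chromosomal-region stratification, and the
#' statistical battery linking the layers. Genes missing an annotation
#' required by a given test are dropped from that test only (e.g. genes
#' without a probe within reach are excluded from replication-timing tests
#' but still counted in the CNV-by-age table), so different tests use
#' different gene universes; the per-gene master table records everything.
#'
#' @param inputs List with `genes`, `chrom_map`, `trees`, `copies`,
#'   `probes` -- as produced by [simulate_dataset()] or
#'   [read_pipeline_inputs()].
#' @param timeline A [phylo_timeline()] or a name for [load_timeline()];
#'   defaults to the simulation's timeline when `inputs` is a
#'   `duplirep_sim`.
#' @param score_threshold Duplication-consistency acceptance threshold
#'   (default 0.3).
#' @param min_gene_length,gain_threshold,loss_threshold,min_individuals,autosomes_only
#'   CNV-calling parameters, see [call_cnv_genes()].
#' @param max_distance Nearest-probe cutoff in bp (default 10000).
#' @param sign_convention Probe log-ratio sign convention, see
#'   [median_probe_rank()].
#' @param window Pericentromeric/subtelomeric window in bp (default 5e6).
#' @param split_class Oldest class counted as "young", see
#'   [young_old_split()]; default `"Simiiformes"` (the primate-era split on
#'   the human timeline). Ignored with a message if absent from the
#'   timeline.
#' @return A `duplirep_report`: list with `master` (per-gene annotation
#'   table), `cnv_by_age`, `tests` (all test results, one row each, with a
#'   `comparison` column), `region_correlations`, `counts`, and `params`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 3, n_genes = 300))
#' rep <- run_full_analysis(sim)
#' rep$cnv_by_age
run_full_analysis <- function(inputs,
                              timeline = NULL,
                              score_threshold = 0.3,
                              min_gene_length = 1000,
                              gain_threshold = 4,
                              loss_threshold = 2,
                              min_individuals = 2,
                              autosomes_only = TRUE,
                              max_distance = 10000,
                              sign_convention = "higher_is_earlier",
                              window = 5e6,
                              split_class = "Simiiformes") {
  for (nm in c("genes", "chrom_map", "trees", "copies", "probes")) {
    if (is.null(inputs[[nm]])) stop("missing input: ", nm, call. = FALSE)
  }
  if (is.null(timeline) && inherits(inputs, "duplirep_sim")) {
    timeline <- inputs$config$timeline
  }
  if (is.character(timeline)) timeline <- load_timeline(timeline)
  stopifnot(inherits(timeline, "phylo_timeline"))
  if (nrow(inputs$genes) == 0L) stop("empty gene table", call. = FALSE)

  ages <- assign_duplication_age(inputs$trees, timeline, score_threshold)
  if (match(split_class, timeline$classes, nomatch = 0L) > 0L) {
    ages <- young_old_split(ages, timeline, split_class)
  } else {
    message("split class '", split_class,
            "' not in timeline; skipping young/old split")
    ages$age_group <- NA_character_
  }
  calls <- call_cnv_genes(inputs$copies, inputs$genes,
                          min_gene_length = min_gene_length,
                          gain_threshold = gain_threshold,
                          loss_threshold = loss_threshold,
                          min_individuals = min_individuals,
                          autosomes_only = autosomes_only)
  med <- median_probe_rank(inputs$probes, sign_convention = sign_convention)
  rt <- assign_gene_rt(inputs$genes, med, max_distance = max_distance)
  regions <- classify_gene_region(inputs$genes, inputs$chrom_map,
                                  window = window)

  master <- inputs$genes |>
    dplyr::select("gene_id", "chrom", "start", "end") |>
    dplyr::left_join(ages, by = "gene_id") |>
    dplyr::left_join(dplyr::select(calls, "gene_id",
                                   cnv_status = "status",
                                   "exclusion_reason", "n_gain", "n_loss"),
                     by = "gene_id") |>
    dplyr::left_join(rt, by = "gene_id") |>
    dplyr::left_join(regions, by = "gene_id")
  if (nrow(master) == 0L) stop("empty master table", call. = FALSE)

  cnv_by_age <- suppressMessages(cnv_by_age_table(calls, ages))

  tests <- list()
  add <- function(comparison, res) {
    res$comparison <- comparison
    tests[[length(tests) + 1L]] <<- res
  }

  # CNV fraction across phylostrata (needs both margins populated)
  add("cnv_fraction_by_age_class", safe_test({
    tab <- rbind(cnv_by_age$n_cnv, cnv_by_age$n_non_cnv)
    keep <- colSums(tab) > 0
    chi_squared_independence(tab[, keep, drop = FALSE])
  }, "chi_squared"))

  # PDG vs singleton CNV proportions
  cnv_univ <- dplyr::filter(master, .data$cnv_status != "EXCLUDED",
                            .data$status %in% c("PDG", "SINGLETON"))
  add("cnv_proportion_pdg_vs_singleton", safe_test({
    k1 <- sum(cnv_univ$status == "PDG" & cnv_univ$cnv_status == "CNV")
    n1 <- sum(cnv_univ$status == "PDG")
    k2 <- sum(cnv_univ$status == "SINGLETON" & cnv_univ$cnv_status == "CNV")
    n2 <- sum(cnv_univ$status == "SINGLETON")
    two_proportion_test(k1, n1, k2, n2)
  }, "two_proportion"))

  # replication-timing comparisons: CNV vs non-CNV within gene subsets
  rt_univ <- dplyr::filter(master, !is.na(.data$order_of_replication),
                           .data$cnv_status %in% c("CNV", "NON_CNV"))
  rt_subsets <- list(
    rt_cnv_vs_noncnv_all = rt_univ,
    rt_cnv_vs_noncnv_pdg = dplyr::filter(rt_univ, .data$status == "PDG"),
    rt_cnv_vs_noncnv_singleton = dplyr::filter(rt_univ,
                                               .data$status == "SINGLETON"),
    rt_cnv_vs_noncnv_young_pdg = dplyr::filter(rt_univ,
                                               .data$age_group %in% "young"),
    rt_cnv_vs_noncnv_old_pdg = dplyr::filter(rt_univ,
                                             .data$age_group %in% "old"))
  for (nm in names(rt_subsets)) {
    d <- rt_subsets[[nm]]
    add(nm, safe_test(
      wilcoxon_rank_sum(d$order_of_replication[d$cnv_status == "CNV"],
                        d$order_of_replication[d$cnv_status == "NON_CNV"]),
      "wilcoxon_rank_sum"))
  }
  add("rt_young_vs_old_pdg", safe_test({
    d <- dplyr::filter(master, !is.na(.data$order_of_replication))
    wilcoxon_rank_sum(d$order_of_replication[d$age_group %in% "young"],
                      d$order_of_replication[d$age_group %in% "old"])
  }, "wilcoxon_rank_sum"))

  # age vs replication timing (positive rho: younger class index, later)
  pdg_rt <- dplyr::filter(master, .data$status == "PDG",
                          !is.na(.data$order_of_replication))
  add("rt_vs_age_all_pdg", safe_test(
    spearman_correlation(pdg_rt$age_class, pdg_rt$order_of_replication),
    "spearman"))

  region_correlations <- pdg_rt |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(~ safe_test(
      spearman_correlation(.x$age_class, .x$order_of_replication),
      "spearman")) |>
    dplyr::ungroup()
  for (i in seq_len(nrow(region_correlations))) {
    add(paste0("rt_vs_age_", region_correlations$region[i]),
        region_correlations[i, setdiff(names(region_correlations),
                                       "region")])
  }

  # young PDGs at pericentromeres; CNV PDGs enriched near both landmarks
  pdg <- dplyr::filter(master, .data$status == "PDG",
                       !is.na(.data$age_group))
  add("young_pdg_pericentromeric_enrichment", safe_test({
    tab <- table(factor(pdg$age_group, c("young", "old")),
                 factor(pdg$region == "pericentromeric", c(TRUE, FALSE)))
    chi_squared_independence(as.matrix(tab))
  }, "chi_squared"))
  pdg_call <- dplyr::filter(master, .data$status == "PDG",
                            .data$cnv_status %in% c("CNV", "NON_CNV"))
  for (reg in c("subtelomeric", "pericentromeric")) {
    add(paste0("cnv_pdg_fold_enrichment_", reg), safe_test({
      in_reg <- pdg_call$region == reg
      fold_enrichment(sum(in_reg & pdg_call$cnv_status == "CNV"),
                      sum(in_reg),
                      sum(pdg_call$cnv_status == "CNV"),
                      nrow(pdg_call))
    }, "fold_enrichment"))
  }

  tests <- dplyr::bind_rows(tests) |>
    dplyr::select("comparison", dplyr::everything())

  counts <- tibble::tibble(
    n_genes = nrow(master),
    n_pdg = sum(master$status == "PDG", na.rm = TRUE),
    n_singleton = sum(master$status == "SINGLETON", na.rm = TRUE),
    n_unassigned = sum(master$status == "UNASSIGNED", na.rm = TRUE),
    n_cnv = sum(master$cnv_status == "CNV", na.rm = TRUE),
    n_excluded_cnv = sum(master$cnv_status == "EXCLUDED", na.rm = TRUE),
    n_with_rt = sum(!is.na(master$order_of_replication)),
    n_pericentromeric = sum(master$region == "pericentromeric", na.rm = TRUE),
    n_subtelomeric = sum(master$region == "subtelomeric", na.rm = TRUE),
    n_interstitial = sum(master$region == "interstitial", na.rm = TRUE))

  structure(
    list(master = master, cnv_by_age = cnv_by_age, tests = tests,
         region_correlations = region_correlations, counts = counts,
         params = list(timeline = timeline$name,
                       score_threshold = score_threshold,
                       min_gene_length = min_gene_length,
                       gain_threshold = gain_threshold,
                       loss_threshold = loss_threshold,
                       min_individuals = min_individuals,
                       autosomes_only = autosomes_only,
                       max_distance = max_distance,
                       sign_convention = sign_convention,
                       window = window, split_class = split_class,
                       n_tests = nrow(tests))),
    class = "duplirep_report")
}

#' @export
print.duplirep_report <- function(x, ...) {
  cat("<duplirep_report>\n")
  cat("  genes: ", x$counts$n_genes, " (", x$counts$n_pdg, " PDG, ",
      x$counts$n_singleton, " singleton, ", x$counts$n_unassigned,
      " unassigned)\n", sep = "")
  cat("  CNV genes: ", x$counts$n_cnv, " (", x$counts$n_excluded_cnv,
      " excluded from calling); with RT: ", x$counts$n_with_rt, "\n",
      sep = "")
  rho <- x$tests[x$tests$comparison == "rt_vs_age_all_pdg", ]
  if (nrow(rho) == 1L && !is.na(rho$effect)) {
    cat(sprintf("  age-RT Spearman rho = %.3f (p = %.3g, n = %d)\n",
                rho$effect, rho$p_value, rho$n))
  }
  cat("  ", nrow(x$tests), " tests; see $tests, $cnv_by_age, $master\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a duplirep report into its test-result table
#'
#' @param x A `duplirep_report`.
#' @param ... Unused.
#' @return Tibble of all test results (one row per test).
#' @method tidy duplirep_report
#' @export
tidy.duplirep_report <- function(x, ...) x$tests

#' One-row summary of a duplirep report
#'
#' @param x A `duplirep_report`.
#' @param ... Unused.
#' @return One-row tibble: gene counts plus the headline age-RT Spearman
#'   rho and p-value and the PDG-vs-singleton CNV proportion difference.
#' @method glance duplirep_report
#' @export
glance.duplirep_report <- function(x, ...) {
  pick <- function(cmp, col) {
    r <- x$tests[x$tests$comparison == cmp, ]
    if (nrow(r) == 1L) r[[col]] else NA_real_
  }
  dplyr::bind_cols(
    x$counts,
    tibble::tibble(
      rho_age_rt = pick("rt_vs_age_all_pdg", "effect"),
      p_age_rt = pick("rt_vs_age_all_pdg", "p_value"),
      cnv_prop_diff_pdg_singleton =
        pick("cnv_proportion_pdg_vs_singleton", "effect"),
      n_tests = nrow(x$tests)))
}

#' Check the three qualitative headline patterns in a report
#'
#' The patterns (all directions fixed a priori, tested at `alpha`):
#' 1. CNV fraction rises toward younger phylostrata (per-gene Spearman of
#'    age-class index vs CNV indicator positive and significant, and the
#'    class-by-CNV chi-squared significant).
#' 2. Among young duplicates, CNV genes replicate later than non-CNV genes
#'    (significant, positive rank-biserial), while among old duplicates the
#'    same comparison is not significant.
#' 3. Replication timing grows later with youth: positive, significant
#'    age-RT Spearman overall and within each chromosomal region present.
#'
#' @param report A `duplirep_report`.
#' @param alpha Significance level (default 0.01).
#' @return One-row tibble of logicals: `cnv_age_gradient`,
#'   `young_cnv_late`, `rt_age_correlation`, and `all_patterns`.
#' @export
check_qualitative_patterns <- function(report, alpha = 0.01) {
  tst <- function(cmp) report$tests[report$tests$comparison == cmp, ]

  m <- dplyr::filter(report$master, .data$status == "PDG",
                     .data$cnv_status %in% c("CNV", "NON_CNV"))
  p1 <- FALSE
  if (nrow(m) >= 10L) {
    sp <- safe_test(spearman_correlation(m$age_class,
                                         as.numeric(m$cnv_status == "CNV")),
                    "spearman")
    chi <- tst("cnv_fraction_by_age_class")
    p1 <- isTRUE(sp$effect > 0 && sp$p_value < alpha &&
                   nrow(chi) == 1L && chi$p_value < alpha)
  }

  yw <- tst("rt_cnv_vs_noncnv_young_pdg")
  ow <- tst("rt_cnv_vs_noncnv_old_pdg")
  p2 <- isTRUE(nrow(yw) == 1L && nrow(ow) == 1L &&
                 yw$p_value < alpha && yw$effect > 0 &&
                 ow$p_value >= alpha)

  ov <- tst("rt_vs_age_all_pdg")
  regs <- report$region_correlations
  p3 <- isTRUE(nrow(ov) == 1L && ov$effect > 0 && ov$p_value < alpha &&
                 nrow(regs) >= 1L &&
                 all(regs$effect > 0 & regs$p_value < alpha))

  tibble::tibble(cnv_age_gradient = p1, young_cnv_late = p2,
                 rt_age_correlation = p3,
                 all_patterns = p1 && p2 && p3)
}
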