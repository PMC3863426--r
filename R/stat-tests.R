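test_result <- function(test, statistic = NA_real_, df = NA_real_,
                        p_value, effect = NA_real_, n, note = NA_character_) {
  tibble::tibble(test = test, statistic = as.numeric(statistic),
                 df = as.numeric(df), p_value = as.numeric(p_value),
                 effect = as.numeric(effect), n = as.integer(n), note = note)
}

#' Chi-squared test of independence on a contingency table
#'
#' Pearson's chi-squared without continuity correction: statistic
#' \eqn{\sum (O - E)^2 / E} with \eqn{(R-1)(C-1)} degrees of freedom and an
#' upper-tail p-value. For a 2x2 table with any expected cell below 5,
#' Fisher's exact p-value is computed alongside and reported in the note
#' column (the chi-squared p remains the primary value).
#'
#' @param tab Integer matrix (at least 2x2) of non-negative counts.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`, `effect`
#'   (`NA`: no single effect size for a general table), `n` (total count),
#'   `note`.
#' @export
#' @examples
#' chi_squared_independence(matrix(c(20, 5, 5, 20), 2))
chi_squared_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table cells must be non-negative integers",
         call. = FALSE)
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0)) {
    stop("zero row sum at row ", which(rs == 0)[1], call. = FALSE)
  }
  if (any(cs == 0)) {
    stop("zero column sum at column ", which(cs == 0)[1], call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  note <- NA_character_
  if (all(dim(tab) == c(2L, 2L)) && any(ct$expected < 5)) {
    pf <- stats::fisher.test(tab)$p.value
    note <- sprintf("expected cell < 5; Fisher exact p = %.4g", pf)
  }
  test_result("chi_squared", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p_value = ct$p.value,
              n = sum(tab), note = note)
}

#' Two-proportion comparison
#'
#' Compares `k1/n1` against `k2/n2` via the 2x2 chi-squared of
#' `[[k1, n1-k1], [k2, n2-k2]]` (no continuity correction, Fisher fallback
#' note as in [chi_squared_independence()]). The effect is the proportion
#' difference `k1/n1 - k2/n2`.
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @return One-row tibble as in [chi_squared_independence()], with
#'   `effect` = proportion difference.
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  res <- chi_squared_independence(matrix(c(k1, n1 - k1, k2, n2 - k2),
                                         nrow = 2, byrow = TRUE))
  res$test <- "two_proportion"
  res$effect <- k1 / n1 - k2 / n2
  res
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with midranks for ties. The exact null
#' distribution is used when the smaller group has at most `exact_max_n`
#' observations and there are no ties; otherwise the normal approximation
#' with the tie-corrected variance is used (noted in the output). The
#' statistic is the Mann-Whitney U for `values_a`; the effect is the
#' rank-biserial correlation `2U/(n_a n_b) - 1` (positive when `values_a`
#' tends larger).
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @param exact_max_n Largest min-group size for which the exact
#'   distribution is used (default 20).
#' @return One-row tibble: `test`, `statistic` (U), `df` (`NA`), `p_value`,
#'   `effect` (rank-biserial), `n` (total), `note`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
wilcoxon_rank_sum <- function(values_a, values_b, exact_max_n = 20) {
  stopifnot(length(values_a) > 0, length(values_b) > 0,
            !anyNA(values_a), !anyNA(values_b))
  n_a <- length(values_a); n_b <- length(values_b)
  combined <- c(values_a, values_b)
  u <- sum(rank(combined)[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  rb <- 2 * u / (n_a * n_b) - 1

  if (length(unique(combined)) == 1L) {
    # complete overlap with zero variance: no evidence of a shift
    return(test_result("wilcoxon_rank_sum", statistic = u, p_value = 1,
                       effect = rb, n = n_a + n_b,
                       note = "degenerate: all values identical"))
  }
  has_ties <- anyDuplicated(combined) > 0L
  use_exact <- min(n_a, n_b) <= exact_max_n && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = use_exact, correct = FALSE))
  note <- if (use_exact) "exact" else {
    if (has_ties && min(n_a, n_b) <= exact_max_n) {
      "normal approximation (ties prevent exact)"
    } else "normal approximation, tie-corrected"
  }
  test_result("wilcoxon_rank_sum", statistic = u, p_value = wt$p.value,
              effect = rb, n = n_a + n_b, note = note)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; the two-sided p-value uses
#' the t approximation with `n - 2` degrees of freedom. Pairs with a missing
#' value in either variable are dropped. For small samples an optional
#' permutation p-value (permuting `y`) can be computed alongside.
#'
#' @param x,y Paired numeric (or ordinal integer) vectors.
#' @param n_perm Number of permutations for the optional permutation
#'   p-value; 0 (default) skips it.
#' @param perm_seed Seed for the permutation draw (ignored when
#'   `n_perm = 0`).
#' @return One-row tibble: `test`, `statistic` (t), `df`, `p_value`,
#'   `effect` (rho), `n` (pairs used), `note` (permutation p, if requested).
#' @export
#' @examples
#' spearman_correlation(1:10, (1:10)^2)
spearman_correlation <- function(x, y, n_perm = 0, perm_seed = NULL) {
  keep <- !(is.na(x) | is.na(y))
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("zero variance in a rank vector: rho undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    tstat <- sign(rho) * Inf
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  note <- NA_character_
  if (n_perm > 0) {
    if (!is.null(perm_seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(perm_seed)
    }
    rho_perm <- replicate(n_perm, stats::cor(rx, sample(ry)))
    p_perm <- (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    note <- sprintf("permutation p = %.4g (%d permutations)", p_perm, n_perm)
  }
  test_result("spearman", statistic = tstat, df = n - 2, p_value = p,
              effect = rho, n = n, note = note)
}

#' Fold enrichment of a trait in a genomic region
#'
#' The effect is the ratio of the in-region trait proportion to the
#' genome-wide trait proportion. The p-value comes from the 2x2 chi-squared
#' comparing trait counts inside versus outside the region (the genome-wide
#' counts include the region).
#'
#' @param k_region,n_region Trait-positive and total genes in the region.
#' @param k_genome,n_genome Trait-positive and total genes genome-wide.
#' @return One-row tibble with `effect` = fold enrichment.
#' @export
#' @examples
#' fold_enrichment(20, 40, 100, 400)
fold_enrichment <- function(k_region, n_region, k_genome, n_genome) {
  stopifnot(n_region > 0, n_genome > 0, k_region >= 0,
            k_region <= n_region, k_genome <= n_genome,
            n_region <= n_genome, k_region <= k_genome)
  if (k_genome == 0) {
    stop("zero genome-wide trait count: fold enrichment undefined",
         call. = FALSE)
  }
  fold <- (k_region / n_region) / (k_genome / n_genome)
  out_k <- k_genome - k_region
  out_n <- n_genome - n_region
  res <- chi_squared_independence(matrix(c(k_region, n_region - k_region,
                                           out_k, out_n - out_k),
                                         nrow = 2, byrow = TRUE))
  res$test <- "fold_enrichment"
  res$effect <- fold
  res
}
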