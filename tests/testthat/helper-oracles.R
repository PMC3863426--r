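# Brute-force rule appliers, independent of the package's vectorised
# implementations. Each re-derives its answer literally from the stated
# rule, typically with explicit loops.

# Walk each focal leaf's root path and apply the dating rules one node at a
# time: accept the first duplication with score > threshold, skip score 0,
# stop UNASSIGNED on (0, threshold], SINGLETON when exhausted; accepted
# nodes older than the timeline are SINGLETON.
oracle_assign_age <- function(tree, timeline, score_threshold = 0.3) {
  focal <- tree[tree$is_leaf &
                  !is.na(tree$species) &
                  gsub("_", " ", tree$species) == timeline$focal_species, ]
  out <- list()
  for (i in seq_len(nrow(focal))) {
    status <- NA_character_
    age <- NA_integer_
    node <- focal$parent[i]
    while (!is.na(node)) {
      row <- tree[tree$node == node, ]
      if (!row$is_leaf && !is.na(row$event) && row$event == "duplication") {
        s <- row$score
        if (s > score_threshold) {
          cls <- map_taxon_to_class(row$taxon, timeline)
          if (is.na(cls)) {
            status <- "SINGLETON"
          } else {
            status <- "PDG"
            age <- cls
          }
          break
        } else if (s == 0) {
          # artifact: move on to the previous (older) node
        } else {
          status <- "UNASSIGNED"
          break
        }
      }
      node <- row$parent
    }
    if (is.na(status)) status <- "SINGLETON"
    out[[i]] <- tibble::tibble(gene_id = focal$label[i], status = status,
                               age_class = age)
  }
  dplyr::bind_rows(out)
}

# Literal re-derivation of the CNV call for one gene.
oracle_cnv_one <- function(copies, length_bp, autosomal,
                           min_gene_length = 1000, gain_threshold = 4,
                           loss_threshold = 2, min_individuals = 2,
                           autosomes_only = TRUE) {
  if (length_bp < min_gene_length) return("EXCLUDED")
  if (autosomes_only && !autosomal) return("EXCLUDED")
  n_gain <- 0L; n_loss <- 0L
  for (cn in copies) {
    if (cn >= gain_threshold) n_gain <- n_gain + 1L
    if (cn < loss_threshold) n_loss <- n_loss + 1L
  }
  if (n_gain >= min_individuals || n_loss >= min_individuals) "CNV"
  else "NON_CNV"
}

# All-pairs nearest probe (same chromosome, lower coordinate wins ties,
# strictly-beyond-max-distance genes get NA).
oracle_nearest_probe <- function(genes, probe_medians, max_distance = 10000) {
  med <- rep(NA_real_, nrow(genes))
  dist <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ctr <- floor((genes$start[i] + genes$end[i]) / 2)
    best_d <- Inf; best_pos <- Inf; best_v <- NA_real_
    for (j in seq_len(nrow(probe_medians))) {
      if (probe_medians$chrom[j] != genes$chrom[i]) next
      d <- abs(probe_medians$pos[j] - ctr)
      if (d < best_d || (d == best_d && probe_medians$pos[j] < best_pos)) {
        best_d <- d
        best_pos <- probe_medians$pos[j]
        best_v <- probe_medians$median_rank[j]
      }
    }
    if (is.finite(best_d)) {
      dist[i] <- best_d
      if (best_d <= max_distance) med[i] <- best_v
    }
  }
  list(median_probe_rank = med, nearest_probe_distance = dist)
}

# midrank transform written out longhand
oracle_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman rho via explicit rank transform + covariance formula
oracle_spearman_rho <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exact two-sided rank-sum p by enumeration of all group assignments
# (no ties). Matches the min(2 * tail, 1) convention.
oracle_wilcoxon_exact_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  sets <- utils::combn(n_a + n_b, n_a)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(2 * min(p_le, p_ge), 1)
}

# Pearson chi-squared statistic written as the O/E sum
oracle_chi2_stat <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Region classification with both distances recomputed independently
oracle_region <- function(center, len, cen_start, cen_end, window = 5e6) {
  d_cen <- if (center >= cen_start && center <= cen_end) 0 else {
    min(abs(center - cen_start), abs(center - cen_end))
  }
  d_tel <- min(center, len - center)
  if (d_cen <= window) "pericentromeric"
  else if (d_tel <= window) "subtelomeric"
  else "interstitial"
}
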