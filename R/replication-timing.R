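#' Rank replication-timing probes within one sample
#'
#' Replication-timing arrays report one early/late log-ratio per probe and
#' sample. Within a sample, probes are ranked so that rank 1 is the earliest
#' replicating probe; ties get midranks. Under the default
#' `"higher_is_earlier"` sign convention a larger log-ratio means earlier
#' replication, so ranking is on the negated values.
#'
#' @param probes Probe tibble with `chrom`, `pos` and one numeric log-ratio
#'   column per sample.
#' @param sample Name of the sample column to rank.
#' @param sign_convention `"higher_is_earlier"` (default) or
#'   `"higher_is_later"`.
#' @return Numeric vector of ranks (1 = earliest), one per probe row.
#' @export
rank_probes_within_sample <- function(probes, sample,
                                      sign_convention = c("higher_is_earlier",
                                                          "higher_is_later")) {
  sign_convention <- match.arg(sign_convention)
  if (!sample %in% names(probes)) {
    stop("sample '", sample, "' not found in probe table", call. = FALSE)
  }
  x <- probes[[sample]]
  if (anyNA(x)) {
    stop("missing log-ratio(s) in sample '", sample, "'", call. = FALSE)
  }
  if (sign_convention == "higher_is_earlier") x <- -x
  rank(x, ties.method = "average")
}

#' Median probe rank across replication-timing samples
#'
#' Combines several samples' profiles into one reference system: each sample
#' is rank-transformed with [rank_probes_within_sample()] and each probe is
#' assigned the median of its within-sample ranks (for an even number of
#' samples, the mean of the two central ranks). Because only ranks enter,
#' any per-sample monotone rescaling of the log-ratios leaves the result
#' unchanged.
#'
#' @inheritParams rank_probes_within_sample
#' @param sample_ids Columns to use as samples; defaults to every column
#'   other than `chrom` and `pos`.
#' @return Tibble `chrom`, `pos`, `median_rank` (1 = earliest).
#' @export
#' @examples
#' probes <- tibble::tibble(chrom = "1", pos = c(100, 200, 300),
#'                          s1 = c(3, 1, 2), s2 = c(2.9, 0.5, 2.2))
#' median_probe_rank(probes)
median_probe_rank <- function(probes, sample_ids = NULL,
                              sign_convention = c("higher_is_earlier",
                                                  "higher_is_later")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(all(c("chrom", "pos") %in% names(probes)))
  if (anyDuplicated(paste(probes$chrom, probes$pos))) {
    stop("duplicate (chrom, pos) probe positions", call. = FALSE)
  }
  sample_ids <- sample_ids %||% setdiff(names(probes), c("chrom", "pos"))
  if (length(sample_ids) < 1L) {
    stop("at least one sample column is required", call. = FALSE)
  }
  ranks <- vapply(sample_ids,
                  function(s) rank_probes_within_sample(probes, s,
                                                        sign_convention),
                  numeric(nrow(probes)))
  ranks <- matrix(ranks, nrow = nrow(probes))
  tibble::tibble(
    chrom = probes$chrom,
    pos = probes$pos,
    median_rank = apply(ranks, 1L, stats::median)
  )
}

#' Assign each gene a replication-timing rank from its nearest probe
#'
#' Each gene takes the median rank of the probe closest to its center
#' (`floor((start + end) / 2)` on 0-based half-open coordinates), searching
#' the same chromosome only. If two probes are equidistant the
#' lower-coordinate probe is used. A gene whose nearest probe lies strictly
#' further than `max_distance` away receives no replication-timing value
#' (a probe at exactly `max_distance` is kept). Genes with a value are then
#' sorted into the genome-wide order of replication: midranks over the
#' median probe ranks, smaller = earlier.
#'
#' @param genes Gene table with `gene_id`, `chrom`, `start`, `end`.
#' @param probe_medians Output of [median_probe_rank()].
#' @param max_distance Maximum probe-to-center distance in bp (default
#'   10000).
#' @return Tibble: `gene_id`, `median_probe_rank`, `order_of_replication`,
#'   `nearest_probe_distance`. The rank columns are `NA` for genes without a
#'   probe within reach.
#' @export
assign_gene_rt <- function(genes, probe_medians, max_distance = 10000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(c("chrom", "pos", "median_rank") %in% names(probe_medians)),
            max_distance >= 0)

  center <- floor((genes$start + genes$end) / 2)
  n <- nrow(genes)
  med <- rep(NA_real_, n)
  dist <- rep(NA_real_, n)

  by_chrom <- split(seq_len(nrow(probe_medians)), probe_medians$chrom)
  gene_groups <- split(seq_len(n), genes$chrom)
  missing_chrom <- setdiff(names(gene_groups), names(by_chrom))
  if (length(missing_chrom) > 0L) {
    message("assign_gene_rt: no probes on chromosome(s) ",
            paste(missing_chrom, collapse = ", "), "; ",
            sum(lengths(gene_groups[missing_chrom])),
            " gene(s) get no replication-timing value")
  }

  for (chr in intersect(names(gene_groups), names(by_chrom))) {
    gi <- gene_groups[[chr]]
    pi <- by_chrom[[chr]]
    ord <- order(probe_medians$pos[pi])
    pos <- probe_medians$pos[pi][ord]
    val <- probe_medians$median_rank[pi][ord]
    ctr <- center[gi]
    # nearest sorted probe; equidistant ties resolve to the lower coordinate
    right <- findInterval(ctr, pos) + 1L
    left <- right - 1L
    d_left <- ifelse(left >= 1L, abs(ctr - pos[pmax(left, 1L)]), Inf)
    d_right <- ifelse(right <= length(pos), abs(pos[pmin(right, length(pos))] - ctr),
                      Inf)
    use_left <- d_left <= d_right
    idx <- ifelse(use_left, left, right)
    d <- pmin(d_left, d_right)
    med[gi] <- val[idx]
    dist[gi] <- d
  }

  out_of_reach <- !is.na(dist) & dist > max_distance
  med[out_of_reach] <- NA_real_

  oor <- rep(NA_real_, n)
  has <- !is.na(med)
  oor[has] <- rank(med[has], ties.method = "average")

  tibble::tibble(
    gene_id = genes$gene_id,
    median_probe_rank = med,
    order_of_replication = oor,
    nearest_probe_distance = dist
  )
}
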