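#' Score distribution specification for simulated duplication nodes
#'
#' Duplication-consistency scores are drawn from a three-component mixture:
#' exactly 0 (reconstruction artifacts, skipped by the dating walk), a "low"
#' band inside `(0, 0.3]` (unclear cases), and a "high" band above the
#' acceptance threshold. Point masses are expressed by collapsing a range,
#' e.g. `high_range = c(1, 1)`.
#'
#' @param p_high,p_low,p_zero Mixture weights (must sum to 1).
#' @param high_range,low_range Uniform ranges for the high and low bands.
#' @return A list usable as `score_distribution` in [sim_config()].
#' @export
score_dist <- function(p_high = 1, p_low = 0, p_zero = 0,
                       high_range = c(0.35, 1), low_range = c(0.01, 0.3)) {
  stopifnot(abs(p_high + p_low + p_zero - 1) < 1e-9,
            p_high >= 0, p_low >= 0, p_zero >= 0,
            high_range[1] > 0.3, high_range[2] <= 1,
            low_range[1] > 0, low_range[2] <= 0.3)
  list(p_high = p_high, p_low = p_low, p_zero = p_zero,
       high_range = high_range, low_range = low_range)
}

draw_scores <- function(n, sd) {
  cat_ <- sample(c("high", "low", "zero"), n, replace = TRUE,
                 prob = c(sd$p_high, sd$p_low, sd$p_zero))
  s <- numeric(n)
  s[cat_ == "high"] <- stats::runif(sum(cat_ == "high"),
                                    sd$high_range[1], sd$high_range[2])
  s[cat_ == "low"] <- stats::runif(sum(cat_ == "low"),
                                   sd$low_range[1], sd$low_range[2])
  s
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the shape of the real inputs the pipeline was designed for: a human-like
#' timeline of 14 age classes, 159 individuals with gene copy-number
#' estimates, four replication-timing samples (embryonic stem cell lines),
#' copy-number variability concentrated in the primate-era classes
#' (~3% in singletons and pre-primate classes, rising to ~65% in the
#' youngest class), and replication timing that grows later with youth by
#' `rt_age_effect` log-ratio units per age-class step.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_genes Number of focal-species genes (one gene family each).
#' @param n_individuals Individuals in the copy-number panel (default 159).
#' @param n_rt_samples Replication-timing samples (default 4).
#' @param timeline A [phylo_timeline()] or a name for [load_timeline()].
#' @param singleton_prob Probability a gene is a singleton (default 0.28,
#'   the approximate singleton share among classifiable genes).
#' @param age_weights Relative weights over the timeline classes for
#'   duplicated genes (default uniform); normalised internally.
#' @param score_distribution A [score_dist()] for the planted (most recent
#'   true) duplication node; default point mass well above the 0.3
#'   threshold.
#' @param extra_dup_prob Probability of inserting an additional, younger
#'   duplication node between the planted node and the focal leaf (used to
#'   exercise the skip/unclear rules; default 0).
#' @param extra_score_distribution [score_dist()] for those extra nodes.
#' @param cnv_prob_by_age Probability a gene is copy-number variable, one
#'   entry per age class (oldest first) plus a final entry for singletons.
#'   Default: 0.03 for singletons and all pre-primate classes, then
#'   0.25/0.35/0.45/0.55/0.65 across the five youngest classes.
#' @param rt_age_effect Planted decrease in the latent log-ratio per
#'   age-class step toward youth (later replication; default 0.2).
#' @param rt_noise_sd Per-sample Gaussian noise on probe log-ratios
#'   (default 0.3).
#' @param rt_baseline Latent log-ratio of the oldest class (default 1.5).
#' @param probe_spacing Probe tiling interval in bp (default 6000, keeping
#'   every gene center within the 10 kb nearest-probe cutoff).
#' @param n_chromosomes,chromosome_length Autosome count and length
#'   (default 4 x 60 Mb).
#' @param centromere_position Centromere midpoint as a fraction of the
#'   chromosome length (default 0.5; 0 gives acrocentric chromosomes).
#' @param centromere_halfwidth Half-width of the centromere interval in bp.
#' @param gene_length_range Uniform range of gene lengths in bp.
#' @param p_short_gene Probability a gene is drawn short (300-900 bp, below
#'   the 1 kb copy-number filter; default 0.02).
#' @param include_sex_chromosome Add an X chromosome carrying ~5% of genes
#'   (exercises the autosome filter; default `FALSE`).
#' @param cnv_min_individuals Carriers planted for a true-CNV gene
#'   (default 2, the callable minimum).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_individuals = 159L,
                       n_rt_samples = 4L,
                       timeline = "human",
                       singleton_prob = 0.28,
                       age_weights = NULL,
                       score_distribution = score_dist(high_range = c(0.9, 1)),
                       extra_dup_prob = 0,
                       extra_score_distribution = score_distribution,
                       cnv_prob_by_age = NULL,
                       rt_age_effect = 0.2,
                       rt_noise_sd = 0.3,
                       rt_baseline = 1.5,
                       probe_spacing = 6000L,
                       n_chromosomes = 4L,
                       chromosome_length = 6e7,
                       centromere_position = 0.5,
                       centromere_halfwidth = 1.5e6,
                       gene_length_range = c(1500, 20000),
                       p_short_gene = 0.02,
                       include_sex_chromosome = FALSE,
                       cnv_min_individuals = 2L) {
  if (is.character(timeline)) timeline <- load_timeline(timeline)
  stopifnot(inherits(timeline, "phylo_timeline"))
  k <- n_age_classes(timeline)
  if (is.null(age_weights)) age_weights <- rep(1, k)
  stopifnot(length(age_weights) == k, all(age_weights >= 0),
            sum(age_weights) > 0,
            singleton_prob >= 0, singleton_prob <= 1)
  if (is.null(cnv_prob_by_age)) {
    cnv_prob_by_age <- c(rep(0.03, max(k - 5L, 0L)),
                         seq(0.25, 0.65, length.out = min(5L, k)),
                         0.03) # last entry: singletons
  }
  stopifnot(length(cnv_prob_by_age) == k + 1L,
            all(cnv_prob_by_age >= 0), all(cnv_prob_by_age <= 1),
            n_genes >= 0, n_individuals >= 1, n_rt_samples >= 1,
            probe_spacing > 0, n_chromosomes >= 1, chromosome_length > 0,
            centromere_position >= 0, centromere_position <= 1,
            rt_noise_sd >= 0, extra_dup_prob >= 0, extra_dup_prob <= 1,
            p_short_gene >= 0, p_short_gene <= 1,
            gene_length_range[1] > 0,
            gene_length_range[2] >= gene_length_range[1],
            cnv_min_individuals >= 1)
  # age distribution over (classes, singleton) is a simplex
  age_distribution <- c(age_weights / sum(age_weights) * (1 - singleton_prob),
                        singleton_prob)
  stopifnot(abs(sum(age_distribution) - 1) < 1e-9)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_individuals = as.integer(n_individuals),
         n_rt_samples = as.integer(n_rt_samples),
         timeline = timeline, age_distribution = age_distribution,
         score_distribution = score_distribution,
         extra_dup_prob = extra_dup_prob,
         extra_score_distribution = extra_score_distribution,
         cnv_prob_by_age = cnv_prob_by_age,
         rt_age_effect = rt_age_effect, rt_noise_sd = rt_noise_sd,
         rt_baseline = rt_baseline,
         probe_spacing = as.integer(probe_spacing),
         n_chromosomes = as.integer(n_chromosomes),
         chromosome_length = chromosome_length,
         centromere_position = centromere_position,
         centromere_halfwidth = centromere_halfwidth,
         gene_length_range = gene_length_range,
         p_short_gene = p_short_gene,
         include_sex_chromosome = include_sex_chromosome,
         cnv_min_individuals = as.integer(cnv_min_individuals)),
    class = "sim_config")
}

# stage-specific deterministic seed streams derived from config$seed
stage_seed <- function(config, stage) {
  offsets <- c(annotation = 101L, trees = 202L, cnv = 303L, rt = 404L)
  (config$seed %% 1000000L) * 1000L + offsets[[stage]]
}

#' Simulate gene coordinates and a chromosome map
#'
#' Genes are placed uniformly at random on the configured autosomes (plus an
#' optional X chromosome), with 0-based half-open coordinates and lengths
#' drawn from `gene_length_range` (a fraction `p_short_gene` are drawn below
#' 1 kb). The chromosome map carries lengths and centromere intervals.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (tibble `chrom`, `start`, `end`, `gene_id`,
#'   `score`, `strand`, BED6 column order) and `chrom_map` (tibble `chrom`,
#'   `length`, `cen_start`, `cen_end`).
#' @export
simulate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- as.character(seq_len(config$n_chromosomes))
  if (config$include_sex_chromosome) chroms <- c(chroms, "X")
  cen_mid <- config$centromere_position * config$chromosome_length
  cen_start <- max(0, cen_mid - config$centromere_halfwidth)
  cen_end <- min(config$chromosome_length,
                 cen_mid + config$centromere_halfwidth)
  if (cen_end <= cen_start) cen_end <- cen_start + 1
  chrom_map <- tibble::tibble(
    chrom = chroms, length = config$chromosome_length,
    cen_start = cen_start, cen_end = cen_end)

  total_len <- config$chromosome_length * length(chroms)
  if (config$n_genes * 1000 > total_len) {
    stop("capacity error: ", config$n_genes,
         " genes do not fit at minimum 1 kb spacing on ",
         total_len, " bp of sequence", call. = FALSE)
  }
  if (config$probe_spacing > config$chromosome_length) {
    stop("probe_spacing exceeds chromosome_length", call. = FALSE)
  }

  n <- config$n_genes
  if (n == 0L) {
    genes <- tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric(), gene_id = character(),
                            score = integer(), strand = character())
    return(list(genes = genes, chrom_map = chrom_map))
  }
  withr::with_seed(stage_seed(config, "annotation"), {
    probs <- rep(1, length(chroms))
    if (config$include_sex_chromosome) {
      probs[length(probs)] <- 0.05 * length(chroms)
    }
    chrom <- sample(chroms, n, replace = TRUE, prob = probs)
    short <- stats::runif(n) < config$p_short_gene
    len <- ifelse(short,
                  round(stats::runif(n, 300, 900)),
                  round(stats::runif(n, config$gene_length_range[1],
                                     config$gene_length_range[2])))
    start <- floor(stats::runif(n, 0, config$chromosome_length - len))
    genes <- tibble::tibble(
      chrom = chrom, start = start, end = start + len,
      gene_id = sprintf("gene_%05d", seq_len(n)),
      score = 0L,
      strand = sample(c("+", "-"), n, replace = TRUE))
    list(genes = genes, chrom_map = chrom_map)
  })
}

#' Simulate annotated gene-family trees with planted duplication ages
#'
#' One tree per focal gene. Each tree is a caterpillar backbone of
#' speciation nodes following the timeline oldest to youngest; for a gene
#' planted at age class `a`, a duplication node annotated with class `a`'s
#' taxon and a consistency score drawn from `score_distribution` is spliced
#' onto the focal leaf's root path below the class-`a` speciation node.
#' Singletons get no duplication node on their root path. With probability
#' `extra_dup_prob` an additional duplication node at an age class at or
#' younger than the planted one (score from `extra_score_distribution`) is
#' inserted nearer the leaf; with high-scoring extras the most recent
#' duplication wins, with zero-score extras the walk must skip to the
#' planted node. Duplication-node children include a same-species paralog
#' leaf (`par_*`), which therefore also receives an age assignment
#' downstream; paralogs are not part of the gene table or truth table.
#'
#' @param config A [sim_config()].
#' @param gene_ids Optional gene identifiers (default `gene_00001`...).
#' @return List with `trees` (a bound node table with a `family` column,
#'   consumable by [assign_duplication_age()]) and `truth` (tibble
#'   `gene_id`, `true_status`, `true_age_class`, `planted_score`,
#'   `extra_class`, `extra_score`).
#' @export
simulate_gene_trees <- function(config, gene_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tl <- config$timeline
  k <- n_age_classes(tl)
  n <- config$n_genes
  gene_ids <- gene_ids %||% sprintf("gene_%05d", seq_len(n))
  stopifnot(length(gene_ids) == n)

  withr::with_seed(stage_seed(config, "trees"), {
    draw <- sample.int(k + 1L, n, replace = TRUE,
                       prob = config$age_distribution)
    singleton <- draw == k + 1L
    age <- ifelse(singleton, NA_integer_, draw)
    p_score <- draw_scores(n, config$score_distribution)
    has_extra <- !singleton & stats::runif(n) < config$extra_dup_prob
    extra_class <- rep(NA_integer_, n)
    extra_class[has_extra] <- vapply(which(has_extra), function(i) {
      if (age[i] >= k) k else sample(age[i]:k, 1L)
    }, integer(1))
    e_score <- rep(NA_real_, n)
    e_score[has_extra] <- draw_scores(sum(has_extra),
                                      config$extra_score_distribution)

    chain_len <- ifelse(singleton, k, age)        # speciation backbone depth
    n_dup <- ifelse(singleton, 0L, 1L) + has_extra
    n_int <- chain_len + n_dup
    n_leaf <- chain_len + n_dup + 1L              # sisters + paralogs + focal
    n_nodes <- n_int + n_leaf

    # --- internal nodes, vectorised over genes ---
    g_int <- rep(seq_len(n), n_int)
    within <- sequence(n_int)                     # 1..n_int per gene
    is_chain <- within <= chain_len[g_int]
    is_primary <- !singleton[g_int] & within == chain_len[g_int] + 1L
    parent_int <- within - 1L                     # chain node k-1; 0 => root
    taxon <- character(length(within))
    taxon[is_chain] <- tl$classes[within[is_chain]]
    taxon[is_primary] <- tl$classes[age[g_int[is_primary]]]
    is_extra_node <- !is_chain & !is_primary
    taxon[is_extra_node] <- tl$classes[extra_class[g_int[is_extra_node]]]
    event <- ifelse(is_chain, "speciation", "duplication")
    score <- rep(NA_real_, length(within))
    score[is_primary] <- p_score[g_int[is_primary]]
    score[is_extra_node] <- e_score[g_int[is_extra_node]]

    internals <- tibble::tibble(
      family = gene_ids[g_int],
      node = within,
      parent = ifelse(parent_int == 0L, NA_integer_, parent_int),
      is_leaf = FALSE,
      label = "",
      species = NA_character_,
      event = event, taxon = taxon, score = score,
      branch_length = 1)

    # --- leaves ---
    # sister leaf under each speciation node; paralog under each duplication
    g_leaf <- rep(seq_len(n), n_leaf)
    wl <- sequence(n_leaf)
    attach_to <- pmin(wl, n_int[g_leaf])          # leaf j hangs off internal j
    is_focal <- wl == n_leaf[g_leaf]
    under_chain <- !is_focal & wl <= chain_len[g_leaf]
    under_dup <- !is_focal & !under_chain
    label <- character(length(wl))
    label[is_focal] <- gene_ids[g_leaf[is_focal]]
    label[under_chain] <- paste0("sis_", gene_ids[g_leaf[under_chain]], "_",
                                 wl[under_chain])
    label[under_dup] <- paste0("par_", gene_ids[g_leaf[under_dup]], "_",
                               wl[under_dup])
    species <- character(length(wl))
    species[is_focal | under_dup] <- tl$focal_species
    species[under_chain] <- paste0("sister_taxon_", wl[under_chain])

    leaves <- tibble::tibble(
      family = gene_ids[g_leaf],
      node = n_int[g_leaf] + wl,
      parent = attach_to,
      is_leaf = TRUE,
      label = label,
      species = species,
      event = NA_character_, taxon = NA_character_, score = NA_real_,
      branch_length = 1)

    trees <- dplyr::arrange(dplyr::bind_rows(internals, leaves),
                            .data$family, .data$node)
    truth <- tibble::tibble(
      gene_id = gene_ids,
      true_status = ifelse(singleton, "SINGLETON", "PDG"),
      true_age_class = as.integer(age),
      planted_score = ifelse(singleton, NA_real_, p_score),
      extra_class = as.integer(extra_class),
      extra_score = e_score)
    list(trees = trees, truth = truth)
  })
}

#' Export simulated trees as NHX text
#'
#' @param trees Bound node table from [simulate_gene_trees()].
#' @return Named character vector, one NHX string per family.
#' @export
trees_to_nhx <- function(trees) {
  fams <- split(trees[setdiff(names(trees), "family")], trees$family)
  vapply(fams, function(tr) write_gene_tree(new_gene_tree(tr)), character(1))
}

#' Simulate a gene x individual copy-number matrix
#'
#' Each gene is drawn copy-number variable with the probability its true age
#' class specifies (`cnv_prob_by_age`; the last entry applies to
#' singletons). A true-CNV gene gets `cnv_min_individuals` or a few more
#' carriers set to gains (4-6 copies) or losses (0-1), direction 50/50;
#' everyone else sits at the diploid baseline (2, occasionally 3). A
#' non-CNV gene has all individuals in {2, 3}, except that with small
#' probability one single individual is aberrant -- exercising, without
#' crossing, the two-carrier calling rule.
#'
#' @param genes Gene table from [simulate_genome_annotation()].
#' @param truth Truth table from [simulate_gene_trees()].
#' @param config A [sim_config()].
#' @return List with `copies` (tibble: `gene_id` + one integer column per
#'   individual) and `truth` (input truth with a `true_cnv` column added).
#' @export
simulate_copy_number_matrix <- function(genes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_individuals < 2L) {
    stop("n_individuals must be at least 2 to plant a callable CNV",
         call. = FALSE)
  }
  k <- n_age_classes(config$timeline)
  n <- nrow(truth)
  withr::with_seed(stage_seed(config, "cnv"), {
    cls <- ifelse(is.na(truth$true_age_class), k + 1L, truth$true_age_class)
    p <- config$cnv_prob_by_age[cls]
    true_cnv <- stats::runif(n) < p

    m <- config$n_individuals
    cn <- matrix(2L, nrow = n, ncol = m)
    cn[stats::runif(n * m) < 0.1] <- 3L

    for (i in which(true_cnv)) {
      extra <- stats::rbinom(1L, size = min(3L, m - config$cnv_min_individuals),
                             prob = 0.3)
      carriers <- sample.int(m, config$cnv_min_individuals + extra)
      if (stats::runif(1) < 0.5) {
        cn[i, carriers] <- sample(4:6, length(carriers), replace = TRUE)
      } else {
        cn[i, carriers] <- sample(0:1, length(carriers), replace = TRUE)
      }
    }
    aberrant <- which(!true_cnv & stats::runif(n) < 0.05)
    for (i in aberrant) {
      cn[i, sample.int(m, 1L)] <- sample(c(1L, 4L), 1L)
    }

    copies <- tibble::as_tibble(as.data.frame(cn))
    names(copies) <- sprintf("ind_%03d", seq_len(m))
    copies <- dplyr::bind_cols(tibble::tibble(gene_id = truth$gene_id),
                               copies)
    list(copies = copies,
         truth = dplyr::mutate(truth, true_cnv = true_cnv))
  })
}

#' Simulate replication-timing probe tracks
#'
#' Probes tile every chromosome at `probe_spacing`. Each probe's latent
#' log-ratio is `rt_baseline - rt_age_effect * (a - 1)` where `a` is the age
#' class of the nearest gene by center (singletons and gene-free stretches
#' behave as the oldest class, `a = 1`): younger genes replicate later,
#' which under the `higher_is_earlier` convention means a lower log-ratio.
#' Each sample observes the latent value plus independent Gaussian noise.
#'
#' @param genes,truth,chrom_map Outputs of the upstream generators.
#' @param config A [sim_config()].
#' @return List with `probes` (tibble `chrom`, `pos`, `sample_1`...) and
#'   `truth` (input truth with `true_rt_latent` added).
#' @export
simulate_rt_probes <- function(genes, truth, chrom_map, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$probe_spacing > min(chrom_map$length)) {
    stop("probe_spacing exceeds chromosome length", call. = FALSE)
  }
  k <- n_age_classes(config$timeline)
  withr::with_seed(stage_seed(config, "rt"), {
    probe_list <- lapply(seq_len(nrow(chrom_map)), function(ci) {
      tibble::tibble(
        chrom = chrom_map$chrom[ci],
        pos = seq(floor(config$probe_spacing / 2), chrom_map$length[ci] - 1,
                  by = config$probe_spacing))
    })
    probes <- dplyr::bind_rows(probe_list)

    age_idx <- ifelse(is.na(truth$true_age_class), 1L, truth$true_age_class)
    gene_latent <- config$rt_baseline -
      config$rt_age_effect * (age_idx - 1L)

    latent <- rep(config$rt_baseline, nrow(probes))
    if (nrow(genes) > 0L) {
      center <- floor((genes$start + genes$end) / 2)
      for (chr in unique(probes$chrom)) {
        pi <- which(probes$chrom == chr)
        gi <- which(genes$chrom == chr)
        if (length(gi) == 0L) next
        ord <- order(center[gi])
        ctr <- center[gi][ord]
        lat <- gene_latent[match(genes$gene_id[gi][ord], truth$gene_id)]
        pp <- probes$pos[pi]
        right <- findInterval(pp, ctr) + 1L
        left <- right - 1L
        d_left <- ifelse(left >= 1L, abs(pp - ctr[pmax(left, 1L)]), Inf)
        d_right <- ifelse(right <= length(ctr),
                          abs(ctr[pmin(right, length(ctr))] - pp), Inf)
        idx <- ifelse(d_left <= d_right, left, right)
        latent[pi] <- lat[idx]
      }
    }
    for (s in seq_len(config$n_rt_samples)) {
      probes[[sprintf("sample_%d", s)]] <-
        latent + stats::rnorm(nrow(probes), sd = config$rt_noise_sd)
    }
    list(probes = probes,
         truth = dplyr::mutate(truth, true_rt_latent = gene_latent))
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs all four generators in order and returns every pipeline input plus
#' the complete truth table. Deterministic: the same config (including seed)
#' reproduces every table exactly.
#'
#' @param config A [sim_config()].
#' @return List of class `duplirep_sim`: `genes`, `chrom_map`, `trees`,
#'   `copies`, `probes`, `truth`, `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 7, n_genes = 50))
#' names(sim)
simulate_dataset <- function(config) {
  ann <- simulate_genome_annotation(config)
  tr <- simulate_gene_trees(config, gene_ids = ann$genes$gene_id)
  cn <- simulate_copy_number_matrix(ann$genes, tr$truth, config)
  rt <- simulate_rt_probes(ann$genes, cn$truth, ann$chrom_map, config)
  structure(
    list(genes = ann$genes, chrom_map = ann$chrom_map, trees = tr$trees,
         copies = cn$copies, probes = rt$probes, truth = rt$truth,
         config = config),
    class = "duplirep_sim")
}

#' @export
print.duplirep_sim <- function(x, ...) {
  cat("<duplirep_sim> ", nrow(x$truth), " genes, ",
      length(unique(x$trees$family)), " trees, ",
      ncol(x$copies) - 1L, " individuals, ",
      sum(startsWith(names(x$probes), "sample_")), " RT samples, ",
      nrow(x$chrom_map), " chromosomes\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the on-disk dialects the pipeline reads: one NHX file per family
#' under `trees/`, genes as BED6, copy numbers / probes / chromosome map /
#' truth as TSV.
#'
#' @param sim A `duplirep_sim` from [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "duplirep_sim"))
  dir.create(file.path(outdir, "trees"), recursive = TRUE,
             showWarnings = FALSE)
  nhx <- trees_to_nhx(sim$trees)
  for (fam in names(nhx)) {
    writeLines(nhx[[fam]], file.path(outdir, "trees",
                                     paste0("family_", fam, ".nhx")))
  }
  readr::write_tsv(sim$genes, file.path(outdir, "genes.bed"),
                   col_names = FALSE)
  readr::write_tsv(sim$copies, file.path(outdir, "copy_number.tsv"))
  readr::write_tsv(sim$probes, file.path(outdir, "rt_probes.tsv"))
  readr::write_tsv(sim$chrom_map, file.path(outdir, "chrom_map.tsv"))
  readr::write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}

#' Read pipeline inputs written by [write_simulation()]
#'
#' @param dir Directory holding `trees/`, `genes.bed`, `copy_number.tsv`,
#'   `rt_probes.tsv`, `chrom_map.tsv`.
#' @return List with `genes`, `chrom_map`, `trees`, `copies`, `probes`.
#' @export
read_pipeline_inputs <- function(dir) {
  genes <- readr::read_tsv(
    file.path(dir, "genes.bed"),
    col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
    col_types = "cddcic", progress = FALSE)
  trees <- bind_gene_trees(read_tree_dir(file.path(dir, "trees")))
  trees$family <- sub("^family_", "", trees$family)
  list(
    genes = genes,
    chrom_map = readr::read_tsv(file.path(dir, "chrom_map.tsv"),
                                col_types = "cddd", progress = FALSE),
    trees = trees,
    copies = readr::read_tsv(file.path(dir, "copy_number.tsv"),
                             col_types = readr::cols(
                               gene_id = readr::col_character(),
                               .default = readr::col_integer()),
                             progress = FALSE),
    probes = readr::read_tsv(file.path(dir, "rt_probes.tsv"),
                             col_types = readr::cols(
                               chrom = readr::col_character(),
                               .default = readr::col_double()),
                             progress = FALSE))
}
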