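test_that("genome annotation honours its contracts", {
  # empty case
  ann0 <- simulate_genome_annotation(sim_config(seed = 1, n_genes = 0))
  expect_equal(nrow(ann0$genes), 0L)
  expect_equal(nrow(ann0$chrom_map), 4L)
  # forced centromere placement
  ann <- simulate_genome_annotation(
    sim_config(seed = 1, n_genes = 10, n_chromosomes = 1,
               chromosome_length = 1e7, centromere_position = 0.5,
               centromere_halfwidth = 1e6))
  expect_equal((ann$chrom_map$cen_start + ann$chrom_map$cen_end) / 2, 5e6)
  # determinism
  a1 <- simulate_genome_annotation(sim_config(seed = 4, n_genes = 100))
  a2 <- simulate_genome_annotation(sim_config(seed = 4, n_genes = 100))
  expect_identical(a1, a2)
  # capacity error
  expect_error(
    simulate_genome_annotation(
      sim_config(seed = 1, n_genes = 200000, n_chromosomes = 1,
                 chromosome_length = 1e7)),
    "capacity")
  # coordinates valid and 0-based half-open
  expect_true(all(a1$genes$start >= 0))
  expect_true(all(a1$genes$end > a1$genes$start))
  expect_true(all(a1$genes$end <= 6e7))
  # sex chromosome only when asked
  expect_false("X" %in% a1$genes$chrom)
  ax <- simulate_genome_annotation(
    sim_config(seed = 4, n_genes = 400, include_sex_chromosome = TRUE))
  expect_true("X" %in% ax$chrom_map$chrom)
})

test_that("tree simulation plants ages exactly where stated", {
  hs <- load_timeline("human")
  # all mass on singletons: no duplication nodes on focal root paths
  cfg <- sim_config(seed = 3, n_genes = 50, singleton_prob = 1)
  out <- simulate_gene_trees(cfg)
  expect_true(all(out$truth$true_status == "SINGLETON"))
  expect_false(any(out$trees$event %in% "duplication"))
  a <- assign_duplication_age(out$trees, hs)
  a <- a[a$gene_id %in% out$truth$gene_id, ]
  expect_true(all(a$status == "SINGLETON"))

  # point mass at score 1: downstream assignment recovers every truth age
  cfg <- sim_config(seed = 13, n_genes = 800,
                    score_distribution = score_dist(high_range = c(1, 1)))
  out <- simulate_gene_trees(cfg)
  a <- assign_duplication_age(out$trees, hs)
  cmp <- dplyr::inner_join(out$truth, a, by = "gene_id")
  expect_equal(nrow(cmp), 800L)
  expect_identical(cmp$status, cmp$true_status)
  expect_equal(cmp$age_class[cmp$status == "PDG"],
               cmp$true_age_class[cmp$status == "PDG"])

  # a zero-score young duplication in front of a high-scoring older one:
  # the walk must skip to the older node
  cfg <- sim_config(seed = 7, n_genes = 600, singleton_prob = 0,
                    score_distribution = score_dist(high_range = c(1, 1)),
                    extra_dup_prob = 1,
                    extra_score_distribution = score_dist(0, 0, 1))
  out <- simulate_gene_trees(cfg)
  expect_true(all(out$truth$extra_score == 0))
  a <- assign_duplication_age(out$trees, hs)
  cmp <- dplyr::inner_join(out$truth, a, by = "gene_id")
  expect_true(all(cmp$status == "PDG"))
  expect_equal(cmp$age_class, cmp$true_age_class)

  # determinism
  t1 <- simulate_gene_trees(sim_config(seed = 5, n_genes = 60))
  t2 <- simulate_gene_trees(sim_config(seed = 5, n_genes = 60))
  expect_identical(t1, t2)
  expect_identical(trees_to_nhx(t1$trees), trees_to_nhx(t2$trees))
})

test_that("copy-number simulation plants callable CNVs and clean non-CNVs", {
  cfg <- sim_config(seed = 37, n_genes = 1200, p_short_gene = 0)
  ann <- simulate_genome_annotation(cfg)
  truth0 <- simulate_gene_trees(cfg)$truth
  cn <- simulate_copy_number_matrix(ann$genes, truth0, cfg)
  m <- as.matrix(cn$copies[-1])
  expect_equal(ncol(m), 159L)
  # planted CNV genes always have >= 2 carriers; non-CNV at most 1 aberrant
  n_gain <- rowSums(m >= 4); n_loss <- rowSums(m < 2)
  callable <- n_gain >= 2 | n_loss >= 2
  expect_identical(unname(callable), cn$truth$true_cnv)
  outside <- rowSums(matrix(!(m %in% 2:3), nrow = nrow(m)))
  expect_true(all(outside[!cn$truth$true_cnv] <= 1))
  # all-zero probabilities: nothing is planted, nothing is called
  cfg0 <- sim_config(seed = 37, n_genes = 300,
                     cnv_prob_by_age = rep(0, 15), p_short_gene = 0)
  sim0 <- simulate_dataset(cfg0)
  expect_false(any(sim0$truth$true_cnv))
  calls0 <- call_cnv_genes(sim0$copies, sim0$genes)
  expect_false(any(calls0$status == "CNV"))
  # determinism and the 2-individual floor
  c1 <- simulate_copy_number_matrix(ann$genes, truth0, cfg)
  expect_identical(c1, cn)
  cfg_bad <- sim_config(seed = 1, n_genes = 10, n_individuals = 1)
  expect_error(simulate_copy_number_matrix(ann$genes, truth0, cfg_bad),
               "at least 2")
})

test_that("CNV fractions recover the planted step function under calling", {
  k <- 14
  cfg <- sim_config(seed = 41, n_genes = 5000, p_short_gene = 0,
                    cnv_prob_by_age = c(rep(0, k - 1), 1, 0))
  sim <- simulate_dataset(cfg)
  calls <- call_cnv_genes(sim$copies, sim$genes)
  j <- dplyr::inner_join(calls, sim$truth, by = "gene_id")
  j <- j[j$status != "EXCLUDED", ]
  expect_identical(j$status == "CNV", j$true_cnv)
  frac <- tapply(j$status == "CNV",
                 ifelse(is.na(j$true_age_class), 0L, j$true_age_class), mean)
  expect_equal(unname(frac[as.character(k)]), 1)
  expect_true(all(frac[names(frac) != as.character(k)] == 0))
})

test_that("CNV marginal rates converge to the configured probabilities", {
  cfg <- sim_config(seed = 43, n_genes = 6000, p_short_gene = 0)
  sim <- simulate_dataset(cfg)
  j <- dplyr::mutate(sim$truth,
                     cls = ifelse(is.na(.data$true_age_class), 15L,
                                  .data$true_age_class))
  emp <- tapply(j$true_cnv, j$cls, mean)
  n_cls <- tapply(j$true_cnv, j$cls, length)
  p <- sim$config$cnv_prob_by_age[as.integer(names(emp))]
  # within 4 binomial standard errors of the plant, every class
  se <- sqrt(p * (1 - p) / n_cls)
  expect_true(all(abs(emp - p) <= 4 * pmax(se, 1e-3)))
})

test_that("probe tracks have the declared shape and planted gradient", {
  cfg <- sim_config(seed = 47, n_genes = 200, n_rt_samples = 4)
  sim <- simulate_dataset(cfg)
  expect_equal(sum(startsWith(names(sim$probes), "sample_")), 4L)
  # tiling at probe_spacing on every chromosome
  for (chr in unique(sim$probes$chrom)) {
    pos <- sim$probes$pos[sim$probes$chrom == chr]
    expect_equal(unique(diff(pos)), cfg$probe_spacing)
  }
  expect_error(
    simulate_rt_probes(sim$genes, sim$truth, sim$chrom_map,
                       sim_config(seed = 1, probe_spacing = 1e9)),
    "probe_spacing exceeds")
  # zero effect, zero noise: a totally flat landscape
  cfg0 <- sim_config(seed = 47, n_genes = 100, rt_age_effect = 0,
                     rt_noise_sd = 0)
  sim0 <- simulate_dataset(cfg0)
  expect_equal(length(unique(sim0$probes$sample_1)), 1L)
  # latent values recorded per gene follow the planted linear age effect
  lat <- sim$truth$true_rt_latent
  age <- ifelse(is.na(sim$truth$true_age_class), 1L, sim$truth$true_age_class)
  expect_equal(lat, cfg$rt_baseline - cfg$rt_age_effect * (age - 1))
})

test_that("the complete dataset generator is deterministic end to end", {
  s1 <- simulate_dataset(sim_config(seed = 53, n_genes = 150,
                                    extra_dup_prob = 0.3,
                                    score_distribution =
                                      score_dist(0.6, 0.2, 0.2)))
  s2 <- simulate_dataset(sim_config(seed = 53, n_genes = 150,
                                    extra_dup_prob = 0.3,
                                    score_distribution =
                                      score_dist(0.6, 0.2, 0.2)))
  for (nm in c("genes", "chrom_map", "trees", "copies", "probes", "truth")) {
    expect_identical(s1[[nm]], s2[[nm]])
  }
  s3 <- simulate_dataset(sim_config(seed = 54, n_genes = 150))
  expect_false(identical(s1$copies, s3$copies))
})

test_that("on-disk round trip preserves every table", {
  sim <- simulate_dataset(sim_config(seed = 59, n_genes = 40))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "trees",
                                    "family_gene_00001.nhx")))
  back <- read_pipeline_inputs(dir)
  expect_equal(as.data.frame(back$genes), as.data.frame(sim$genes))
  expect_equal(as.data.frame(back$chrom_map), as.data.frame(sim$chrom_map))
  expect_equal(as.data.frame(back$copies), as.data.frame(sim$copies),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(back$probes), as.data.frame(sim$probes),
               tolerance = 1e-12)
  # the reread trees assign identically to the in-memory ones
  hs <- load_timeline("human")
  expect_equal(assign_duplication_age(back$trees, hs),
               assign_duplication_age(sim$trees, hs))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(singleton_prob = 1.2))
  expect_error(sim_config(cnv_prob_by_age = rep(0.5, 3)))
  expect_error(sim_config(probe_spacing = 0))
  expect_error(sim_config(n_chromosomes = 0))
  expect_error(score_dist(0.5, 0.2, 0.2)) # weights must sum to 1
  cfg <- sim_config()
  expect_equal(sum(cfg$age_distribution), 1, tolerance = 1e-12)
  expect_true(all(cfg$age_distribution >= 0))
})
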