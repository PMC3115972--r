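# Synthetic study generator: determinism, manifest bookkeeping, planted
# variant statistics, read simulation, truth oracle.

test_that("genome and gene generation is byte-deterministic for a fixed seed", {
  cfg <- simulation_config(seed = 1)
  a <- simulate_genome_and_genes(cfg)
  b <- simulate_genome_and_genes(cfg)
  fa <- tempfile(fileext = ".fa"); fb <- tempfile(fileext = ".fa")
  write_genome_fasta(a$genome, fa); write_genome_fasta(b$genome, fb)
  expect_identical(readLines(fa), readLines(fb))
  ga <- tempfile(fileext = ".tsv"); gb <- tempfile(fileext = ".tsv")
  write_gene_models(a$genes, ga); write_gene_models(b$genes, gb)
  expect_identical(readLines(ga), readLines(gb))
})

test_that("a small configuration yields valid gene models", {
  cfg <- simulation_config(seed = 2, n_chroms = 1, chrom_length = 50000,
                           n_genes = 5)
  gg <- simulate_genome_and_genes(cfg)
  expect_length(gg$genes, 5)
  clens <- chrom_lengths(gg$genome)
  for (g in gg$genes) {
    expect_silent(validate_gene_model(g, chrom_len = clens[[g$chrom]]))
    expect_true(g$cds_frame_ok)
    expect_equal(cds_length(g) %% 3, 0)
  }
  # exon totals agree with the manifest
  expect_equal(vapply(gg$genes, function(g)
    as.integer(sum(g$exons$end - g$exons$start)), 0L),
    gg$manifest$exon_bases)
  # too many genes for the chromosome is an error
  expect_error(simulate_genome_and_genes(
    simulation_config(seed = 2, n_chroms = 1, chrom_length = 20000,
                      n_genes = 50)),
    "too large")
})

test_that("variant planting matches densities, recurrence and degenerate settings", {
  sim <- default_sim()
  cfg0 <- sim$config
  # density 0 -> empty truth set
  cfg_zero <- simulation_config(seed = 3, coding_density = 0,
                                noncoding_density = 0, systematic_sites = 0)
  gg <- simulate_genome_and_genes(cfg_zero)
  design <- build_target_design(gg$genes, chrom_lengths(gg$genome))
  t0 <- plant_variants(cfg_zero, gg$genome, design, gg$genes)
  expect_equal(nrow(t0$planted), 0)

  # recurrence 0 -> every allele confined to a single sample
  cfg_r0 <- simulation_config(seed = 7, recurrence_prob = 0)
  gg7 <- simulate_genome_and_genes(cfg_r0)
  d7 <- build_target_design(gg7$genes, chrom_lengths(gg7$genome))
  t7 <- plant_variants(cfg_r0, gg7$genome, d7, gg7$genes)
  k <- variant_key(t7$planted$chrom, t7$planted$pos, t7$planted$ref,
                   t7$planted$alt)
  per_allele <- tapply(t7$planted$sample_id, k, function(s) length(unique(s)))
  expect_true(all(per_allele == 1))

  # planted count within 4 sigma of density * bases * samples (binomial)
  n_bases <- d7$total_bases
  p_mix <- (cfg_r0$coding_density * d7$coding_bases +
              cfg_r0$noncoding_density * (n_bases - d7$coding_bases)) / n_bases
  expected <- p_mix * n_bases * cfg_r0$n_samples
  sigma <- sqrt(n_bases * cfg_r0$n_samples * p_mix * (1 - p_mix))
  expect_lt(abs(nrow(t7$planted) - expected), 4 * sigma)

  # planted and systematic key sets are disjoint
  sk <- position_key(sim$truth$systematic$chrom, sim$truth$systematic$pos)
  pk <- position_key(sim$truth$planted$chrom, sim$truth$planted$pos)
  expect_length(intersect(sk, pk), 0)
  # planted variants are germline and heterozygous by construction
  expect_true(all(sim$truth$planted$germline))
})

test_that("read simulation respects the manifest and the coverage profile", {
  sim <- default_sim()
  cfg <- sim$config
  # zero coverage -> zero reads
  cfg0 <- simulation_config(seed = 4, sample_coverage = rep(0, 10))
  gg <- simulate_genome_and_genes(cfg0)
  d <- build_target_design(gg$genes, chrom_lengths(gg$genome))
  t0 <- plant_variants(cfg0, gg$genome, d, gg$genes)
  rr0 <- simulate_reads(cfg0, gg$genome, d, t0)
  expect_equal(nrow(rr0$reads), 0)
  expect_error(simulate_reads(
    simulation_config(seed = 4, read_length = 0), gg$genome, d, t0),
    "read_length")

  # emitted per-sample counts equal the manifest exactly
  counts <- table(sim$reads$mid)
  expect_equal(unname(as.integer(counts[sim$read_manifest$sample_id])),
               sim$read_manifest$n_reads)

  # pooled pileup depth at 100 random target positions within 4 sigma of
  # the configured total coverage (binomial over reads)
  run <- default_run()
  pool <- stats::aggregate(depth ~ chrom + pos, run$pileup, sum)
  set.seed(12)
  idx <- sample(nrow(pool), 100)
  total_cov <- sum(cfg$sample_coverage)
  n_reads_on <- sum(sim$read_manifest$n_on_target)
  p_cover <- total_cov / n_reads_on
  sigma <- sqrt(n_reads_on * p_cover * (1 - p_cover))
  for (i in idx) {
    expect_lt(abs(pool$depth[i] - total_cov), 4 * sigma)
  }
})

test_that("the truth oracle verifies planted keys and rejects artifacts", {
  sim <- default_sim()
  oracle <- sim$oracle
  pk <- variant_key(sim$truth$planted$chrom, sim$truth$planted$pos,
                    sim$truth$planted$ref, sim$truth$planted$alt)
  sk <- variant_key(sim$truth$systematic$chrom, sim$truth$systematic$pos,
                    sim$truth$systematic$ref, sim$truth$systematic$alt)
  expect_true(all(oracle(pk) == "verified"))
  expect_true(all(oracle(sk) == "false_positive"))
  expect_equal(oracle("chrX:1:A:C"), "false_positive")
})

test_that("the near-dropout sample yields far fewer calls than the median sample", {
  # larger target than the shared fixture so the per-sample call counts give
  # the ratio statistical resolution (~40 planted variants per sample)
  cfg <- simulation_config(seed = 904, n_chroms = 3, chrom_length = 100000,
                           n_genes = 36)
  sim <- simulate_study(cfg)
  run <- run_pipeline(sim$reads, sim$genome, sim$genes, sim$design,
                      sim$catalog, sim$oracle, mids = cfg$sample_ids)
  dropout <- cfg$sample_ids[which.min(cfg$sample_coverage)]
  per_sample <- table(factor(run$calls$sample_id, levels = cfg$sample_ids))
  expect_lt(per_sample[[dropout]],
            0.25 * stats::median(per_sample[names(per_sample) != dropout]))
})

test_that("a written study directory round-trips through the file readers", {
  sim <- default_sim()
  dir <- file.path(tempdir(), "study")
  write_study(sim, dir)
  expect_identical(read_genome_fasta(file.path(dir, "genome.fa")), sim$genome)
  models <- read_gene_models(file.path(dir, "genes.tsv"))
  expect_equal(length(models), length(sim$genes))
  reads <- read_reads_tsv(file.path(dir, "reads.tsv"))
  expect_equal(nrow(reads), nrow(sim$reads))
  cat_back <- read_catalog(file.path(dir, "catalog.tsv"))
  expect_equal(cat_back, sim$catalog, ignore_attr = TRUE)
  bed <- read_bed(file.path(dir, "targets.bed"))
  expect_equal(bed, sim$design$regions, ignore_attr = TRUE)
})
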