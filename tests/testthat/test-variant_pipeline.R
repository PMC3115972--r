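# Demultiplexing, pileup construction, SNV calling, annotation, novelty,
# recurrence and verification.

mk_reads <- function(mid, chrom, start, seqs) {
  data.frame(read_id = sprintf("%s_r%03d", mid, seq_along(seqs)), mid = mid,
             chrom = chrom, start = start, sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("demultiplexing assigns every read exactly once", {
  reads <- rbind(mk_reads("MID1", "chr1", 0, rep("ACGT", 3)),
                 mk_reads("MID2", "chr1", 0, rep("ACGT", 2)),
                 mk_reads("MIDX", "chr1", 0, "ACGT"))
  dm <- demultiplex(reads, c("MID1", "MID2"))
  expect_equal(vapply(dm$samples, nrow, 0L), c(MID1 = 3L, MID2 = 2L))
  expect_equal(nrow(dm$unassigned), 1)
  expect_equal(sum(vapply(dm$samples, nrow, 0L)) + nrow(dm$unassigned),
               nrow(reads))
  expect_error(demultiplex(reads, c("MID1", "MID1")), "duplicate barcode")
})

test_that("demultiplexed counts match the generator manifest exactly", {
  sim <- default_sim()
  dm <- demultiplex(sim$reads, sim$config$sample_ids)
  expect_equal(unname(vapply(dm$samples, nrow, 0L)[sim$read_manifest$sample_id]),
               sim$read_manifest$n_reads)
  expect_equal(nrow(dm$unassigned), 0)
})

test_that("FASTA reads round-trip with barcode prefixes recovered", {
  sim <- default_sim()
  sub <- sim$reads[1:50, ]
  f <- tempfile(fileext = ".fa")
  write_reads_fasta(sub, f)
  back <- read_reads_fasta(f)
  rownames(sub) <- NULL
  expect_equal(back, sub)
})

test_that("pileup covers read footprints intersected with the target", {
  genome <- c(chr1 = strrep("A", 100))
  design <- data.frame(chrom = "chr1", start = 12L, end = 60L)
  reads <- mk_reads("MID1", "chr1", 10L, "CCCCC")  # covers 10..14
  pu <- build_pileup(list(MID1 = reads), genome, design)
  expect_equal(pu$pos, 12:14)                      # clipped to the target
  expect_equal(pu$depth, rep(1L, 3))
  expect_equal(pu$C, rep(1L, 3))
  expect_equal(nrow(build_pileup(list(MID1 = reads[0, ]), genome, design)), 0)
  # read past the chromosome end is truncated with a warning
  long <- mk_reads("MID1", "chr1", 98L, "GGGGG")
  expect_warning(pu2 <- build_pileup(list(MID1 = long), genome,
                                     data.frame(chrom = "chr1", start = 0L,
                                                end = 100L)),
                 "truncated")
  expect_equal(pu2$pos, 98:99)
})

test_that("pileup equals the independent per-base tally on 2,000 synthetic reads", {
  sim <- default_sim()
  set.seed(3)
  sub <- sim$reads[sample(nrow(sim$reads), 2000), ]
  dm <- demultiplex(sub, sim$config$sample_ids)
  pu <- build_pileup(dm$samples, sim$genome, sim$design)
  oracle <- bf_pileup(sub, sim$design$regions)
  # every pileup count matches the oracle tally, and vice versa
  for (b in c("A", "C", "G", "T")) {
    keys <- paste(pu$sample_id, pu$chrom, pu$pos, b, sep = "|")
    cnt <- vapply(keys, function(k) oracle[[k]] %||% 0L, 0L, USE.NAMES = FALSE)
    expect_equal(pu[[b]], cnt)
  }
  expect_equal(sum(pu$depth), sum(unlist(as.list(oracle))))
  expect_equal(pu$depth, pu$A + pu$C + pu$G + pu$T)
})

test_that("the allele-fraction threshold is strict and depth-gated", {
  genome <- c(chr1 = strrep("A", 50))
  pu <- data.frame(sample_id = "MID1", chrom = "chr1", pos = c(10L, 11L, 12L),
                   A = c(8L, 7L, 3L), C = c(2L, 3L, 1L), G = 0L, T = 0L,
                   depth = c(10L, 10L, 4L), stringsAsFactors = FALSE)
  calls <- call_snvs(pu, genome, min_fraction = 0.20, min_depth = 5)
  # 2/10 = 0.20 is not above the threshold; 3/10 is; depth 4 is too shallow
  expect_equal(calls$pos, 11L)
  expect_equal(calls$alt_fraction, 0.3)
  expect_equal(calls$alt, "C")
  # reference N positions are skipped
  genomeN <- c(chr1 = paste0(strrep("A", 11), "N", strrep("A", 38)))
  expect_message(cn <- call_snvs(pu, genomeN, 0.20, 5), "reference base N")
  expect_equal(nrow(cn), 0)
})

test_that("multi-allelic positions emit one call per alternative allele", {
  genome <- c(chr1 = strrep("A", 20))
  pu <- data.frame(sample_id = "s", chrom = "chr1", pos = 5L, A = 2L, C = 4L,
                   G = 4L, T = 0L, depth = 10L, stringsAsFactors = FALSE)
  calls <- call_snvs(pu, genome)
  expect_equal(sort(calls$alt), c("C", "G"))
})

test_that("calls match the brute-force rule on the full synthetic pileup", {
  run <- default_run()
  sim <- default_sim()
  bf <- bf_calls(run$pileup, sim$genome)
  got <- run$calls[, c("sample_id", "chrom", "pos", "ref", "alt")]
  rownames(got) <- rownames(bf) <- NULL
  expect_equal(got, bf)
  # conservation: every call's depth and count re-derivable from the pileup
  pk <- paste(run$pileup$sample_id, run$pileup$chrom, run$pileup$pos)
  i <- match(paste(run$calls$sample_id, run$calls$chrom, run$calls$pos), pk)
  expect_equal(run$calls$depth, run$pileup$depth[i])
  for (b in c("A", "C", "G", "T")) {
    j <- run$calls$alt == b
    expect_equal(run$calls$alt_count[j], run$pileup[[b]][i][j])
  }
})

test_that("raising min_fraction or min_depth never adds calls", {
  run <- default_run()
  sim <- default_sim()
  base_keys <- with(run$calls, paste(sample_id, chrom, pos, alt))
  for (mf in c(0.25, 0.35)) {
    k <- with(call_snvs(run$pileup, sim$genome, mf, 5),
              paste(sample_id, chrom, pos, alt))
    expect_true(all(k %in% base_keys))
  }
  k <- with(call_snvs(run$pileup, sim$genome, 0.20, 12),
            paste(sample_id, chrom, pos, alt))
  expect_true(all(k %in% base_keys))
})

test_that("coding-effect annotation translates codons strand-aware", {
  # plus-strand gene with a known codon layout: ATG GCT CTG ...
  genome <- c(chr1 = paste0(strrep("T", 10), "ATGGCTCTG", strrep("T", 11)))
  g <- gene_model("g", "chr1", "+", 10, 19,
                  exons = data.frame(start = 10, end = 19),
                  cds_start = 10, cds_end = 19)
  ann <- annotate_variants(
    data.frame(chrom = "chr1", pos = c(12L, 18L), ref = c("G", "G"),
               alt = c("A", "A"), stringsAsFactors = FALSE),
    list(g), genome)
  # ATG -> ATA is M -> I (non-synonymous); CTG -> CTA stays L (synonymous)
  expect_equal(ann$effect, c("non_synonymous", "synonymous"))
  expect_equal(ann$ref_aa, c("M", "L"))
  expect_equal(ann$alt_aa, c("I", "L"))

  # same codons read from the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGGCTCTG")))
  genome2 <- c(chr1 = paste0(strrep("T", 10), rc, strrep("T", 11)))
  g2 <- gene_model("g2", "chr1", "-", 10, 19,
                   exons = data.frame(start = 10, end = 19),
                   cds_start = 10, cds_end = 19)
  # genomic position of the third base of codon 0 (ATG) is pos 16; G->A on
  # the coding strand is C->T on the reference
  ann2 <- annotate_variants(
    data.frame(chrom = "chr1", pos = 16L, ref = "C", alt = "T",
               stringsAsFactors = FALSE),
    list(g2), genome2)
  expect_equal(ann2$effect, "non_synonymous")
  expect_equal(c(ann2$ref_aa, ann2$alt_aa), c("M", "I"))

  # intronic variant: non-coding effect
  g3 <- toy_gene_two_exon("+")
  genome3 <- toy_genome(c(chr1 = 3000))
  ann3 <- annotate_variants(
    data.frame(chrom = "chr1", pos = 1400L, ref = "A", alt = "G"),
    list(g3), genome3)
  expect_equal(ann3$region_class, "INTRON")
  expect_equal(ann3$effect, "non_coding")
})

test_that("single-codon effects agree with the full-protein translation oracle", {
  sim <- default_sim()
  set.seed(21)
  genes <- Filter(function(g) isTRUE(g$cds_frame_ok), sim$genes)
  checked <- 0
  for (g in genes[1:4]) {
    seg <- cds_segments(g)
    cds_pos <- unlist(Map(seq, seg$start, seg$end - 1))
    for (p in sample(cds_pos, 30)) {
      ref <- substr(sim$genome[[g$chrom]], p + 1, p + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      ann <- annotate_variants(
        data.frame(chrom = g$chrom, pos = p, ref = ref, alt = alt),
        list(g), sim$genome)
      expect_equal(ann$effect, bf_effect(g, sim$genome, p, alt),
                   info = sprintf("%s:%d %s>%s", g$chrom, p, ref, alt))
      checked <- checked + 1
    }
  }
  expect_equal(checked, 120)
})

test_that("annotation is deterministic and independent of variant order", {
  run <- default_run()
  sim <- default_sim()
  uv <- unique_variants(run$calls)
  set.seed(4)
  perm <- uv[sample(nrow(uv)), ]
  a1 <- annotate_variants(uv, sim$genes, sim$genome)
  a2 <- annotate_variants(perm, sim$genes, sim$genome)
  a2 <- a2[order(a2$chrom, a2$pos, a2$alt), ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1[order(a1$chrom, a1$pos, a1$alt), ], a2, ignore_attr = TRUE)
})

test_that("novelty flags are the complement of the catalog", {
  v <- data.frame(chrom = "chr1", pos = c(5L, 9L), ref = "A", alt = c("C", "G"))
  cat1 <- data.frame(chrom = "chr1", pos = 5L, ref = "A", alt = "C")
  expect_equal(flag_novelty(v, cat1)$novel, c(FALSE, TRUE))
  empty_cat <- cat1[0, ]
  expect_true(all(flag_novelty(v, empty_cat)$novel))
  # position-only matching ignores the allele
  cat2 <- data.frame(chrom = "chr1", pos = 9L, ref = "A", alt = "T")
  expect_equal(flag_novelty(v, cat2, match_on = "position")$novel,
               c(TRUE, FALSE))
  # catalog reference mismatching the genome warns but keeps the entry
  genome <- c(chr1 = strrep("G", 20))
  expect_warning(out <- flag_novelty(v, cat1, genome = genome),
                 "reference mismatch")
  expect_equal(out$novel, c(FALSE, TRUE))
})

test_that("novel set on the synthetic run is the catalog complement of the manifest", {
  run <- default_run()
  sim <- default_sim()
  called_keys <- variant_key(run$variants$chrom, run$variants$pos,
                             run$variants$ref, run$variants$alt)
  cat_keys <- variant_key(sim$catalog$chrom, sim$catalog$pos,
                          sim$catalog$ref, sim$catalog$alt)
  expect_equal(run$variants$novel, !(called_keys %in% cat_keys))
})

test_that("recurrence counts distinct samples per allele", {
  calls <- data.frame(sample_id = c("s1", "s4", "s4", "s2"), chrom = "chr1",
                      pos = c(10L, 10L, 10L, 20L), ref = "A",
                      alt = c("G", "G", "G", "C"), stringsAsFactors = FALSE)
  rec <- compute_recurrence(calls)
  expect_equal(rec$n_samples[rec$pos == 10], 2L)
  expect_equal(rec$n_samples[rec$pos == 20], 1L)

  run <- default_run()
  # brute-force group-by on the full synthetic call set
  key <- variant_key(run$calls$chrom, run$calls$pos, run$calls$ref,
                     run$calls$alt)
  bf <- tapply(run$calls$sample_id, key, function(s) length(unique(s)))
  vkey <- variant_key(run$variants$chrom, run$variants$pos, run$variants$ref,
                      run$variants$alt)
  expect_equal(run$variants$n_samples, unname(as.integer(bf[vkey])))
})

test_that("verification is total and errors on an incomplete oracle", {
  cands <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "C")
  oracle <- function(keys) ifelse(grepl(":1:", keys), "verified",
                                  "false_positive")
  out <- verify_candidates(cands, oracle)
  expect_equal(out$verification, c("verified", "false_positive"))
  broken <- function(keys) rep(NA_character_, length(keys))
  expect_error(verify_candidates(cands, broken), "not total")
})

test_that("planted heterozygous variants at depth >= 20 are recovered with high sensitivity", {
  # direct binomial construction: 200 planted het positions, depth 30,
  # per-base error 1%
  set.seed(71)
  L <- 200L
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2 * L, TRUE),
                           collapse = ""))
  pos <- seq(0L, 2L * L - 1L, by = 2L)
  ref <- vapply(pos, function(p) substr(genome, p + 1, p + 1), "")
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  depth <- 30L
  rows <- lapply(seq_along(pos), function(i) {
    alt_n <- rbinom(1, depth, 0.5)
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    counts[ref[i]] <- depth - alt_n
    counts[alt[i]] <- counts[alt[i]] + alt_n
    # sprinkle 1% errors
    err <- rbinom(1, depth, 0.01)
    if (err > 0) {
      from <- sample(c(ref[i], alt[i]), 1)
      if (counts[from] >= err) {
        counts[from] <- counts[from] - err
        to <- sample(setdiff(names(counts), from), 1)
        counts[to] <- counts[to] + err
      }
    }
    data.frame(sample_id = "s", chrom = "chr1", pos = pos[i],
               A = counts["A"], C = counts["C"], G = counts["G"],
               T = counts["T"], depth = depth, stringsAsFactors = FALSE)
  })
  pu <- do.call(rbind, rows)
  calls <- call_snvs(pu, genome)
  hit <- variant_key("chr1", pos, ref, alt) %in%
    variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  expect_gte(mean(hit), 0.99)
})

test_that("calls export to a well-formed minimal VCF", {
  run <- default_run()
  sim <- default_sim()
  f <- tempfile(fileext = ".vcf")
  write_snv_vcf(run$calls, sim$genome, f, sample_ids = sim$config$sample_ids)
  lines <- readLines(f)
  expect_true(lines[1] == "##fileformat=VCFv4.2")
  body <- lines[!grepl("^#", lines)]
  expect_equal(length(body), nrow(unique_variants(run$calls)))
  fields <- strsplit(body[1], "\t")[[1]]
  expect_length(fields, 9 + sim$config$n_samples)
  # POS is 1-based
  expect_equal(as.integer(fields[2]),
               unique_variants(run$calls)$pos[1] + 1L)
  # catalog VCF reader inverts the conversion
  cat_back <- read_catalog(f)
  uv <- unique_variants(run$calls)
  expect_equal(cat_back[, c("chrom", "pos", "ref", "alt")], uv,
               ignore_attr = TRUE)
})
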