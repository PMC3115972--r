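# Brute-force oracles and shared fixtures. Every oracle here recomputes the
# quantity under test by explicit per-base / per-element enumeration,
# independently of the package's interval- and vector-arithmetic code paths.

# ---- fixtures ---------------------------------------------------------------

# deterministic toy genome of given chromosome lengths
toy_genome <- function(lens, seed = 42) {
  set.seed(seed)
  stats::setNames(
    vapply(lens, function(L) paste(sample(c("A", "C", "G", "T"), L,
                                          replace = TRUE), collapse = ""), ""),
    names(lens))
}

# single-exon plus-strand gene used across files (CDS length 699)
toy_gene_plus <- function() {
  gene_model("gplus", "chr1", "+", tx_start = 2000, tx_end = 3200,
             exons = data.frame(start = 2000, end = 3200),
             cds_start = 2301, cds_end = 3000)
}

# two-exon gene, either strand (CDS segments 200 + 298 = 498 bases)
toy_gene_two_exon <- function(strand = "+") {
  gene_model("g2", "chr1", strand, tx_start = 1000, tx_end = 2000,
             exons = data.frame(start = c(1000, 1600), end = c(1300, 2000)),
             cds_start = 1100, cds_end = 1898)
}

# ---- per-base classification oracle ----------------------------------------

# explicit base sets per class, built from first principles
bf_class_sets <- function(gene, chrom_len, promoter_len = 1000) {
  exonic <- unlist(Map(seq, gene$exons$start, gene$exons$end - 1))
  tx <- seq(gene$tx_start, gene$tx_end - 1)
  cds <- intersect(exonic, seq(gene$cds_start, gene$cds_end - 1))
  left <- exonic[exonic < gene$cds_start]
  right <- exonic[exonic >= gene$cds_end]
  if (gene$strand == "+") {
    utr5 <- left; utr3 <- right
    prom <- seq(gene$tx_start - promoter_len, gene$tx_start - 1)
  } else {
    utr5 <- right; utr3 <- left
    prom <- seq(gene$tx_end, gene$tx_end + promoter_len - 1)
  }
  prom <- prom[prom >= 0 & prom < chrom_len]
  intron <- setdiff(tx, exonic)
  all <- seq(0, chrom_len - 1)
  list(CDS = cds, UTR5 = utr5, UTR3 = utr3, PROMOTER = prom, INTRON = intron,
       INTERGENIC = setdiff(all, c(cds, utr5, utr3, prom, intron)))
}

# ---- interval oracles -------------------------------------------------------

# base-set union membership over a window
bf_union_membership <- function(regions, chrom, window_end) {
  covered <- logical(window_end)
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    idx <- seq(r$start[i] + 1, r$end[i])
    covered[idx] <- TRUE
  }
  covered
}

# ---- pileup / calling oracles ----------------------------------------------

# per-base tally over reads, by explicit iteration
bf_pileup <- function(reads_df, regions) {
  tally <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reads_df))) {
    ch <- reads_df$chrom[i]; s <- reads_df$start[i]
    bases <- strsplit(reads_df$sequence[i], "")[[1]]
    for (j in seq_along(bases)) {
      p <- s + j - 1
      in_target <- any(regions$chrom == ch & regions$start <= p & p < regions$end)
      if (!in_target || !(bases[j] %in% c("A", "C", "G", "T"))) next
      k <- paste(reads_df$mid[i], ch, p, bases[j], sep = "|")
      tally[[k]] <- (tally[[k]] %||% 0L) + 1L
    }
  }
  tally
}
`%||%` <- function(a, b) if (is.null(a)) b else a

bf_calls <- function(pileup, genome, min_fraction = 0.2, min_depth = 5) {
  out <- list()
  for (i in seq_len(nrow(pileup))) {
    row <- pileup[i, ]
    ref <- substr(genome[[row$chrom]], row$pos + 1, row$pos + 1)
    if (ref == "N") next
    for (b in c("A", "C", "G", "T")) {
      if (b == ref) next
      cnt <- row[[b]]
      if (row$depth >= min_depth && cnt / row$depth > min_fraction) {
        out[[length(out) + 1]] <- data.frame(
          sample_id = row$sample_id, chrom = row$chrom, pos = row$pos,
          ref = ref, alt = b, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  df <- do.call(rbind, out)
  df[order(df$sample_id, df$chrom, df$pos, df$alt), , drop = FALSE]
}

# full-protein translation oracle: mutate the genome, translate the whole
# CDS with Biostrings, compare proteins
bf_effect <- function(gene, genome, pos, alt) {
  chrom <- genome[[gene$chrom]]
  mutated <- chrom
  substr(mutated, pos + 1, pos + 1) <- alt
  g2 <- genome
  g2[[gene$chrom]] <- mutated
  tr <- function(gn) {
    as.character(Biostrings::translate(Biostrings::DNAString(spliced_cds(gene, gn)),
                                       if.fuzzy.codon = "X"))
  }
  if (tr(genome) == tr(g2)) "synonymous" else "non_synonymous"
}

# ---- staining selection oracle ---------------------------------------------

bf_select <- function(records, level_required_normal, min_tumor, tumor_set,
                      normal_mode = "all") {
  hits <- character()
  for (p in unique(records$protein_id)) {
    r <- records[records$protein_id == p, ]
    nl <- r$level[r$tissue == "normal_glandular"]
    tl <- r$level[r$tissue == "tumor"]
    if (length(nl) == 0) next
    ok_n <- if (normal_mode == "all") all(nl == level_required_normal)
            else any(nl == level_required_normal)
    if (ok_n && sum(tl %in% tumor_set) >= min_tumor) hits <- c(hits, p)
  }
  sort(hits)
}

# random staining table with no structural guarantees
random_staining_table <- function(n_proteins, seed) {
  set.seed(seed)
  lv <- c("none", "weak", "moderate", "strong")
  do.call(rbind, lapply(sprintf("P%03d", seq_len(n_proteins)), function(p) {
    nn <- sample(1:4, 1); nt <- sample(4:10, 1)
    rbind(
      data.frame(protein_id = p, tissue = "normal_glandular",
                 patient_id = paste0("n", seq_len(nn)),
                 level = sample(lv, nn, replace = TRUE, prob = c(.5, .2, .2, .1)),
                 stringsAsFactors = FALSE),
      data.frame(protein_id = p, tissue = "tumor",
                 patient_id = paste0("t", seq_len(nt)),
                 level = sample(lv, nt, replace = TRUE, prob = c(.2, .2, .2, .4)),
                 stringsAsFactors = FALSE))
  }))
}

# ---- shared default simulation (computed once per test run) -----------------

.sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_study(simulation_config(seed = 104729))
  }
  .sim_cache$sim
}

default_run <- function() {
  if (is.null(.sim_cache$run)) {
    s <- default_sim()
    .sim_cache$run <- run_pipeline(s$reads, s$genome, s$genes, s$design,
                                   s$catalog, s$oracle,
                                   mids = s$config$sample_ids)
  }
  .sim_cache$run
}
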