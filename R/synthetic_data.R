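# Synthetic study generator: genome, gene models, staining table, planted
# germline heterozygous variants, known-variant catalog, barcoded reads with
# random and systematic sequencing error, and a manifest/truth oracle.
#
# The defaults emulate a ten-sample multiplexed capture experiment: the
# per-sample coverage vector reproduces an uneven pool with one near-dropout
# library (~3x, a failed amplification) and one underloaded library (~7x),
# planted heterozygous variant densities are 0.05% of coding and 0.07% of
# non-coding target bases per sample, and a small number of systematic-error
# sites emit a non-reference allele above the calling threshold so that
# verification encounters genuine false positives.
#
# Determinism: one integer seed drives everything. Each stage seeds its own
# stream at a fixed offset from config$seed (genome +0, staining +1,
# variants +2, reads +3, catalog +4) so stages are individually reproducible.

#' Simulation configuration
#'
#' @param seed integer seed for all randomness.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of genes (spread round-robin over chromosomes).
#' @param n_samples number of barcoded libraries (default 10, labelled
#'   `MID1`..`MIDn`).
#' @param sample_coverage per-sample target mean coverage; the default
#'   ten-sample vector includes a near-dropout library at 3x and an
#'   underloaded one at 7x.
#' @param read_length read length in bases.
#' @param per_base_error uniform substitution error rate per sequenced base
#'   (default 0.1%).
#' @param coding_density,noncoding_density germline heterozygous variant
#'   density per target base per sample (defaults 0.05% coding, 0.07%
#'   non-coding).
#' @param recurrence_prob probability that a drawn variant reuses an allele
#'   already planted in another sample instead of a fresh position.
#' @param systematic_sites number of systematic-error sites; each emits a
#'   non-synonymous coding alternative allele at `systematic_fraction` of
#'   the reads in its affected samples, i.e. above the 20% calling
#'   threshold.
#' @param systematic_fraction alternative-allele fraction at systematic
#'   sites (default 0.35).
#' @param catalog_fraction fraction of planted alleles present in the
#'   known-variant catalog (default 0.77, so roughly a quarter of real
#'   variants are novel).
#' @param catalog_background extra catalog entries at non-variant positions.
#' @param off_target_fraction fraction of reads drawn from outside the
#'   capture target (default 0.77; they exercise demultiplexing and are
#'   dropped at pileup time).
#' @param promoter_len,min_region_len design parameters passed through to
#'   [build_target_design()].
#' @return a validated `simulation_config` object.
#' @export
simulation_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 60000L,
                              n_genes = 12L, n_samples = 10L,
                              sample_coverage = c(33, 28, 3, 21, 28, 17, 18,
                                                  35, 7, 38),
                              read_length = 200L, per_base_error = 0.001,
                              coding_density = 5e-4, noncoding_density = 7e-4,
                              recurrence_prob = 0.1, systematic_sites = 6L,
                              systematic_fraction = 0.35,
                              catalog_fraction = 0.77,
                              catalog_background = 50L,
                              off_target_fraction = 0.77,
                              promoter_len = 1000L, min_region_len = 250L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              sample_coverage = sample_coverage,
              read_length = as.integer(read_length),
              per_base_error = per_base_error,
              coding_density = coding_density,
              noncoding_density = noncoding_density,
              recurrence_prob = recurrence_prob,
              systematic_sites = as.integer(systematic_sites),
              systematic_fraction = systematic_fraction,
              catalog_fraction = catalog_fraction,
              catalog_background = as.integer(catalog_background),
              off_target_fraction = off_target_fraction,
              promoter_len = as.integer(promoter_len),
              min_region_len = as.integer(min_region_len))
  rates <- c(cfg$per_base_error, cfg$coding_density, cfg$noncoding_density,
             cfg$recurrence_prob, cfg$systematic_fraction,
             cfg$catalog_fraction, cfg$off_target_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]", call. = FALSE)
  if (cfg$n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (length(cfg$sample_coverage) != cfg$n_samples) {
    stop("sample_coverage must have one entry per sample", call. = FALSE)
  }
  if (any(cfg$sample_coverage < 0)) stop("coverage must be >= 0", call. = FALSE)
  if (cfg$read_length < 1L) stop("read_length must be >= 1", call. = FALSE)
  cfg$sample_ids <- paste0("MID", seq_len(cfg$n_samples))
  structure(cfg, class = "simulation_config")
}

#' Simulate a reference genome and gene models
#'
#' Chromosomes are uniform random sequence; genes are laid out left to right
#' with room for promoter windows and read overhangs, each with 2-4 exons,
#' random strand, and translation bounds adjusted so the CDS length is
#' divisible by 3.
#'
#' @param config a [simulation_config()].
#' @return list with `genome`, `genes` and a per-gene `manifest` data.frame
#'   (`gene_id`, `n_exons`, `exon_bases`, `cds_bases`).
#' @export
simulate_genome_and_genes <- function(config) {
  set.seed(config$seed)
  genome <- stats::setNames(
    vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(DNA_BASES, config$chrom_length, replace = TRUE),
            collapse = "")
    }, ""),
    paste0("chr", seq_len(config$n_chroms)))

  chrom_of <- rep(names(genome), length.out = config$n_genes)
  cursor <- stats::setNames(rep(config$promoter_len + 200L, config$n_chroms),
                            names(genome))
  tail_margin <- config$promoter_len + config$read_length + 300L
  genes <- vector("list", config$n_genes)
  for (k in seq_len(config$n_genes)) {
    ch <- chrom_of[k]
    n_ex <- sample(2:4, 1)
    ex_len <- sample(120:300, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(200:600, n_ex - 1L, replace = TRUE) else integer()
    start <- cursor[[ch]]
    ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len
    tx_start <- ex_start[1L]; tx_end <- ex_end[n_ex]
    if (tx_end > config$chrom_length - tail_margin) {
      stop("n_genes too large for chrom_length", call. = FALSE)
    }
    cds_start <- ex_start[1L] + sample(30:80, 1)
    cds_end <- ex_end[n_ex] - sample(30:80, 1)
    g <- suppressWarnings(
      gene_model(sprintf("gene%02d", k), ch, sample(c("+", "-"), 1),
                 tx_start, tx_end,
                 data.frame(start = ex_start, end = ex_end),
                 cds_start, cds_end, check_frame = FALSE))
    # trim cds_end down to restore frame
    extra <- cds_length(g) %% 3L
    if (extra != 0L) {
      g <- suppressWarnings(
        gene_model(g$gene_id, ch, g$strand, tx_start, tx_end, g$exons,
                   cds_start, cds_end - extra, check_frame = TRUE))
    }
    genes[[k]] <- g
    cursor[[ch]] <- tx_end + sample(1400:2000, 1)
  }
  manifest <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    n_exons = vapply(genes, function(g) nrow(g$exons), 0L),
    exon_bases = vapply(genes, function(g)
      as.integer(sum(g$exons$end - g$exons$start)), 0L),
    cds_bases = vapply(genes, cds_length, 0L),
    stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, manifest = manifest)
}

#' Simulate a differential-staining table
#'
#' Builds a staining table in which exactly `n_selected` proteins satisfy
#' the up-in-tumor criteria (no staining in any normal-tissue record, at
#' least five tumor patients with strong staining); all other proteins are
#' constructed to fail one of the two conditions.
#'
#' @param config a [simulation_config()].
#' @param n_proteins total proteins in the table.
#' @param n_selected number that must satisfy the criteria (default 41).
#' @param n_normal,n_tumor patients profiled per protein in each tissue.
#' @return list with `records` (staining data.frame) and `selected_ids`.
#' @export
simulate_staining_table <- function(config, n_proteins = 200L,
                                    n_selected = 41L, n_normal = 3L,
                                    n_tumor = 10L) {
  set.seed(config$seed + 1L)
  if (n_selected > n_proteins) stop("n_selected > n_proteins", call. = FALSE)
  ids <- sprintf("PROT%04d", seq_len(n_proteins))
  selected <- sort(sample(ids, n_selected))
  rows <- lapply(ids, function(p) {
    sel <- p %in% selected
    if (sel) {
      nl <- rep("none", n_normal)
      n_strong <- sample(5:n_tumor, 1)
      tl <- sample(c(rep("strong", n_strong),
                     sample(STAINING_LEVELS[1:3], n_tumor - n_strong,
                            replace = TRUE)))
    } else if (stats::runif(1) < 0.7) {
      # fails the normal-tissue condition
      nl <- sample(STAINING_LEVELS, n_normal, replace = TRUE)
      nl[sample(n_normal, 1)] <- sample(STAINING_LEVELS[-1], 1)
      tl <- sample(STAINING_LEVELS, n_tumor, replace = TRUE)
    } else {
      # clean normal tissue but too few strongly stained tumors
      nl <- rep("none", n_normal)
      n_strong <- sample(0:4, 1)
      tl <- sample(c(rep("strong", n_strong),
                     sample(STAINING_LEVELS[1:3], n_tumor - n_strong,
                            replace = TRUE)))
    }
    rbind(data.frame(protein_id = p, tissue = "normal_glandular",
                     patient_id = sprintf("N%02d", seq_len(n_normal)),
                     level = nl, stringsAsFactors = FALSE),
          data.frame(protein_id = p, tissue = "tumor",
                     patient_id = sprintf("T%02d", seq_len(n_tumor)),
                     level = tl, stringsAsFactors = FALSE))
  })
  records <- do.call(rbind, rows)
  records$validation_score <- sample(1:3, nrow(records), replace = TRUE)
  list(records = records, selected_ids = selected)
}

# Per-base class of every target position (precedence rule), as a
# data.frame (chrom, pos, class). Internal.
target_position_classes <- function(design, genes, promoter_len) {
  pos <- region_positions(design$regions)
  cls <- character(nrow(pos))
  for (ch in unique(pos$chrom)) {
    i <- pos$chrom == ch
    cls[i] <- classify_in_genes(genes, ch, pos$pos[i], promoter_len)$class
  }
  pos$class <- cls
  pos
}

#' Plant germline heterozygous variants and systematic-error sites
#'
#' Per sample, variant positions are drawn from the coding and non-coding
#' target bases at the configured densities; each variant is heterozygous
#' (expected read fraction 0.5) and flagged germline. With probability
#' `recurrence_prob` a draw reuses an allele already planted in another
#' sample, producing recurrent variants. Systematic-error sites are drawn
#' from coding target positions disjoint from all planted variants, with an
#' alternative allele chosen to be non-synonymous where possible, affecting
#' 1-3 random samples each.
#'
#' @param config a [simulation_config()].
#' @param genome named character vector of chromosome sequences.
#' @param design a `target_design`.
#' @param genes list of `gene_model`s.
#' @return a `truth_set`: list with `planted` (chrom, pos, ref, alt,
#'   sample_id, germline), `systematic` (chrom, pos, ref, alt, sample_id,
#'   alt_fraction) and `positions` (the classified target positions).
#' @export
plant_variants <- function(config, genome, design, genes) {
  set.seed(config$seed + 2L)
  pos <- target_position_classes(design, genes, config$promoter_len)
  coding <- pos[pos$class == "CDS", , drop = FALSE]
  noncod <- pos[pos$class != "CDS", , drop = FALSE]

  draw_positions <- function(tbl, density) {
    k <- stats::rbinom(1L, nrow(tbl), density)
    if (k == 0L) return(tbl[0L, , drop = FALSE])
    tbl[sample(nrow(tbl), k), , drop = FALSE]
  }
  pool <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), stringsAsFactors = FALSE)
  planted <- list()
  for (sid in config$sample_ids) {
    drawn <- rbind(draw_positions(coding, config$coding_density),
                   draw_positions(noncod, config$noncoding_density))
    if (nrow(drawn) == 0L && nrow(pool) == 0L) next
    n <- nrow(drawn)
    recur <- if (n > 0L) stats::runif(n) < config$recurrence_prob else logical()
    fresh <- drawn[!recur, , drop = FALSE]
    if (nrow(fresh) > 0L) {
      fresh$ref <- mapply(function(ch, p) genome_base(genome, ch, p),
                          fresh$chrom, fresh$pos, USE.NAMES = FALSE)
      fresh$alt <- vapply(fresh$ref, function(r)
        sample(setdiff(DNA_BASES, r), 1), "", USE.NAMES = FALSE)
      fresh <- fresh[, c("chrom", "pos", "ref", "alt")]
    } else {
      fresh <- pool[0L, , drop = FALSE]
    }
    reused <- if (any(recur) && nrow(pool) > 0L) {
      pool[sample(nrow(pool), min(sum(recur), nrow(pool))), , drop = FALSE]
    } else {
      pool[0L, , drop = FALSE]
    }
    vars <- rbind(fresh, reused)
    vars <- vars[!duplicated(position_key(vars$chrom, vars$pos)), , drop = FALSE]
    if (nrow(vars) == 0L) next
    pool <- rbind(pool, fresh)
    pool <- pool[!duplicated(variant_key(pool$chrom, pool$pos, pool$ref,
                                         pool$alt)), , drop = FALSE]
    vars$sample_id <- sid
    planted[[sid]] <- vars
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), sample_id = character(),
               stringsAsFactors = FALSE)
  planted$germline <- rep(TRUE, nrow(planted))
  rownames(planted) <- NULL

  # systematic-error sites: coding positions disjoint from planted variants
  sys <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), sample_id = character(),
                    alt_fraction = numeric(), stringsAsFactors = FALSE)
  if (config$systematic_sites > 0L) {
    avail <- coding[!(position_key(coding$chrom, coding$pos) %in%
                        position_key(planted$chrom, planted$pos)), , drop = FALSE]
    if (nrow(avail) < config$systematic_sites) {
      stop("not enough coding target positions for systematic-error sites",
           call. = FALSE)
    }
    sites <- avail[sample(nrow(avail), config$systematic_sites), , drop = FALSE]
    gene_by_id <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      ch <- sites$chrom[i]; p <- sites$pos[i]
      ref <- genome_base(genome, ch, p)
      alts <- setdiff(DNA_BASES, ref)
      ann <- annotate_variants(
        data.frame(chrom = ch, pos = p, ref = ref, alt = alts,
                   stringsAsFactors = FALSE),
        genes, genome, config$promoter_len)
      ns <- alts[!is.na(ann$effect) & ann$effect == "non_synonymous"]
      alt <- if (length(ns)) sample(ns, 1) else sample(alts, 1)
      aff <- sample(config$sample_ids, sample(1:3, 1))
      data.frame(chrom = ch, pos = p, ref = ref, alt = alt, sample_id = aff,
                 alt_fraction = config$systematic_fraction,
                 stringsAsFactors = FALSE)
    })
    sys <- do.call(rbind, rows)
    rownames(sys) <- NULL
  }
  structure(list(planted = planted, systematic = sys, positions = pos),
            class = "truth_set")
}

#' Simulate barcoded reads over the capture target
#'
#' Per sample, read starts are drawn uniformly from the target regions
#' expanded by one read length upstream (so coverage is uniform across the
#' target); the read count is set so the expected target coverage matches
#' the configured per-sample coverage. Planted heterozygous alleles are
#' emitted at read fraction 0.5 (binomial per covering read), systematic
#' sites at their boosted fraction in affected samples, and uniform
#' substitution errors at the per-base rate. Off-target reads are drawn from
#' the complement of the expanded target at the configured fraction.
#'
#' @param config a [simulation_config()].
#' @param genome named character vector of chromosome sequences.
#' @param design a `target_design`.
#' @param truth a `truth_set` from [plant_variants()].
#' @return list with `reads` (read data.frame, shuffled) and `manifest`
#'   (per-sample data.frame: `sample_id`, `n_reads`, `n_on_target`,
#'   `n_off_target`, `n_planted`).
#' @export
simulate_reads <- function(config, genome, design, truth) {
  set.seed(config$seed + 3L)
  L <- config$read_length
  clens <- chrom_lengths(genome)
  exp_regions <- design$regions
  exp_regions$start <- pmax(exp_regions$start - (L - 1L), 0L)
  exp_regions <- fuse_overlaps(exp_regions, merge_adjacent = TRUE)
  exp_pos <- region_positions(exp_regions)
  E <- nrow(exp_pos)

  # complement of the expanded target, for off-target reads; keep a read
  # length clear of chromosome ends
  comp <- do.call(rbind, lapply(names(genome), function(ch) {
    r <- exp_regions[exp_regions$chrom == ch, , drop = FALSE]
    ir <- IRanges::setdiff(IRanges::IRanges(1L, clens[[ch]] - L),
                           IRanges::IRanges(r$start + 1L, r$end))
    if (length(ir) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }))
  comp_pos <- if (is.null(comp)) exp_pos[0L, ] else region_positions(comp)

  all_reads <- vector("list", config$n_samples)
  manifest <- data.frame(sample_id = config$sample_ids, n_reads = 0L,
                         n_on_target = 0L, n_off_target = 0L, n_planted = 0L,
                         stringsAsFactors = FALSE)
  for (si in seq_along(config$sample_ids)) {
    sid <- config$sample_ids[si]
    n_on <- round(config$sample_coverage[si] * E / L)
    if (n_on == 0L) next
    pick <- sample(E, n_on, replace = TRUE)
    ch <- exp_pos$chrom[pick]
    start <- exp_pos$pos[pick]
    end <- pmin(start + L, clens[ch])
    seqs <- substring(genome[ch], start + 1L, end)

    apply_allele <- function(variants, frac) {
      for (i in seq_len(nrow(variants))) {
        v <- variants[i, ]
        cover <- which(ch == v$chrom & start <= v$pos & v$pos < start + nchar(seqs))
        if (length(cover) == 0L) next
        flip <- cover[stats::runif(length(cover)) < frac]
        off <- v$pos - start[flip] + 1L
        substr(seqs[flip], off, off) <<- rep(v$alt, length(flip))
      }
    }
    pl <- truth$planted[truth$planted$sample_id == sid, , drop = FALSE]
    apply_allele(pl, 0.5)
    sy <- truth$systematic[truth$systematic$sample_id == sid, , drop = FALSE]
    if (nrow(sy)) {
      for (i in seq_len(nrow(sy))) {
        apply_allele(sy[i, , drop = FALSE], sy$alt_fraction[i])
      }
    }
    # uniform substitution errors
    if (config$per_base_error > 0) {
      lens <- nchar(seqs)
      n_err <- stats::rbinom(1L, sum(lens), config$per_base_error)
      if (n_err > 0L) {
        ridx <- sample(n_on, n_err, replace = TRUE, prob = lens)
        off <- floor(stats::runif(n_err) * lens[ridx]) + 1L
        for (k in seq_len(n_err)) {
          old <- substr(seqs[ridx[k]], off[k], off[k])
          substr(seqs[ridx[k]], off[k], off[k]) <-
            sample(setdiff(DNA_BASES, old), 1)
        }
      }
    }

    n_off <- if (config$off_target_fraction > 0 && nrow(comp_pos) > 0L) {
      round(n_on * config$off_target_fraction / (1 - config$off_target_fraction))
    } else 0L
    if (n_off > 0L) {
      pick2 <- sample(nrow(comp_pos), n_off, replace = TRUE)
      ch2 <- comp_pos$chrom[pick2]
      start2 <- comp_pos$pos[pick2]
      seqs2 <- substring(genome[ch2], start2 + 1L,
                         pmin(start2 + L, clens[ch2]))
      ch <- c(ch, ch2); start <- c(start, start2); seqs <- c(seqs, seqs2)
    }
    n_tot <- n_on + n_off
    all_reads[[si]] <- data.frame(
      read_id = sprintf("%s_r%06d", sid, seq_len(n_tot)),
      mid = sid, chrom = ch, start = start, sequence = seqs,
      stringsAsFactors = FALSE)
    manifest$n_reads[si] <- n_tot
    manifest$n_on_target[si] <- n_on
    manifest$n_off_target[si] <- n_off
    manifest$n_planted[si] <- nrow(pl)
  }
  reads <- do.call(rbind, all_reads[!vapply(all_reads, is.null, logical(1))])
  if (is.null(reads)) {
    reads <- data.frame(read_id = character(), mid = character(),
                        chrom = character(), start = integer(),
                        sequence = character(), stringsAsFactors = FALSE)
  } else {
    reads <- reads[sample(nrow(reads)), , drop = FALSE]
    rownames(reads) <- NULL
  }
  list(reads = reads, manifest = manifest)
}

#' Verification oracle from a truth set
#'
#' Models orthogonal bidirectional (Sanger-style) re-sequencing of candidate
#' variants as a total oracle: a candidate allele is `verified` exactly when
#' it is a planted germline variant, and `false_positive` otherwise
#' (systematic-error artifacts and anything else).
#'
#' @param truth a `truth_set`.
#' @return function mapping a character vector of variant keys to
#'   `"verified"` / `"false_positive"`.
#' @export
sanger_oracle <- function(truth) {
  planted_keys <- unique(variant_key(truth$planted$chrom, truth$planted$pos,
                                     truth$planted$ref, truth$planted$alt))
  function(keys) {
    ifelse(keys %in% planted_keys, "verified", "false_positive")
  }
}

#' Simulate a complete study
#'
#' Runs every generator in order under the single seed stream: genome and
#' genes, staining table, capture design over all genes, planted variants
#' and systematic sites, barcoded reads, and a known-variant catalog
#' covering `catalog_fraction` of the planted alleles plus background
#' entries (never a systematic site).
#'
#' @param config a [simulation_config()].
#' @return list with `config`, `genome`, `genes`, `gene_manifest`,
#'   `staining`, `design`, `truth`, `reads`, `read_manifest`, `catalog`,
#'   `oracle`.
#' @export
simulate_study <- function(config = simulation_config()) {
  gg <- simulate_genome_and_genes(config)
  st <- simulate_staining_table(config)
  design <- build_target_design(gg$genes, chrom_lengths(gg$genome),
                                promoter_len = config$promoter_len,
                                min_len = config$min_region_len)
  truth <- plant_variants(config, gg$genome, design, gg$genes)
  rr <- simulate_reads(config, gg$genome, design, truth)

  set.seed(config$seed + 4L)
  pl_keys <- unique(variant_key(truth$planted$chrom, truth$planted$pos,
                                truth$planted$ref, truth$planted$alt))
  n_known <- round(config$catalog_fraction * length(pl_keys))
  known <- if (n_known > 0L) sample(pl_keys, n_known) else character()
  cat_df <- if (length(known)) {
    parts <- do.call(rbind, strsplit(known, ":", fixed = TRUE))
    data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
               ref = parts[, 3], alt = parts[, 4], stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  }
  if (config$catalog_background > 0L) {
    taken <- c(position_key(truth$planted$chrom, truth$planted$pos),
               position_key(truth$systematic$chrom, truth$systematic$pos))
    avail <- truth$positions[!(position_key(truth$positions$chrom,
                                            truth$positions$pos) %in% taken), ,
                             drop = FALSE]
    bg <- avail[sample(nrow(avail), min(config$catalog_background,
                                        nrow(avail))), , drop = FALSE]
    bg$ref <- mapply(function(ch, p) genome_base(gg$genome, ch, p),
                     bg$chrom, bg$pos, USE.NAMES = FALSE)
    bg$alt <- vapply(bg$ref, function(r) sample(setdiff(DNA_BASES, r), 1), "",
                     USE.NAMES = FALSE)
    cat_df <- rbind(cat_df, bg[, c("chrom", "pos", "ref", "alt")])
  }
  cat_df <- cat_df[order(cat_df$chrom, cat_df$pos, cat_df$alt), , drop = FALSE]
  rownames(cat_df) <- NULL

  list(config = config, genome = gg$genome, genes = gg$genes,
       gene_manifest = gg$manifest, staining = st, design = design,
       truth = truth, reads = rr$reads, read_manifest = rr$manifest,
       catalog = cat_df, oracle = sanger_oracle(truth))
}

#' Write all simulated inputs to a directory
#'
#' Writes the genome (FASTA), annotation (gene-table TSV and GFF3), target
#' BED, reads (TSV), catalog (TSV), staining table (TSV), the truth tables
#' and the per-sample read manifest, all as plain text.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_genome_fasta(sim$genome, p("genome.fa"))
  write_gene_models(sim$genes, p("genes.tsv"), format = "tsv")
  write_gene_models(sim$genes, p("genes.gff3"), format = "gff3")
  write_bed(sim$design$regions, p("targets.bed"))
  write_reads_tsv(sim$reads, p("reads.tsv"))
  write_catalog(sim$catalog, p("catalog.tsv"))
  write_staining_table(sim$staining$records, p("staining.tsv"))
  utils::write.table(sim$truth$planted, p("truth_planted.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$systematic, p("truth_systematic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$read_manifest, p("read_manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
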