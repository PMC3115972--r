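# Multiplexed per-sample SNV calling and annotation.
#
# Reads carry their true genomic origin (read_id, mid, chrom, start,
# sequence); no alignment is performed. Pileups tally per-sample per-position
# base counts over the capture target only, and SNVs are called with a
# strict allele-fraction threshold (> min_fraction of the reads) at a
# minimum depth.

#' Standard 454-style multiplex identifier (MID) barcodes
#'
#' The ten canonical 10-mer library barcodes, named `MID1`..`MID10`.
#'
#' @return named character vector of barcode sequences.
#' @export
roche_mids <- function() {
  c(MID1 = "ACGAGTGCGT", MID2 = "ACGCTCGACA", MID3 = "AGACGCACTC",
    MID4 = "AGCACTGTAG", MID5 = "ATCAGACACG", MID6 = "ATATCGCGAG",
    MID7 = "CGTGTCTCTA", MID8 = "CTCGCGTGTC", MID9 = "TAGTATCAGC",
    MID10 = "TCTCTATGCG")
}

validate_reads <- function(reads) {
  need <- c("read_id", "mid", "chrom", "start", "sequence")
  missing <- setdiff(need, names(reads))
  if (length(missing)) {
    stop("read table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(reads$sequence))) stop("empty read sequence", call. = FALSE)
  if (any(grepl("[^ACGTN]", reads$sequence))) {
    stop("read sequence outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(reads)
}

#' Demultiplex barcoded reads into per-sample bins
#'
#' Each read is assigned to exactly one sample by exact match of its `mid`
#' tag against the configured barcode labels; reads with an unknown tag go
#' to the `unassigned` bin. Assigned plus unassigned counts always sum to
#' the input count.
#'
#' @param reads data.frame with columns `read_id`, `mid`, `chrom`, `start`,
#'   `sequence`.
#' @param mids character vector of barcode labels (e.g.
#'   `names(roche_mids())`), one sample per barcode; must be pairwise
#'   distinct.
#' @return list with `samples` (named list of per-sample read data.frames,
#'   one entry per barcode, possibly empty) and `unassigned`.
#' @export
demultiplex <- function(reads, mids) {
  if (anyDuplicated(mids)) {
    stop("duplicate barcode in 'mids' configuration", call. = FALSE)
  }
  validate_reads(reads)
  samples <- lapply(mids, function(m) reads[reads$mid == m, , drop = FALSE])
  names(samples) <- mids
  list(samples = samples,
       unassigned = reads[!(reads$mid %in% mids), , drop = FALSE])
}

# Tally one sample's reads on one chromosome into a 4 x chrom_len count
# matrix (rows A,C,G,T; column j = 0-based position j-1).
tally_reads_chrom <- function(seqs, starts, chrom_len) {
  lens <- nchar(seqs)
  over <- starts + lens > chrom_len
  if (any(over)) {
    warning(sprintf("%d read(s) extend past the chromosome end; truncated",
                    sum(over)), call. = FALSE)
    seqs[over] <- substring(seqs[over], 1L, chrom_len - starts[over])
    lens <- nchar(seqs)
    keep <- lens > 0L
    seqs <- seqs[keep]; starts <- starts[keep]; lens <- lens[keep]
  }
  base <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  pos <- sequence(lens, from = starts + 1L)  # 1-based
  bi <- match(base, DNA_BASES)               # N and friends drop out
  ok <- !is.na(bi)
  idx <- (pos[ok] - 1L) * 4L + bi[ok]
  matrix(tabulate(idx, nbins = 4L * chrom_len), nrow = 4L,
         dimnames = list(DNA_BASES, NULL))
}

#' Build per-sample pileups over the capture target
#'
#' Tallies base counts per (sample, chromosome, position) from
#' origin-annotated reads, keeping only positions inside the target design.
#' Reads extending past a chromosome end are truncated with a warning; reads
#' that do not touch the target contribute nothing.
#'
#' @param sample_reads named list of per-sample read data.frames (the
#'   `samples` element of [demultiplex()]).
#' @param genome named character vector of chromosome sequences.
#' @param design a `target_design` or a data.frame of fused regions.
#' @return data.frame with columns `sample_id`, `chrom`, `pos` (0-based),
#'   `A`, `C`, `G`, `T`, `depth`, restricted to target positions with
#'   depth > 0.
#' @export
build_pileup <- function(sample_reads, genome, design) {
  regions <- if (inherits(design, "target_design")) design$regions else design
  clens <- chrom_lengths(genome)
  out <- list()
  for (sid in names(sample_reads)) {
    reads <- sample_reads[[sid]]
    if (nrow(reads) == 0L) next
    if (!all(reads$chrom %in% names(genome))) {
      stop("read origin on unknown chromosome", call. = FALSE)
    }
    for (ch in intersect(unique(regions$chrom), unique(reads$chrom))) {
      r <- regions[regions$chrom == ch, , drop = FALSE]
      rd <- reads[reads$chrom == ch, , drop = FALSE]
      # keep only reads overlapping some target region
      len <- nchar(rd$sequence)
      ir_reads <- IRanges::IRanges(start = rd$start + 1L, end = rd$start + len)
      ir_reg <- IRanges::IRanges(start = r$start + 1L, end = r$end)
      hit <- IRanges::overlapsAny(ir_reads, ir_reg)
      rd <- rd[hit, , drop = FALSE]
      if (nrow(rd) == 0L) next
      m <- tally_reads_chrom(rd$sequence, rd$start, clens[[ch]])
      tpos <- unlist(Map(function(s, e) seq.int(s, e - 1L), r$start, r$end),
                     use.names = FALSE)
      depth <- colSums(m)[tpos + 1L]
      keep <- depth > 0L
      if (!any(keep)) next
      tpos <- tpos[keep]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, chrom = ch, pos = tpos,
        A = m["A", tpos + 1L], C = m["C", tpos + 1L],
        G = m["G", tpos + 1L], T = m["T", tpos + 1L],
        depth = as.integer(depth[keep]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), A = integer(), C = integer(),
                      G = integer(), T = integer(), depth = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Call SNVs from a pileup with an allele-fraction threshold
#'
#' A call is emitted for every (sample, position, alternative base) with
#' depth at least `min_depth` and alternative-base fraction strictly above
#' `min_fraction`. Multiple alternative alleles at one position may each be
#' emitted. Positions whose reference base is N are skipped.
#'
#' @param pileup pileup data.frame from [build_pileup()].
#' @param genome named character vector of chromosome sequences.
#' @param min_fraction strict lower bound on alt_count/depth (default 0.20,
#'   i.e. variants must be seen in more than 20% of the reads).
#' @param min_depth minimum read depth to consider a position (default 5).
#' @return data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_count`, `alt_fraction`.
#' @export
call_snvs <- function(pileup, genome, min_fraction = 0.20, min_depth = 5) {
  empty <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      depth = integer(), alt_count = integer(),
                      alt_fraction = numeric(), stringsAsFactors = FALSE)
  if (nrow(pileup) == 0L) return(empty)
  ref <- character(nrow(pileup))
  for (ch in unique(pileup$chrom)) {
    i <- pileup$chrom == ch
    ref[i] <- genome_base(genome, ch, pileup$pos[i])
  }
  nref <- ref == "N"
  if (any(nref)) {
    message(sprintf("call_snvs: skipped %d position(s) with reference base N",
                    length(unique(position_key(pileup$chrom[nref],
                                               pileup$pos[nref])))))
  }
  calls <- lapply(DNA_BASES, function(b) {
    cnt <- pileup[[b]]
    keep <- !nref & b != ref & pileup$depth >= min_depth &
      cnt / pileup$depth > min_fraction
    if (!any(keep)) return(NULL)
    data.frame(sample_id = pileup$sample_id[keep], chrom = pileup$chrom[keep],
               pos = pileup$pos[keep], ref = ref[keep], alt = b,
               depth = pileup$depth[keep], alt_count = as.integer(cnt[keep]),
               alt_fraction = cnt[keep] / pileup$depth[keep],
               stringsAsFactors = FALSE)
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0L) return(empty)
  df <- do.call(rbind, calls)
  df <- df[order(df$sample_id, df$chrom, df$pos, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Annotate variant alleles with region class and coding effect
#'
#' Region class comes from [classify_in_genes()] (precedence
#' CDS > UTR5 > UTR3 > PROMOTER > INTRON > INTERGENIC). For CDS alleles the
#' affected codon is rebuilt strand-aware from the spliced coding sequence,
#' the alternative base (complemented on minus-strand genes) is substituted,
#' and both codons are translated with the standard nuclear genetic code;
#' the effect is `synonymous` when the amino acid is unchanged and
#' `non_synonymous` otherwise. Non-CDS alleles get effect `non_coding`.
#' Variants in a CDS whose gene is out of frame are flagged unannotatable
#' (effect `NA`) with a warning.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per unique allele; per-sample call tables work too, but see
#'   [unique_variants()]).
#' @param genes list of `gene_model`s.
#' @param genome named character vector of chromosome sequences.
#' @param promoter_len promoter window length used for classification.
#' @return the input with columns `gene_id`, `region_class`, `effect`,
#'   `ref_aa`, `codon_number`, `alt_aa` appended.
#' @export
annotate_variants <- function(variants, genes, genome, promoter_len = 1000) {
  n <- nrow(variants)
  region_class <- character(n); gene_id <- rep(NA_character_, n)
  effect <- rep("non_coding", n)
  ref_aa <- rep(NA_character_, n); alt_aa <- rep(NA_character_, n)
  codon_number <- rep(NA_integer_, n)
  gene_by_id <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  cds_cache <- new.env(parent = emptyenv())

  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    cl <- classify_in_genes(genes, ch, variants$pos[i], promoter_len)
    region_class[i] <- cl$class
    gene_id[i] <- cl$gene_id
  }

  unannotatable <- 0L
  for (j in which(region_class == "CDS")) {
    g <- gene_by_id[[gene_id[j]]]
    if (!isTRUE(g$cds_frame_ok)) {
      effect[j] <- NA_character_
      unannotatable <- unannotatable + 1L
      next
    }
    cc <- cds_coordinates(g, variants$pos[j])
    key <- g$gene_id
    if (is.null(cds_cache[[key]])) cds_cache[[key]] <- spliced_cds(g, genome)
    cds <- cds_cache[[key]]
    cstart <- cc$codon_number * 3L + 1L
    codon <- substring(cds, cstart, cstart + 2L)
    alt_base <- if (g$strand == "+") variants$alt[j] else COMPLEMENT[[variants$alt[j]]]
    alt_codon <- codon
    substr(alt_codon, cc$position_in_codon + 1L, cc$position_in_codon + 1L) <- alt_base
    ref_aa[j] <- Biostrings::GENETIC_CODE[[codon]]
    alt_aa[j] <- Biostrings::GENETIC_CODE[[alt_codon]]
    codon_number[j] <- cc$codon_number
    effect[j] <- if (ref_aa[j] == alt_aa[j]) "synonymous" else "non_synonymous"
  }
  if (unannotatable > 0L) {
    warning(sprintf(
      "%d CDS variant(s) in out-of-frame gene(s) flagged unannotatable",
      unannotatable), call. = FALSE)
  }
  out <- variants
  out$gene_id <- gene_id
  out$region_class <- region_class
  out$effect <- effect
  out$ref_aa <- ref_aa
  out$codon_number <- codon_number
  out$alt_aa <- alt_aa
  out
}

#' Collapse per-sample calls to unique variant alleles
#'
#' @param calls call data.frame from [call_snvs()].
#' @return data.frame with one row per unique (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @export
unique_variants <- function(calls) {
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  df <- calls[!duplicated(key), c("chrom", "pos", "ref", "alt"), drop = FALSE]
  df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Flag variant novelty against a known-variant catalog
#'
#' A variant is novel when its key is absent from the catalog. Matching is
#' by full allele (`chrom`, `pos`, `ref`, `alt`) by default, or by position
#' only (`chrom`, `pos`) as older variant catalogs were matched.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param catalog data.frame with `chrom`, `pos` and (for allele matching)
#'   `ref`, `alt`; 0-based positions.
#' @param match_on `"allele"` (default) or `"position"`.
#' @param genome optional; when given, catalog entries whose `ref` disagrees
#'   with the genome are warned about (and kept).
#' @return `variants` with a logical `novel` column appended.
#' @export
flag_novelty <- function(variants, catalog, match_on = c("allele", "position"),
                         genome = NULL) {
  match_on <- match.arg(match_on)
  if (!is.null(genome) && nrow(catalog) > 0L && !is.null(catalog$ref)) {
    gref <- mapply(function(ch, p) genome_base(genome, ch, p),
                   catalog$chrom, catalog$pos)
    bad <- gref != catalog$ref
    if (any(bad)) {
      warning(sprintf("%d catalog entr(ies) with reference mismatch; kept",
                      sum(bad)), call. = FALSE)
    }
  }
  if (match_on == "allele") {
    have <- variant_key(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
    key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  } else {
    have <- position_key(catalog$chrom, catalog$pos)
    key <- position_key(variants$chrom, variants$pos)
  }
  variants$novel <- !(key %in% have)
  variants
}

#' Count per-variant sample recurrence
#'
#' @param calls per-sample call data.frame.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `n_samples` (number
#'   of distinct samples carrying the allele).
#' @export
compute_recurrence <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  tab <- tapply(calls$sample_id, key, function(s) length(unique(s)))
  uv <- unique_variants(calls)
  uv$n_samples <- as.integer(tab[variant_key(uv$chrom, uv$pos, uv$ref, uv$alt)])
  uv
}

#' Apply the verification oracle to candidate variants
#'
#' Models orthogonal (Sanger-style) verification as a total oracle over the
#' candidate list: each candidate becomes `verified` or `false_positive`.
#'
#' @param candidates annotated variant data.frame with `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param oracle a function mapping a vector of variant keys
#'   (see [variant_key()]) to `"verified"` / `"false_positive"`; see
#'   [sanger_oracle()].
#' @return `candidates` with a `verification` column set.
#' @export
verify_candidates <- function(candidates, oracle) {
  key <- variant_key(candidates$chrom, candidates$pos, candidates$ref,
                     candidates$alt)
  v <- oracle(key)
  if (length(v) != length(key) || anyNA(v) ||
      !all(v %in% c("verified", "false_positive"))) {
    stop("verification oracle is not total over the candidate list",
         call. = FALSE)
  }
  candidates$verification <- v
  candidates
}
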