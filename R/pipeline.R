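# End-to-end driver: demultiplex -> pileup -> call -> annotate -> novelty ->
# recurrence -> candidate selection -> verification -> reports.

#' Run the full candidate-filtering pipeline
#'
#' Demultiplexes the reads, builds per-sample pileups over the target,
#' calls SNVs with the allele-fraction rule, annotates unique alleles
#' (region class, coding effect, novelty, sample recurrence), selects the
#' candidate set (novel non-synonymous alleles), optionally verifies it
#' against an oracle, and assembles the coverage table, per-base variation
#' rates and candidate funnel.
#'
#' @param reads read data.frame (`read_id`, `mid`, `chrom`, `start`,
#'   `sequence`).
#' @param genome named character vector of chromosome sequences.
#' @param genes list of `gene_model`s.
#' @param design a `target_design`.
#' @param catalog known-variant catalog data.frame (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @param oracle optional verification oracle (see [sanger_oracle()]);
#'   when `NULL` candidates stay `untested` and verified funnel rows are
#'   `NA`.
#' @param mids barcode labels defining the samples (default the ten
#'   standard MIDs).
#' @param min_fraction,min_depth calling thresholds, see [call_snvs()].
#' @param promoter_len promoter window for classification.
#' @param match_on novelty matching mode, see [flag_novelty()].
#' @return list with `demux`, `pileup`, `calls`, `variants` (annotated
#'   unique alleles), `candidates`, `coverage`, `rates`, `funnel`,
#'   `fp_rate_pct` (`NA` without an oracle).
#' @export
run_pipeline <- function(reads, genome, genes, design, catalog,
                         oracle = NULL, mids = names(roche_mids()),
                         min_fraction = 0.20, min_depth = 5,
                         promoter_len = 1000, match_on = "allele") {
  dm <- demultiplex(reads, mids)
  pileup <- build_pileup(dm$samples, genome, design)
  calls <- call_snvs(pileup, genome, min_fraction, min_depth)

  variants <- compute_recurrence(calls)
  variants <- annotate_variants(variants, genes, genome, promoter_len)
  variants <- flag_novelty(variants, catalog, match_on = match_on)
  variants$verification <- rep("untested", nrow(variants))

  is_cand <- variants$novel & !is.na(variants$effect) &
    variants$effect == "non_synonymous"
  if (!is.null(oracle) && any(is_cand)) {
    verified <- verify_candidates(variants[is_cand, , drop = FALSE], oracle)
    variants$verification[is_cand] <- verified$verification
  }
  candidates <- variants[is_cand, , drop = FALSE]

  # per-sample tallies: reads overlapping the target, bases inside it
  regions <- design$regions
  tallies <- do.call(rbind, lapply(mids, function(sid) {
    rd <- dm$samples[[sid]]
    on_target <- 0L
    if (nrow(rd) > 0L) {
      for (ch in intersect(unique(rd$chrom), unique(regions$chrom))) {
        r <- regions[regions$chrom == ch, , drop = FALSE]
        rr <- rd[rd$chrom == ch, , drop = FALSE]
        ir <- IRanges::IRanges(start = rr$start + 1L,
                               end = rr$start + nchar(rr$sequence))
        on_target <- on_target +
          sum(IRanges::overlapsAny(ir, IRanges::IRanges(r$start + 1L, r$end)))
      }
    }
    pu <- pileup[pileup$sample_id == sid, , drop = FALSE]
    cs <- calls[calls$sample_id == sid, , drop = FALSE]
    ck <- variant_key(cs$chrom, cs$pos, cs$ref, cs$alt)
    vk <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
    coding <- sum(variants$region_class[match(ck, vk)] == "CDS")
    data.frame(sample_id = sid, mapped_reads = on_target,
               mapped_bases = sum(pu$depth), snv_count = nrow(cs),
               coding_snv_count = coding, stringsAsFactors = FALSE)
  }))
  coverage <- coverage_table(tallies, design$total_bases)

  total_snvs <- nrow(calls)
  vk <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  ck <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  coding_snvs <- sum(variants$region_class[match(ck, vk)] == "CDS")
  rates <- variation_rates(total_snvs, coding_snvs, length(mids),
                           design$total_bases, design$coding_bases)
  funnel <- build_funnel(variants)
  fp <- if (!is.null(oracle) && nrow(candidates) > 0L) {
    false_positive_rate(nrow(candidates),
                        sum(candidates$verification == "verified"))
  } else NA_real_
  list(demux = dm, pileup = pileup, calls = calls, variants = variants,
       candidates = candidates, coverage = coverage, rates = rates,
       funnel = funnel, fp_rate_pct = fp)
}
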