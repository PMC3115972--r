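# Summary surfaces: per-sample coverage table, per-base variation rates,
# the candidate funnel, and the false-positive rate of verification.

#' Per-sample coverage and variant table
#'
#' One row per sample plus a `Total` row. Mean coverage is
#' `mapped_bases / target_bases` rounded half away from zero to an integer;
#' the total row sums reads, bases and variant counts and computes the
#' pooled coverage from the summed bases.
#'
#' @param tallies data.frame with columns `sample_id`, `mapped_reads`,
#'   `mapped_bases` and optionally `snv_count`, `coding_snv_count`.
#' @param target_bases size of the capture target in bases (> 0).
#' @return data.frame with a `mean_coverage` column and a final `Total` row.
#' @export
coverage_table <- function(tallies, target_bases) {
  if (!is.numeric(target_bases) || length(target_bases) != 1L ||
      is.na(target_bases) || target_bases <= 0) {
    stop("target_bases must be a single positive number", call. = FALSE)
  }
  df <- data.frame(sample_id = as.character(tallies$sample_id),
                   mapped_reads = tallies$mapped_reads,
                   mapped_bases = tallies$mapped_bases,
                   mean_coverage = round_half_away(tallies$mapped_bases /
                                                     target_bases),
                   snv_count = tallies$snv_count %||%
                     rep(NA_integer_, nrow(tallies)),
                   coding_snv_count = tallies$coding_snv_count %||%
                     rep(NA_integer_, nrow(tallies)),
                   stringsAsFactors = FALSE)
  if (any(!is.na(df$coding_snv_count) & !is.na(df$snv_count) &
          df$coding_snv_count > df$snv_count)) {
    stop("coding_snv_count exceeds snv_count", call. = FALSE)
  }
  total <- data.frame(sample_id = "Total",
                      mapped_reads = sum(df$mapped_reads),
                      mapped_bases = sum(df$mapped_bases),
                      mean_coverage = round_half_away(sum(df$mapped_bases) /
                                                        target_bases),
                      snv_count = sum(df$snv_count),
                      coding_snv_count = sum(df$coding_snv_count),
                      stringsAsFactors = FALSE)
  rbind(df, total)
}

#' Per-base variation rates, coding vs non-coding
#'
#' Rates are per-sample averages: the SNV calls are divided by the number of
#' samples before dividing by the corresponding base counts, then expressed
#' as percent and rounded half away from zero to two decimals. This
#' per-sample averaging is what makes the rates reproducible from the
#' pooled per-sample call counts of a multiplexed run.
#'
#' @param total_snvs total per-sample SNV calls across all samples.
#' @param coding_snvs the subset of `total_snvs` in coding sequence.
#' @param n_samples number of samples (>= 1).
#' @param total_bases total target bases.
#' @param coding_bases coding target bases (< `total_bases`).
#' @return named numeric vector `c(non_coding_rate_pct, coding_rate_pct)`.
#' @export
variation_rates <- function(total_snvs, coding_snvs, n_samples, total_bases,
                            coding_bases) {
  if (coding_snvs > total_snvs) stop("coding_snvs > total_snvs", call. = FALSE)
  stopifnot_scalar_count(n_samples, "n_samples", min = 1)
  if (coding_bases >= total_bases) {
    stop("coding_bases must be smaller than total_bases", call. = FALSE)
  }
  nc <- ((total_snvs - coding_snvs) / n_samples) / (total_bases - coding_bases) * 100
  cc <- (coding_snvs / n_samples) / coding_bases * 100
  c(non_coding_rate_pct = round_half_away(nc, 2),
    coding_rate_pct = round_half_away(cc, 2))
}

FUNNEL_FIELDS <- c("unique_positions_total", "in_target_genes",
                   "in_exons_incl_utr", "in_introns", "in_promoter",
                   "in_cds", "in_non_coding", "non_synonymous_in_cds",
                   "novel_non_synonymous", "verified_novel",
                   "novel_recurrent", "verified_novel_recurrent")

#' Construct and validate funnel counts
#'
#' Container for the candidate-funnel summary. Position rows count unique
#' genomic positions; novelty rows count unique alleles. `in_promoter`
#' makes the gene-association partition exact:
#' `in_exons_incl_utr + in_introns + in_promoter = in_target_genes`.
#' `verified_novel` / `verified_novel_recurrent` are `NA` while candidates
#' are untested.
#'
#' @param unique_positions_total,in_target_genes,in_exons_incl_utr,in_introns,in_promoter,in_cds,in_non_coding,non_synonymous_in_cds,novel_non_synonymous,verified_novel,novel_recurrent,verified_novel_recurrent counts.
#' @return a `funnel_counts` object.
#' @export
funnel_counts <- function(unique_positions_total, in_target_genes,
                          in_exons_incl_utr, in_introns, in_promoter = 0L,
                          in_cds = 0L, in_non_coding = 0L,
                          non_synonymous_in_cds = 0L,
                          novel_non_synonymous = 0L, verified_novel = NA,
                          novel_recurrent = 0L,
                          verified_novel_recurrent = NA) {
  f <- structure(list(unique_positions_total = unique_positions_total,
                      in_target_genes = in_target_genes,
                      in_exons_incl_utr = in_exons_incl_utr,
                      in_introns = in_introns, in_promoter = in_promoter,
                      in_cds = in_cds, in_non_coding = in_non_coding,
                      non_synonymous_in_cds = non_synonymous_in_cds,
                      novel_non_synonymous = novel_non_synonymous,
                      verified_novel = verified_novel,
                      novel_recurrent = novel_recurrent,
                      verified_novel_recurrent = verified_novel_recurrent),
                 class = "funnel_counts")
  validate_funnel(f)
  f
}

#' Check the internal-consistency invariants of funnel counts
#'
#' Verifies `in_cds + in_non_coding = unique_positions_total`,
#' `in_exons_incl_utr + in_introns + in_promoter = in_target_genes`,
#' `in_target_genes <= unique_positions_total`, the monotone candidate
#' chain `novel_non_synonymous <= non_synonymous_in_cds <= in_cds`, and the
#' verification bounds.
#'
#' @param f a `funnel_counts` object.
#' @return `f`, invisibly; errors on violation.
#' @export
validate_funnel <- function(f) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("funnel: ", msg, call. = FALSE)
  chk(f$in_cds + f$in_non_coding == f$unique_positions_total,
      "in_cds + in_non_coding != unique_positions_total")
  chk(f$in_exons_incl_utr + f$in_introns + f$in_promoter == f$in_target_genes,
      "exons + introns + promoter != in_target_genes")
  chk(f$in_target_genes <= f$unique_positions_total,
      "in_target_genes > unique_positions_total")
  chk(f$non_synonymous_in_cds <= f$in_cds,
      "non_synonymous_in_cds > in_cds")
  chk(f$novel_recurrent <= f$novel_non_synonymous,
      "novel_recurrent > novel_non_synonymous")
  if (!is.na(f$verified_novel)) {
    chk(f$verified_novel <= f$novel_non_synonymous,
        "verified_novel > novel_non_synonymous")
  }
  if (!is.na(f$verified_novel_recurrent)) {
    chk(f$verified_novel_recurrent <=
          min(f$verified_novel, f$novel_recurrent),
        "verified_novel_recurrent > min(verified_novel, novel_recurrent)")
  }
  invisible(f)
}

#' Build the candidate funnel from annotated variants
#'
#' Position rows (total, gene association, CDS vs non-coding,
#' non-synonymous) are counted over unique genomic positions; novelty and
#' verification rows over unique alleles. Variants flagged unannotatable
#' (CDS in an out-of-frame gene, effect `NA`) are dropped with a warning
#' before counting.
#'
#' @param variants annotated variant data.frame with `region_class`,
#'   `effect`, `novel`, `n_samples` and optionally `verification` columns
#'   (one row per unique allele).
#' @return a `funnel_counts` object.
#' @export
build_funnel <- function(variants) {
  if (nrow(variants) == 0L) {
    return(funnel_counts(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, NA, 0L, NA))
  }
  bad <- variants$region_class == "CDS" & !is.na(variants$effect) &
    variants$effect == "non_coding"
  if (any(bad)) stop("inconsistent annotation: CDS variant with non_coding effect",
                     call. = FALSE)
  drop <- variants$region_class == "CDS" & is.na(variants$effect)
  if (any(drop)) {
    warning(sprintf("dropping %d unannotatable variant(s) from the funnel",
                    sum(drop)), call. = FALSE)
    variants <- variants[!drop, , drop = FALSE]
  }
  pkey <- position_key(variants$chrom, variants$pos)
  by_pos <- variants[!duplicated(pkey), , drop = FALSE]

  in_gene_classes <- c("PROMOTER", "UTR5", "UTR3", "CDS", "INTRON")
  exonic <- c("UTR5", "UTR3", "CDS")
  # a position is non-synonymous if any allele at it changes the amino acid
  nonsyn_pos <- unique(pkey[!is.na(variants$effect) &
                              variants$effect == "non_synonymous"])

  novel_ns <- variants$novel & !is.na(variants$effect) &
    variants$effect == "non_synonymous"
  have_verif <- !is.null(variants$verification) &&
    !all(variants$verification[novel_ns] == "untested")
  verified <- if (have_verif) {
    novel_ns & variants$verification == "verified"
  } else NULL

  funnel_counts(
    unique_positions_total = nrow(by_pos),
    in_target_genes = sum(by_pos$region_class %in% in_gene_classes),
    in_exons_incl_utr = sum(by_pos$region_class %in% exonic),
    in_introns = sum(by_pos$region_class == "INTRON"),
    in_promoter = sum(by_pos$region_class == "PROMOTER"),
    in_cds = sum(by_pos$region_class == "CDS"),
    in_non_coding = sum(by_pos$region_class != "CDS"),
    non_synonymous_in_cds = length(nonsyn_pos),
    novel_non_synonymous = sum(novel_ns),
    verified_novel = if (have_verif) sum(verified) else NA,
    novel_recurrent = sum(novel_ns & variants$n_samples > 1L),
    verified_novel_recurrent = if (have_verif) {
      sum(verified & variants$n_samples > 1L)
    } else NA)
}

#' @export
print.funnel_counts <- function(x, ...) {
  cat("Candidate funnel\n")
  labels <- c("Unique positions with SNVs", "  in target genes",
              "    in exons (incl UTR)", "    in introns", "    in promoter",
              "  in coding sequence (CDS)", "  in non-coding sequence",
              "Non-synonymous in CDS", "Novel non-synonymous",
              "Verified novel non-synonymous",
              "Novel non-synonymous in >1 sample",
              "Verified novel non-synonymous in >1 sample")
  for (i in seq_along(FUNNEL_FIELDS)) {
    v <- x[[FUNNEL_FIELDS[i]]]
    cat(sprintf("  %-45s %s\n", labels[i], if (is.na(v)) "-" else v))
  }
  invisible(x)
}

#' Write funnel counts as TSV
#'
#' @param f a `funnel_counts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_funnel <- function(f, path) {
  utils::write.table(
    data.frame(metric = FUNNEL_FIELDS,
               count = unlist(f[FUNNEL_FIELDS], use.names = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' False-positive rate of a verification experiment
#'
#' @param n_candidates number of candidates submitted to verification
#'   (>= 1).
#' @param n_verified number confirmed (0 <= `n_verified` <=
#'   `n_candidates`).
#' @return percentage of candidates that failed verification.
#' @export
false_positive_rate <- function(n_candidates, n_verified) {
  stopifnot_scalar_count(n_candidates, "n_candidates", min = 1)
  stopifnot_scalar_count(n_verified, "n_verified", min = 0)
  if (n_verified > n_candidates) {
    stop("n_verified exceeds n_candidates", call. = FALSE)
  }
  100 * (n_candidates - n_verified) / n_candidates
}
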