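# Capture target-region design: extract coding exons, UTR exons and a
# promoter window per gene, pad short regions to a minimum capture length,
# fuse strictly overlapping regions, and summarize the design.

#' Extract raw capture regions from gene models
#'
#' For each gene this yields one interval per coding-exon segment, one per
#' UTR exon segment, and one promoter interval of `promoter_len` bases
#' strand-upstream of the transcript start (clamped at chromosome bounds).
#' Introns are excluded.
#'
#' @param genes list of `gene_model`s.
#' @param promoter_len promoter window length in bases (default 1000).
#' @param chrom_lengths named integer vector of chromosome lengths, used for
#'   clamping; see [chrom_lengths()].
#' @return data.frame with columns `chrom`, `start`, `end`, `class`,
#'   `gene_id`.
#' @export
extract_raw_regions <- function(genes, promoter_len = 1000, chrom_lengths) {
  rows <- lapply(genes, function(g) {
    clen <- chrom_lengths[[g$chrom]]
    if (is.null(clen)) stop("unknown chromosome: ", g$chrom, call. = FALSE)
    if (g$strand == "+") {
      ps <- g$tx_start - promoter_len; pe <- g$tx_start
    } else {
      ps <- g$tx_end; pe <- g$tx_end + promoter_len
    }
    ps <- max(ps, 0L); pe <- min(pe, clen)
    prom <- if (ps < pe) {
      data.frame(start = ps, end = pe, class = "PROMOTER")
    } else {
      warning(sprintf("gene '%s': promoter window entirely off-chromosome; dropped",
                      g$gene_id), call. = FALSE)
      NULL
    }
    # split each exon at the translation bounds
    seg <- do.call(rbind, lapply(seq_len(nrow(g$exons)), function(i) {
      es <- g$exons$start[i]; ee <- g$exons$end[i]
      cut <- sort(unique(pmax(pmin(c(g$cds_start, g$cds_end), ee), es)))
      bounds <- unique(c(es, cut, ee))
      s <- bounds[-length(bounds)]; e <- bounds[-1L]
      keep <- s < e
      s <- s[keep]; e <- e[keep]
      mid <- s  # class determined by the segment start
      cls <- ifelse(mid >= g$cds_start & mid < g$cds_end, "CDS",
             ifelse(mid < g$cds_start,
                    if (g$strand == "+") "UTR5" else "UTR3",
                    if (g$strand == "+") "UTR3" else "UTR5"))
      data.frame(start = s, end = e, class = cls)
    }))
    out <- rbind(prom, seg)
    out$chrom <- g$chrom
    out$gene_id <- g$gene_id
    out
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[, c("chrom", "start", "end", "class", "gene_id")]
}

#' Pad regions to a minimum capture length
#'
#' Short regions are expanded symmetrically (half the deficit on each side,
#' odd remainder to the right in chromosome coordinates). Padding clamped at
#' a chromosome bound is redistributed to the other side, so every output
#' reaches `min_len` unless the chromosome itself is shorter. Regions
#' already at least `min_len` long are returned unchanged, and every input
#' interval is contained in its padded output.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (extra columns are
#'   preserved).
#' @param min_len minimum region length in bases (default 250).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return data.frame of the same shape with padded coordinates.
#' @export
pad_regions <- function(regions, min_len = 250, chrom_lengths) {
  s <- as.integer(regions$start); e <- as.integer(regions$end)
  clen <- as.integer(chrom_lengths[regions$chrom])
  if (anyNA(clen)) stop("region on unknown chromosome", call. = FALSE)
  deficit <- pmax(min_len - (e - s), 0L)
  left <- deficit %/% 2L
  right <- deficit - left
  ns <- s - left
  ne <- e + right
  # clamp left, push the loss right, then clamp right and push back left
  loss <- pmax(-ns, 0L); ns <- ns + loss; ne <- ne + loss
  loss <- pmax(ne - clen, 0L); ne <- ne - loss; ns <- pmax(ns - loss, 0L)
  out <- regions
  out$start <- ns
  out$end <- ne
  out
}

#' Fuse overlapping regions
#'
#' Strictly overlapping intervals are merged; merely bookended (adjacent)
#' intervals are kept separate unless `merge_adjacent = TRUE`. The base-set
#' union of the output equals that of the input, and the output is sorted by
#' `(chrom, start)` and pairwise non-overlapping.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param merge_adjacent also fuse intervals that touch without overlapping.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
fuse_overlaps <- function(regions, merge_adjacent = FALSE) {
  if (nrow(regions) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  gap <- if (merge_adjacent) 1L else 0L
  out <- lapply(sort(unique(regions$chrom)), function(ch) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = r$start + 1L, end = r$end),
                          min.gapwidth = gap)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Subtract an exclusion set from a design
#'
#' Removes user-supplied intervals (e.g. repetitive regions) from the
#' design; the remainder keeps the 0-based half-open convention.
#'
#' @param regions design intervals.
#' @param exclude intervals to subtract (`chrom`, `start`, `end`).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
subtract_regions <- function(regions, exclude) {
  out <- lapply(sort(unique(regions$chrom)), function(ch) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    x <- exclude[exclude$chrom == ch, , drop = FALSE]
    if (nrow(x)) {
      ir <- IRanges::setdiff(ir, IRanges::IRanges(start = x$start + 1L, end = x$end))
    }
    if (length(ir) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(chrom = character(), start = integer(), end = integer())
  }
  rownames(df) <- NULL
  df
}

#' Summarize a fused target design
#'
#' Counts regions and bases; `coding_bases` is the number of target bases
#' classified CDS under the class-precedence rule, computed by intersecting
#' the design with the union of all genes' CDS segments.
#'
#' @param regions fused design intervals.
#' @param genes list of `gene_model`s used to identify coding bases.
#' @return a `target_design` object: list with `regions`, `n_regions`,
#'   `total_bases`, `coding_bases`.
#' @export
summarize_design <- function(regions, genes) {
  total <- as.integer(sum(regions$end - regions$start))
  coding <- 0L
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    segs <- do.call(rbind, lapply(genes, function(g) {
      if (g$chrom != ch) return(NULL)
      cds_segments(g)
    }))
    if (is.null(segs) || nrow(segs) == 0L) next
    cds_ir <- IRanges::reduce(IRanges::IRanges(start = segs$start + 1L,
                                               end = segs$end))
    reg_ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    coding <- coding + sum(IRanges::width(IRanges::intersect(reg_ir, cds_ir)))
  }
  structure(list(regions = regions, n_regions = nrow(regions),
                 total_bases = total, coding_bases = as.integer(coding)),
            class = "target_design")
}

#' @export
print.target_design <- function(x, ...) {
  cat(sprintf("<target_design> %d regions, %d bases (%d coding)\n",
              x$n_regions, x$total_bases, x$coding_bases))
  invisible(x)
}

#' Build a complete capture design from gene models
#'
#' Convenience pipeline: extract raw regions, pad to the minimum capture
#' length, fuse overlaps, optionally subtract an exclusion set, and
#' summarize.
#'
#' @inheritParams extract_raw_regions
#' @inheritParams pad_regions
#' @inheritParams fuse_overlaps
#' @param exclude optional exclusion intervals (see [subtract_regions()]).
#' @return a `target_design` object.
#' @export
build_target_design <- function(genes, chrom_lengths, promoter_len = 1000,
                                min_len = 250, merge_adjacent = FALSE,
                                exclude = NULL) {
  raw <- extract_raw_regions(genes, promoter_len, chrom_lengths)
  padded <- pad_regions(raw, min_len, chrom_lengths)
  fused <- fuse_overlaps(padded, merge_adjacent)
  if (!is.null(exclude)) fused <- subtract_regions(fused, exclude)
  summarize_design(fused, genes)
}

# All 0-based positions covered by a set of intervals, as a data.frame
# (chrom, pos). Internal; used by the simulator and pipeline.
region_positions <- function(regions) {
  n <- regions$end - regions$start
  data.frame(chrom = rep(regions$chrom, n),
             pos = unlist(Map(function(s, e) seq.int(s, e - 1L),
                              regions$start, regions$end), use.names = FALSE),
             stringsAsFactors = FALSE)
}
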