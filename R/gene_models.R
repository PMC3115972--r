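# Gene models and strand-aware region classification.
#
# A gene model holds one transcript: strand, transcript bounds, an ordered
# disjoint exon list and genomic CDS bounds. Coordinates are 0-based
# half-open. The region classes partition every chromosome position with
# respect to a gene: PROMOTER (a fixed window strand-upstream of the
# transcript start), UTR5, CDS, UTR3, INTRON, INTERGENIC.

REGION_CLASSES <- c("CDS", "UTR5", "UTR3", "PROMOTER", "INTRON", "INTERGENIC")

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end transcript bounds, 0-based half-open.
#' @param exons data.frame with integer columns `start`, `end` (0-based
#'   half-open), sorted and non-overlapping.
#' @param cds_start,cds_end genomic translation bounds; the CDS is the
#'   intersection of the exons with `[cds_start, cds_end)`.
#' @param check_frame if `TRUE`, a CDS length not divisible by 3 is an error;
#'   if `FALSE` it is recorded in the `cds_frame_ok` field and warned about
#'   (the behaviour used when reading third-party annotation).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, tx_start, tx_end, exons,
                       cds_start, cds_end, check_frame = TRUE) {
  g <- structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, tx_start = as.integer(tx_start),
         tx_end = as.integer(tx_end),
         exons = data.frame(start = as.integer(exons$start),
                            end = as.integer(exons$end)),
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         cds_frame_ok = TRUE),
    class = "gene_model")
  validate_gene_model(g, check_frame = check_frame)
}

#' Validate a gene model's invariants
#'
#' Checks exon ordering/disjointness, containment in the transcript span,
#' CDS bounds landing inside exons, and CDS length divisible by 3.
#'
#' @inheritParams gene_model
#' @param gene a `gene_model`.
#' @param chrom_len optional chromosome length; transcript and promoter-free
#'   bounds are checked against it when given.
#' @return the validated gene model (with `cds_frame_ok` possibly set).
#' @export
validate_gene_model <- function(gene, chrom_len = NULL, check_frame = TRUE) {
  e <- gene$exons
  fail <- function(msg) stop(sprintf("gene '%s': %s", gene$gene_id, msg), call. = FALSE)
  if (!gene$strand %in% c("+", "-")) fail("strand must be '+' or '-'")
  if (nrow(e) < 1L) fail("at least one exon required")
  if (any(e$end <= e$start)) fail("exon with end <= start")
  if (is.unsorted(e$start, strictly = TRUE)) fail("exons not sorted by start")
  if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
    fail("exon overlaps previous exon")
  }
  if (gene$tx_start >= gene$tx_end) fail("tx_start >= tx_end")
  if (e$start[1L] < gene$tx_start || e$end[nrow(e)] > gene$tx_end) {
    fail("exons outside transcript bounds")
  }
  if (gene$cds_start >= gene$cds_end) fail("cds_start >= cds_end")
  in_exon <- function(p) any(e$start <= p & p < e$end)
  if (!in_exon(gene$cds_start) || !in_exon(gene$cds_end - 1L)) {
    fail("CDS bounds outside exon-covered span")
  }
  if (!is.null(chrom_len) && gene$tx_end > chrom_len) {
    fail("transcript extends past chromosome end")
  }
  len <- cds_length(gene)
  if (len %% 3L != 0L) {
    if (check_frame) fail(sprintf("CDS length %d not divisible by 3", len))
    warning(sprintf("gene '%s': CDS length %d not divisible by 3; flagged",
                    gene$gene_id, len), call. = FALSE)
    gene$cds_frame_ok <- FALSE
  }
  gene
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), CDS %d-%d\n",
              x$gene_id, x$chrom, x$tx_start, x$tx_end, x$strand,
              nrow(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

#' CDS segments of a gene
#'
#' Genomic intervals (0-based half-open) formed by intersecting the exons
#' with the translation bounds, in genomic order.
#'
#' @param gene a `gene_model`.
#' @return data.frame with columns `start`, `end`.
#' @export
cds_segments <- function(gene) {
  s <- pmax(gene$exons$start, gene$cds_start)
  e <- pmin(gene$exons$end, gene$cds_end)
  keep <- s < e
  data.frame(start = s[keep], end = e[keep])
}

#' Spliced CDS length in bases
#' @param gene a `gene_model`.
#' @return integer length.
#' @export
cds_length <- function(gene) {
  seg <- cds_segments(gene)
  as.integer(sum(seg$end - seg$start))
}

#' Classify positions relative to one gene
#'
#' Assigns each position exactly one region class. The promoter is the
#' `promoter_len` window strand-upstream of the transcript start (upstream of
#' `tx_start` on `+`, downstream of `tx_end` on `-`). Exonic positions split
#' into UTR5 / CDS / UTR3 around the translation bounds, strand-aware;
#' non-exonic positions inside the transcript span are INTRON; everything
#' else is INTERGENIC.
#'
#' @param gene a `gene_model`.
#' @param pos integer vector of 0-based positions on the gene's chromosome.
#' @param promoter_len promoter window length in bases (default 1000).
#' @return character vector of region classes, one per position.
#' @export
classify_position <- function(gene, pos, promoter_len = 1000) {
  pos <- as.integer(pos)
  out <- rep("INTERGENIC", length(pos))

  if (gene$strand == "+") {
    prom <- pos >= gene$tx_start - promoter_len & pos < gene$tx_start
  } else {
    prom <- pos >= gene$tx_end & pos < gene$tx_end + promoter_len
  }
  out[prom] <- "PROMOTER"

  inside <- pos >= gene$tx_start & pos < gene$tx_end
  out[inside] <- "INTRON"

  e <- gene$exons
  exonic <- inside
  if (any(inside)) {
    idx <- findInterval(pos, e$start)
    exonic <- inside & idx >= 1L & pos < e$end[pmax(idx, 1L)]
  }
  if (any(exonic)) {
    in_cds <- exonic & pos >= gene$cds_start & pos < gene$cds_end
    before <- exonic & pos < gene$cds_start
    after <- exonic & pos >= gene$cds_end
    out[in_cds] <- "CDS"
    if (gene$strand == "+") {
      out[before] <- "UTR5"; out[after] <- "UTR3"
    } else {
      out[before] <- "UTR3"; out[after] <- "UTR5"
    }
  }
  out
}

#' Classify positions against a set of genes with precedence
#'
#' Per-gene classification is combined across overlapping genes with the
#' precedence CDS > UTR5 > UTR3 > PROMOTER > INTRON > INTERGENIC, so a
#' position always receives its most consequence-bearing class. Ties at the
#' same precedence are attributed to the first gene in `genes` order.
#'
#' @param genes list of `gene_model`s.
#' @param chrom chromosome of the positions.
#' @param pos integer vector of 0-based positions.
#' @param promoter_len promoter window length.
#' @return data.frame with columns `class` and `gene_id` (`NA` for
#'   INTERGENIC positions).
#' @export
classify_in_genes <- function(genes, chrom, pos, promoter_len = 1000) {
  rank <- stats::setNames(seq_along(REGION_CLASSES), REGION_CLASSES)
  best <- rep(rank[["INTERGENIC"]], length(pos))
  gene_id <- rep(NA_character_, length(pos))
  for (g in genes) {
    if (g$chrom != chrom) next
    r <- rank[classify_position(g, pos, promoter_len)]
    better <- r < best
    best[better] <- r[better]
    gene_id[better] <- g$gene_id
  }
  data.frame(class = REGION_CLASSES[best], gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' Coordinates of a position within the spliced CDS
#'
#' Maps a genomic CDS position to its 0-based offset in the spliced,
#' strand-aware coding sequence, the codon it falls in and its position
#' within the codon (`cds_index == 3 * codon_number + position_in_codon`).
#' On the minus strand the index counts from the strand-aware translation
#' start (the genomic `cds_end - 1`).
#'
#' @param gene a `gene_model`.
#' @param pos a single 0-based position classified as CDS for this gene.
#' @return list with `cds_index`, `codon_number`, `position_in_codon`.
#' @export
cds_coordinates <- function(gene, pos) {
  if (classify_position(gene, pos, promoter_len = 0)[1] != "CDS") {
    stop(sprintf("position %d is not in the CDS of gene '%s'", pos, gene$gene_id),
         call. = FALSE)
  }
  seg <- cds_segments(gene)
  plus_index <- 0L
  for (i in seq_len(nrow(seg))) {
    if (pos >= seg$end[i]) {
      plus_index <- plus_index + (seg$end[i] - seg$start[i])
    } else {
      plus_index <- plus_index + (pos - seg$start[i])
      break
    }
  }
  idx <- if (gene$strand == "+") plus_index else cds_length(gene) - 1L - plus_index
  list(cds_index = as.integer(idx),
       codon_number = as.integer(idx %/% 3L),
       position_in_codon = as.integer(idx %% 3L))
}

#' Spliced coding sequence of a gene
#'
#' Concatenated CDS segments in translation order (reverse-complemented for
#' minus-strand genes).
#'
#' @param gene a `gene_model`.
#' @param genome named character vector of chromosome sequences.
#' @return character scalar, the coding sequence 5'->3'.
#' @export
spliced_cds <- function(gene, genome) {
  seg <- cds_segments(gene)
  parts <- substring(genome[[gene$chrom]], seg$start + 1, seg$end)
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
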