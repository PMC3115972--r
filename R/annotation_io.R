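# Annotation I/O: a documented GFF3 subset (gene/exon/CDS features) and an
# equivalent single-line-per-gene TSV gene table. Both parsers feed the same
# validator. GFF3 is 1-based closed on disk; the gene table uses the
# package's internal 0-based half-open convention.

GENE_TABLE_COLS <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
                     "exon_starts", "exon_ends", "cds_start", "cds_end")

#' Read gene models from annotation
#'
#' Accepts either the package's GFF3 subset (`gene`, `exon` and `CDS`
#' features linked by `ID`/`Parent`) or a tab-delimited gene table with
#' columns `r paste(GENE_TABLE_COLS, collapse = ", ")` where the exon columns
#' are comma-separated and all coordinates are 0-based half-open. The format
#' is chosen by file extension unless forced.
#'
#' @param path annotation file.
#' @param format `"auto"`, `"gff3"` or `"tsv"`.
#' @return list of validated `gene_model`s, in file order. Genes whose CDS
#'   length is not divisible by 3 are kept but flagged
#'   (`cds_frame_ok = FALSE`) with a warning.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") read_gene_models_gff3(path) else read_gene_models_tsv(path)
}

read_gene_models_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty gene table: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, GENE_TABLE_COLS)) {
    stop(sprintf("parse error at line 1 of '%s': expected header '%s'",
                 path, paste(GENE_TABLE_COLS, collapse = "\t")), call. = FALSE)
  }
  models <- vector("list", length(lines) - 1L)
  for (i in seq_along(models)) {
    lineno <- i + 1L
    f <- strsplit(lines[lineno], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(GENE_TABLE_COLS)) {
      stop(sprintf("parse error at line %d of '%s': expected %d fields, got %d",
                   lineno, path, length(GENE_TABLE_COLS), length(f)), call. = FALSE)
    }
    num <- suppressWarnings(as.integer(f[c(4, 5, 8, 9)]))
    ex_s <- suppressWarnings(as.integer(strsplit(f[6], ",", fixed = TRUE)[[1L]]))
    ex_e <- suppressWarnings(as.integer(strsplit(f[7], ",", fixed = TRUE)[[1L]]))
    if (anyNA(num) || anyNA(ex_s) || anyNA(ex_e) || length(ex_s) != length(ex_e)) {
      stop(sprintf("parse error at line %d of '%s': malformed coordinates",
                   lineno, path), call. = FALSE)
    }
    models[[i]] <- gene_model(f[1], f[2], f[3], num[1], num[2],
                              data.frame(start = ex_s, end = ex_e),
                              num[3], num[4], check_frame = FALSE)
  }
  models
}

read_gene_models_gff3 <- function(path) {
  # Light syntax pre-scan so malformed lines are reported by number before
  # the semantic import.
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L ||
        anyNA(suppressWarnings(as.integer(f[4:5])))) {
      stop(sprintf("parse error at line %d of '%s': not a 9-field GFF3 record",
                   i, path), call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  parent_of <- function(i) {
    p <- gr$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1L])
  }
  gene_rows <- which(type == "gene")
  models <- vector("list", length(gene_rows))
  for (k in seq_along(gene_rows)) {
    i <- gene_rows[k]
    gid <- as.character(gr$ID[i])
    kids <- which(vapply(seq_along(gr), parent_of, "") == gid)
    ex <- kids[type[kids] == "exon"]
    cds <- kids[type[kids] == "CDS"]
    if (length(ex) == 0L || length(cds) == 0L) {
      stop(sprintf("gene '%s' lacks exon or CDS features", gid), call. = FALSE)
    }
    ex <- ex[order(GenomicRanges::start(gr)[ex])]
    models[[k]] <- gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      strand = as.character(GenomicRanges::strand(gr)[i]),
      tx_start = GenomicRanges::start(gr)[i] - 1L,
      tx_end = GenomicRanges::end(gr)[i],
      exons = data.frame(start = GenomicRanges::start(gr)[ex] - 1L,
                         end = GenomicRanges::end(gr)[ex]),
      cds_start = min(GenomicRanges::start(gr)[cds]) - 1L,
      cds_end = max(GenomicRanges::end(gr)[cds]),
      check_frame = FALSE)
  }
  models
}

#' Write gene models to annotation
#'
#' Emits the canonical form of whichever dialect is requested; reading the
#' result back yields identical models, and re-writing what was read
#' reproduces the file byte for byte.
#'
#' @param models list of `gene_model`s.
#' @param path output file.
#' @param format `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  lines <- if (format == "tsv") {
    rows <- vapply(models, function(g) {
      paste(g$gene_id, g$chrom, g$strand, g$tx_start, g$tx_end,
            paste(g$exons$start, collapse = ","),
            paste(g$exons$end, collapse = ","),
            g$cds_start, g$cds_end, sep = "\t")
    }, "")
    c(paste(GENE_TABLE_COLS, collapse = "\t"), rows)
  } else {
    recs <- unlist(lapply(models, function(g) {
      seg <- cds_segments(g)
      # phase: bases to skip at the 5' end of each CDS segment, in
      # translation order
      n <- nrow(seg)
      lens <- seg$end - seg$start
      cum <- if (g$strand == "+") cumsum(c(0L, lens))[seq_len(n)]
             else rev(cumsum(c(0L, rev(lens)))[seq_len(n)])
      phase <- (3L - cum %% 3L) %% 3L
      c(sprintf("%s\tvarfunnel\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$chrom, g$tx_start + 1L, g$tx_end, g$strand, g$gene_id),
        sprintf("%s\tvarfunnel\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                g$chrom, g$exons$start + 1L, g$exons$end, g$strand, g$gene_id),
        sprintf("%s\tvarfunnel\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                g$chrom, seg$start + 1L, seg$end, g$strand, phase, g$gene_id))
    }))
    c("##gff-version 3", recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`; capture regions are strand-agnostic so
#'   strand is written as `.`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- regions$name %||% sprintf("region_%d", seq_len(nrow(regions)))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.",
                   regions$chrom, regions$start, regions$end, name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file as an interval data.frame
#'
#' @param path BED3+ file.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}
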