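# Read-set and variant-file I/O.
#
# Two read dialects are supported: an origin-annotated TSV
# (read_id, mid, chrom, start, sequence) and FASTA in which each record's
# sequence begins with its sample's MID barcode and the header carries the
# true origin as `chrom=... start=...` tokens. Calls are exported as a
# minimal VCF (1-based positions) with per-sample depth and allele fraction.

#' Read / write origin-annotated reads as TSV
#'
#' @param path file path.
#' @return `read_reads_tsv`: validated read data.frame.
#' @export
read_reads_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(read_id = "character",
                                         mid = "character",
                                         chrom = "character",
                                         start = "integer",
                                         sequence = "character"))
  validate_reads(df)
  df
}

#' @rdname read_reads_tsv
#' @param reads read data.frame.
#' @export
write_reads_tsv <- function(reads, path) {
  validate_reads(reads)
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write barcoded reads as FASTA
#'
#' The barcode sequence of each read's MID is prepended to the genomic
#' sequence; the true origin is recorded in the header as
#' `>read_id chrom=<chrom> start=<start>`.
#'
#' @param reads read data.frame.
#' @param path output path.
#' @param mid_sequences named character vector mapping MID labels to barcode
#'   sequences (default [roche_mids()]).
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path, mid_sequences = roche_mids()) {
  validate_reads(reads)
  bc <- mid_sequences[reads$mid]
  if (anyNA(bc)) stop("read with MID absent from 'mid_sequences'", call. = FALSE)
  ss <- Biostrings::DNAStringSet(paste0(bc, reads$sequence))
  names(ss) <- sprintf("%s chrom=%s start=%d", reads$read_id, reads$chrom,
                       reads$start)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read barcoded reads from FASTA
#'
#' Demultiplex-by-prefix entry point for the FASTA dialect: the MID is
#' recovered by exact prefix match against `mid_sequences` and stripped from
#' the sequence; reads matching no barcode keep their full sequence and get
#' `mid = "unknown"`.
#'
#' @param path FASTA file written by [write_reads_fasta()] (or compatible).
#' @param mid_sequences named character vector of barcode sequences.
#' @return read data.frame (`read_id`, `mid`, `chrom`, `start`, `sequence`).
#' @export
read_reads_fasta <- function(path, mid_sequences = roche_mids()) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  seqs <- toupper(as.character(ss))
  read_id <- sub("\\s.*$", "", hdr)
  chrom <- sub(".*chrom=(\\S+).*", "\\1", hdr)
  start <- as.integer(sub(".*start=(\\d+).*", "\\1", hdr))
  mid <- rep("unknown", length(seqs))
  for (m in names(mid_sequences)) {
    pref <- mid_sequences[[m]]
    hit <- mid == "unknown" & startsWith(seqs, pref)
    mid[hit] <- m
    seqs[hit] <- substring(seqs[hit], nchar(pref) + 1L)
  }
  df <- data.frame(read_id = unname(read_id), mid = mid,
                   chrom = unname(chrom), start = unname(start),
                   sequence = unname(seqs), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  validate_reads(df)
  df
}

#' Write SNV calls as minimal VCF
#'
#' One row per unique allele, POS 1-based; per-sample depth and allele
#' fraction in the FORMAT field (`DP:AF`), `.` for samples without the call.
#'
#' @param calls per-sample call data.frame from [call_snvs()].
#' @param genome named character vector (for contig headers).
#' @param path output path.
#' @param sample_ids column order of the genotype fields; defaults to the
#'   samples present in `calls`, sorted.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(calls, genome, path, sample_ids = NULL) {
  sample_ids <- sample_ids %||% sort(unique(calls$sample_id))
  uv <- unique_variants(calls)
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  ukey <- variant_key(uv$chrom, uv$pos, uv$ref, uv$alt)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=varfunnel",
           sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Alternate allele fraction">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids), collapse = "\t"))
  rows <- vapply(seq_len(nrow(uv)), function(i) {
    hit <- calls[key == ukey[i], , drop = FALSE]
    gt <- vapply(sample_ids, function(s) {
      j <- match(s, hit$sample_id)
      if (is.na(j)) "." else sprintf("%d:%.4f", hit$depth[j], hit$alt_fraction[j])
    }, "")
    paste(c(uv$chrom[i], uv$pos[i] + 1L, ".", uv$ref[i], uv$alt[i], ".",
            "PASS", ".", "DP:AF", gt), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read / write a known-variant catalog
#'
#' TSV catalogs have header columns `chrom`, `pos` (0-based), `ref`, `alt`.
#' VCF catalogs (extension `.vcf`) are converted from 1-based positions;
#' multi-allelic ALT entries are split into one row per allele.
#'
#' @param path catalog file (`.tsv` or `.vcf`).
#' @return `read_catalog`: data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @export
read_catalog <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF catalogs requires the 'vcfR' package", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
    n <- lengths(alt_list)
    df <- data.frame(chrom = rep(fix[, "CHROM"], n),
                     pos = rep(as.integer(fix[, "POS"]) - 1L, n),
                     ref = rep(fix[, "REF"], n),
                     alt = unlist(alt_list), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$pos <- as.integer(df$pos)
  }
  df[, c("chrom", "pos", "ref", "alt")]
}

#' @rdname read_catalog
#' @param catalog catalog data.frame.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog[, c("chrom", "pos", "ref", "alt")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotated variant table as TSV
#'
#' @param variants annotated variant data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
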