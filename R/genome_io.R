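# Reference genome container and FASTA I/O.
#
# A reference genome is represented as a named character vector of uppercase
# nucleotide strings over {A,C,G,T,N}; names are chromosome identifiers.
# All internal coordinates are 0-based half-open; conversion to 1-based
# happens only at I/O boundaries (VCF, GFF3).

#' Validate a reference genome
#'
#' @param genome named character vector of chromosome sequences.
#' @return the genome, invisibly, after validation.
#' @export
validate_genome <- function(genome) {
  if (!is.character(genome) || is.null(names(genome)) || anyNA(genome)) {
    stop("genome must be a named character vector of sequences", call. = FALSE)
  }
  if (anyDuplicated(names(genome))) {
    stop("duplicate chromosome names in genome", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    stop(sprintf("chromosome '%s' contains characters outside {A,C,G,T,N}",
                 names(genome)[bad][1]), call. = FALSE)
  }
  invisible(genome)
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased to the canonical form; the chromosome name is the
#' first whitespace-delimited token of the FASTA header.
#'
#' @param path path to a (possibly wrapped) FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  genome <- toupper(as.character(ss))
  names(genome) <- sub("\\s.*$", "", names(ss))
  validate_genome(genome)
  genome
}

#' Write a reference genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70) {
  validate_genome(genome)
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome named character vector of sequences.
#' @return named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

# Base at 0-based positions (vectorised over pos).
genome_base <- function(genome, chrom, pos) {
  substring(genome[[chrom]], pos + 1, pos + 1)
}
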