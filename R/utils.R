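# Shared small helpers.

#' Round half away from zero
#'
#' Commercial rounding used for all reported coverages and rates: halves are
#' rounded away from zero rather than to even (which is what [base::round()]
#' does). Mean coverages are reported as integers, per-base rates to two
#' decimals of percent.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_away(0.5)   # 1, where round(0.5) == 0
#' round_half_away(37.51) # 38
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Canonical variant key
#'
#' Unique identifier for a variant allele, `chrom:pos:ref:alt` with `pos`
#' 0-based. Used to join calls, annotations, catalogs and the truth oracle.
#'
#' @param chrom,pos,ref,alt vectors describing variant alleles (recycled).
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

position_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

stopifnot_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %s", name, min), call. = FALSE)
  }
}
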