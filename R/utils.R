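# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# substring of a character scalar in 0-based half-open coordinates
subseq0 <- function(seq, start, end) substr(seq, start + 1L, end)

#' Reverse complement of a DNA sequence
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character scalars.
#'
#' @param seq DNA sequence (character scalar, A/C/G/T/N).
#' @return character scalar.
#' @export
revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Convert genomic minus-strand inputs to locus sense-strand coordinates
#'
#' All internal coordinates of this package are 0-based half-open on the
#' gene sense strand of the supplied locus sequence.  For genes on the
#' genomic minus strand, sequence and coordinates
#' obtained from genome-strand resources must be flipped once at the I/O
#' boundary: the sequence is reverse-complemented and an interval
#' \code{[start, end)} becomes \code{[L - end, L - start)}.
#'
#' @param seq locus sequence on the genomic plus strand (or \code{NULL} to
#'   convert coordinates only).
#' @param intervals data.frame with columns \code{start}, \code{end}
#'   (0-based half-open, genomic-plus-strand locus coordinates), or NULL.
#' @param seqLength locus length; required when \code{seq} is NULL.
#' @return list with elements \code{seq} (reverse-complemented sequence or
#'   NULL) and \code{intervals} (flipped, re-sorted data.frame or NULL).
#' @export
flipToSenseStrand <- function(seq = NULL, intervals = NULL,
                              seqLength = if (is.null(seq)) NULL
                                          else nchar(seq)) {
  if (is.null(seqLength))
    stop("seqLength is required when no sequence is supplied")
  out <- list(seq = NULL, intervals = NULL)
  if (!is.null(seq)) out$seq <- revComp(seq)
  if (!is.null(intervals)) {
    flipped <- intervals
    flipped$start <- seqLength - intervals$end
    flipped$end <- seqLength - intervals$start
    out$intervals <- flipped[order(flipped$start), , drop = FALSE]
    rownames(out$intervals) <- NULL
  }
  out
}

# logistic site-usability curve used by the splicing simulator
logisticUsability <- function(score, midpoint, slope) {
  1 / (1 + exp(-slope * (score - midpoint)))
}

stopIfBadBases <- function(seq, context = "sequence") {
  if (grepl("[^ACGT]", seq))
    stop(sprintf("%s contains bases outside A/C/G/T (no IUPAC expansion)",
                 context))
  invisible(TRUE)
}

# distance from a position to an exon interval [start, end); 0 when inside
distanceToExon <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos >= end, pos - end + 1L, 0L))
}

# deterministic child seed derivation, kept below 2^31
deriveSeed <- function(seed, salt) {
  (as.numeric(seed) * 69069 + salt) %% 2147483647
}
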