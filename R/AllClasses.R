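#' @import methods
#' @importFrom stats rnorm rmultinom setNames
#' @importFrom utils read.delim write.table head modifyList
NULL

#' GeneModel: exon/CDS layout of a locus on its sense strand
#'
#' Container for the exon structure of a single gene locus.  All coordinates
#' are 0-based half-open on the gene sense strand of the locus sequence the
#' model refers to; the first base of the locus is position 0 and an exon
#' spanning positions \code{start <= i < end} has length \code{end - start}.
#'
#' @slot locusName single character, name of the locus.
#' @slot sequenceLength integer, length of the locus sequence in bp.
#' @slot exons data.frame with columns \code{exon_id}, \code{start},
#'   \code{end}; sorted, non-overlapping, separated by at least one intronic
#'   base.
#' @slot cdsStart locus coordinate of the first coding base (c.1), or
#'   \code{NA} for a non-coding model (consequence annotation disabled).
#' @slot cdsPhase named integer vector, reading-frame phase at the start of
#'   each exon (number of bases of the split codon carried over).
#' @slot transcriptId annotated transcript identifier the model was built
#'   from.
#'
#' @seealso [parseGeneModel()], [modelExons()], [modelIntrons()]
#' @export
setClass("GeneModel",
  slots = c(
    locusName      = "character",
    sequenceLength = "integer",
    exons          = "data.frame",
    cdsStart       = "integer",
    cdsPhase       = "integer",
    transcriptId   = "character"
  )
)

setValidity("GeneModel", function(object) {
  ex <- object@exons
  msgs <- character()
  if (!all(c("exon_id", "start", "end") %in% names(ex)))
    return("exons must have columns exon_id, start, end")
  if (nrow(ex) == 0L) return("gene model must contain at least one exon")
  if (any(ex$end <= ex$start))
    msgs <- c(msgs, sprintf("exon '%s' has end <= start",
                            ex$exon_id[which(ex$end <= ex$start)[1L]]))
  if (is.unsorted(ex$start, strictly = TRUE))
    msgs <- c(msgs, "exons must be sorted by start")
  if (nrow(ex) > 1L) {
    gap <- ex$start[-1L] - ex$end[-nrow(ex)]
    bad <- which(gap < 1L)
    if (length(bad))
      msgs <- c(msgs, sprintf(
        "exons '%s' and '%s' overlap or are not separated by an intronic base",
        ex$exon_id[bad[1L]], ex$exon_id[bad[1L] + 1L]))
  }
  if (any(ex$start < 0L) || any(ex$end > object@sequenceLength))
    msgs <- c(msgs, "exons must lie within the locus sequence")
  if (!is.na(object@cdsStart)) {
    inside <- any(object@cdsStart >= ex$start & object@cdsStart < ex$end)
    if (!inside) msgs <- c(msgs, "cdsStart does not fall within an exon")
  }
  if (length(msgs)) msgs else TRUE
})

#' PWMatrix: position weight matrix for splice sites or ESE motifs
#'
#' Log-odds position weight matrix.  Scores are sums over positions of the
#' weight of the observed base; a hit is reportable when the score reaches
#' \code{threshold}.
#'
#' @slot motifName motif identifier (e.g. \code{"SRSF2"} for the SC35 motif).
#' @slot weights numeric matrix, one row per position, columns
#'   \code{A,C,G,T}, log2-odds weights.
#' @slot threshold minimum reportable score.
#' @export
setClass("PWMatrix",
  slots = c(motifName = "character", weights = "matrix",
            threshold = "numeric")
)

setValidity("PWMatrix", function(object) {
  w <- object@weights
  if (!is.numeric(w)) return("weights must be numeric")
  if (!identical(colnames(w), c("A", "C", "G", "T")))
    return("weights must have columns A,C,G,T")
  if (nrow(w) < 4L) return("matrix length must be >= 4 positions")
  if (anyNA(w)) return("weights must not contain NA")
  TRUE
})

#' IsoformQuantification: normalised isoform fractions for one sample
#'
#' @slot sampleId sample identifier.
#' @slot fractions named numeric vector of isoform fractions; non-negative
#'   and summing to one.
#' @slot displayThreshold fraction below which isoforms are hidden from the
#'   default display (they remain in the data; the filter is display-only).
#' @export
setClass("IsoformQuantification",
  slots = c(sampleId = "character", fractions = "numeric",
            displayThreshold = "numeric")
)

setValidity("IsoformQuantification", function(object) {
  fr <- object@fractions
  if (is.null(names(fr)) || any(!nzchar(names(fr))))
    return("fractions must be named by isoform")
  if (any(fr < -1e-12)) return("fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) return("fractions must sum to 1")
  if (object@displayThreshold < 0 || object@displayThreshold > 1)
    return("displayThreshold must be in [0,1]")
  TRUE
})

#' AccessibilityProfile: per-base openness of an RNA region
#'
#' Openness at base i is \code{1 - P(i paired)} under the package's
#' Boltzmann ensemble of nested secondary structures (see
#' [accessibilityProfile()]).
#'
#' @slot region the region sequence (RNA alphabet stored as DNA characters).
#' @slot openness numeric vector in \code{[0,1]}, one value per base.
#' @slot pairWeight Boltzmann weight contributed by each base pair.
#' @export
setClass("AccessibilityProfile",
  slots = c(region = "character", openness = "numeric",
            pairWeight = "numeric")
)

setValidity("AccessibilityProfile", function(object) {
  if (nchar(object@region) != length(object@openness))
    return("openness length must equal region length")
  if (any(object@openness < -1e-9 | object@openness > 1 + 1e-9))
    return("openness values must be in [0,1]")
  TRUE
})

#' MinigeneConstruct: a synthetic minigene with two constitutive vector exons
#'
#' The construct sequence is V1 vector arm + cloned locus insert + V2 vector
#' arm.  Coordinates of the slots are 0-based half-open positions in the
#' construct sequence; \code{insertLocusStart} maps construct positions back
#' to the locus (locus = construct - insertSpan[1] + insertLocusStart).
#'
#' @slot name construct name.
#' @slot sequence construct DNA sequence.
#' @slot v1Exon,v2Exon integer \code{c(start, end)} spans of the two
#'   constitutive vector exons.
#' @slot insertSpan integer \code{c(start, end)} span of the cloned locus
#'   fragment.
#' @slot insertLocusStart locus coordinate of the first inserted base.
#' @slot exonsInInsert data.frame of canonical exons that fall inside the
#'   insert (construct coordinates), columns exon_id,start,end.
#' @slot siteRegistry data.frame of registered splice sites with latent
#'   usabilities: kind, boundary_pos (construct coords), score, method,
#'   constitutive.
#' @slot variants data.frame of injected variants (construct_pos, ref, alt).
#' @export
setClass("MinigeneConstruct",
  slots = c(
    name = "character", sequence = "character",
    v1Exon = "integer", v2Exon = "integer", insertSpan = "integer",
    insertLocusStart = "integer",
    exonsInInsert = "data.frame", siteRegistry = "data.frame",
    variants = "data.frame"
  )
)

setValidity("MinigeneConstruct", function(object) {
  n <- nchar(object@sequence)
  spans <- rbind(object@v1Exon, object@insertSpan, object@v2Exon)
  if (any(spans < 0L) || any(spans > n))
    return("v1/insert/v2 spans must lie within the construct sequence")
  if (!(object@v1Exon[2L] <= object@insertSpan[1L] &&
        object@insertSpan[2L] <= object@v2Exon[1L]))
    return("V1 must precede the insert, which must precede V2")
  reg <- object@siteRegistry
  if (nrow(reg) && (any(reg$boundary_pos < 0L) || any(reg$boundary_pos > n)))
    return("registered splice sites must lie inside the construct")
  TRUE
})
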