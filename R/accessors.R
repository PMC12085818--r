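#' @describeIn GeneModel-accessors exon table (0-based half-open coordinates)
#' @export
modelExons <- function(model) model@exons

#' Accessors for GeneModel
#'
#' @param model a [GeneModel-class] object.
#' @return \code{modelExons}: data.frame of exons; \code{modelIntrons}:
#'   data.frame of introns (columns intron_id, start, end, the gaps between
#'   consecutive exons); \code{isCoding}: logical; \code{locusName},
#'   \code{cdsStart}: scalars.
#' @name GeneModel-accessors
NULL

#' @describeIn GeneModel-accessors intron table derived from the exon layout
#' @export
modelIntrons <- function(model) {
  ex <- model@exons
  if (nrow(ex) < 2L)
    return(data.frame(intron_id = character(), start = integer(),
                      end = integer()))
  data.frame(
    intron_id = paste0("I", seq_len(nrow(ex) - 1L)),
    start = ex$end[-nrow(ex)],
    end = ex$start[-1L]
  )
}

#' @describeIn GeneModel-accessors TRUE when the model carries a CDS
#' @export
isCoding <- function(model) !is.na(model@cdsStart)

#' @describeIn GeneModel-accessors locus name
#' @export
locusName <- function(model) model@locusName

#' @describeIn GeneModel-accessors locus coordinate of the first coding base
#' @export
cdsStart <- function(model) model@cdsStart

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel:", object@locusName,
      sprintf("(%d bp, transcript %s)\n", object@sequenceLength,
              object@transcriptId))
  cat(sprintf("  %d exons; %s\n", nrow(object@exons),
              if (isCoding(object))
                sprintf("CDS starts at locus %d", object@cdsStart)
              else "non-coding mode (no CDS)"))
  print(head(object@exons, 5L), row.names = FALSE)
  if (nrow(object@exons) > 5L)
    cat(sprintf("  ... and %d more exons\n", nrow(object@exons) - 5L))
})

#' Accessors for PWMatrix
#'
#' @param x a [PWMatrix-class].
#' @return \code{motifName}: character; \code{motifLength}: number of
#'   positions; \code{motifThreshold}: minimum reportable score;
#'   \code{motifWeights}: the log-odds weight matrix.
#' @name PWMatrix-accessors
NULL

#' @describeIn PWMatrix-accessors motif identifier
#' @export
motifName <- function(x) x@motifName

#' @describeIn PWMatrix-accessors number of positions
#' @export
motifLength <- function(x) nrow(x@weights)

#' @describeIn PWMatrix-accessors minimum reportable score
#' @export
motifThreshold <- function(x) x@threshold

#' @describeIn PWMatrix-accessors log-odds weight matrix
#' @export
motifWeights <- function(x) x@weights

setMethod("show", "PWMatrix", function(object) {
  cat(sprintf("PWMatrix '%s': %d positions, threshold %.3f, max score %.3f\n",
              object@motifName, nrow(object@weights), object@threshold,
              sum(apply(object@weights, 1L, max))))
})

#' Accessors for IsoformQuantification
#'
#' @param x an [IsoformQuantification-class].
#' @param all logical; when \code{FALSE} (default for display), fractions
#'   below the display threshold are omitted.  The threshold is display-only:
#'   all computations use the full-precision fractions.
#' @return named numeric vector of fractions.
#' @export
isoformFractions <- function(x, all = TRUE) {
  fr <- x@fractions
  if (all) fr else fr[fr >= x@displayThreshold]
}

#' @describeIn isoformFractions sample identifier
#' @export
sampleId <- function(x) x@sampleId

setMethod("show", "IsoformQuantification", function(object) {
  fr <- sort(object@fractions, decreasing = TRUE)
  shown <- fr[fr >= object@displayThreshold]
  cat(sprintf("IsoformQuantification '%s' (%d isoforms, showing %d >= %.0f%%)\n",
              object@sampleId, length(fr), length(shown),
              100 * object@displayThreshold))
  for (nm in names(shown))
    cat(sprintf("  %-18s %5.1f%%\n", nm, 100 * shown[[nm]]))
  hidden <- length(fr) - length(shown)
  if (hidden > 0L)
    cat(sprintf("  (%d isoform(s) below display threshold, kept in data)\n",
                hidden))
})

#' @describeIn accessibilityProfile per-base openness values
#' @export
openness <- function(x) x@openness

setMethod("show", "AccessibilityProfile", function(object) {
  cat(sprintf(
    "AccessibilityProfile: %d nt, pair weight %.3f, mean openness %.3f\n",
    length(object@openness), object@pairWeight, mean(object@openness)))
})

setMethod("show", "MinigeneConstruct", function(object) {
  cat(sprintf("MinigeneConstruct '%s': %d bp\n", object@name,
              nchar(object@sequence)))
  cat(sprintf("  V1 [%d,%d)  insert [%d,%d) (locus offset %d)  V2 [%d,%d)\n",
              object@v1Exon[1L], object@v1Exon[2L],
              object@insertSpan[1L], object@insertSpan[2L],
              object@insertLocusStart,
              object@v2Exon[1L], object@v2Exon[2L]))
  cat(sprintf("  %d canonical exon(s) in insert, %d registered splice sites, %d injected variant(s)\n",
              nrow(object@exonsInInsert), nrow(object@siteRegistry),
              nrow(object@variants)))
})
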