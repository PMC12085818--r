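# Fragment-analysis peak tables -> isoform fractions, fold-changes, and
# antisense-efficacy metrics.

#' Match fragment-analysis peaks to expected isoform lengths
#'
#' Each peak is assigned to the nearest expected amplicon length within the
#' sizing tolerance; peaks matching nothing are reported separately, never
#' dropped.  Expected lengths closer than twice the tolerance would make
#' the assignment ambiguous and are a configuration error.
#'
#' @param peaks peak data.frame (see [readPeakTable()]).
#' @param expected named numeric vector, isoform name -> expected fragment
#'   length (bp).
#' @param tol sizing tolerance in bp (default 2, typical capillary
#'   precision).
#' @return list with \code{areas} (named numeric, summed area per isoform,
#'   zero-filled) and \code{unassigned} (data.frame of unmatched peaks).
#' @export
matchPeaksToIsoforms <- function(peaks, expected,
                                 tol = pipelineDefaults()$quantification$peak_tol_bp) {
  if (is.null(names(expected)) || any(!nzchar(names(expected))))
    stop("expected lengths must be named by isoform")
  d <- diff(sort(expected))
  if (any(d <= 2 * tol))
    stop("expected lengths closer than 2*tol (", 2 * tol,
         " bp); assignment would be ambiguous")
  areas <- setNames(numeric(length(expected)), names(expected))
  unassigned <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    dist <- abs(expected - peaks$fragment_length_bp[i])
    j <- which.min(dist)
    if (dist[j] <= tol)
      areas[j] <- areas[j] + peaks$area[i]
    else
      unassigned <- c(unassigned, i)
  }
  list(areas = areas,
       unassigned = peaks[unassigned, , drop = FALSE])
}

#' Normalise matched peak areas to isoform fractions
#'
#' Fractions are area / total area.  The display threshold (default 5%)
#' only hides minor isoforms from the default display -- it never removes
#' them from the data, and all computations use full-precision fractions.
#'
#' @param areas named numeric vector of summed areas per isoform (e.g.
#'   \code{matchPeaksToIsoforms(...)$areas}).
#' @param sampleId sample identifier.
#' @param displayThreshold display-only minimum fraction.
#' @return an [IsoformQuantification-class].
#' @examples
#' quantifyFractions(c(correct = 510, PE = 490), "demo")
#' @export
quantifyFractions <- function(areas, sampleId = "sample",
                              displayThreshold =
                                pipelineDefaults()$quantification$display_threshold) {
  total <- sum(areas)
  if (total <= 0) stop("total peak area is zero; nothing to quantify")
  new("IsoformQuantification", sampleId = sampleId,
      fractions = areas / total,
      displayThreshold = displayThreshold)
}

#' Fold-change between two isoform fractions
#'
#' Reference over test, rounded to one decimal as conventionally reported
#' (e.g. a correct-transcript drop from 51% to 16% is a 3.2-fold
#' reduction).  A test fraction of zero is a complete loss and is reported
#' as the \code{"complete_loss"} sentinel (an NA with attribute), not as
#' infinity.
#'
#' @param reference_fraction,test_fraction fractions in \code{(0, 1]}
#'   (test may be 0, triggering the sentinel).
#' @return numeric fold-change (1 decimal), or the complete-loss sentinel.
#' @examples
#' foldChange(0.51, 0.16)  # 3.2
#' foldChange(0.51, 0.04)  # 12.8
#' @export
foldChange <- function(reference_fraction, test_fraction) {
  if (reference_fraction <= 0 || reference_fraction > 1)
    stop("reference fraction must be in (0, 1]")
  if (test_fraction < 0 || test_fraction > 1)
    stop("test fraction must be in [0, 1]")
  if (test_fraction == 0)
    return(structure(NA_real_, sentinel = "complete_loss"))
  round(reference_fraction / test_fraction, 1L)
}

#' Antisense-molecule efficacy report
#'
#' Efficacy of an antisense molecule is the reduction of all PE-containing
#' isoforms between a control (untreated) and a treated quantification:
#' reported both in percentage points and relative to the control level.
#' The correct-transcript and neighbour-exon-skip fractions of the treated
#' sample are carried along, the latter because antisense blockers can
#' increase skipping of the neighbouring canonical exon as a side effect.
#'
#' @param control,treated [IsoformQuantification-class] objects over the
#'   same isoform universe.
#' @param pe_isoform_names names of the PE-containing isoforms.
#' @param am_id identifier of the tested antisense molecule.
#' @param correct_name name of the correct-transcript isoform.
#' @param neighbor_skip_names names of neighbour-exon-skip isoforms
#'   (optional).
#' @return one-row data.frame: \code{am_id, pe_control, pe_treated,
#'   pe_reduction_points, pe_reduction_relative,
#'   correct_transcript_fraction, neighbor_skip_fraction}.
#' @export
amEfficacy <- function(control, treated, pe_isoform_names,
                       am_id = sampleId(treated),
                       correct_name = "correct",
                       neighbor_skip_names = character()) {
  frC <- isoformFractions(control)
  frT <- isoformFractions(treated)
  if (!setequal(names(frC), names(frT)))
    stop("control and treated samples must share one isoform universe")
  unknown <- setdiff(c(pe_isoform_names, neighbor_skip_names), names(frC))
  if (length(unknown))
    stop("unknown isoform name(s): ", paste(unknown, collapse = ", "))
  peC <- sum(frC[pe_isoform_names])
  peT <- sum(frT[pe_isoform_names])
  data.frame(
    am_id = am_id,
    pe_control = peC,
    pe_treated = peT,
    pe_reduction_points = 100 * (peC - peT),
    pe_reduction_relative = if (peC > 0) 100 * (peC - peT) / peC else 0,
    correct_transcript_fraction =
      if (correct_name %in% names(frT)) unname(frT[correct_name]) else NA_real_,
    neighbor_skip_fraction = sum(frT[neighbor_skip_names])
  )
}

#' Flag splice-altering variants from paired minigene quantifications
#'
#' A variant construct is called splice-altering when its correct-transcript
#' fraction drops by more than \code{delta} (default 10 points) relative to
#' the matched wild-type construct -- the quantitative analogue of a "clear
#' difference between wild-type and mutant minigenes".
#'
#' @param wildtype,mutant [IsoformQuantification-class] objects for the
#'   wild-type and variant-carrying construct.
#' @param correct_name name of the correct-transcript isoform.
#' @param delta minimum drop in correct-transcript fraction (absolute).
#' @return logical scalar.
#' @export
classifySpliceAltering <- function(wildtype, mutant,
                                   correct_name = "correct",
                                   delta = pipelineDefaults()$quantification$altering_delta) {
  frW <- isoformFractions(wildtype)
  frM <- isoformFractions(mutant)
  cw <- if (correct_name %in% names(frW)) frW[[correct_name]] else 0
  cm <- if (correct_name %in% names(frM)) frM[[correct_name]] else 0
  (cw - cm) > delta
}
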