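# Antisense-molecule candidate generation and ranking against a pseudoexon.
#
# Candidates are ranked on three design criteria: overlap with the PE's
# splice-site core windows, coverage of high-scoring SC35 (SRSF2) exonic
# splicing enhancer motifs, and accessibility (openness) of the target
# region under the package's secondary-structure ensemble, with a penalty
# for lengths above the modality optimum.

#' Per-base accessibility profile of an RNA region
#'
#' Openness at base i is 1 - P(i paired), with the pairing probability
#' computed over the Boltzmann ensemble of nested, pseudoknot-free
#' secondary structures in which every Watson-Crick and G.U pair
#' contributes the constant Boltzmann weight exp(pair_score/temperature)
#' and hairpin loops span at least 3 unpaired bases.  The partition
#' function uses the standard inside recursion (with an outside pass for
#' the per-base probabilities); this deliberately simple ensemble admits an
#' exhaustive enumeration oracle.  An external thermodynamic folding
#' backend can be plugged in by constructing an
#' [AccessibilityProfile-class] from its per-base pairing probabilities and
#' passing it wherever a profile is accepted.
#'
#' @param region_seq region sequence (DNA alphabet; T is read as U).
#' @param pair_score score per base pair (default 1, the unit-pair-score
#'   ensemble).
#' @param temperature ensemble temperature parameter (default 1); higher
#'   values flatten the ensemble towards the uniform structure
#'   distribution.
#' @return an [AccessibilityProfile-class].
#' @examples
#' openness(accessibilityProfile(strrep("A", 30)))  # all 1: no pairs
#' @export
accessibilityProfile <- function(region_seq,
                                 pair_score = 1, temperature = 1) {
  n <- nchar(region_seq)
  if (n < 10L)
    stop("region too short (< 10 nt) for a meaningful profile")
  if (n > 2000L)
    stop("region longer than 2000 nt; fold overlapping windows instead")
  stopIfBadBases(region_seq, "region")
  bases <- match(strsplit(region_seq, "")[[1L]], BASES) - 1L
  q <- exp(pair_score / temperature)
  punp <- .accessibility_unpaired(bases, q, 3L)
  new("AccessibilityProfile", region = region_seq,
      openness = pmin(pmax(punp, 0), 1), pairWeight = q)
}

# splice-site core windows of a PE given acceptor/donor positions
peCoreWindows <- function(acceptor_pos, donor_pos) {
  list(acceptor = siteWindowSpan("acceptor", acceptor_pos),
       donor = siteWindowSpan("donor", donor_pos))
}

# fraction of a core window covered by [s, e)
coreOverlapFraction <- function(s, e, core) {
  pmax(0, pmin(e, core[2L]) - pmax(s, core[1L])) / (core[2L] - core[1L])
}

# score candidate intervals (locus coordinates) against a PE
annotateCandidates <- function(starts, ends, pe, modality, locus_seq,
                               prof, regionStart, eseHits) {
  cores <- peCoreWindows(pe$acceptor_pos, pe$donor_pos)
  site <- pmax(coreOverlapFraction(starts, ends, cores$acceptor),
               coreOverlapFraction(starts, ends, cores$donor))
  op <- openness(prof)
  cumOp <- c(0, cumsum(op))
  sIdx <- starts - regionStart
  eIdx <- ends - regionStart
  acc <- (cumOp[eIdx + 1L] - cumOp[sIdx + 1L]) / (ends - starts)
  eseSum <- numeric(length(starts))
  if (nrow(eseHits)) {
    for (h in seq_len(nrow(eseHits))) {
      hs <- regionStart + eseHits$start[h]
      he <- hs + eseHits$width[h]
      inWin <- starts <= hs & ends >= he
      eseSum[inWin] <- eseSum[inWin] + eseHits$score[h]
    }
  }
  lens <- ends - starts
  antisense <- vapply(seq_along(starts), function(i)
    revComp(subseq0(locus_seq, starts[i], ends[i])), character(1))
  data.frame(
    am_id = sprintf("%s_%d_%d", modality, starts, lens),
    modality = modality,
    target_start = starts, target_end = ends, length = lens,
    antisense_seq = antisense,
    site_overlap_score = site,
    ese_score = eseSum / lens,          # length-normalised
    accessibility_score = acc
  )
}

#' Enumerate antisense candidates against a pseudoexon
#'
#' Generates every target window of the allowed lengths (at the configured
#' stride) over the pseudoexon plus its intronic flanks, and annotates each
#' window with the three component scores: \code{site_overlap_score} (1
#' when the window covers a splice-site core window -- the donor 9-mer or
#' acceptor 23-mer -- graded by overlap fraction otherwise),
#' \code{ese_score} (summed scores of above-threshold SC35 motif hits
#' contained in the window, length-normalised) and
#' \code{accessibility_score} (mean openness over the window).  The
#' antisense sequence of each candidate is the exact reverse complement of
#' its target span.
#'
#' @param pe one-row data.frame with \code{acceptor_pos, donor_pos} (locus
#'   coordinates of the PE span).
#' @param locus_seq locus sense-strand sequence.
#' @param modality \code{"u7"} (length bounds 18-30 by default, the
#'   modU7snRNA antisense range) or \code{"circ"} (40-150, the circRNA
#'   range).
#' @param cfg design configuration (see [pipelineDefaults()]
#'   \code{$design}).
#' @param ese_matrices ESE matrix list used for the enhancer criterion;
#'   default: the SC35-style \code{SRSF2} matrix, the preferred antisense
#'   target set.
#' @param profile optional precomputed [AccessibilityProfile-class] over
#'   the PE +/- flank region (e.g. from an external folding backend).
#' @return data.frame of [AntisenseCandidate]-style rows (see
#'   \code{annotateCandidates} fields above).
#' @export
enumerateCandidates <- function(pe, locus_seq, modality = c("u7", "circ"),
                                cfg = pipelineDefaults()$design,
                                ese_matrices = eseMatrices()["SRSF2"],
                                profile = NULL) {
  modality <- match.arg(modality)
  bounds <- if (modality == "u7") cfg$u7_length else cfg$circ_length
  flank <- cfg$flank
  regionStart <- max(0L, pe$acceptor_pos - flank)
  regionEnd <- min(nchar(locus_seq), pe$donor_pos + flank)
  regionSeq <- subseq0(locus_seq, regionStart, regionEnd)
  if (nchar(regionSeq) < bounds[1L]) {
    warning("pseudoexon region shorter than the minimum candidate length; ",
            "empty candidate set")
    return(data.frame())
  }
  if (is.null(profile)) {
    profile <- accessibilityProfile(regionSeq, cfg$pair_score,
                                    cfg$temperature)
  } else if (nchar(profile@region) != nchar(regionSeq)) {
    stop("supplied profile does not cover the PE +/- flank region")
  }
  hits <- scanESE(regionSeq, ese_matrices)
  hits$width <- vapply(hits$motif_name, function(nm)
    motifLength(ese_matrices[[match(nm, vapply(ese_matrices, motifName,
                                               character(1)))]]),
    integer(1))
  rows <- lapply(seq.int(bounds[1L], min(bounds[2L], nchar(regionSeq))),
                 function(L) {
    starts <- seq.int(regionStart, regionEnd - L, by = cfg$stride)
    annotateCandidates(starts, starts + L, pe, modality, locus_seq,
                       profile, regionStart, hits)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shift-by-k variants of a seed candidate
#'
#' Returns the seed candidate plus copies shifted k bp in both directions
#' (the rescue move for candidates suspected of self-structure or
#' processing problems), re-annotated against the same pseudoexon.
#'
#' @param candidate one-row candidate data.frame (from
#'   [enumerateCandidates()]).
#' @param pe,locus_seq,cfg,ese_matrices,profile as in
#'   [enumerateCandidates()]; the profile must cover the PE +/- flank
#'   region (it is recomputed when omitted).
#' @param k shift in bp (default 5).
#' @return data.frame of 3 candidates differing only in target interval.
#' @export
shiftCandidate <- function(candidate, pe, locus_seq,
                           cfg = pipelineDefaults()$design,
                           ese_matrices = eseMatrices()["SRSF2"],
                           profile = NULL, k = cfg$shift_k) {
  flank <- cfg$flank
  regionStart <- max(0L, pe$acceptor_pos - flank)
  regionEnd <- min(nchar(locus_seq), pe$donor_pos + flank)
  regionSeq <- subseq0(locus_seq, regionStart, regionEnd)
  if (is.null(profile))
    profile <- accessibilityProfile(regionSeq, cfg$pair_score,
                                    cfg$temperature)
  starts <- candidate$target_start + c(0L, -k, k)
  ends <- candidate$target_end + c(0L, -k, k)
  if (any(starts < regionStart) || any(ends > regionEnd))
    stop("shifted candidate leaves the PE +/- flank region")
  hits <- scanESE(regionSeq, ese_matrices)
  hits$width <- vapply(hits$motif_name, function(nm)
    motifLength(ese_matrices[[match(nm, vapply(ese_matrices, motifName,
                                               character(1)))]]),
    integer(1))
  out <- annotateCandidates(starts, ends, pe, candidate$modality,
                            locus_seq, profile, regionStart, hits)
  out$am_id <- paste0(candidate$am_id, c("", ".minus", ".plus"))
  out
}

#' Rank antisense candidates by composite score
#'
#' composite = w_site * site_overlap + w_ese * (ese / max ese) +
#' w_acc * accessibility - w_len * length penalty, where the penalty is
#' the relative excess over the modality's optimum length (25 nt for
#' modU7snRNA, 80 nt for circRNA by default; shorter candidates are not
#' penalised).  Stable sort by descending composite, ties broken by the
#' 5'-most target.
#'
#' @param candidates candidate data.frame, all of one modality.
#' @param weights named non-negative weights \code{c(site, ese, acc, len)}.
#' @param cfg design configuration (for the modality optimum).
#' @return the candidates with a \code{composite_score} column, ranked.
#' @export
rankCandidates <- function(candidates,
                           weights = pipelineDefaults()$design$weights,
                           cfg = pipelineDefaults()$design) {
  if (length(unique(candidates$modality)) != 1L)
    stop("all candidates must share one modality")
  if (any(weights < 0)) stop("ranking weights must be non-negative")
  optimum <- if (candidates$modality[1L] == "u7") cfg$u7_optimum
             else cfg$circ_optimum
  eseMax <- max(candidates$ese_score)
  eseNorm <- if (eseMax > 0) candidates$ese_score / eseMax else 0
  penalty <- pmax(0, (candidates$length - optimum) / optimum)
  candidates$composite_score <-
    weights[["site"]] * candidates$site_overlap_score +
    weights[["ese"]] * eseNorm +
    weights[["acc"]] * candidates$accessibility_score -
    weights[["len"]] * penalty
  ord <- order(-candidates$composite_score, candidates$target_start)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
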