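# Background-splicing event calling, pseudoexon grouping/naming, and
# frame/PTC consequence annotation.

#' Call background-splicing events from a junction table
#'
#' A junction is \emph{discordant} when its (start, end) pair matches no
#' annotated intron of the supplied model (an operational definition; the
#' originating RNA-seq compendium's own notion is not reproduced).
#' Discordant junctions are classified:
#' \itemize{
#'   \item two discordant junctions inside one annotated intron, the first
#'     anchored at the intron start and the second at the intron end,
#'     bracketing an unannotated segment, form a \code{pe_inclusion} event
#'     (the segment is the pseudoexon; inter-intron chimeras are rejected);
#'   \item a single junction running from one annotated donor boundary to a
#'     later acceptor boundary spans the annotated exon(s) between them and
#'     becomes an \code{exon_skip} event;
#'   \item anything else (one-sided anchors without a partner, segments
#'     lacking one splice site) is reported as a \code{cryptic_site} event,
#'     never silently dropped.
#' }
#' Events are ranked by discordant read support and truncated to
#' \code{top_k}.  The supporting-read count of a pseudoexon event is the
#' smaller of its two junction counts (a conservative molecule estimate);
#' its inclusion fraction is support / (support + concordant reads of the
#' same intron).
#'
#' @param junctions junction data.frame (see [readJunctionTable()]).
#' @param model a [GeneModel-class].
#' @param top_k number of top events to keep (default 20); \code{Inf}
#'   keeps every discordant junction in some event.
#' @param max_pe_length longest segment (bp) accepted as a pseudoexon when
#'   pairing junctions; wider left/right combinations are implausible
#'   single exons and fall back to \code{cryptic_site} evidence.
#' @return data.frame of events: \code{event_type, start, end} (pseudoexon
#'   span or skipped-region span), junction coordinates,
#'   \code{discordant_reads, inclusion_fraction, intron_id, skipped_exons}.
#' @export
callBackgroundEvents <- function(junctions, model, top_k = 20,
                                 max_pe_length = 500L) {
  if (any(junctions$start < 0L) ||
      any(junctions$end > model@sequenceLength))
    stop("junction outside the locus sequence")
  introns <- modelIntrons(model)
  ex <- modelExons(model)
  key <- function(s, e) paste(s, e)
  intronKey <- key(introns$start, introns$end)
  concordant <- junctions[key(junctions$start, junctions$end) %in%
                            intronKey, , drop = FALSE]
  disc <- junctions[!key(junctions$start, junctions$end) %in% intronKey, ,
                    drop = FALSE]
  concReads <- setNames(rep(0L, nrow(introns)), introns$intron_id)
  if (nrow(concordant)) {
    m <- match(key(concordant$start, concordant$end), intronKey)
    for (i in seq_len(nrow(concordant)))
      concReads[m[i]] <- concReads[m[i]] + concordant$read_count[i]
  }

  events <- list()
  used <- rep(FALSE, nrow(disc))
  addEvent <- function(type, start, end, j1, j2, reads, intron, skipped) {
    conc <- if (!is.na(intron)) concReads[[intron]] else 0L
    events[[length(events) + 1L]] <<- data.frame(
      event_type = type, start = start, end = end,
      j1_start = j1[1L], j1_end = j1[2L],
      j2_start = j2[1L], j2_end = j2[2L],
      discordant_reads = reads,
      inclusion_fraction = reads / (reads + conc),
      intron_id = intron, skipped_exons = skipped)
  }

  # exon skips: donor boundary of one intron to acceptor boundary of a later
  donorIdx <- match(disc$start, introns$start)
  accIdx <- match(disc$end, introns$end)
  for (i in seq_len(nrow(disc))) {
    di <- donorIdx[i]; ai <- accIdx[i]
    if (!is.na(di) && !is.na(ai) && ai > di) {
      skipped <- ex$exon_id[(di + 1L):ai]
      addEvent("exon_skip", disc$start[i], disc$end[i],
               c(disc$start[i], disc$end[i]), c(NA, NA),
               disc$read_count[i], NA_character_,
               paste(skipped, collapse = ","))
      used[i] <- TRUE
    }
  }

  # pseudoexon inclusion: left + right junction pairs within one intron
  for (k in seq_len(nrow(introns))) {
    within <- !used & disc$start >= introns$start[k] &
      disc$end <= introns$end[k]
    left <- which(within & disc$start == introns$start[k] &
                    disc$end < introns$end[k])
    right <- which(within & disc$end == introns$end[k] &
                     disc$start > introns$start[k])
    for (l in left) for (r in right) {
      if (disc$end[l] < disc$start[r] &&
          disc$start[r] - disc$end[l] <= max_pe_length) {
        addEvent("pe_inclusion", disc$end[l], disc$start[r],
                 c(disc$start[l], disc$end[l]),
                 c(disc$start[r], disc$end[r]),
                 min(disc$read_count[l], disc$read_count[r]),
                 introns$intron_id[k], NA_character_)
        used[l] <- TRUE; used[r] <- TRUE
      }
    }
  }

  # everything else: unclassifiable / one-sided segments
  for (i in which(!used)) {
    k <- which(disc$start[i] >= introns$start &
                 disc$end[i] <= introns$end)
    addEvent("cryptic_site", disc$start[i], disc$end[i],
             c(disc$start[i], disc$end[i]), c(NA, NA),
             disc$read_count[i],
             if (length(k)) introns$intron_id[k[1L]] else NA_character_,
             NA_character_)
  }

  out <- do.call(rbind, events)
  if (is.null(out)) return(invisible(data.frame()))
  out <- out[order(-out$discordant_reads, out$start), ]
  rownames(out) <- NULL
  if (is.finite(top_k)) out <- head(out, top_k)
  out
}

#' Group overlapping pseudoexon isoforms and name them
#'
#' Isoforms whose exonic spans overlap form a group (wild-type and
#' variant-activated isoforms are grouped separately; the status is an
#' input flag, not inferred).  Within a group the longest isoform takes the
#' base name -- \code{PE-k} for variant-activated groups, \code{PE-wt-k}
#' for wild-type groups, with \code{k} assigned 5' to 3' by group start --
#' and shorter isoforms are named by their alternative splice site: those
#' sharing the group acceptor get \code{_D2}, \code{_D3}, ... (alternative
#' donors) by decreasing length, those sharing the group donor get
#' \code{_A2}, \code{_A3}, ...  An isoform sharing neither boundary with
#' its group's longest is split into a new group with a warning.  Naming is
#' deterministic and invariant to the input row order.
#'
#' @param isoforms data.frame with columns \code{acceptor_pos, donor_pos}
#'   (0-based half-open span) and \code{wild_type} (logical).
#' @return the isoforms with added \code{pe_group_id, name, length},
#'   ordered by group and decreasing length.
#' @export
groupAndNamePseudoexons <- function(isoforms) {
  iso <- as.data.frame(isoforms)
  if (is.null(iso$wild_type)) iso$wild_type <- FALSE
  iso$length <- iso$donor_pos - iso$acceptor_pos
  if (any(iso$length <= 0L))
    stop("pseudoexon with non-positive length (donor must follow acceptor)")
  iso <- iso[!duplicated(iso[, c("acceptor_pos", "donor_pos",
                                 "wild_type")]), , drop = FALSE]
  iso <- iso[order(iso$acceptor_pos, iso$donor_pos), , drop = FALSE]
  rownames(iso) <- NULL

  # connected components of span overlap, per wild-type class
  groups <- list()
  for (wt in unique(iso$wild_type)) {
    sub <- which(iso$wild_type == wt)
    ir <- IRanges::IRanges(start = iso$acceptor_pos[sub] + 1L,
                           end = iso$donor_pos[sub])
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    memb <- split(sub[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov))
    # split members sharing neither boundary with the longest into new groups
    for (ids in memb) {
      while (length(ids)) {
        lens <- iso$length[ids]
        base <- ids[which.max(lens)]
        shares <- iso$acceptor_pos[ids] == iso$acceptor_pos[base] |
          iso$donor_pos[ids] == iso$donor_pos[base]
        if (!all(shares))
          warning("isoform sharing neither boundary with its group's ",
                  "longest; starting a new group")
        groups[[length(groups) + 1L]] <- ids[shares]
        ids <- ids[!shares]
      }
    }
  }

  starts <- vapply(groups, function(ids) min(iso$acceptor_pos[ids]),
                   numeric(1))
  groups <- groups[order(starts)]
  counters <- c(wt = 0L, var = 0L)
  iso$pe_group_id <- iso$name <- NA_character_
  for (ids in groups) {
    wt <- iso$wild_type[ids[1L]]
    cls <- if (wt) "wt" else "var"
    counters[cls] <- counters[cls] + 1L
    baseName <- if (wt) sprintf("PE-wt-%d", counters[cls])
                else sprintf("PE-%d", counters[cls])
    ids <- ids[order(-iso$length[ids])]
    base <- ids[1L]
    iso$pe_group_id[ids] <- baseName
    iso$name[base] <- baseName
    shareAcc <- ids[-1L][iso$acceptor_pos[ids[-1L]] ==
                           iso$acceptor_pos[base]]
    shareDon <- setdiff(ids[-1L][iso$donor_pos[ids[-1L]] ==
                                   iso$donor_pos[base]], shareAcc)
    if (length(shareAcc))
      iso$name[shareAcc] <- sprintf("%s_D%d", baseName,
                                    1L + seq_along(shareAcc))
    if (length(shareDon))
      iso$name[shareDon] <- sprintf("%s_A%d", baseName,
                                    1L + seq_along(shareDon))
  }
  ord <- order(match(iso$pe_group_id, unique(iso$pe_group_id[order(
    iso$acceptor_pos)])), -iso$length)
  iso <- iso[ord, , drop = FALSE]
  rownames(iso) <- NULL
  iso
}

# spliced transcript pieces and the transcript offset of each exon end
splicedTranscript <- function(model, locus_seq) {
  ex <- modelExons(model)
  pieces <- vapply(seq_len(nrow(ex)), function(i)
    subseq0(locus_seq, ex$start[i], ex$end[i]), character(1))
  list(seq = paste(pieces, collapse = ""),
       cumEnd = cumsum(ex$end - ex$start))
}

firstStopOffset <- function(seq, from) {
  # 0-based offset (in the sequence) of the first stop codon at or after
  # `from`, reading in frame; NA when none
  n <- nchar(seq)
  if (from > n - 3L) return(NA_integer_)
  starts <- seq.int(from, n - 3L, by = 3L)
  codons <- substring(seq, starts + 1L, starts + 3L)
  hit <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (!length(hit)) NA_integer_ else starts[hit[1L]]
}

#' Annotate the coding consequence of a pseudoexon
#'
#' Frameshift status is pure arithmetic: a pseudoexon whose length is not a
#' multiple of 3 shifts the reading frame.  Premature-termination-codon
#' (PTC) status is computed by in-silico splicing: the pseudoexon sequence
#' is inserted into the spliced mRNA at its intron position and the
#' PE-containing reading frame is scanned for a stop codon upstream of the
#' annotated terminator.
#'
#' @param pe data.frame of pseudoexon isoforms (columns \code{acceptor_pos,
#'   donor_pos}, e.g. from [groupAndNamePseudoexons()]).
#' @param model a [GeneModel-class]; must be coding for PTC annotation
#'   (non-coding mode leaves \code{introduces_ptc} undetermined).
#' @param locus_seq locus sense-strand sequence.
#' @return \code{pe} with columns \code{length, frame_consequence,
#'   introduces_ptc} filled.
#' @export
annotateConsequence <- function(pe, model, locus_seq) {
  pe <- as.data.frame(pe)
  pe$length <- pe$donor_pos - pe$acceptor_pos
  if (any(pe$length <= 0L))
    stop("degenerate pseudoexon with non-positive length")
  pe$frame_consequence <- ifelse(pe$length %% 3L != 0L, "frameshift",
                                 "in_frame")
  if (!isCoding(model)) {
    pe$introduces_ptc <- NA
    return(pe)
  }
  introns <- modelIntrons(model)
  tx <- splicedTranscript(model, locus_seq)
  ex <- modelExons(model)
  cdsOffsets <- codingPositions(model)
  cdsTx <- match(cdsOffsets[1L],
                 unlist(lapply(seq_len(nrow(ex)), function(i)
                   seq.int(ex$start[i], ex$end[i] - 1L)))) - 1L
  refStop <- firstStopOffset(tx$seq, cdsTx)

  pe$introduces_ptc <- vapply(seq_len(nrow(pe)), function(i) {
    k <- which(pe$acceptor_pos[i] >= introns$start &
                 pe$donor_pos[i] <= introns$end)
    if (!length(k))
      stop("pseudoexon [", pe$acceptor_pos[i], ",", pe$donor_pos[i],
           ") does not lie within a single intron of the model")
    insertAt <- tx$cumEnd[k[1L]]           # after the upstream exon
    peSeq <- subseq0(locus_seq, pe$acceptor_pos[i], pe$donor_pos[i])
    mutSeq <- paste0(substr(tx$seq, 1L, insertAt), peSeq,
                     substring(tx$seq, insertAt + 1L))
    mutStop <- firstStopOffset(mutSeq, cdsTx)
    refStopMapped <- if (is.na(refStop)) NA_integer_
      else refStop + if (insertAt <= refStop) pe$length[i] else 0L
    if (is.na(mutStop)) return(FALSE)
    if (is.na(refStopMapped)) return(TRUE)
    mutStop < refStopMapped
  }, logical(1))
  pe
}
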