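# Splice-site strength scoring, ESE scanning, and per-variant splice-site
# delta reports.
#
# Window conventions (maximum-entropy model standard): a donor site at
# exon/intron boundary d (0-based half-open exon end) is scored on the
# 9-mer [d-3, d+6); an acceptor site at exon start a on the 23-mer
# [a-20, a+3).

DONOR_WIDTH <- 9L
DONOR_EXONIC <- 3L     # exonic bases 5' of the boundary in the window
ACCEPTOR_WIDTH <- 23L
ACCEPTOR_INTRONIC <- 20L

siteWindowWidth <- function(kind) {
  switch(kind, donor = DONOR_WIDTH, acceptor = ACCEPTOR_WIDTH,
         stop("kind must be 'donor' or 'acceptor'"))
}

# window span [start, end) for a site at boundary position b
siteWindowSpan <- function(kind, boundary_pos) {
  if (kind == "donor")
    c(boundary_pos - DONOR_EXONIC, boundary_pos - DONOR_EXONIC + DONOR_WIDTH)
  else
    c(boundary_pos - ACCEPTOR_INTRONIC,
      boundary_pos - ACCEPTOR_INTRONIC + ACCEPTOR_WIDTH)
}

#' Score a splice-site window with a position weight matrix
#'
#' Returns the sum over positions of the log2-odds weight of the observed
#' base.  The default matrices are the packaged frequency-derived donor
#' (9-mer) and acceptor (23-mer) matrices.
#'
#' @param window_seq window sequence of exactly the matrix length,
#'   bases A/C/G/T only (no IUPAC expansion).
#' @param kind \code{"donor"} or \code{"acceptor"} (selects the default
#'   matrix).
#' @param matrix a [PWMatrix-class]; overrides \code{kind}'s default.
#' @return numeric score (log2-odds sum).
#' @examples
#' scoreSitePWM("CAGGTAAGT", "donor")
#' @export
scoreSitePWM <- function(window_seq, kind = c("donor", "acceptor"),
                         matrix = NULL) {
  if (is.null(matrix)) {
    kind <- match.arg(kind)
    matrix <- if (kind == "donor") donorPWM() else acceptorPWM()
  }
  w <- matrix@weights
  if (nchar(window_seq) != nrow(w))
    stop("window length ", nchar(window_seq),
         " does not match matrix length ", nrow(w))
  stopIfBadBases(window_seq, "window")
  bases <- strsplit(window_seq, "")[[1L]]
  sum(w[cbind(seq_len(nrow(w)), match(bases, BASES))])
}

# ---- maximum-entropy scoring (external parameter tables) -------------------

#' Load external maximum-entropy splice-site model tables
#'
#' The maximum-entropy scorer works in the published model's units but the
#' model parameter tables are not redistributed with this package; the user
#' supplies a directory containing \code{donor.tsv} and/or
#' \code{acceptor.tsv}.  Each file is a TSV with columns \code{component,
#' start, width, role, kmer, weight}: the score of a window is
#' \deqn{\sum_{num} \log_2 w(kmer) - \sum_{den} \log_2 w(kmer)}
#' over the components, where each component reads the sub-window
#' \code{[start, start+width)} (0-based within the site window).  Full-kmer
#' toy models use a single numerator component; converted published tables
#' factorise the 23-mer acceptor model into overlapping sub-window
#' components with numerator and denominator roles.  Background odds are
#' baked into the weights by the conversion.
#'
#' @param dir directory holding the table files.
#' @return named list of maxent models (one per available kind).
#' @seealso [scoreSiteMaxent()], [maxentAvailable()]
#' @export
readMaxentModel <- function(dir) {
  out <- list()
  for (kind in c("donor", "acceptor")) {
    path <- file.path(dir, paste0(kind, ".tsv"))
    if (!file.exists(path)) next
    tab <- read.delim(path, comment.char = "#",
                      colClasses = c(kmer = "character"))
    need <- c("component", "start", "width", "role", "kmer", "weight")
    if (!all(need %in% names(tab)))
      stop("maxent table ", path, " lacks required columns")
    if (!all(tab$role %in% c("num", "den")))
      stop("maxent table roles must be 'num' or 'den'")
    out[[kind]] <- list(kind = kind,
                        window = max(tab$start + tab$width),
                        components = split(tab, tab$component))
  }
  if (!length(out))
    stop("no donor.tsv or acceptor.tsv found in ", dir)
  out
}

#' @rdname readMaxentModel
#' @return \code{maxentAvailable}: TRUE when the directory supplies a table
#'   for the kind.
#' @param kind \code{"donor"} or \code{"acceptor"}.
#' @export
maxentAvailable <- function(dir, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  !is.null(dir) && file.exists(file.path(dir, paste0(kind, ".tsv")))
}

#' Maximum-entropy splice-site score from external tables
#'
#' Scores a donor 9-mer or acceptor 23-mer with a user-supplied
#' maximum-entropy model (see [readMaxentModel()]).  Without tables the
#' operation is unavailable: calling it raises an informative error, but
#' nothing fails at package load.
#'
#' @param window_seq site window sequence (9-mer for donors, 23-mer for
#'   acceptors).
#' @param kind \code{"donor"} or \code{"acceptor"}.
#' @param model a model list from [readMaxentModel()], or the directory it
#'   would be read from.
#' @return numeric score in the model's units (log2 ratio).
#' @export
scoreSiteMaxent <- function(window_seq, kind = c("donor", "acceptor"),
                            model) {
  kind <- match.arg(kind)
  if (missing(model) || is.null(model))
    stop("maximum-entropy model tables were not supplied; ",
         "provide a table directory via readMaxentModel()")
  if (is.character(model)) model <- readMaxentModel(model)
  if (is.null(model[[kind]]))
    stop("no ", kind, " table in the supplied maximum-entropy model")
  m <- model[[kind]]
  if (nchar(window_seq) != m$window)
    stop("window length ", nchar(window_seq),
         " does not match the model's window length ", m$window)
  stopIfBadBases(window_seq, "window")
  score <- 0
  for (comp in m$components) {
    sub <- subseq0(window_seq, comp$start[1L],
                   comp$start[1L] + comp$width[1L])
    hit <- match(sub, comp$kmer)
    if (is.na(hit))
      stop("k-mer ", sub, " not covered by maxent component ",
           comp$component[1L])
    term <- log2(comp$weight[hit])
    score <- score + if (comp$role[hit] == "num") term else -term
  }
  score
}

# ---- ESE scanning ----------------------------------------------------------

#' Scan a region for exonic-splicing-enhancer motif hits
#'
#' Slides every matrix over the region and reports all windows scoring at
#' or above the matrix threshold.  Hits are sorted by start, ties broken by
#' descending score and then motif name.  An empty result is valid.
#'
#' @param region_seq region sequence (A/C/G/T).
#' @param matrices list of [PWMatrix-class]; default [eseMatrices()].
#' @return data.frame with columns \code{motif_name, start, score}
#'   (\code{start} 0-based within the region).
#' @export
scanESE <- function(region_seq, matrices = eseMatrices()) {
  stopIfBadBases(region_seq, "region")
  n <- nchar(region_seq)
  if (n < max(vapply(matrices, motifLength, integer(1))))
    stop("region is shorter than the longest matrix")
  baseIdx <- match(strsplit(region_seq, "")[[1L]], BASES)
  hits <- lapply(matrices, function(m) {
    w <- m@weights
    L <- nrow(w)
    if (n < L) return(NULL)
    starts <- 0:(n - L)
    scores <- vapply(starts, function(s)
      sum(w[cbind(seq_len(L), baseIdx[(s + 1L):(s + L)])]), numeric(1))
    keep <- scores >= m@threshold - 1e-9   # tolerance at the boundary
    if (!any(keep)) return(NULL)
    data.frame(motif_name = m@motifName, start = starts[keep],
               score = scores[keep])
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(motif_name = character(), start = integer(),
                      score = numeric()))
  out <- out[order(out$start, -round(out$score, 9L), out$motif_name), ]
  rownames(out) <- NULL
  out
}

# ---- per-variant site delta ------------------------------------------------

#' Splice-site delta report for a single variant
#'
#' Scores every donor and acceptor window overlapping the variant position
#' in the reference and alternate sequence.  A window counts as a
#' reportable site only when it carries the obligate core dinucleotide (GT
#' for donors, AG for acceptors) and scores at or above the reporting
#' floor.  Windows that become reportable or change by more than the gain
#' delta are reported; the classification reflects the largest gain: a
#' window reportable only on the alternate allele is a site creation
#' (\code{donor_gain} / \code{acceptor_gain}), a gain on an
#' already-reportable window is a \code{strengthening}; losses only give
#' \code{weakening}; otherwise \code{none}.
#'
#' @param variant one-row variant data.frame (columns \code{locus_pos, ref,
#'   alt}; see [readVariantTable()]).
#' @param locus_seq locus sense-strand sequence.
#' @param scorer \code{"pwm"} (default) or a function
#'   \code{(window_seq, kind) -> score} (e.g. a maximum-entropy scorer
#'   closed over external tables).
#' @param cfg scoring configuration (see [pipelineDefaults()]
#'   \code{$scoring}): \code{report_floor}, \code{gain_delta},
#'   \code{scan_radius}.
#' @return list with elements \code{variant}, \code{gained} and \code{lost}
#'   (data.frames \code{kind, boundary_pos, ref_score, alt_score}), and
#'   \code{classification}.
#' @export
variantSiteDelta <- function(variant, locus_seq, scorer = "pwm",
                             cfg = pipelineDefaults()$scoring) {
  p <- as.integer(variant$locus_pos)
  if (p < 0L || p >= nchar(locus_seq))
    stop("variant position ", p, " lies outside the locus")
  refBase <- subseq0(locus_seq, p, p + 1L)
  if (refBase != variant$ref)
    stop("reference mismatch at locus position ", p, ": sequence has ",
         refBase, ", variant table says ", variant$ref)
  altSeq <- paste0(substr(locus_seq, 1L, p), variant$alt,
                   substr(locus_seq, p + 2L, nchar(locus_seq)))
  scoreFun <- if (is.function(scorer)) scorer
              else function(win, kind) scoreSitePWM(win, kind)

  hasCore <- function(win, kind) {
    if (kind == "donor") substr(win, DONOR_EXONIC + 1L,
                                DONOR_EXONIC + 2L) == "GT"
    else substr(win, ACCEPTOR_INTRONIC - 1L, ACCEPTOR_INTRONIC) == "AG"
  }
  rows <- list()
  for (kind in c("donor", "acceptor")) {
    L <- siteWindowWidth(kind)
    starts <- max(0L, p - L + 1L):min(p, nchar(locus_seq) - L)
    for (s in starts) {
      refWin <- subseq0(locus_seq, s, s + L)
      altWin <- subseq0(altSeq, s, s + L)
      boundary <- if (kind == "donor") s + DONOR_EXONIC
                  else s + ACCEPTOR_INTRONIC
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, boundary_pos = boundary,
        ref_score = scoreFun(refWin, kind),
        alt_score = scoreFun(altWin, kind),
        ref_site = hasCore(refWin, kind),
        alt_site = hasCore(altWin, kind))
    }
  }
  tab <- do.call(rbind, rows)
  refOk <- tab$ref_site & tab$ref_score >= cfg$report_floor
  altOk <- tab$alt_site & tab$alt_score >= cfg$report_floor
  delta <- tab$alt_score - tab$ref_score
  gained <- tab[altOk & (!refOk | delta > cfg$gain_delta) & delta > 0, ]
  lost <- tab[refOk & (!altOk | -delta > cfg$gain_delta) & delta < 0, ]
  rownames(gained) <- rownames(lost) <- NULL

  classification <- "none"
  if (nrow(gained)) {
    top <- gained[which.max(gained$alt_score - gained$ref_score), ]
    classification <- if (!(top$ref_site &&
                            top$ref_score >= cfg$report_floor))
      paste0(top$kind, "_gain") else "strengthening"
  } else if (nrow(lost)) {
    classification <- "weakening"
  }
  list(variant = variant, gained = gained, lost = lost,
       classification = classification)
}
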