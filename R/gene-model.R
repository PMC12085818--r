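#' Construct a GeneModel
#'
#' Programmatic constructor for [GeneModel-class].  Coordinates are 0-based
#' half-open on the gene sense strand of the locus sequence.
#'
#' @param locusName name of the locus.
#' @param sequenceLength length of the locus sequence (bp).
#' @param exons data.frame with columns \code{exon_id}, \code{start},
#'   \code{end}; will be sorted by start.
#' @param cdsStart locus coordinate of the first coding base (c.1), or
#'   \code{NA} for a non-coding model.
#' @param transcriptId annotated transcript identifier.
#' @return a validated [GeneModel-class].
#' @examples
#' GeneModel("toy", 2000L,
#'           data.frame(exon_id = c("E1", "E2"),
#'                      start = c(0L, 500L), end = c(100L, 700L)),
#'           cdsStart = 10L)
#' @export
GeneModel <- function(locusName, sequenceLength, exons, cdsStart = NA_integer_,
                      transcriptId = "custom") {
  exons <- data.frame(exon_id = as.character(exons$exon_id),
                      start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  model <- new("GeneModel", locusName = as.character(locusName),
               sequenceLength = as.integer(sequenceLength), exons = exons,
               cdsStart = as.integer(cdsStart),
               cdsPhase = integer(0), transcriptId = as.character(transcriptId))
  model@cdsPhase <- computeCdsPhases(model)
  validObject(model)
  model
}

# GFF-style phase (bases to skip to reach the first complete codon) at the
# start of each exon, counted from cdsStart; NA for exons upstream of the CDS.
computeCdsPhases <- function(model) {
  ex <- model@exons
  phases <- setNames(rep(NA_integer_, nrow(ex)), ex$exon_id)
  if (is.na(model@cdsStart)) return(phases)
  coding <- 0L
  for (i in seq_len(nrow(ex))) {
    if (ex$end[i] <= model@cdsStart) next
    phases[i] <- (3L - coding %% 3L) %% 3L
    from <- max(ex$start[i], model@cdsStart)
    coding <- coding + (ex$end[i] - from)
  }
  phases
}

#' Read a gene model from a BED12 or GFF3 file
#'
#' BED blocks or GFF3 \code{exon} features become the model's exons;
#' coordinates are normalised to 0-based half-open.  The BED \code{thick}
#' range or the first GFF3 \code{CDS} feature supplies the CDS start.  A
#' file without CDS information yields a model in non-coding mode, in which
#' consequence annotation is disabled.
#'
#' @param path path to the gene-model file.
#' @param format \code{"bed"} (BED12) or \code{"gff3"}.
#' @param locusName locus name recorded in the model (default: file stem).
#' @param sequenceLength locus length; defaults to the rightmost exon end.
#' @return a [GeneModel-class].
#' @export
parseGeneModel <- function(path, format = c("bed", "gff3"),
                           locusName = sub("\\.[^.]+$", "", basename(path)),
                           sequenceLength = NA_integer_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene-model file not found: ", path)
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) != 1L)
      stop("expected a single BED transcript record, found ", length(gr))
    blocks <- S4Vectors::mcols(gr)$blocks
    if (is.null(blocks) || length(blocks[[1L]]) == 0L)
      stop("BED record has no blocks (BED12 required)")
    b <- blocks[[1L]]
    chromStart <- BiocGenerics::start(gr) - 1L           # back to 0-based
    starts <- chromStart + BiocGenerics::start(b) - 1L
    ends <- starts + BiocGenerics::width(b)
    thick <- S4Vectors::mcols(gr)$thick
    cds <- NA_integer_
    if (!is.null(thick) && BiocGenerics::width(thick)[1L] > 0L)
      cds <- BiocGenerics::start(thick)[1L] - 1L
    exons <- data.frame(exon_id = paste0("E", seq_along(starts)),
                        start = starts, end = ends)
    txid <- if (!is.null(gr$name) && !is.na(gr$name[1L])) gr$name[1L]
            else locusName
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    exf <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(exf) == 0L) stop("GFF3 file contains no exon features")
    exf <- exf[order(BiocGenerics::start(exf))]
    ids <- if (!is.null(exf$ID) && !anyNA(exf$ID)) as.character(exf$ID)
           else paste0("E", seq_along(exf))
    exons <- data.frame(exon_id = ids,
                        start = BiocGenerics::start(exf) - 1L,
                        end = BiocGenerics::end(exf))
    cdf <- gr[tolower(as.character(gr$type)) == "cds"]
    cds <- if (length(cdf)) min(BiocGenerics::start(cdf)) - 1L
           else NA_integer_
    txf <- gr[tolower(as.character(gr$type)) %in% c("mrna", "transcript")]
    txid <- if (length(txf) && !is.null(txf$ID)) as.character(txf$ID[1L])
            else locusName
  }
  if (is.na(sequenceLength)) sequenceLength <- max(exons$end)
  if (is.na(cds))
    message("no CDS found in ", basename(path),
            "; model is in non-coding mode (consequence annotation disabled)")
  GeneModel(locusName, sequenceLength, exons, cdsStart = cds,
            transcriptId = txid)
}

#' Write a gene model as GFF3
#'
#' Emits gene/mRNA/exon (and CDS, for coding models) features, 1-based
#' closed, in the locus coordinate system.  Round-trips through
#' [parseGeneModel()].
#'
#' @param model a [GeneModel-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModelGFF3 <- function(model, path) {
  ex <- model@exons
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", model@locusName,
                     model@sequenceLength), con)
  row <- function(type, start, end, attrs, phase = ".")
    sprintf("%s\tpseudosplice\t%s\t%d\t%d\t.\t+\t%s\t%s",
            model@locusName, type, start + 1L, end, phase, attrs)
  lines <- c(
    row("gene", min(ex$start), max(ex$end),
        sprintf("ID=%s_gene", model@locusName)),
    row("mRNA", min(ex$start), max(ex$end),
        sprintf("ID=%s;Parent=%s_gene", model@transcriptId,
                model@locusName)),
    vapply(seq_len(nrow(ex)), function(i)
      row("exon", ex$start[i], ex$end[i],
          sprintf("ID=%s;Parent=%s", ex$exon_id[i], model@transcriptId)),
      character(1))
  )
  if (isCoding(model)) {
    cdsEx <- ex[ex$end > model@cdsStart, , drop = FALSE]
    lines <- c(lines, vapply(seq_len(nrow(cdsEx)), function(i)
      row("CDS", max(cdsEx$start[i], model@cdsStart), cdsEx$end[i],
          sprintf("ID=cds_%s;Parent=%s", cdsEx$exon_id[i],
                  model@transcriptId),
          phase = as.character(model@cdsPhase[[cdsEx$exon_id[i]]])),
      character(1)))
  }
  writeLines(lines, con)
  invisible(path)
}

# ordered locus positions of coding exonic bases (c.1, c.2, ...)
codingPositions <- function(model) {
  if (!isCoding(model))
    stop("gene model is in non-coding mode: no CDS coordinates")
  ex <- model@exons
  unlist(lapply(seq_len(nrow(ex)), function(i) {
    if (ex$end[i] <= model@cdsStart) return(integer(0))
    seq.int(max(ex$start[i], model@cdsStart), ex$end[i] - 1L)
  }), use.names = FALSE)
}

#' Convert CDS coordinate to locus coordinate
#'
#' @param model a coding [GeneModel-class].
#' @param n CDS position (c.\code{n}, 1-based over the spliced CDS).
#' @return 0-based locus coordinate of that exonic base.
#' @export
cdsToLocus <- function(model, n) {
  pos <- codingPositions(model)
  if (any(n < 1L | n > length(pos)))
    stop("CDS position outside the model's coding sequence: c.", n[1L])
  pos[n]
}

#' Convert an intronic HGVS-like c. description to a locus coordinate
#'
#' Supports the intronic-offset SNV subset \code{c.N+M} / \code{c.N-M}
#' (an optional \code{ref>alt} suffix is tolerated and ignored); anything
#' else is rejected.  \code{c.N-M} is M bases upstream of the exonic base at
#' CDS position N; \code{c.N+M} is M bases downstream.
#'
#' @param hgvs_c HGVS-like string, e.g. \code{"c.121-210C>T"}.
#' @param model a coding [GeneModel-class].
#' @return 0-based locus coordinate (integer).
#' @seealso [locusToHgvs()], its inverse for intronic positions.
#' @export
hgvsToLocus <- function(hgvs_c, model) {
  m <- regmatches(hgvs_c,
         regexec("^c\\.(\\d+)([+-])(\\d+)(?:[ACGT]>[ACGT])?$", hgvs_c))[[1L]]
  if (length(m) == 0L)
    stop("unsupported HGVS description (only intronic-offset c.N+M / c.N-M ",
         "SNVs are handled): ", hgvs_c)
  n <- as.integer(m[2L]); sign <- m[3L]; off <- as.integer(m[4L])
  if (off < 1L)
    stop("intronic offset must be >= 1 in ", hgvs_c)
  anchor <- cdsToLocus(model, n)
  pos <- if (sign == "+") anchor + off else anchor - off
  if (pos < 0L || pos >= model@sequenceLength)
    stop(hgvs_c, " falls outside the locus sequence")
  ex <- model@exons
  if (any(pos >= ex$start & pos < ex$end))
    stop(hgvs_c, " resolves to an exonic base (not intronic)")
  pos
}

#' Convert an intronic locus coordinate to HGVS-like c. notation
#'
#' The description is anchored to the nearer exon boundary (the 5' boundary
#' wins ties), matching the usual HGVS convention for intronic positions.
#' Mutual inverse of [hgvsToLocus()] for every intronic position.
#'
#' @param pos 0-based intronic locus coordinate.
#' @param model a coding [GeneModel-class].
#' @return character scalar like \code{"c.120+1336"}.
#' @export
locusToHgvs <- function(pos, model) {
  ex <- model@exons
  if (any(pos >= ex$start & pos < ex$end))
    stop("position ", pos, " is exonic, not intronic")
  prev <- which(ex$end <= pos)
  nxt <- which(ex$start > pos)
  if (length(prev) == 0L || length(nxt) == 0L)
    stop("position ", pos, " lies outside the intron space of the model")
  prevEnd <- ex$end[max(prev)]
  nextStart <- ex$start[min(nxt)]
  dPlus <- pos - (prevEnd - 1L)
  dMinus <- nextStart - pos
  coding <- codingPositions(model)
  if (dPlus <= dMinus) {
    n <- match(prevEnd - 1L, coding)
    if (is.na(n)) stop("flanking exonic base is not in the CDS")
    sprintf("c.%d+%d", n, dPlus)
  } else {
    n <- match(nextStart, coding)
    if (is.na(n)) stop("flanking exonic base is not in the CDS")
    sprintf("c.%d-%d", n, dMinus)
  }
}
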