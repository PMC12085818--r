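# Packaged synthetic demo locus: a 14-exon toy gene emulating the splicing
# landscape the pipeline targets -- canonical exons of varying strength,
# low-level wild-type pseudoexons, and deep-intronic variants that create
# or strengthen pseudoexon splice sites.  All coordinates are internally
# consistent toy values; pseudoexon lengths, variant names, SpliceAI delta
# scores, and population frequencies follow the published per-variant
# facts they emulate.  The sequence is fully deterministic: intron
# background comes from a fixed linear-congruential stream and every
# planted splice-site window is derived from the packaged weight matrices
# by a deterministic greedy tuner, so no RNG state is touched.

# Greedy tuner: mutate a region so each window scores close to its target.
# windows: list of list(start (0-based in region), pwm, target).
# fixed: integer positions (0-based) that must not be touched.
tuneRegion <- function(region, windows, fixed = integer(0),
                       tolerance = 0.35, max_iter = 200L) {
  chars <- strsplit(region, "")[[1L]]
  scoreWin <- function(w) {
    idx <- match(chars[(w$start + 1L):(w$start + motifLength(w$pwm))],
                 BASES)
    sum(motifWeights(w$pwm)[cbind(seq_len(motifLength(w$pwm)), idx)])
  }
  objective <- function() {
    sum(vapply(windows, function(w) {
      s <- scoreWin(w)
      if (isTRUE(w$le)) max(0, s - w$target)^2
      else max(0, abs(s - w$target) - tolerance)^2
    }, numeric(1)))
  }
  editable <- setdiff(
    sort(unique(unlist(lapply(windows, function(w)
      w$start:(w$start + motifLength(w$pwm) - 1L))))), fixed)
  best <- objective()
  for (iter in seq_len(max_iter)) {
    if (best <= 0) break
    improved <- FALSE
    for (p in editable) {
      cur <- chars[p + 1L]
      for (b in BASES) {
        if (b == cur) next
        chars[p + 1L] <- b
        val <- objective()
        if (val < best - 1e-9) {
          best <- val
          cur <- b
          improved <- TRUE
        } else {
          chars[p + 1L] <- cur
        }
      }
    }
    if (!improved) break
  }
  paste(chars, collapse = "")
}

# Disrupt decoy splice-site windows in the intronic background (real
# introns are depleted of such decoys by selection; the fixture enforces
# it so the registered site set is the planted one).  Windows overlapping
# `protect` intervals or touching exons keep those bases; elsewhere a
# decoy is weakened by writing C at its highest-leverage position.  C is
# the one base that can seed neither a GT donor core nor an AG acceptor,
# and a kill never rewrites an existing C, so the pass loop converges
# monotonically (an all-C window scores far below any floor under both
# matrices).
depleteLatentSites <- function(locus, model, floor, protect) {
  ex <- modelExons(model)
  for (pass in 1:60) {
    reg <- scanLatentSites(locus, 0L, nchar(locus), floor)
    if (!nrow(reg)) break
    hit <- FALSE
    chars <- strsplit(locus, "")[[1L]]
    inProtected <- rep(FALSE, length(chars))
    for (p in protect)
      if (p[2L] > p[1L]) inProtected[(p[1L] + 1L):p[2L]] <- TRUE
    for (i in seq_len(nrow(reg))) {
      span <- siteWindowSpan(reg$kind[i], reg$boundary_pos[i])
      if (any(ex$start < span[2L] & ex$end > span[1L])) next
      w <- motifWeights(if (reg$kind[i] == "donor") donorPWM()
                        else acceptorPWM())
      pos <- (span[1L] + 1L):span[2L]               # 1-based
      free <- which(!inProtected[pos])
      if (!length(free)) next
      repeat {
        win <- chars[pos]
        cur <- w[cbind(seq_along(win), match(win, BASES))]
        if (sum(cur) < floor - 2) break
        drop <- cur[free] - w[free, "C"]
        if (max(drop) <= 0) break
        chars[pos[free[which.max(drop)]]] <- "C"
        hit <- TRUE
      }
    }
    locus <- paste(chars, collapse = "")
    if (!hit) break
  }
  locus
}

# deterministic stop-free CDS (no in-frame stop until the terminator)
detCds <- function(nCodons, seed) {
  codons <- character(nCodons)
  state <- seed
  i <- 1L
  while (i <= nCodons) {
    state <- (state * 48271) %% 2147483647
    cod <- paste0(BASES[(state %/% c(1L, 4L, 16L)) %% 4L + 1L],
                  collapse = "")
    if (cod %in% c("TAA", "TAG", "TGA")) next
    codons[i] <- cod
    i <- i + 1L
  }
  paste(codons, collapse = "")
}

# stop codons in all three frames, planted inside pseudoexon bodies
# (G-free on purpose: it can seed neither an AG acceptor nor a GT donor)
ALL_FRAME_STOPS <- "TAACTAACTAAC"

demoCache <- new.env(parent = emptyenv())

#' The packaged synthetic demo locus
#'
#' Builds (deterministically) a 14-exon toy gene on a ~14.5 kb locus whose
#' intronic landscape emulates the pseudoexon biology the pipeline
#' addresses: a pseudoexon-dense intron 1 carrying a wild-type PE with two
#' alternative donors (223 and 170 bp isoforms), a long intron 4 with a
#' cluster of weak pseudoexon acceptors, a short pseudoexon in intron 8,
#' and a polypyrimidine-tract-controlled pseudoexon in intron 9; weak
#' canonical exons are represented through skipping propensities in the
#' simulator.  Deep-intronic variants in [demoVariantTable()] create or
#' strengthen donor/acceptor sites at these cassettes.
#'
#' @return list with \code{model} (a [GeneModel-class]), \code{sequence}
#'   (locus sense strand), and \code{features} (named list of planted
#'   feature coordinates).
#' @export
demoLocus <- function() {
  if (!is.null(demoCache$locus)) return(demoCache$locus)
  cdsLen <- c(120L, 126L, 99L, 77L, 133L, 87L, 108L, 148L, 104L, 99L,
              93L, 90L, 96L, 75L)
  intronLen <- c(2800L, 400L, 350L, 2600L, 500L, 420L, 380L, 600L,
                 3200L, 450L, 380L, 420L, 350L)
  utr5 <- 60L; utr3 <- 90L
  cds <- detCds(sum(cdsLen) / 3L, 101L)
  pieces <- substring(cds, cumsum(c(0L, head(cdsLen, -1L))) + 1L,
                      cumsum(cdsLen))
  exonSeq <- pieces
  exonSeq[1L] <- paste0(detSeq(utr5, 21L), pieces[1L])
  exonSeq[14L] <- paste0(pieces[14L], "TAA", detSeq(utr3, 22L))

  canonicalTail <- "TTCCTTTCTTTCCTTCACAG"      # acceptor: PPT + AG
  intronSeq <- vapply(seq_along(intronLen), function(i) {
    mid <- detSeq(intronLen[i] - 6L - 20L, 30L + i)
    paste0("GTAAGT", mid, canonicalTail)
  }, character(1))

  seqParts <- character(27L)
  seqParts[seq(1L, 27L, 2L)] <- exonSeq
  seqParts[seq(2L, 26L, 2L)] <- intronSeq
  locus <- paste(seqParts, collapse = "")

  exonWidth <- nchar(exonSeq)
  starts <- cumsum(c(0L, head(exonWidth + c(intronLen, 0L), -1L)))
  exons <- data.frame(exon_id = paste0("E", 1:14),
                      start = starts, end = starts + exonWidth)
  model <- GeneModel("demo_locus", nchar(locus), exons, cdsStart = utr5,
                     transcriptId = "DEMO-TX-1")

  e1e <- exons$end[1L]; e2s <- exons$start[2L]
  e4e <- exons$end[4L]; e5s <- exons$start[5L]
  e9s <- exons$start[9L]; e10s <- exons$start[10L]

  don <- donorPWM(); acc <- acceptorPWM()

  # strip decoy splice sites from the raw intronic background first
  locus <- depleteLatentSites(locus, model, floor = -1, protect = list())

  protectList <- list()
  protect <- function(s, e) protectList[[length(protectList) + 1L]] <<- c(s, e)
  plant <- function(locus, at, str) {
    protect(at, at + nchar(str))
    substr(locus, at + 1L, at + nchar(str)) <- str
    locus
  }

  # Tune a cassette of splice-site windows in place.  Each site is
  # list(boundary, kind, target, fixed = list(list(window_offset, base))).
  # Besides hitting the targets, every same-kind boundary within
  # `suppress` bp of a planted one and every opposite-kind window inside
  # the cassette region is pushed below the registry floor, so the
  # cassette contributes exactly the intended sites; windows covering a
  # `hot` position (a variant base that will gain score on the alternate
  # allele) are pushed further down.
  tuneCassette <- function(locus, sites, suppress = 6L, hot = integer(0),
                           extraFixed = list()) {
    spans <- lapply(sites, function(st)
      siteWindowSpan(st$kind, st$boundary))
    regionSpan <- c(min(vapply(spans, `[`, numeric(1), 1L)) - suppress,
                    max(vapply(spans, `[`, numeric(1), 2L)) + suppress)
    region <- subseq0(locus, regionSpan[1L], regionSpan[2L])
    fixedPos <- integer(0)
    applyFixed <- function(fx, base0) {
      for (fb in fx) {
        pos <- base0 + fb[[1L]]
        substr(region, pos + 1L, pos + 1L) <<- fb[[2L]]
        fixedPos <<- c(fixedPos, pos)
      }
    }
    windows <- list()
    mainBoundaries <- list(donor = integer(0), acceptor = integer(0))
    for (i in seq_along(sites)) {
      st <- sites[[i]]
      base0 <- spans[[i]][1L] - regionSpan[1L]
      # obligate core dinucleotide of the planted site (a user-supplied
      # fixed base at the same offset wins)
      core <- if (st$kind == "donor")
        list(list(3L, "G"), list(4L, "T"))
      else
        list(list(18L, "A"), list(19L, "G"))
      userOffsets <- if (is.null(st$fixed)) numeric(0)
                     else vapply(st$fixed, `[[`, numeric(1), 1L)
      core <- Filter(function(fb) !fb[[1L]] %in% userOffsets, core)
      applyFixed(c(st$fixed, core), base0)
      windows[[length(windows) + 1L]] <-
        list(start = base0, pwm = if (st$kind == "donor") don else acc,
             target = st$target)
      mainBoundaries[[st$kind]] <- c(mainBoundaries[[st$kind]],
                                     st$boundary)
    }
    applyFixed(extraFixed, -regionSpan[1L])
    # suppression windows
    addSuppression <- function(boundary, kind) {
      if (boundary %in% mainBoundaries[[kind]]) return()
      sp <- siteWindowSpan(kind, boundary)
      if (sp[1L] < regionSpan[1L] || sp[2L] > regionSpan[2L]) return()
      isHot <- length(hot) && any(hot >= sp[1L] & hot < sp[2L])
      windows[[length(windows) + 1L]] <<-
        list(start = sp[1L] - regionSpan[1L],
             pwm = if (kind == "donor") don else acc,
             target = if (isHot) -4.6 else -1.6, le = TRUE)
    }
    for (i in seq_along(sites))
      for (k in setdiff(-suppress:suppress, 0L))
        addSuppression(sites[[i]]$boundary + k, sites[[i]]$kind)
    for (kind in c("donor", "acceptor")) {
      W <- siteWindowWidth(kind)
      off <- if (kind == "donor") DONOR_EXONIC else ACCEPTOR_INTRONIC
      for (b in (regionSpan[1L] + off):(regionSpan[2L] - W + off))
        if (!b %in% unlist(lapply(sites, function(st)
              if (st$kind == kind) st$boundary)))
          addSuppression(b, kind)
    }
    region <- tuneRegion(region, windows, fixed = fixedPos)
    substr(locus, regionSpan[1L] + 1L, regionSpan[2L]) <- region
    for (sp in spans) protect(sp[1L], sp[2L])
    locus
  }

  f <- list()

  ## intron 1: wild-type PE (223/170 bp) + variant-created donors
  f$pe1_acceptor <- e1e + 1235L      # strong acceptor (used by PE-1)
  f$pe1_donor <- e1e + 1335L         # created by the A>G variant at +1
  f$pewt4_acceptor <- e2s - 370L
  f$pewt4_d2 <- e2s - 200L           # 170 bp isoform donor
  f$pewt4_d1 <- e2s - 147L           # 223 bp isoform donor (weak in wt)
  f$pe2_acceptor <- f$pewt4_acceptor
  f$pe2_donor <- e2s - 211L          # created by the C>T variant at +2

  locus <- tuneCassette(locus, list(
    list(boundary = f$pe1_acceptor, kind = "acceptor", target = 8)))
  # donor tuned to +8 with the alternate G at +1; wild type carries ref A
  locus <- tuneCassette(locus, list(
    list(boundary = f$pe1_donor, kind = "donor", target = 8,
         fixed = list(list(3L, "G"), list(1L, "C")))),
    hot = f$pe1_donor)
  locus <- plant(locus, f$pe1_donor, "A")
  locus <- tuneCassette(locus, list(
    list(boundary = f$pewt4_acceptor, kind = "acceptor", target = 4)))
  locus <- tuneCassette(locus, list(
    list(boundary = f$pewt4_d2, kind = "donor", target = 1.5,
         fixed = list(list(1L, "C")))))
  # weak wild-type donor of the 223 bp isoform; ref G at -2 is the base
  # the G>A variant strengthens
  locus <- tuneCassette(locus, list(
    list(boundary = f$pewt4_d1, kind = "donor", target = -0.8,
         fixed = list(list(1L, "G")))),
    hot = f$pewt4_d1 - 2L)
  # donor created by the C>T variant: tuned with alt T at +2, ref C planted
  locus <- tuneCassette(locus, list(
    list(boundary = f$pe2_donor, kind = "donor", target = 7.5,
         fixed = list(list(4L, "T"), list(1L, "C"), list(6L, "A")))),
    hot = f$pe2_donor + 1L)
  locus <- plant(locus, f$pe2_donor + 1L, "C")
  locus <- plant(locus, f$pewt4_acceptor + 40L, ALL_FRAME_STOPS)

  ## intron 4: acceptor cluster (PE-4 group) + PE-5 pair
  f$pe4_donor <- e4e + 931L          # created by the G>T variant at +2
  f$pe4_acceptors <- f$pe4_donor - c(307L, 290L, 268L, 246L)
  f$pe5_donor <- e5s - 863L          # created by the C>T variant at +2
  f$pe5_acceptors <- f$pe5_donor - c(160L, 89L)

  targets4 <- c(0.3, 1.5, 1.8, 2.2)
  locus <- tuneCassette(locus, lapply(seq_along(targets4), function(i)
    list(boundary = f$pe4_acceptors[i], kind = "acceptor",
         target = targets4[i])))
  locus <- tuneCassette(locus, list(
    list(boundary = f$pe4_donor, kind = "donor", target = 7.5,
         fixed = list(list(4L, "T"), list(1L, "C")))),
    hot = f$pe4_donor + 1L)
  locus <- plant(locus, f$pe4_donor + 1L, "G")
  locus <- plant(locus, f$pe4_acceptors[1L] + 30L, ALL_FRAME_STOPS)

  locus <- tuneCassette(locus, list(
    list(boundary = f$pe5_acceptors[1L], kind = "acceptor", target = 1.0)))
  locus <- tuneCassette(locus, list(
    list(boundary = f$pe5_acceptors[2L], kind = "acceptor", target = 0.6)))
  locus <- tuneCassette(locus, list(
    list(boundary = f$pe5_donor, kind = "donor", target = 8,
         fixed = list(list(4L, "T"), list(1L, "C")))),
    hot = f$pe5_donor + 1L)
  locus <- plant(locus, f$pe5_donor + 1L, "C")
  locus <- plant(locus, f$pe5_acceptors[1L] + 25L, ALL_FRAME_STOPS)

  ## intron 8: 53 bp pseudoexon
  f$pe6_donor <- e9s - 167L          # created by the A>G variant at +1
  f$pe6_acceptor <- f$pe6_donor - 53L
  locus <- tuneCassette(locus, list(
    list(boundary = f$pe6_acceptor, kind = "acceptor", target = 2.0)))
  locus <- tuneCassette(locus, list(
    list(boundary = f$pe6_donor, kind = "donor", target = 8,
         fixed = list(list(3L, "G"), list(1L, "C")))),
    hot = f$pe6_donor)
  locus <- plant(locus, f$pe6_donor, "A")
  locus <- plant(locus, f$pe6_acceptor + 20L, ALL_FRAME_STOPS)

  ## intron 9: polypyrimidine-tract-controlled pseudoexon (376 bp)
  p6 <- e10s - 1570L                 # the G>T PPT variant position
  f$ppt_variant <- p6
  f$pewt6_acceptor <- p6 + 16L       # 376 bp isoform
  f$pewt6_alt_acceptors <- c(p6 + 9L, p6 + 3L)   # lifted by the variant
  f$pewt6_donor <- f$pewt6_acceptor + 376L
  f$pe8_donor <- e10s - 1397L        # created by the A>G variant at +1
  # three overlapping acceptor windows share the polypyrimidine tract
  # carrying the variant; tuned jointly, with the base 5prime of the
  # variant pinned to T so the G>T change cannot seed a GT donor
  locus <- tuneCassette(locus, list(
    list(boundary = f$pewt6_acceptor, kind = "acceptor", target = 0.6),
    list(boundary = f$pewt6_alt_acceptors[1L], kind = "acceptor",
         target = -0.9),
    list(boundary = f$pewt6_alt_acceptors[2L], kind = "acceptor",
         target = -1.5)),
    hot = p6,
    extraFixed = list(list(p6, "G"), list(p6 - 1L, "T")))
  locus <- tuneCassette(locus, list(
    list(boundary = f$pewt6_donor, kind = "donor", target = 6,
         fixed = list(list(1L, "C")))))
  locus <- tuneCassette(locus, list(
    list(boundary = f$pe8_donor, kind = "donor", target = 8,
         fixed = list(list(3L, "G"), list(1L, "C")))),
    hot = f$pe8_donor)
  locus <- plant(locus, f$pe8_donor, "A")
  locus <- plant(locus, f$pewt6_acceptor + 60L, ALL_FRAME_STOPS)

  ## reference bases of the co-located candidate variants
  duds <- list(list(e1e + 699L, "A"), list(e2s - 500L, "C"),
               list(e2s - 700L, "G"), list(e4e + 499L, "A"),
               list(e5s - 400L, "C"), list(e10s - 900L, "A"),
               list(e10s - 800L, "G"))
  for (d in duds) locus <- plant(locus, d[[1L]], d[[2L]])

  # second pass: remove any decoys introduced around the planted features
  locus <- depleteLatentSites(locus, model, floor = -1,
                              protect = protectList)

  demoCache$locus <- list(model = model, sequence = locus, features = f)
  demoCache$locus
}

#' The packaged 15-variant demo table
#'
#' The deep-intronic candidate set the selection cascade was built
#' against: eight variants with the published SpliceAI delta scores and
#' per-variant facts (six of them high-score, DS >= 0.5), plus seven
#' co-located variants with medium scores (two of which carry published
#' scores).  The common variant \code{c.121-210C>T} carries its 3%
#' population frequency and is the one allow-listed frequency exception.
#' Variants without published values carry synthetic fill-ins chosen to
#' satisfy the stated group structure.
#'
#' @param model the demo [GeneModel-class] (from [demoLocus()]).
#' @return validated, locus-placed variant data.frame.
#' @export
demoVariantTable <- function(model = demoLocus()$model) {
  tab <- rbind(
    # the eight minigene-confirmed variants (published delta scores)
    data.frame(hgvs_c = "c.120+1336A>G", ref = "A", alt = "G",
               ds_ag = 0.04, ds_al = 0.02, ds_dg = 0.53, ds_dl = 0.01,
               maf = 2e-04, source = "DB"),
    data.frame(hgvs_c = "c.121-210C>T", ref = "C", alt = "T",
               ds_ag = 0.02, ds_al = 0.01, ds_dg = 0.63, ds_dl = 0.02,
               maf = 0.03, source = "P"),
    data.frame(hgvs_c = "c.121-149G>A", ref = "G", alt = "A",
               ds_ag = 0.01, ds_al = 0.01, ds_dg = 0.32, ds_dl = 0.03,
               maf = 1e-05, source = "DB"),
    data.frame(hgvs_c = "c.422+933G>T", ref = "G", alt = "T",
               ds_ag = 0.03, ds_al = 0.01, ds_dg = 0.49, ds_dl = 0.01,
               maf = 1e-05, source = "DB"),
    data.frame(hgvs_c = "c.423-862C>T", ref = "C", alt = "T",
               ds_ag = 0.05, ds_al = 0.02, ds_dg = 0.91, ds_dl = 0.02,
               maf = NA_real_, source = "P"),
    data.frame(hgvs_c = "c.899-167A>G", ref = "A", alt = "G",
               ds_ag = 0.02, ds_al = 0.01, ds_dg = 0.79, ds_dl = 0.01,
               maf = NA_real_, source = "P"),
    data.frame(hgvs_c = "c.1003-1570G>T", ref = "G", alt = "T",
               ds_ag = 0.54, ds_al = 0.03, ds_dg = 0.02, ds_dl = 0.01,
               maf = NA_real_, source = "P"),
    data.frame(hgvs_c = "c.1003-1397A>G", ref = "A", alt = "G",
               ds_ag = 0.04, ds_al = 0.01, ds_dg = 0.88, ds_dl = 0.02,
               maf = NA_real_, source = "DB"),
    # seven co-located candidates without minigene confirmation
    # (synthetic scores: two high, five medium)
    data.frame(hgvs_c = "c.120+700A>G", ref = "A", alt = "G",
               ds_ag = 0.02, ds_al = 0.01, ds_dg = 0.55, ds_dl = 0.01,
               maf = 5e-05, source = "DB"),
    data.frame(hgvs_c = "c.121-500C>T", ref = "C", alt = "T",
               ds_ag = 0.31, ds_al = 0.01, ds_dg = 0.02, ds_dl = 0.01,
               maf = 1e-04, source = "DB"),
    data.frame(hgvs_c = "c.121-700G>A", ref = "G", alt = "A",
               ds_ag = 0.01, ds_al = 0.02, ds_dg = 0.27, ds_dl = 0.01,
               maf = NA_real_, source = "DB"),
    data.frame(hgvs_c = "c.422+500A>G", ref = "A", alt = "G",
               ds_ag = 0.01, ds_al = 0.01, ds_dg = 0.61, ds_dl = 0.02,
               maf = 2e-05, source = "DB"),
    data.frame(hgvs_c = "c.423-400C>T", ref = "C", alt = "T",
               ds_ag = 0.28, ds_al = 0.01, ds_dg = 0.03, ds_dl = 0.01,
               maf = NA_real_, source = "DB"),
    data.frame(hgvs_c = "c.1003-900A>G", ref = "A", alt = "G",
               ds_ag = 0.44, ds_al = 0.02, ds_dg = 0.02, ds_dl = 0.01,
               maf = 1e-04, source = "DB"),
    data.frame(hgvs_c = "c.1003-800G>T", ref = "G", alt = "T",
               ds_ag = 0.23, ds_al = 0.01, ds_dg = 0.01, ds_dl = 0.02,
               maf = NA_real_, source = "DB")
  )
  validateVariants(tab, model)
}

#' Snaptron-style background-splicing junction table for the demo locus
#'
#' 118 junction rows: concordant reads over every annotated intron,
#' junction pairs for nine wild-type pseudoexon groups (the fourth is the
#' 223/170 bp alternative-donor pair), single junctions skipping the weak
#' canonical exons 2, 5, 9 and 13, and low-read cryptic noise -- so the
#' twenty strongest-supported events are the pseudoexons and exon skips.
#'
#' @param model the demo [GeneModel-class].
#' @return junction data.frame (columns start, end, read_count,
#'   sample_count).
#' @export
demoJunctionTable <- function(model = demoLocus()$model) {
  demo <- demoLocus()
  f <- demo$features
  ex <- modelExons(model)
  introns <- modelIntrons(model)
  e1e <- ex$end[1L]; e4e <- ex$end[4L]
  e10e <- ex$end[10L]; e11e <- ex$end[11L]; e12e <- ex$end[12L]

  peJunctions <- function(intron, a, d, reads) {
    rbind(data.frame(start = introns$start[intron], end = a,
                     read_count = reads, sample_count = reads %/% 2L),
          data.frame(start = d, end = introns$end[intron],
                     read_count = reads, sample_count = reads %/% 2L))
  }
  rows <- rbind(
    # concordant junctions over annotated introns
    data.frame(start = introns$start, end = introns$end,
               read_count = 900L - 17L * seq_len(nrow(introns)),
               sample_count = 400L),
    # nine wild-type pseudoexon groups, 5' to 3'
    peJunctions(1L, e1e + 150L, e1e + 400L, 64L),      # PE-wt-1
    peJunctions(1L, e1e + 560L, e1e + 680L, 57L),      # PE-wt-2
    peJunctions(1L, f$pe1_acceptor, f$pe1_acceptor + 80L, 71L), # PE-wt-3
    data.frame(start = introns$start[1L], end = f$pewt4_acceptor,
               read_count = 88L, sample_count = 40L),  # PE-wt-4 acceptor
    data.frame(start = f$pewt4_d1, end = introns$end[1L],
               read_count = 52L, sample_count = 22L),  # 223 bp donor
    data.frame(start = f$pewt4_d2, end = introns$end[1L],
               read_count = 86L, sample_count = 40L),  # 170 bp donor
    peJunctions(4L, e4e + 1200L, e4e + 1500L, 49L),    # PE-wt-5
    peJunctions(9L, f$pewt6_acceptor, f$pewt6_donor, 66L), # PE-wt-6
    peJunctions(10L, e10e + 150L, e10e + 270L, 41L),   # PE-wt-7
    peJunctions(11L, e11e + 100L, e11e + 200L, 38L),   # PE-wt-8
    peJunctions(12L, e12e + 120L, e12e + 240L, 35L),   # PE-wt-9
    # skipping of the weak canonical exons 2, 5, 9, 13
    data.frame(start = ex$end[1L], end = ex$start[3L],
               read_count = 120L, sample_count = 60L),
    data.frame(start = ex$end[4L], end = ex$start[6L],
               read_count = 95L, sample_count = 48L),
    data.frame(start = ex$end[8L], end = ex$start[10L],
               read_count = 90L, sample_count = 45L),
    data.frame(start = ex$end[12L], end = ex$start[14L],
               read_count = 47L, sample_count = 20L)
  )
  # low-read cryptic noise up to 118 rows
  nNoise <- 118L - nrow(rows)
  state <- 77L
  noise <- lapply(seq_len(nNoise), function(i) {
    state <<- (state * 48271) %% 2147483647
    k <- state %% nrow(introns) + 1L
    state <<- (state * 48271) %% 2147483647
    off <- state %% max(1L, introns$end[k] - introns$start[k] - 80L)
    data.frame(start = introns$start[k] + off,
               end = introns$start[k] + off + 35L + state %% 30L,
               read_count = 1L + state %% 5L, sample_count = 1L)
  })
  out <- rbind(rows, do.call(rbind, noise))
  rownames(out) <- NULL
  out
}

demoRegions <- function(model = demoLocus()$model) {
  ex <- modelExons(model)
  list(
    r1 = c(ex$start[1L], ex$end[2L]),    # exons 1-2 + intron 1
    r4 = c(ex$start[4L], ex$end[5L]),    # exons 4-5 + intron 4
    r8 = c(ex$start[8L], ex$end[9L]),    # exons 8-9 + intron 8
    r9 = c(ex$end[9L], ex$end[10L])      # intron 9 + exon 10
  )
}

demoRegionOf <- function(hgvs) {
  n <- as.integer(sub("^c\\.(\\d+).*", "\\1", hgvs))
  if (n <= 121L) "r1" else if (n <= 423L) "r4"
  else if (n <= 899L) "r8" else "r9"
}

demoSkipPropensity <- c(E2 = 0.10, E5 = 0.35, E9 = 0.35, E13 = 0.10)

#' Simulate the wild-type / mutant minigene pair for one demo variant
#'
#' Builds the regional minigene around the variant, simulates splicing of
#' the wild-type and variant construct with the demo skipping
#' propensities, and emits the fragment-analysis observables.
#'
#' @param demo result of [demoLocus()].
#' @param variants the placed demo variant table.
#' @param hgvs which variant to inject.
#' @param seed simulation seed.
#' @param n_molecules molecules per construct.
#' @return list with the two constructs, their simulations and
#'   observables, quantifications, and the \code{expected_lengths} map.
#' @export
demoMinigenePanel <- function(demo, variants, hgvs, seed = 1L,
                              n_molecules = 10000L) {
  v <- variants[variants$hgvs_c == hgvs, , drop = FALSE]
  if (nrow(v) != 1L) stop("unknown demo variant: ", hgvs)
  region <- demoRegions(demo$model)[[demoRegionOf(hgvs)]]
  cfg <- simulationConfig(seed = seed, n_molecules = n_molecules,
                          skip_propensity = demoSkipPropensity)
  wt <- buildMinigene(demo$sequence, demo$model, region,
                      name = paste0("wt_", demoRegionOf(hgvs)), cfg = cfg)
  mut <- buildMinigene(demo$sequence, demo$model, region, variants = v,
                       name = paste0("mut_", hgvs), cfg = cfg)
  simWt <- simulateSplicing(wt, cfg)
  cfgMut <- cfg
  cfgMut$seed <- as.integer(deriveSeed(seed, 13L))
  simMut <- simulateSplicing(mut, cfgMut)
  obsWt <- emitObservables(simWt, wt, cfg)
  obsMut <- emitObservables(simMut, mut, cfgMut)
  expected <- setNames(simMut$length, simMut$isoform)
  extra <- setdiff(simWt$isoform, simMut$isoform)
  expected <- c(expected, setNames(simWt$length[match(extra, simWt$isoform)],
                                   extra))
  # isoforms closer than the sizing resolution co-migrate in fragment
  # analysis: keep the better-supported length of each unresolvable pair
  weightOf <- setNames(simMut$weight, simMut$isoform)
  weightOf[extra] <- simWt$weight[match(extra, simWt$isoform)]
  tol <- pipelineDefaults()$quantification$peak_tol_bp
  expected <- expected[order(-weightOf[names(expected)])]
  keep <- character(0)
  for (nm in names(expected))
    if (!any(abs(expected[keep] - expected[[nm]]) <= 2 * tol))
      keep <- c(keep, nm)
  expected <- sort(expected[keep])
  quantify <- function(obs) {
    m <- matchPeaksToIsoforms(obs$peaks, expected)
    quantifyFractions(m$areas, "sample")
  }
  list(wt = wt, mutant = mut, sim_wt = simWt, sim_mut = simMut,
       wt_obs = obsWt, mutant_obs = obsMut,
       wt_quant = quantify(obsWt), mutant_quant = quantify(obsMut),
       expected_lengths = expected)
}
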