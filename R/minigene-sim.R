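# Synthetic minigene construction and stochastic splicing simulation.
#
# The generative model: every candidate isoform of a construct (the correct
# product, each single-exon skip, and each pseudoexon inclusion formed by a
# registered acceptor/donor pair inside one intronic region) receives a
# weight; molecule counts are drawn once from a multinomial over those
# weights.  A pseudoexon isoform's weight is the product of the logistic
# usabilities sigma(score) of its two non-constitutive splice sites times
# the no-skip factors; skipping uses per-exon propensities.  Antisense
# blocking multiplies sigma of a covered site by (1 - epsilon *
# coverage_fraction of the site's core window).  Everything is reproducible
# from the config seed.

# deterministic sequence generator (small LCG), independent of R's RNG
detSeq <- function(n, seed) {
  state <- as.numeric(seed %% 2147483647)
  out <- character(n)
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- BASES[state %% 4 + 1]
  }
  paste(out, collapse = "")
}

# fixed vector arms: V1 exon ends in a strong constitutive donor context,
# V2 exon is preceded by a strong constitutive acceptor context
vectorArms <- function() {
  v1ex <- paste0(detSeq(147L, 11L), "CAG")
  intr5 <- paste0("GTAAGT", detSeq(54L, 12L))
  intr3 <- paste0(detSeq(40L, 13L), "TTTCTTTTCCTTTCCTGCAG")
  v2ex <- paste0("G", detSeq(149L, 14L))
  list(v1ex = v1ex, intr5 = intr5, intr3 = intr3, v2ex = v2ex)
}

#' Simulation configuration
#'
#' @param seed integer seed driving every random draw of the simulator.
#' @param n_molecules number of mRNA molecules sampled (default 10000).
#' @param usability_midpoint,usability_slope parameters of the logistic
#'   mapping splice-site score (model units) to usability in (0,1).
#' @param skip_propensity named numeric in \code{[0,1]}: per-exon skipping
#'   propensity (names are exon ids); unnamed exons do not skip.
#' @param blocking data.frame of active antisense molecules:
#'   \code{am_id, target_start, target_end} (locus coordinates),
#'   \code{epsilon} (per-site blocking efficiency in \code{[0,1]}).
#' @param sizing_noise_sd Gaussian capillary sizing noise (bp).
#' @param area_bias_per_bp multiplicative per-bp dye-binding bias on peak
#'   areas (0 = area proportional to molecule count).
#' @param site_floor minimum PWM score for a latent splice site to enter
#'   the construct's site registry.
#' @param pe_length_range allowed pseudoexon lengths (bp) when pairing
#'   registered sites.
#' @param vector_cryptic_acceptor register a cryptic acceptor inside the
#'   downstream vector intron (reproduces the intron-fragment-retention
#'   minigene artifact); off by default.
#' @return a validated configuration list.
#' @export
simulationConfig <- function(seed = 1L,
                             n_molecules = 10000L,
                             usability_midpoint = 0,
                             usability_slope = 0.5,
                             skip_propensity = numeric(0),
                             blocking = NULL,
                             sizing_noise_sd = 0.5,
                             area_bias_per_bp = 0,
                             site_floor = 0,
                             pe_length_range = c(40L, 500L),
                             vector_cryptic_acceptor = FALSE) {
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  if (!is.null(blocking) &&
      any(blocking$epsilon < 0 | blocking$epsilon > 1))
    stop("blocking efficiencies must lie in [0,1]")
  if (any(skip_propensity < 0 | skip_propensity > 1))
    stop("skip propensities must lie in [0,1]")
  list(seed = as.integer(seed), n_molecules = as.integer(n_molecules),
       usability_midpoint = usability_midpoint,
       usability_slope = usability_slope,
       skip_propensity = skip_propensity, blocking = blocking,
       sizing_noise_sd = sizing_noise_sd,
       area_bias_per_bp = area_bias_per_bp, site_floor = site_floor,
       pe_length_range = pe_length_range,
       vector_cryptic_acceptor = vector_cryptic_acceptor)
}

# Scan a construct subsequence for latent donor/acceptor sites: windows
# carrying the obligate core dinucleotide (GT for donors, AG for
# acceptors) whose matrix score reaches the floor.
scanLatentSites <- function(seq, from, to, floor) {
  rows <- list()
  baseIdx <- match(strsplit(seq, "")[[1L]], BASES)
  for (kind in c("donor", "acceptor")) {
    L <- siteWindowWidth(kind)
    pwm <- if (kind == "donor") donorPWM() else acceptorPWM()
    w <- motifWeights(pwm)
    starts <- seq.int(max(0L, from), to - L)
    scores <- numeric(length(starts))
    for (j in seq_len(L))
      scores <- scores + w[j, ][baseIdx[starts + j]]
    core <- if (kind == "donor")
      baseIdx[starts + DONOR_EXONIC + 1L] == 3L &
        baseIdx[starts + DONOR_EXONIC + 2L] == 4L        # GT
    else
      baseIdx[starts + ACCEPTOR_INTRONIC - 1L] == 1L &
        baseIdx[starts + ACCEPTOR_INTRONIC] == 3L        # AG
    keep <- which(scores >= floor & core)
    if (length(keep)) {
      boundary <- if (kind == "donor") starts[keep] + DONOR_EXONIC
                  else starts[keep] + ACCEPTOR_INTRONIC
      rows[[kind]] <- data.frame(kind = kind, boundary_pos = boundary,
                                 score = scores[keep], method = "pwm",
                                 constitutive = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(), boundary_pos = integer(),
                      score = numeric(), method = character(),
                      constitutive = logical())
  rownames(out) <- NULL
  out
}

#' Build a minigene construct from a locus fragment
#'
#' Clones the fragment between the two constitutive vector exons V1 and V2
#' and injects the requested variants (wild-type and mutant constructs
#' share all coordinates; the mutant differs at exactly the injected
#' positions).  The site registry is built by scanning the insert's
#' intronic space with the packaged splice-site matrices.
#'
#' @param locus_seq locus sense-strand sequence.
#' @param model the [GeneModel-class].
#' @param fragment integer \code{c(start, end)}: locus span to clone.
#' @param variants optional data.frame (\code{locus_pos, ref, alt}) of
#'   variants to inject; a reference mismatch is an error.
#' @param name construct name.
#' @param cfg a [simulationConfig()] (supplies the registry score floor).
#' @return a [MinigeneConstruct-class].
#' @export
buildMinigene <- function(locus_seq, model, fragment, variants = NULL,
                          name = "minigene", cfg = simulationConfig()) {
  if (fragment[1L] < 0L || fragment[2L] > nchar(locus_seq))
    stop("fragment outside the locus")
  arms <- vectorArms()
  insertSeq <- subseq0(locus_seq, fragment[1L], fragment[2L])
  insertStart <- nchar(arms$v1ex) + nchar(arms$intr5)
  if (!is.null(variants) && nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      p <- variants$locus_pos[i] - fragment[1L]
      if (p < 0L || p >= nchar(insertSeq))
        stop("injected variant outside the cloned fragment")
      have <- substr(insertSeq, p + 1L, p + 1L)
      if (have != variants$ref[i])
        stop("reference mismatch for injected variant at locus ",
             variants$locus_pos[i], ": fragment has ", have)
      substr(insertSeq, p + 1L, p + 1L) <- variants$alt[i]
    }
    variants <- data.frame(construct_pos = variants$locus_pos -
                             fragment[1L] + insertStart,
                           ref = variants$ref, alt = variants$alt)
  } else {
    variants <- data.frame(construct_pos = integer(), ref = character(),
                           alt = character())
  }
  sequence <- paste0(arms$v1ex, arms$intr5, insertSeq, arms$intr3,
                     arms$v2ex)
  insertEnd <- insertStart + nchar(insertSeq)
  v1 <- c(0L, nchar(arms$v1ex))
  v2 <- c(nchar(sequence) - nchar(arms$v2ex), nchar(sequence))

  ex <- modelExons(model)
  inFrag <- ex[ex$start >= fragment[1L] & ex$end <= fragment[2L], ,
               drop = FALSE]
  exIns <- data.frame(exon_id = inFrag$exon_id,
                      start = inFrag$start - fragment[1L] + insertStart,
                      end = inFrag$end - fragment[1L] + insertStart)

  # latent sites: scan the insert's intronic space (exclude canonical
  # exons and their core windows so canonical sites stay constitutive)
  exonic <- rep(FALSE, nchar(sequence))
  for (i in seq_len(nrow(exIns)))
    exonic[(exIns$start[i] + 1L):exIns$end[i]] <- TRUE
  reg <- scanLatentSites(sequence, insertStart, insertEnd, cfg$site_floor)
  if (nrow(reg)) {
    core <- t(vapply(seq_len(nrow(reg)), function(i)
      siteWindowSpan(reg$kind[i], reg$boundary_pos[i]), numeric(2)))
    touchesExon <- vapply(seq_len(nrow(reg)), function(i)
      any(exonic[(core[i, 1L] + 1L):core[i, 2L]]), logical(1))
    reg <- reg[!touchesExon, , drop = FALSE]
  }
  if (isTRUE(cfg$vector_cryptic_acceptor)) {
    # cryptic acceptor just inside the downstream vector intron
    reg <- rbind(reg, data.frame(
      kind = "acceptor", boundary_pos = insertEnd + 30L, score = 2,
      method = "registered", constitutive = FALSE))
  }
  rownames(reg) <- NULL
  new("MinigeneConstruct", name = name, sequence = sequence,
      v1Exon = as.integer(v1), v2Exon = as.integer(v2),
      insertSpan = c(insertStart, insertEnd),
      insertLocusStart = as.integer(fragment[1L]),
      exonsInInsert = exIns, siteRegistry = reg, variants = variants)
}

# enumerate candidate isoforms of a construct with their weights
candidateIsoforms <- function(construct, cfg) {
  exIns <- construct@exonsInInsert
  reg <- construct@siteRegistry
  sigma <- if (nrow(reg))
    logisticUsability(reg$score, cfg$usability_midpoint,
                      cfg$usability_slope)
  else numeric(0)

  # antisense blocking attenuates covered sites
  if (!is.null(cfg$blocking) && nrow(cfg$blocking) && nrow(reg)) {
    off <- construct@insertSpan[1L] - construct@insertLocusStart
    for (b in seq_len(nrow(cfg$blocking))) {
      bs <- cfg$blocking$target_start[b] + off
      be <- cfg$blocking$target_end[b] + off
      for (i in seq_len(nrow(reg))) {
        core <- siteWindowSpan(reg$kind[i], reg$boundary_pos[i])
        cov <- max(0, min(be, core[2L]) - max(bs, core[1L])) /
          (core[2L] - core[1L])
        sigma[i] <- sigma[i] * (1 - cfg$blocking$epsilon[b] * cov)
      }
    }
  }

  skip <- cfg$skip_propensity
  skipOf <- function(id) if (id %in% names(skip)) skip[[id]] else 0
  noSkip <- prod(vapply(exIns$exon_id, function(id) 1 - skipOf(id),
                        numeric(1)))

  # intronic segments of the construct (between V1/exons/V2)
  bounds <- rbind(
    data.frame(start = construct@v1Exon[2L],
               end = if (nrow(exIns)) exIns$start[1L]
                     else construct@v2Exon[1L]),
    if (nrow(exIns) > 1L)
      data.frame(start = exIns$end[-nrow(exIns)], end = exIns$start[-1L]),
    if (nrow(exIns))
      data.frame(start = exIns$end[nrow(exIns)],
                 end = construct@v2Exon[1L]))

  exonWidths <- if (nrow(exIns)) sum(exIns$end - exIns$start) else 0L
  baseLen <- (construct@v1Exon[2L] - construct@v1Exon[1L]) +
    exonWidths + (construct@v2Exon[2L] - construct@v2Exon[1L])

  # exon-exon junction chain of the correct product (construct coords)
  chain <- rbind(construct@v1Exon, as.matrix(exIns[, c("start", "end")]),
                 construct@v2Exon)
  correctJunctions <- data.frame(start = chain[-nrow(chain), 2L],
                                 end = chain[-1L, 1L])

  iso <- list(list(name = "correct", weight = noSkip, length = baseLen,
                   junctions = correctJunctions, pe = NULL))

  for (i in seq_len(nrow(exIns))) {
    if (skipOf(exIns$exon_id[i]) == 0) next
    others <- prod(vapply(exIns$exon_id[-i], function(id) 1 - skipOf(id),
                          numeric(1)))
    keep <- chain[-(i + 1L), , drop = FALSE]
    iso[[length(iso) + 1L]] <- list(
      name = paste0("skip_", exIns$exon_id[i]),
      weight = skipOf(exIns$exon_id[i]) * others,
      length = baseLen - (exIns$end[i] - exIns$start[i]),
      junctions = data.frame(start = keep[-nrow(keep), 2L],
                             end = keep[-1L, 1L]),
      pe = NULL)
  }

  if (nrow(reg)) {
    segOf <- function(pos) {
      k <- which(pos > bounds$start & pos < bounds$end)
      if (length(k)) k[1L] else NA_integer_
    }
    accIdx <- which(reg$kind == "acceptor")
    donIdx <- which(reg$kind == "donor")
    for (a in accIdx) for (d in donIdx) {
      len <- reg$boundary_pos[d] - reg$boundary_pos[a]
      if (len < cfg$pe_length_range[1L] || len > cfg$pe_length_range[2L])
        next
      sa <- segOf(reg$boundary_pos[a]); sd <- segOf(reg$boundary_pos[d])
      if (is.na(sa) || is.na(sd) || sa != sd) next
      # the PE replaces part of intronic segment sa: splice junctions
      # flank it within that segment
      jA <- data.frame(start = bounds$start[sa],
                       end = reg$boundary_pos[a])
      jB <- data.frame(start = reg$boundary_pos[d], end = bounds$end[sa])
      junctions <- rbind(
        correctJunctions[correctJunctions$start != bounds$start[sa], ],
        jA, jB)
      iso[[length(iso) + 1L]] <- list(
        name = sprintf("PE_%d_%d",
                       reg$boundary_pos[a] - construct@insertSpan[1L] +
                         construct@insertLocusStart,
                       reg$boundary_pos[d] - construct@insertSpan[1L] +
                         construct@insertLocusStart),
        weight = sigma[a] * sigma[d] * noSkip,
        length = baseLen + len,
        junctions = junctions[order(junctions$start), ],
        pe = c(reg$boundary_pos[a], reg$boundary_pos[d]))
    }
  }
  iso
}

#' Simulate splicing of a minigene construct
#'
#' Enumerates the construct's candidate isoforms, computes their weights
#' under the logistic-usability model (attenuated by any active antisense
#' blocking), and draws molecule counts from a single multinomial.  Fully
#' reproducible: the same seed gives bit-identical counts.
#'
#' @param construct a [MinigeneConstruct-class].
#' @param cfg a [simulationConfig()].
#' @return data.frame with one row per candidate isoform: \code{isoform,
#'   weight, count, length}, plus a \code{junctions} attribute (list of
#'   per-isoform junction data.frames in construct coordinates) used by
#'   [emitObservables()].
#' @export
simulateSplicing <- function(construct, cfg = simulationConfig()) {
  iso <- candidateIsoforms(construct, cfg)
  w <- vapply(iso, `[[`, numeric(1), "weight")
  if (sum(w) <= 0)
    stop("no viable isoform: all candidate weights are zero")
  counts <- withSeed(cfg$seed, {
    as.integer(rmultinom(1L, cfg$n_molecules, w))
  })
  out <- data.frame(isoform = vapply(iso, `[[`, character(1), "name"),
                    weight = w, count = counts,
                    length = vapply(iso, `[[`, numeric(1), "length"))
  attr(out, "junctions") <- lapply(iso, `[[`, "junctions")
  attr(out, "construct") <- construct@name
  out
}

# evaluate expr with a temporary RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Emit observable tables from simulated molecule counts
#'
#' Produces the two observables of the minigene assay: a fragment-analysis
#' peak table (one peak per isoform; capillary sizing noise on the length,
#' area proportional to molecule count with an optional per-bp dye bias)
#' and a splice-junction table in locus coordinates (junctions touching
#' the vector arms have no locus analogue and are omitted).  Both tables
#' round-trip through [readPeakTable()] / [readJunctionTable()].
#'
#' @param sim result of [simulateSplicing()].
#' @param construct the [MinigeneConstruct-class] that was simulated.
#' @param cfg the [simulationConfig()] used.
#' @return list with \code{peaks} and \code{junctions} data.frames.
#' @export
emitObservables <- function(sim, construct, cfg = simulationConfig()) {
  keep <- sim$count > 0L
  noise <- withSeed(deriveSeed(cfg$seed, 7L), {
    rnorm(sum(keep), 0, cfg$sizing_noise_sd)
  })
  peaks <- data.frame(
    fragment_length_bp = sim$length[keep] + noise,
    area = sim$count[keep] *
      (1 + cfg$area_bias_per_bp * sim$length[keep]))

  off <- construct@insertLocusStart - construct@insertSpan[1L]
  ins <- construct@insertSpan
  jl <- attr(sim, "junctions")
  jrows <- list()
  for (i in which(keep)) {
    j <- jl[[i]]
    inIns <- j$start >= ins[1L] & j$end <= ins[2L]
    if (!any(inIns)) next
    jrows[[length(jrows) + 1L]] <- data.frame(
      start = j$start[inIns] + off, end = j$end[inIns] + off,
      read_count = sim$count[i])
  }
  junctions <- do.call(rbind, jrows)
  if (is.null(junctions)) {
    junctions <- data.frame(start = integer(), end = integer(),
                            read_count = integer(),
                            sample_count = integer())
  } else {
    junctions <- aggregate(read_count ~ start + end, junctions, sum)
    junctions$sample_count <- 1L
    junctions <- junctions[order(junctions$start, junctions$end), ]
    rownames(junctions) <- NULL
  }
  list(peaks = peaks, junctions = junctions)
}
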