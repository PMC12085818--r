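# Independent oracles used across the suite.  These deliberately use the
# slowest, most transparent formulation available (explicit enumeration,
# per-position arithmetic) so they share no code path with the package.

# All nested structures (lists of pair matrices) of a sequence under
# Watson-Crick + G.U pairing with a minimum hairpin loop.
oracleCanPair <- function(a, b) {
  p <- paste0(min(a, b), max(a, b))
  paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
}

oracleStructures <- function(bases, minHairpin = 3L) {
  n <- length(bases)
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), ncol = 2)))
    out <- list()
    # i unpaired
    for (s in rec(i + 1L, j)) out[[length(out) + 1L]] <- s
    # i paired with k
    ks <- seq.int(i + minHairpin + 1L, j)
    ks <- ks[ks <= j]
    if (i + minHairpin + 1L <= j) {
      for (k in ks) {
        if (!oracleCanPair(bases[i], bases[k])) next
        for (s1 in rec(i + 1L, k - 1L)) for (s2 in rec(k + 1L, j)) {
          out[[length(out) + 1L]] <- rbind(s1, s2, c(i, k))
        }
      }
    }
    out
  }
  rec(1L, n)
}

# per-base unpaired probability by exhaustive enumeration
oracleUnpaired <- function(seq, pairWeight = exp(1), minHairpin = 3L) {
  bases <- strsplit(seq, "")[[1L]]
  structs <- oracleStructures(bases, minHairpin)
  w <- vapply(structs, function(s) pairWeight^nrow(s), numeric(1))
  Z <- sum(w)
  punp <- numeric(length(bases))
  for (i in seq_along(structs)) {
    paired <- structs[[i]][, , drop = FALSE]
    idx <- unique(as.vector(paired))
    unp <- setdiff(seq_along(bases), idx)
    punp[unp] <- punp[unp] + w[i]
  }
  punp / Z
}

# exhaustive window scan oracle for ESE hits
oracleScanESE <- function(region, matrices) {
  rows <- list()
  for (m in matrices) {
    w <- motifWeights(m)
    L <- nrow(w)
    for (s in 0:(nchar(region) - L)) {
      win <- substr(region, s + 1L, s + L)
      sc <- 0
      for (j in seq_len(L))
        sc <- sc + w[j, substr(win, j, j)]
      if (sc >= motifThreshold(m) - 1e-9)
        rows[[length(rows) + 1L]] <- data.frame(
          motif_name = motifName(m), start = s, score = sc)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(motif_name = character(), start = integer(),
                      score = numeric()))
  out <- out[order(out$start, -round(out$score, 9L), out$motif_name), ]
  rownames(out) <- NULL
  out
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# small coding toy model: 3 exons on a 3 kb locus, CDS from 380
toyModel <- function() {
  GeneModel("toy", 3000L,
            data.frame(exon_id = c("E1", "E2", "E3"),
                       start = c(0L, 1000L, 2500L),
                       end = c(500L, 1200L, 2600L)),
            cdsStart = 380L)
}
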