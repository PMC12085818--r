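# Deep-intronic candidate-variant filter cascade.
#
# A variant passes when it is (1) a single-nucleotide variant, (2) at least
# min_intron_distance bp (default 100, the optimal minimal-intron length)
# from every annotated exon, (3) tiered by its splice-gain delta score:
# high when max(ds_ag, ds_dg) >= 0.5, medium when 0.2 < max < 0.5 AND the
# variant lies within colocate_window (default 5000 bp, the same-minigene
# rule) of a high-tier variant, and (4) not common (maf > 1%) unless on the
# explicit allow-list of evidence-backed exceptions.  Every rule is
# evaluated for every variant, so the outcome is independent of rule order
# and each exclusion carries the complete set of violated rules.

#' Run the deep-intronic variant selection cascade
#'
#' @param variants variant data.frame with \code{locus_pos} (see
#'   [readVariantTable()] with a model, or [validateVariants()]).
#' @param model the [GeneModel-class] providing annotated exon boundaries.
#' @param cfg selection configuration (see [pipelineDefaults()]
#'   \code{$selection}).
#' @return data.frame with one row per variant: \code{hgvs_c, locus_pos,
#'   max_gain_ds, exon_distance, tier} (\code{high}, \code{medium} or
#'   \code{excluded}), \code{passed}, and pipe-joined \code{reasons}
#'   (rule identifiers with values; empty when passed).
#' @examples
#' ## see demoVariantTable() for the packaged fixture
#' @export
selectVariants <- function(variants, model,
                           cfg = pipelineDefaults()$selection) {
  if (is.null(variants$locus_pos))
    stop("variants must carry locus_pos; read them with a gene model")
  ex <- modelExons(model)
  n <- nrow(variants)

  dsMax <- pmax(ifelse(is.na(variants$ds_ag), -Inf, variants$ds_ag),
                ifelse(is.na(variants$ds_dg), -Inf, variants$ds_dg))
  noPrediction <- is.na(variants$ds_ag) & is.na(variants$ds_dg)
  exonDist <- vapply(variants$locus_pos, function(p)
    min(distanceToExon(p, ex$start, ex$end)), integer(1))

  isSnv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref != variants$alt
  deepIntronic <- exonDist >= cfg$min_intron_distance
  mafKnown <- !is.na(variants$maf)
  mafOk <- !mafKnown | variants$maf <= cfg$max_maf |
    variants$hgvs_c %in% cfg$maf_exceptions

  # high-tier anchors: high-DS variants that themselves survive the
  # non-tier rules; medium-tier membership requires proximity to one
  anchor <- isSnv & deepIntronic & mafOk & !noPrediction &
    dsMax >= cfg$high_ds
  nearAnchor <- vapply(seq_len(n), function(i) {
    others <- anchor & seq_len(n) != i
    any(abs(variants$locus_pos[others] - variants$locus_pos[i]) <=
          cfg$colocate_window)
  }, logical(1))

  tier <- rep("excluded", n)
  tier[anchor] <- "high"
  medium <- isSnv & deepIntronic & mafOk & !noPrediction &
    dsMax > cfg$medium_ds & dsMax < cfg$high_ds & nearAnchor
  tier[medium] <- "medium"

  reasons <- lapply(seq_len(n), function(i) {
    r <- character()
    if (!isSnv[i]) r <- c(r, "not_snv")
    if (!deepIntronic[i])
      r <- c(r, sprintf("distance=%d<%d", exonDist[i],
                        as.integer(cfg$min_intron_distance)))
    if (noPrediction[i]) {
      r <- c(r, "no_prediction")
    } else if (dsMax[i] <= cfg$medium_ds) {
      r <- c(r, sprintf("low_ds=%.2f", dsMax[i]))
    } else if (dsMax[i] < cfg$high_ds && !nearAnchor[i]) {
      r <- c(r, sprintf("medium_ds=%.2f_not_colocated", dsMax[i]))
    }
    if (!mafOk[i]) r <- c(r, sprintf("maf=%.3g>%.3g", variants$maf[i],
                                     cfg$max_maf))
    r
  })

  passed <- tier != "excluded"
  stopifnot(all(passed == (lengths(reasons) == 0L)))
  data.frame(
    hgvs_c = variants$hgvs_c,
    locus_pos = variants$locus_pos,
    max_gain_ds = ifelse(is.finite(dsMax), dsMax, NA_real_),
    exon_distance = exonDist,
    tier = tier,
    passed = passed,
    reasons = vapply(reasons, paste, character(1), collapse = "|")
  )
}
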