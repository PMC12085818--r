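# Readers and writers for the external formats the pipeline touches.
# All tabular dialects are TSV with a required header; writers emit the
# exact dialect the readers parse.

#' Read a locus sequence from FASTA
#'
#' The sequence is expected to be the gene sense strand.  Use
#' [flipToSenseStrand()] first for genes annotated on the genomic minus
#' strand.
#'
#' @param path FASTA file with a single record.
#' @return character scalar (upper-case DNA).
#' @export
readLocusSequence <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected a single FASTA record, found ", length(ss))
  toupper(as.character(ss[[1L]]))
}

#' Write a locus sequence as FASTA
#' @param seq DNA sequence (character scalar).
#' @param name FASTA record name.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLocusSequence <- function(seq, name, path) {
  ss <- Biostrings::DNAStringSet(seq)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

variantColumns <- c("hgvs_c", "ref", "alt", "ds_ag", "ds_al", "ds_dg",
                    "ds_dl", "maf", "source")

#' Read a variant table
#'
#' TSV dialect with required header columns \code{hgvs_c, ref, alt, ds_ag,
#' ds_al, ds_dg, ds_dl, maf, source}.  SpliceAI delta scores (DS) are
#' consumed as inputs in \code{[0,1]}; \code{maf} may be empty (absent);
#' \code{source} is \code{P} (identified in patients) or \code{DB}
#' (database-only).  When a gene model is supplied, each variant is placed
#' on the locus (\code{locus_pos}) via [hgvsToLocus()] and the placement is
#' checked by conversion round-trip.
#'
#' @param path TSV path.
#' @param model optional coding [GeneModel-class] used to place variants.
#' @return data.frame of validated variant records.
#' @export
readVariantTable <- function(path, model = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(variantColumns, names(tab))
  if (length(missing))
    stop("variant table lacks required column(s): ",
         paste(missing, collapse = ", "))
  validateVariants(tab, model)
}

#' Validate (and place) a variant data.frame
#'
#' @param tab data.frame with the variant-table columns.
#' @param model optional coding [GeneModel-class]; adds/checks
#'   \code{locus_pos}.
#' @return the validated data.frame.
#' @export
validateVariants <- function(tab, model = NULL) {
  if (any(nchar(tab$ref) != 1L | nchar(tab$alt) != 1L))
    stop("only single-nucleotide variants are supported")
  if (any(tab$ref == tab$alt))
    stop("ref and alt must differ for ", tab$hgvs_c[tab$ref == tab$alt][1L])
  for (col in c("ds_ag", "ds_al", "ds_dg", "ds_dl")) {
    v <- tab[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("delta score column ", col, " must lie in [0,1]")
  }
  if (any(!is.na(tab$maf) & (tab$maf < 0 | tab$maf > 1)))
    stop("maf must lie in [0,1]")
  if (!all(tab$source %in% c("P", "DB")))
    stop("source must be 'P' or 'DB'")
  if (!is.null(model)) {
    tab$locus_pos <- vapply(tab$hgvs_c, hgvsToLocus, integer(1),
                            model = model)
    back <- vapply(tab$locus_pos, locusToHgvs, character(1), model = model)
    stated <- sub("[ACGT]>[ACGT]$", "", tab$hgvs_c)
    bad <- which(back != stated)
    if (length(bad))
      stop("hgvs_c/locus position round-trip failed for ",
           tab$hgvs_c[bad[1L]], " (canonical form is ", back[bad[1L]], ")")
  }
  rownames(tab) <- NULL
  tab
}

#' Write a variant table
#' @param tab variant data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(tab, path) {
  write.table(tab[, intersect(c(variantColumns, "locus_pos"), names(tab))],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a splice-junction table
#'
#' TSV dialect with required header columns \code{start, end, read_count,
#' sample_count}: 0-based half-open coordinates of the spliced-out segment
#' plus supporting read/sample counts, one junction per row.  Snaptron-style
#' extracts are converted to this dialect by selecting/renaming those four
#' columns.  Invariant violations (end <= start, negative counts) are
#' rejected, never repaired.
#'
#' @param path TSV path.
#' @return data.frame of junction records.
#' @export
readJunctionTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "read_count", "sample_count")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("junction table lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (any(tab$end <= tab$start))
    stop("junction with end <= start at row ",
         which(tab$end <= tab$start)[1L])
  if (any(tab$read_count < 0L | tab$sample_count < 0L))
    stop("junction counts must be non-negative")
  tab[, need]
}

#' Write a splice-junction table
#' @param tab junction data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeJunctionTable <- function(tab, path) {
  write.table(tab[, c("start", "end", "read_count", "sample_count")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fragment-analysis peak table
#'
#' TSV dialect with required header columns \code{fragment_length_bp}
#' (capillary-sized fragment length, may be fractional) and \code{area}
#' (fluorescence peak area).
#'
#' @param path TSV path.
#' @return data.frame of peaks.
#' @export
readPeakTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("fragment_length_bp", "area")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("peak table lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (any(tab$area < 0)) stop("peak areas must be non-negative")
  tab[, need]
}

#' Write a fragment-analysis peak table
#' @param tab peak data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writePeakTable <- function(tab, path) {
  write.table(tab[, c("fragment_length_bp", "area")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults.  User config
#' files (YAML) are merged over these; unknown keys are rejected loudly.
#'
#' @return nested named list of defaults.
#' @export
pipelineDefaults <- function() {
  list(
    selection = list(
      min_intron_distance = 100,    # bp, minimal-intron rule
      high_ds = 0.5,                # DS >= high_ds: high tier
      medium_ds = 0.2,              # medium tier open interval lower bound
      colocate_window = 5000,       # bp to a high-tier anchor ("same minigene")
      max_maf = 0.01,               # population-frequency exclusion
      maf_exceptions = character()  # explicit allow-list of hgvs_c ids
    ),
    scoring = list(
      scan_radius = 30,             # bp around a variant scanned for sites
      report_floor = 0,             # minimum score for a site to be reported
      gain_delta = 1.0              # model units; smaller changes ignored
    ),
    annotation = list(top_k = 20),
    quantification = list(
      peak_tol_bp = 2,              # capillary sizing tolerance
      display_threshold = 0.05,     # 5% display rule (display-only)
      altering_delta = 0.10         # correct-fraction drop calling a variant
    ),                              #   splice-altering
    design = list(
      flank = 50,                   # bp of intron flanking the PE
      u7_length = c(18, 30), u7_optimum = 25,
      circ_length = c(40, 150), circ_optimum = 80,
      stride = 1, shift_k = 5,
      weights = c(site = 1, ese = 1, acc = 1, len = 0.5),
      pair_score = 1, temperature = 1
    ),
    simulation = list(
      n_molecules = 10000,
      usability_midpoint = 0, usability_slope = 0.5,
      sizing_noise_sd = 0.5, area_bias_per_bp = 0,
      vector_cryptic_acceptor = FALSE
    )
  )
}

mergeConfig <- function(defaults, user, prefix = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key: ", prefix, unknown[1L])
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- mergeConfig(defaults[[nm]], as.list(user[[nm]]),
                                    paste0(prefix, nm, "."))
    } else {
      val <- user[[nm]]
      if (!is.null(names(defaults[[nm]])) && is.list(val))
        val <- unlist(val)
      defaults[[nm]] <- val
    }
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' YAML key-value file validated against [pipelineDefaults()]: unknown keys
#' raise an error naming the key, missing keys take their defaults.
#'
#' @param path YAML path, or \code{NULL} for pure defaults.
#' @return nested named list (full configuration).
#' @export
readPipelineConfig <- function(path = NULL) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  mergeConfig(pipelineDefaults(), user)
}

#' Write a pipeline configuration file
#' @param cfg nested configuration list.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
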