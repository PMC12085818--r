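# Position weight matrices: construction from packaged frequency tables,
# the matrix-file dialect, and the bundled ESE motif set.

#' Construct a PWMatrix
#'
#' @param motifName motif identifier.
#' @param weights numeric matrix (rows = positions, columns \code{A,C,G,T})
#'   of log2-odds weights.
#' @param threshold minimum reportable score.
#' @return a validated [PWMatrix-class].
#' @export
PWMatrix <- function(motifName, weights, threshold = -Inf) {
  weights <- as.matrix(weights)
  dimnames(weights) <- list(NULL, c("A", "C", "G", "T"))
  new("PWMatrix", motifName = motifName, weights = weights,
      threshold = threshold)
}

# log2-odds weights from a percent-frequency table with pseudocount 0.25
# per base against a uniform background
frequencyToWeights <- function(freq, pseudocount = 0.25) {
  freq <- as.matrix(freq[, c("A", "C", "G", "T")])
  p <- (freq + pseudocount) / (rowSums(freq) + 4 * pseudocount)
  log2(p / 0.25)
}

pkgFile <- function(...) system.file("extdata", ..., package = "pseudosplice",
                                     mustWork = TRUE)

matrixCache <- new.env(parent = emptyenv())

#' Built-in donor / acceptor splice-site matrices
#'
#' Log2-odds matrices built from the packaged splice-site frequency tables
#' (pseudocount 0.25, uniform background).  Window conventions follow the
#' maximum-entropy model standard: donor = 3 exonic + 6 intronic bases
#' (9-mer), acceptor = 20 intronic + 3 exonic bases (23-mer).
#'
#' @return a [PWMatrix-class].
#' @export
donorPWM <- function() {
  if (is.null(matrixCache$donor)) {
    freq <- read.delim(pkgFile("donor_site_frequencies.tsv"),
                       comment.char = "#")
    matrixCache$donor <- PWMatrix("donor", frequencyToWeights(freq))
  }
  matrixCache$donor
}

#' @rdname donorPWM
#' @export
acceptorPWM <- function() {
  if (is.null(matrixCache$acceptor)) {
    freq <- read.delim(pkgFile("acceptor_site_frequencies.tsv"),
                       comment.char = "#")
    matrixCache$acceptor <- PWMatrix("acceptor", frequencyToWeights(freq))
  }
  matrixCache$acceptor
}

#' Bundled ESE motif matrices
#'
#' The four classic SR-protein motif matrices (SRSF1, SRSF1-IgM,
#' SRSF2/SC35, SRSF5) as synthetic consensus-derived stand-ins packaged
#' with this package (see the file header of
#' \code{ese_matrices_synthetic.tsv}); SC35 (\code{SRSF2}) is the default
#' antisense target set.  Users may substitute their own matrix files.
#'
#' @param path stacked matrix TSV (columns motif, threshold, pos, A,C,G,T);
#'   defaults to the packaged file.
#' @return named list of [PWMatrix-class] objects.
#' @export
eseMatrices <- function(path = pkgFile("ese_matrices_synthetic.tsv")) {
  tab <- read.delim(path, comment.char = "#")
  lapply(split(tab, tab$motif)[unique(tab$motif)], function(m) {
    m <- m[order(m$pos), ]
    PWMatrix(m$motif[1L], as.matrix(m[, c("A", "C", "G", "T")]),
             threshold = m$threshold[1L])
  })
}

#' Read / write a single position-weight-matrix file
#'
#' Matrix-file dialect: comment header lines \code{# motif_name: <name>} and
#' \code{# threshold: <value>}, then a TSV with columns \code{pos, A, C, G,
#' T} holding log2-odds weights, one row per position.
#'
#' @param path matrix file path.
#' @return a [PWMatrix-class].
#' @export
readPWMatrix <- function(path) {
  hdr <- readLines(path, n = 20L)
  getMeta <- function(key) {
    ln <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(ln)) stop("matrix file lacks '# ", key, ":' header: ", path)
    trimws(sub(sprintf("^#\\s*%s:", key), "", ln[1L]))
  }
  name <- getMeta("motif_name")
  threshold <- as.numeric(getMeta("threshold"))
  tab <- read.delim(path, comment.char = "#")
  tab <- tab[order(tab$pos), ]
  PWMatrix(name, as.matrix(tab[, c("A", "C", "G", "T")]), threshold)
}

#' @rdname readPWMatrix
#' @param x a [PWMatrix-class] to write.
#' @return \code{writePWMatrix}: \code{path}, invisibly.
#' @export
writePWMatrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# motif_name: %s", x@motifName),
               sprintf("# threshold: %.6g", x@threshold)), con)
  tab <- data.frame(pos = seq_len(nrow(x@weights)), x@weights,
                    check.names = FALSE)
  write.table(format(tab, digits = 10), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
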