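test_that("BED12 blocks become 0-based half-open exons", {
  bed <- tempfile(fileext = ".bed")
  writeLines(paste("toy", 0, 700, "TX1", 0, "+", 10, 650, "0", 2,
                   "100,200", "0,500", sep = "\t"), bed)
  model <- parseGeneModel(bed, "bed")
  expect_equal(modelExons(model)$start, c(0L, 500L))
  expect_equal(modelExons(model)$end, c(100L, 700L))
  expect_true(isCoding(model))
  expect_equal(cdsStart(model), 10L)
})

test_that("overlapping BED blocks are rejected, naming the pair", {
  bed <- tempfile(fileext = ".bed")
  writeLines(paste("toy", 0, 700, "TX1", 0, "+", 0, 700, "0", 2,
                   "300,200", "0,200", sep = "\t"), bed)
  expect_error(parseGeneModel(bed, "bed"), "overlap")
})

test_that("GFF3 round-trip preserves the 14-exon demo model", {
  demo <- demoLocus()
  gff <- tempfile(fileext = ".gff3")
  writeGeneModelGFF3(demo$model, gff)
  back <- parseGeneModel(gff, "gff3")
  expect_equal(nrow(modelExons(back)), 14L)
  expect_equal(modelExons(back)$start, modelExons(demo$model)$start)
  expect_equal(modelExons(back)$end, modelExons(demo$model)$end)
  expect_equal(cdsStart(back), cdsStart(demo$model))
  expect_false(is.unsorted(modelExons(back)$start))
})

test_that("a model without CDS enters non-coding mode", {
  m <- GeneModel("nc", 1000L,
                 data.frame(exon_id = c("E1", "E2"),
                            start = c(0L, 500L), end = c(100L, 700L)))
  expect_false(isCoding(m))
  expect_error(cdsToLocus(m, 1L), "non-coding")
})

test_that("intronic HGVS coordinates resolve as documented", {
  # exon 2 starts at locus 1000 and its first base is c.121;
  # exon 1's last base c.120 sits at locus 499
  m <- toyModel()
  expect_identical(hgvsToLocus("c.121-210", m), 790L)
  expect_identical(hgvsToLocus("c.121-210C>T", m), 790L)
  expect_identical(hgvsToLocus("c.120+1336", m), 1835L)
  expect_error(hgvsToLocus("c.121-0", m), ">= 1")
  expect_error(hgvsToLocus("c.121del", m), "unsupported")
  expect_error(hgvsToLocus("c.121-600", m), "exonic")  # lands in exon 1
})

test_that("hgvs and locus coordinates are mutual inverses on random models", {
  set.seed(11)
  for (rep in 1:5) {
    nEx <- sample(3:6, 1)
    widths <- sample(60:150, nEx, replace = TRUE)
    gaps <- sample(120:400, nEx - 1, replace = TRUE)
    starts <- cumsum(c(10L, widths[-nEx] + gaps))
    m <- GeneModel("rnd", max(starts + widths) + 50L,
                   data.frame(exon_id = paste0("E", 1:nEx),
                              start = starts, end = starts + widths),
                   cdsStart = starts[1L] + 5L)
    introns <- modelIntrons(m)
    pos <- unlist(mapply(seq, introns$start, introns$end - 1L,
                         SIMPLIFY = FALSE))
    back <- vapply(pos, function(p) hgvsToLocus(locusToHgvs(p, m), m),
                   integer(1))
    expect_identical(back, as.integer(pos))
  }
})

test_that("minus-strand inputs flip to sense-strand coordinates", {
  seq <- "AACCGGTTAC"
  iv <- data.frame(start = c(1L, 7L), end = c(4L, 9L))
  fl <- flipToSenseStrand(seq, iv)
  expect_identical(fl$seq, "GTAACCGGTT")
  expect_identical(fl$intervals$start, c(1L, 6L))
  expect_identical(fl$intervals$end, c(3L, 9L))
  # flipping twice restores the original intervals
  back <- flipToSenseStrand(fl$seq, fl$intervals)
  expect_identical(back$seq, seq)
  expect_identical(back$intervals$start, iv$start)
})
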