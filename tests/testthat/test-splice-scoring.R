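test_that("the consensus window attains the matrix maximum", {
  expect_equal(scoreSitePWM("CAGGTAAGT", "donor"),
               sum(apply(motifWeights(donorPWM()), 1L, max)))
  best <- paste(c("A", "C", "G", "T")[apply(motifWeights(acceptorPWM()),
                                            1L, which.max)], collapse = "")
  expect_equal(scoreSitePWM(best, "acceptor"),
               sum(apply(motifWeights(acceptorPWM()), 1L, max)))
})

test_that("a uniform matrix scores every window zero", {
  m <- PWMatrix("flat", matrix(0, 9, 4,
                               dimnames = list(NULL, c("A","C","G","T"))))
  expect_equal(scoreSitePWM("ACGTACGTA", matrix = m), 0)
})

test_that("PWM scores equal the position-by-position hand sum", {
  set.seed(3)
  w <- motifWeights(donorPWM())
  for (i in 1:20) {
    win <- randomDNA(9)
    hand <- 0
    for (j in 1:9) hand <- hand + w[j, substr(win, j, j)]
    expect_equal(scoreSitePWM(win, "donor"), unname(hand))
  }
})

test_that("PWM scoring is additive in single-base differences", {
  set.seed(4)
  w <- motifWeights(acceptorPWM())
  for (i in 1:20) {
    a <- randomDNA(23)
    p <- sample(23, 1)
    b <- a
    nb <- sample(setdiff(c("A","C","G","T"), substr(a, p, p)), 1)
    substr(b, p, p) <- nb
    expect_equal(scoreSitePWM(a, "acceptor") - scoreSitePWM(b, "acceptor"),
                 unname(w[p, substr(a, p, p)] - w[p, nb]))
  }
})

test_that("ambiguous bases and length mismatches are rejected", {
  expect_error(scoreSitePWM("CAGGTANGT", "donor"), "A/C/G/T")
  expect_error(scoreSitePWM("CAGGT", "donor"), "length")
})

toyMaxentDir <- function() {
  dir <- tempfile()
  dir.create(dir)
  kmers <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                             c("A","C","G","T")), 1L, paste, collapse = "")
  set.seed(9)
  probs <- runif(length(kmers)); probs <- probs / sum(probs)
  write.table(data.frame(component = 1L, start = 0L, width = 3L,
                         role = "num", kmer = kmers, weight = probs),
              file.path(dir, "donor.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(dir = dir, kmers = kmers, probs = probs)
}

test_that("maximum-entropy scoring reproduces a toy table exhaustively", {
  toy <- toyMaxentDir()
  model <- readMaxentModel(toy$dir)
  scores <- vapply(toy$kmers, scoreSiteMaxent, numeric(1), kind = "donor",
                   model = model)
  expect_equal(unname(scores), log2(toy$probs))
  # the model's highest-probability sequence attains the maximal score
  expect_equal(names(which.max(scores)), toy$kmers[which.max(toy$probs)])
  expect_error(scoreSiteMaxent("ACGT", "donor", model), "window length")
  expect_error(scoreSiteMaxent("ACG", "acceptor", model), "no acceptor")
})

test_that("maxent scoring without tables is unavailable, not broken", {
  expect_false(maxentAvailable(NULL, "donor"))
  expect_error(scoreSiteMaxent("ACGGTAAGT", "donor", NULL),
               "not supplied")
})

test_that("ESE scanning equals the exhaustive window oracle", {
  mats <- eseMatrices()
  set.seed(7)
  for (i in 1:10) {
    region <- randomDNA(60)
    expect_equal(scanESE(region, mats), oracleScanESE(region, mats))
  }
  # a pyrimidine run has no SR-protein hits: empty result is valid
  expect_identical(nrow(scanESE(strrep("T", 40), mats)), 0L)
})

test_that("a planted consensus motif is the unique maximal hit", {
  # sharply peaked test matrix: off-consensus bases are heavily penalised,
  # so only the exact planted position can clear the threshold
  cons <- "GCGCGTAC"
  w <- matrix(-3, 8L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (j in 1:8) w[j, substr(cons, j, j)] <- 1.2
  m <- PWMatrix("peaked", w, threshold = 6)
  region <- paste0(strrep("A", 10), cons, strrep("A", 10))
  hits <- scanESE(region, list(m))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 10L)
  expect_equal(hits$score, 8 * 1.2)
})

test_that("variant site deltas classify creation vs strengthening", {
  # donor creation: ref breaks the GT, alt completes it
  left <- strrep("C", 40)
  win <- "CAGGTAAGT"
  seq <- paste0(left, sub("T", "A", win), strrep("C", 40))  # GT -> GA
  variant <- data.frame(locus_pos = 44L, ref = "A", alt = "T")
  rep1 <- variantSiteDelta(variant, seq)
  expect_identical(rep1$classification, "donor_gain")
  expect_true(all(rep1$gained$alt_score > rep1$gained$ref_score))

  # reference allele against itself is always 'none'
  rep0 <- variantSiteDelta(data.frame(locus_pos = 44L, ref = "A",
                                      alt = "A"), seq)
  expect_identical(rep0$classification, "none")

  # mismatching reference base is an error
  expect_error(variantSiteDelta(data.frame(locus_pos = 44L, ref = "G",
                                           alt = "T"), seq),
               "reference mismatch")
})

test_that("strengthening an already-reportable acceptor is classified so", {
  # acceptor with a G interrupting its polypyrimidine tract: already above
  # the reporting floor, and the G>T change strengthens it further
  win <- "TTTTTTGTTTCTTTTCTTAGGCC"
  seq <- paste0(strrep("A", 40), win, strrep("A", 40))
  p <- 46L                                  # the G inside the tract
  expect_identical(substr(seq, p + 1L, p + 1L), "G")
  ref <- scoreSitePWM(win, "acceptor")
  expect_gt(ref, 0)                         # reportable before the change
  rep <- variantSiteDelta(data.frame(locus_pos = p, ref = "G",
                                     alt = "T"), seq)
  expect_identical(rep$classification, "strengthening")
})

test_that("a change outside any reportable window classifies as none", {
  seq <- strrep("C", 101)
  rep <- variantSiteDelta(data.frame(locus_pos = 50L, ref = "C",
                                     alt = "A"), seq)
  expect_identical(rep$classification, "none")
})
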