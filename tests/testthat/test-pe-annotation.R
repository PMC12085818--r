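# helpers building junction evidence on the 3-exon toy model
toyJunction <- function(start, end, reads = 50L)
  data.frame(start = start, end = end, read_count = reads,
             sample_count = reads %/% 2L)

test_that("a planted pseudoexon is recovered from its junction pair", {
  m <- toyModel()          # introns [500,1000) and [1200,2500)
  j <- rbind(toyJunction(500L, 700L, 40L),    # exon1 end -> PE acceptor
             toyJunction(820L, 1000L, 40L),   # PE donor -> exon2 start
             toyJunction(500L, 1000L, 900L),  # concordant intron 1
             toyJunction(1200L, 2500L, 900L)) # concordant intron 2
  ev <- callBackgroundEvents(j, m, top_k = Inf)
  pe <- ev[ev$event_type == "pe_inclusion", ]
  expect_identical(nrow(pe), 1L)
  expect_identical(pe$start, 700L)
  expect_identical(pe$end, 820L)
  expect_identical(pe$end - pe$start, 120L)
  expect_equal(pe$inclusion_fraction, 40 / 940)
})

test_that("a junction from exon 1 to exon 3 is skipping of exon 2", {
  m <- toyModel()
  ev <- callBackgroundEvents(toyJunction(500L, 2500L), m, top_k = Inf)
  expect_identical(ev$event_type, "exon_skip")
  expect_identical(ev$skipped_exons, "E2")
})

test_that("top-k ranking equals an independent sort oracle", {
  m <- toyModel()
  set.seed(31)
  reads <- sample(5:500, 30)
  starts <- seq(1250L, by = 40L, length.out = 30L)
  j <- do.call(rbind, lapply(seq_len(30), function(i)
    toyJunction(starts[i], starts[i] + 25L, reads[i])))
  ev <- callBackgroundEvents(j, m, top_k = 20)
  expect_identical(nrow(ev), 20L)
  expect_identical(ev$discordant_reads, sort(reads, decreasing = TRUE)[1:20])
  # with top_k = Inf nothing is dropped: every discordant junction appears
  all_ev <- callBackgroundEvents(j, m, top_k = Inf)
  expect_identical(nrow(all_ev), 30L)
  expect_setequal(all_ev$j1_start, starts)
})

test_that("junctions outside the locus are an error", {
  m <- toyModel()
  expect_error(callBackgroundEvents(toyJunction(100L, 5000L), m),
               "outside the locus")
})

test_that("pseudoexon naming follows the longest-isoform scheme", {
  # shared-acceptor pair: base name + _D2 by decreasing length
  pair <- data.frame(acceptor_pos = c(100L, 100L),
                     donor_pos = c(323L, 270L), wild_type = TRUE)
  named <- groupAndNamePseudoexons(pair)
  expect_identical(named$name, c("PE-wt-1", "PE-wt-1_D2"))
  expect_identical(named$length, c(223L, 170L))

  # shared-donor quartet after three upstream groups: PE-4 + _A2.._A4
  quartet <- data.frame(
    acceptor_pos = c(100L, 600L, 1200L, 2000L, 2017L, 2039L, 2061L),
    donor_pos = c(180L, 680L, 1280L, rep(2307L, 4L)),
    wild_type = FALSE)
  named <- groupAndNamePseudoexons(quartet)
  grp <- named[named$pe_group_id == "PE-4", ]
  expect_identical(grp$name, c("PE-4", "PE-4_A2", "PE-4_A3", "PE-4_A4"))
  expect_identical(grp$length, c(307L, 290L, 268L, 246L))

  # a singleton keeps the bare base name
  single <- groupAndNamePseudoexons(data.frame(acceptor_pos = 10L,
                                               donor_pos = 80L,
                                               wild_type = FALSE))
  expect_identical(single$name, "PE-1")
})

test_that("naming is deterministic under input permutation", {
  set.seed(41)
  iso <- data.frame(
    acceptor_pos = c(100L, 100L, 400L, 400L, 900L),
    donor_pos = c(300L, 250L, 520L, 560L, 1000L),
    wild_type = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  base <- groupAndNamePseudoexons(iso)
  for (i in 1:5) {
    perm <- groupAndNamePseudoexons(iso[sample(nrow(iso)), ])
    expect_identical(perm, base)
  }
})

test_that("an isoform sharing neither boundary starts a new group", {
  iso <- data.frame(acceptor_pos = c(100L, 120L),
                    donor_pos = c(300L, 280L), wild_type = FALSE)
  expect_warning(named <- groupAndNamePseudoexons(iso), "new group")
  expect_identical(sort(unique(named$pe_group_id)), c("PE-1", "PE-2"))
})

test_that("frame and PTC consequences come from in-silico splicing", {
  demo <- demoLocus()
  f <- demo$features
  pes <- data.frame(
    acceptor_pos = c(f$pe6_acceptor, f$pe2_acceptor),
    donor_pos = c(f$pe6_donor, f$pe2_donor))
  ann <- annotateConsequence(pes, demo$model, demo$sequence)
  # 53 bp pseudoexon shifts the frame
  expect_identical(ann$length[1L], 53L)
  expect_identical(ann$frame_consequence[1L], "frameshift")
  expect_true(ann$introduces_ptc[1L])
  # 159 bp pseudoexon keeps the frame but carries a stop codon
  expect_identical(ann$length[2L], 159L)
  expect_identical(ann$frame_consequence[2L], "in_frame")
  expect_true(ann$introduces_ptc[2L])
})

test_that("degenerate pseudoexons and non-coding models are handled", {
  demo <- demoLocus()
  expect_error(annotateConsequence(
    data.frame(acceptor_pos = 700L, donor_pos = 700L),
    demo$model, demo$sequence), "length")
  nc <- GeneModel("nc", demo$model@sequenceLength,
                  modelExons(demo$model))
  ann <- annotateConsequence(
    data.frame(acceptor_pos = demo$features$pe6_acceptor,
               donor_pos = demo$features$pe6_donor),
    nc, demo$sequence)
  expect_true(is.na(ann$introduces_ptc))
  expect_identical(ann$frame_consequence, "frameshift")
})
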