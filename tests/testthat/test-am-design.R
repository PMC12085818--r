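test_that("unpairable sequences are fully open", {
  expect_equal(openness(accessibilityProfile(strrep("A", 30))),
               rep(1, 30))
})

test_that("a perfect stem is less open than its loop", {
  # 8 bp GC stem with a 4 nt A loop
  hp <- paste0("GGGGGGGG", "AAAA", "CCCCCCCC")
  op <- openness(accessibilityProfile(hp))
  expect_lt(mean(op[c(1:8, 13:20)]), mean(op[9:12]))
})

test_that("the profile matches exhaustive structure enumeration", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(10:16, 1)
    seq <- randomDNA(n)
    got <- openness(accessibilityProfile(seq))
    want <- oracleUnpaired(seq)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the temperature parameter flattens the ensemble", {
  seq <- "GGGAGAAACCCGGGAAACCC"
  cold <- openness(accessibilityProfile(seq, pair_score = 2))
  hot <- openness(accessibilityProfile(seq, pair_score = 2,
                                       temperature = 10))
  expect_lt(mean(cold), mean(hot))   # weaker pairing at high temperature
})

test_that("region guards reject too-short and too-long inputs", {
  expect_error(accessibilityProfile("ACGTA"), "too short")
  expect_error(accessibilityProfile(strrep("A", 2100)), "2000")
})

designFixture <- function() {
  demo <- demoLocus()
  list(demo = demo,
       pe = data.frame(acceptor_pos = demo$features$pe6_acceptor,
                       donor_pos = demo$features$pe6_donor))
}

test_that("candidate enumeration covers every window of allowed lengths", {
  fx <- designFixture()
  cfg <- pipelineDefaults()$design
  cfg$u7_length <- c(20, 20)         # single length: count is closed-form
  cand <- enumerateCandidates(fx$pe, fx$demo$sequence, "u7", cfg)
  L <- 53L; FL <- as.integer(cfg$flank)
  expect_identical(nrow(cand), L + 2L * FL - 20L + 1L)
  expect_true(all(cand$length == 20L))
  # every antisense sequence re-complemented equals its target span
  for (i in sample(nrow(cand), 10)) {
    target <- substr(fx$demo$sequence, cand$target_start[i] + 1L,
                     cand$target_end[i])
    expect_identical(revComp(cand$antisense_seq[i]), target)
  }
})

test_that("candidates spanning a splice-site core window score 1", {
  fx <- designFixture()
  cand <- enumerateCandidates(fx$pe, fx$demo$sequence, "u7")
  don <- fx$pe$donor_pos
  covering <- cand$target_start <= don - 3L & cand$target_end >= don + 6L
  expect_true(all(cand$site_overlap_score[covering] == 1))
  expect_true(all(cand$site_overlap_score >= 0 &
                    cand$site_overlap_score <= 1))
})

test_that("ranking is monotone in each component and matches arithmetic", {
  fx <- designFixture()
  cand <- enumerateCandidates(fx$pe, fx$demo$sequence, "u7")
  two <- cand[c(1L, 1L), ]
  two$accessibility_score <- c(0.9, 0.1)
  two$am_id <- c("open", "closed")
  ranked <- rankCandidates(two)
  expect_identical(ranked$am_id, c("open", "closed"))

  ranked_all <- rankCandidates(cand)
  w <- pipelineDefaults()$design$weights
  eseMax <- max(cand$ese_score)
  recompute <- w[["site"]] * cand$site_overlap_score +
    w[["ese"]] * (if (eseMax > 0) cand$ese_score / eseMax else 0) +
    w[["acc"]] * cand$accessibility_score -
    w[["len"]] * pmax(0, (cand$length - 25) / 25)
  ord <- order(-recompute, cand$target_start)
  expect_equal(ranked_all$composite_score, recompute[ord])
  expect_identical(ranked_all$am_id, cand$am_id[ord])

  expect_error(rankCandidates(cand, weights = c(site = -1, ese = 1,
                                                acc = 1, len = 0.5)),
               "non-negative")
})

test_that("shift-by-k generates the two rescue variants", {
  fx <- designFixture()
  cand <- enumerateCandidates(fx$pe, fx$demo$sequence, "u7")
  seed <- cand[10L, ]
  sh <- shiftCandidate(seed, fx$pe, fx$demo$sequence)
  expect_identical(nrow(sh), 3L)
  expect_identical(sh$target_start,
                   seed$target_start + c(0L, -5L, 5L))
  expect_identical(unique(sh$length), seed$length)
  # shifted candidates differ only in target interval (and its scores)
  expect_identical(unique(sh$modality), seed$modality)
})

test_that("a fully paired ESE-rich target ranks below an open one", {
  # identical candidates except that one sits in closed structure
  fx <- designFixture()
  cand <- enumerateCandidates(fx$pe, fx$demo$sequence, "u7")
  eseRich <- cand[which.max(cand$ese_score), ]
  open <- eseRich; open$ese_score <- eseRich$ese_score
  eseRich$accessibility_score <- 0
  open$accessibility_score <- 0.95
  eseRich$am_id <- "paired"; open$am_id <- "open"
  ranked <- rankCandidates(rbind(eseRich, open))
  expect_identical(ranked$am_id[1L], "open")
})
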