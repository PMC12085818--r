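r1Fixture <- function(seed = 1L, n = 10000L) {
  demo <- demoLocus()
  vars <- demoVariantTable(demo$model)
  list(demo = demo, vars = vars,
       region = c(modelExons(demo$model)$start[1L],
                  modelExons(demo$model)$end[2L]),
       cfg = simulationConfig(seed = seed, n_molecules = n))
}

test_that("injected variants change exactly the stated bases", {
  fx <- r1Fixture()
  v <- fx$vars[fx$vars$hgvs_c == "c.120+1336A>G", ]
  wt <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                      cfg = fx$cfg)
  mut <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                       variants = v, cfg = fx$cfg)
  diffs <- which(strsplit(wt@sequence, "")[[1L]] !=
                   strsplit(mut@sequence, "")[[1L]])
  expect_length(diffs, 1L)
  # the mutant registry gains a donor site absent from the wild type
  newSites <- mut@siteRegistry[!paste(mut@siteRegistry$kind,
                                      mut@siteRegistry$boundary_pos) %in%
                                 paste(wt@siteRegistry$kind,
                                       wt@siteRegistry$boundary_pos), ]
  expect_identical(newSites$kind, "donor")

  same <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                        cfg = fx$cfg)
  expect_identical(same@sequence, wt@sequence)

  two <- fx$vars[fx$vars$hgvs_c %in% c("c.121-210C>T", "c.121-149G>A"), ]
  mut2 <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                        variants = two, cfg = fx$cfg)
  expect_identical(sum(strsplit(wt@sequence, "")[[1L]] !=
                         strsplit(mut2@sequence, "")[[1L]]), 2L)

  bad <- v; bad$ref <- "C"
  expect_error(buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                             variants = bad, cfg = fx$cfg),
               "reference mismatch")
})

test_that("without pseudoexon sites or skipping everything is correct", {
  fx <- r1Fixture()
  wt <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                      cfg = fx$cfg)
  bare <- wt
  bare@siteRegistry <- wt@siteRegistry[0L, ]
  sim <- simulateSplicing(bare, fx$cfg)
  expect_identical(sim$count[sim$isoform == "correct"],
                   fx$cfg$n_molecules)
})

test_that("simulated fractions match the closed-form weights", {
  fx <- r1Fixture(seed = 7L)
  mut <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
    variants = fx$vars[fx$vars$hgvs_c == "c.121-210C>T", ], cfg = fx$cfg)
  sim <- simulateSplicing(mut, fx$cfg)
  expected <- sim$weight / sum(sim$weight)
  observed <- sim$count / sum(sim$count)
  # multinomial at n = 10000: all fractions within ~4 binomial sd
  tol <- 4 * sqrt(pmax(expected * (1 - expected), 1e-6) /
                    fx$cfg$n_molecules)
  expect_true(all(abs(observed - expected) < tol))
  # with near-saturated pseudoexon sites the PE fraction is substantial
  peFrac <- sum(observed[grepl("^PE_", sim$isoform)])
  expect_gt(peFrac, 0.3)
})

test_that("full blocking of the pseudoexon donor removes its isoforms", {
  fx <- r1Fixture(seed = 5L)
  v <- fx$vars[fx$vars$hgvs_c == "c.121-210C>T", ]
  don <- fx$demo$features$pe2_donor
  blockCfg <- simulationConfig(seed = 5L,
    blocking = data.frame(am_id = "u7_block", target_start = don - 12L,
                          target_end = don + 13L, epsilon = 1))
  mut <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                       variants = v, cfg = fx$cfg)
  free <- simulateSplicing(mut, fx$cfg)
  blocked <- simulateSplicing(mut, blockCfg)
  target <- sprintf("PE_%d_%d", fx$demo$features$pe2_acceptor, don)
  expect_gt(free$count[free$isoform == target], 0L)
  expect_identical(blocked$count[blocked$isoform == target], 0L)
})

test_that("observables are exact with the noise switched off", {
  fx <- r1Fixture()
  cfg <- simulationConfig(seed = 2L, sizing_noise_sd = 0,
                          area_bias_per_bp = 0)
  wt <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                      cfg = cfg)
  sim <- simulateSplicing(wt, cfg)
  obs <- emitObservables(sim, wt, cfg)
  kept <- sim[sim$count > 0L, ]
  expect_equal(obs$peaks$fragment_length_bp, kept$length)
  expect_equal(obs$peaks$area / sum(obs$peaks$area),
               kept$count / sum(kept$count))
  # tables round-trip through the package readers
  pf <- tempfile(); jf <- tempfile()
  writePeakTable(obs$peaks, pf)
  writeJunctionTable(obs$junctions, jf)
  expect_equal(readPeakTable(pf), obs$peaks, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(readJunctionTable(jf), obs$junctions, ignore_attr = TRUE)
})

test_that("emitted junctions feed back into background-event calling", {
  fx <- r1Fixture(seed = 3L)
  v <- fx$vars[fx$vars$hgvs_c == "c.121-210C>T", ]
  mut <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                       variants = v, cfg = fx$cfg)
  sim <- simulateSplicing(mut, fx$cfg)
  obs <- emitObservables(sim, mut, fx$cfg)
  obs$junctions$sample_count <- 1L
  ev <- callBackgroundEvents(obs$junctions, fx$demo$model, top_k = Inf)
  pe <- ev[ev$event_type == "pe_inclusion", ]
  f <- fx$demo$features
  hit <- pe[pe$start == f$pe2_acceptor & pe$end == f$pe2_donor, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$end - hit$start, 159L)
})

test_that("the same seed reproduces bit-identical outputs", {
  fx <- r1Fixture(seed = 11L)
  wt <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                      cfg = fx$cfg)
  simA <- simulateSplicing(wt, fx$cfg)
  simB <- simulateSplicing(wt, fx$cfg)
  expect_identical(simA, simB)
  obsA <- emitObservables(simA, wt, fx$cfg)
  obsB <- emitObservables(simB, wt, fx$cfg)
  expect_identical(obsA, obsB)
  other <- simulateSplicing(wt, simulationConfig(seed = 12L))
  expect_false(identical(simA$count, other$count))
})

test_that("pseudoexon inclusion responds monotonically to donor strength", {
  fx <- r1Fixture()
  wt <- buildMinigene(fx$demo$sequence, fx$demo$model, fx$region,
                      cfg = fx$cfg)
  acc <- fx$demo$features$pewt4_acceptor
  fracs <- vapply(c(-2, 0, 2, 4, 6), function(sc) {
    con <- wt
    con@siteRegistry <- data.frame(
      kind = c("acceptor", "donor"),
      boundary_pos = c(acc, acc + 170L) - wt@insertLocusStart +
        wt@insertSpan[1L],
      score = c(4, sc), method = "pwm", constitutive = FALSE)
    sim <- simulateSplicing(con, simulationConfig(seed = 31L))
    sum(sim$count[grepl("^PE_", sim$isoform)]) / sum(sim$count)
  }, numeric(1))
  expect_true(all(diff(fracs) >= -0.01))   # isotonic up to sampling noise
})
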