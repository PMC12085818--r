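demoSelectionCfg <- function() {
  cfg <- pipelineDefaults()$selection
  cfg$maf_exceptions <- "c.121-210C>T"   # evidence-backed allow-list entry
  cfg
}

test_that("the packaged candidate table yields 15 selected variants", {
  demo <- demoLocus()
  vars <- demoVariantTable(demo$model)
  sel <- selectVariants(vars, demo$model, demoSelectionCfg())
  expect_identical(sum(sel$passed), 15L)
  expect_identical(sum(sel$tier == "high"), 8L)
  expect_identical(sum(sel$tier == "medium"), 7L)
  expect_true(all(sel$reasons[sel$passed] == ""))
})

test_that("the common variant passes only through the allow-list", {
  demo <- demoLocus()
  vars <- demoVariantTable(demo$model)
  sel <- selectVariants(vars, demo$model, demoSelectionCfg())
  row <- sel[sel$hgvs_c == "c.121-210C>T", ]
  expect_true(row$passed)
  expect_identical(row$tier, "high")
  noEx <- selectVariants(vars, demo$model, pipelineDefaults()$selection)
  row2 <- noEx[noEx$hgvs_c == "c.121-210C>T", ]
  expect_false(row2$passed)
  expect_match(row2$reasons, "maf")
})

test_that("variants too close to an exon are excluded with the distance", {
  m <- toyModel()
  v <- data.frame(hgvs_c = "c.121-50A>G", ref = "A", alt = "G",
                  ds_ag = 0.9, ds_al = 0, ds_dg = 0, ds_dl = 0,
                  maf = NA_real_, source = "DB")
  v$locus_pos <- hgvsToLocus(v$hgvs_c, m)
  sel <- selectVariants(v, m)
  expect_false(sel$passed)
  expect_match(sel$reasons, "distance=50<100")
})

test_that("missing predictions are reported, never silently dropped", {
  m <- toyModel()
  v <- data.frame(hgvs_c = "c.121-300A>G", ref = "A", alt = "G",
                  ds_ag = NA_real_, ds_al = NA_real_, ds_dg = NA_real_,
                  ds_dl = NA_real_, maf = NA_real_, source = "DB")
  v$locus_pos <- hgvsToLocus(v$hgvs_c, m)
  sel <- selectVariants(v, m)
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$tier, "excluded")
  expect_match(sel$reasons, "no_prediction")
})

test_that("medium-score variants need a co-located high-score anchor", {
  m <- toyModel()
  mk <- function(hgvs, ds) {
    v <- data.frame(hgvs_c = hgvs, ref = "A", alt = "G", ds_ag = ds,
                    ds_al = 0, ds_dg = 0, ds_dl = 0, maf = NA_real_,
                    source = "DB")
    v$locus_pos <- hgvsToLocus(hgvs, m)
    v
  }
  lone <- selectVariants(mk("c.121-300A>G", 0.3), m)
  expect_false(lone$passed)
  pair <- selectVariants(rbind(mk("c.121-300A>G", 0.3),
                               mk("c.121-400A>G", 0.8)), m)
  expect_true(all(pair$passed))
  expect_identical(sort(pair$tier), c("high", "medium"))
})

test_that("selection outcome is invariant to input order and monotone in DS", {
  demo <- demoLocus()
  vars <- demoVariantTable(demo$model)
  cfg <- demoSelectionCfg()
  base <- selectVariants(vars, demo$model, cfg)
  set.seed(21)
  for (i in 1:5) {
    perm <- sample(nrow(vars))
    sel <- selectVariants(vars[perm, ], demo$model, cfg)
    expect_identical(sel$passed[order(sel$hgvs_c)],
                     base$passed[order(base$hgvs_c)])
  }
  # raising the splice-gain DS never flips a passed variant to excluded
  for (i in 1:5) {
    boosted <- vars
    j <- sample(nrow(vars), 1)
    boosted$ds_dg[j] <- min(1, max(boosted$ds_dg[j], 0) + runif(1))
    selB <- selectVariants(boosted, demo$model, cfg)
    was <- base$passed
    now <- selB$passed
    expect_true(all(!was | now))
  }
})
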