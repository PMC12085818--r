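test_that("peaks are assigned to the nearest expected length within tol", {
  peaks <- data.frame(fragment_length_bp = c(399.7, 559.2), area = c(510, 490))
  m <- matchPeaksToIsoforms(peaks, c(correct = 400, PE = 559))
  expect_equal(unname(m$areas), c(510, 490))
  expect_identical(nrow(m$unassigned), 0L)

  far <- data.frame(fragment_length_bp = 480, area = 100)
  m2 <- matchPeaksToIsoforms(far, c(correct = 400, PE = 559))
  expect_equal(sum(m2$areas), 0)
  expect_identical(nrow(m2$unassigned), 1L)

  expect_error(matchPeaksToIsoforms(peaks, c(a = 400, b = 403)),
               "2\\*tol")
})

test_that("noisy peak assignment equals the nearest-neighbour oracle", {
  set.seed(51)
  expected <- setNames(seq(200, 690, by = 10), paste0("iso", 1:50))
  truth <- sample(names(expected), 50, replace = TRUE)
  peaks <- data.frame(
    fragment_length_bp = expected[truth] + runif(50, -1.5, 1.5),
    area = runif(50, 10, 100))
  m <- matchPeaksToIsoforms(peaks, expected)
  oracle <- setNames(numeric(50), names(expected))
  for (i in seq_len(50)) {
    d <- abs(expected - peaks$fragment_length_bp[i])
    j <- names(expected)[which.min(d)]
    if (min(d) <= 2) oracle[j] <- oracle[j] + peaks$area[i]
  }
  expect_equal(m$areas, oracle)
})

test_that("fractions normalise to one and respect the display rule", {
  q <- quantifyFractions(c(A = 510, B = 490), "s1")
  expect_equal(unname(isoformFractions(q)), c(0.51, 0.49))
  expect_equal(sum(isoformFractions(q)), 1)

  q1 <- quantifyFractions(c(only = 42), "s2")
  expect_equal(unname(isoformFractions(q1)), 1)

  # the 5% rule is display-only: hidden from display, present in data
  q2 <- quantifyFractions(c(A = 40, B = 960), "s3")
  expect_identical(names(isoformFractions(q2, all = FALSE)), "B")
  expect_equal(unname(isoformFractions(q2)["A"]), 0.04)

  # scaling all areas leaves fractions unchanged
  q3 <- quantifyFractions(c(A = 40, B = 960) * 17.3, "s4")
  expect_equal(isoformFractions(q3), isoformFractions(q2))

  expect_error(quantifyFractions(c(A = 0, B = 0)), "zero")
})

test_that("fold-changes reproduce the reported reductions", {
  expect_equal(foldChange(0.51, 0.16), 3.2)
  expect_equal(foldChange(0.51, 0.04), 12.8)
  expect_equal(foldChange(0.61, 0.16), 3.8)
  expect_equal(foldChange(0.4, 0.4), 1.0)
  lost <- foldChange(0.5, 0)
  expect_true(is.na(lost))
  expect_identical(attr(lost, "sentinel"), "complete_loss")
  expect_error(foldChange(0, 0.5), "reference")
})

test_that("reciprocal fold-changes multiply to one within rounding", {
  # reporting rounds to one decimal, so the reciprocal product deviates
  # from 1 by at most ~0.05 * (r + 1/r) for a ratio r
  set.seed(52)
  for (i in 1:20) {
    a <- runif(1, 0.3, 1)
    b <- min(1, a * runif(1, 1 / 3, 3))
    r <- a / b
    expect_equal(foldChange(a, b) * foldChange(b, a), 1,
                 tolerance = 0.06 * (r + 1 / r))
  }
})

test_that("antisense efficacy is the reduction of PE-containing isoforms", {
  ctrl <- quantifyFractions(c(correct = 8, PE = 89, skip = 3), "ctrl")
  trt <- quantifyFractions(c(correct = 80, PE = 8, skip = 12), "circRNA-60")
  eff <- amEfficacy(ctrl, trt, pe_isoform_names = "PE",
                    neighbor_skip_names = "skip")
  expect_equal(eff$pe_reduction_points, 81)
  expect_equal(eff$correct_transcript_fraction, 0.80)
  expect_equal(eff$neighbor_skip_fraction, 0.12)

  same <- amEfficacy(ctrl, ctrl, pe_isoform_names = "PE")
  expect_equal(same$pe_reduction_points, 0)

  expect_error(amEfficacy(ctrl, trt, pe_isoform_names = "nope"),
               "unknown isoform")
})

test_that("efficacy equals direct arithmetic on random quantifications", {
  set.seed(53)
  for (i in 1:10) {
    a <- runif(4); a <- a / sum(a); names(a) <- c("correct", "p1", "p2", "s")
    b <- runif(4); b <- b / sum(b); names(b) <- names(a)
    eff <- amEfficacy(quantifyFractions(a), quantifyFractions(b),
                      pe_isoform_names = c("p1", "p2"),
                      neighbor_skip_names = "s")
    expect_equal(eff$pe_reduction_points,
                 100 * ((a["p1"] + a["p2"]) - (b["p1"] + b["p2"])),
                 ignore_attr = TRUE)
    expect_equal(eff$pe_reduction_relative,
                 100 * (sum(a[c("p1","p2")]) - sum(b[c("p1","p2")])) /
                   sum(a[c("p1","p2")]), ignore_attr = TRUE)
  }
})

test_that("the splice-altering classifier keys on the correct transcript", {
  wt <- quantifyFractions(c(correct = 60, PE = 40), "wt")
  mut <- quantifyFractions(c(correct = 20, PE = 80), "mut")
  expect_true(classifySpliceAltering(wt, mut))
  expect_false(classifySpliceAltering(wt, wt))
})
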