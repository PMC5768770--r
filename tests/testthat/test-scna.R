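test_that("median integer ploidy is the weighted median of total CN", {
  expect_equal(medianIntegerPloidy(toyProfile(rep(1, 4), rep(1, 4))), 2L)
  expect_equal(medianIntegerPloidy(toyProfile(rep(2, 4), rep(2, 4))), 4L)
  # 60% of weight at CN 3, 40% at CN 2
  p <- toyProfile(c(2, 1), c(1, 1), w = c(6e6, 4e6))
  expect_equal(medianIntegerPloidy(p), 3L)
  # exact half-weight tie resolves to the lower integer
  p <- toyProfile(c(1, 2), c(1, 2), w = c(5e6, 5e6))
  expect_equal(medianIntegerPloidy(p), 2L)
  # SNP counts outweigh segment lengths when present on every segment
  p <- toyProfile(c(2, 1), c(1, 1), w = c(1e6, 9e6), nSNPs = c(900, 100))
  expect_equal(medianIntegerPloidy(p), 3L)
})

test_that("relative calls classify deviations from ploidy", {
  p <- toyProfile(c(1, 1, 2, 3, 1), c(1, 0, 1, 3, 0),
                  w = rep(2e6, 5))                     # ploidy 2
  rc <- relativeCalls(p)
  expect_equal(rc$delta, c(0L, -1L, 1L, 4L, -1L))
  expect_equal(rc$class, c("neutral", "loss1", "gain1", "gain2plus",
                           "loss1"))
})

test_that("GII and adGII reproduce hand-computed fractions", {
  # no deviation
  s <- instabilityScores(toyProfile(rep(1, 10), rep(1, 10)))
  expect_equal(c(s$gii, s$adgii), c(0, 0))
  # 30% of the genome at delta +1
  p <- toyProfile(c(rep(2, 3), rep(1, 7)), rep(1, 10))
  s <- instabilityScores(p)
  expect_equal(s$gii, 0.3)
  expect_equal(s$adgii, 0)
  # 10% at delta +2, 20% at delta -1
  p <- toyProfile(c(3, 1, 1, rep(1, 7)), c(1, 0, 0, rep(1, 7)))
  s <- instabilityScores(p)
  expect_equal(s$gii, 0.3)
  expect_equal(s$adgii, 0.1)
})

test_that("gii >= adgii on random profiles", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    nMin <- sample(0:2, n, TRUE)
    nMaj <- pmax(nMin + sample(0:3, n, TRUE), 1L)
    s <- instabilityScores(toyProfile(nMaj, pmin(nMin, nMaj),
                                      w = sample(1e5:1e7, n)))
    expect_gte(s$gii, s$adgii)
  }
})

test_that("instability scores are invariant to segment splitting", {
  nMaj <- c(3, 1, 2, 1); nMin <- c(2, 1, 0, 0)
  w <- c(4e6, 3e6, 2e6, 1e6)
  s1 <- instabilityScores(toyProfile(nMaj, nMin, w))
  # split every segment into two adjacent halves
  s2 <- instabilityScores(toyProfile(rep(nMaj, each = 2),
                                     rep(nMin, each = 2),
                                     rep(w / 2, each = 2)))
  expect_identical(s1$gii, s2$gii)
  expect_identical(s1$adgii, s2$adgii)
  expect_identical(s1$ploidy, s2$ploidy)
})

test_that("relative call directions survive a uniform genome doubling", {
  set.seed(81)
  nMin <- sample(0:2, 12, TRUE)
  nMaj <- nMin + sample(0:2, 12, TRUE)
  p1 <- toyProfile(nMaj, nMin)
  p2 <- toyProfile(2L * nMaj, 2L * nMin)
  expect_equal(ploidy(p2), 2L * ploidy(p1))
  expect_identical(sign(relativeCalls(p2)$delta),
                   sign(relativeCalls(p1)$delta))
})

test_that("feature mapping applies the 25%-overlap largest-wins rule", {
  seg <- data.frame(chrom = "1", start = c(1, 1001, 2001),
                    end = c(1000, 2000, 5000),
                    nMajor = c(2, 3, 1), nMinor = c(1, 1, 1))
  p <- SectorProfile("S1", seg, purity = 0.8)
  feat <- function(s, e, nm) {
    gr <- GenomicRanges::GRanges("1", IRanges::IRanges(s, e))
    S4Vectors::mcols(gr)$name <- nm
    gr
  }
  # gene fully inside one segment takes its CN
  fc <- mapToFeatures(p, feat(100, 200, "inside"))
  expect_true(fc$assigned)
  expect_equal(fc$totalCN, 3L)
  # 60%/40% split between two segments: the 60% segment wins
  fc <- mapToFeatures(p, feat(601, 1600, "split"))   # 400 in seg1, 600 in seg2
  expect_equal(fc$totalCN, 4L)
  # no segment reaches 25% of the feature: unassigned
  segGap <- data.frame(chrom = "1", start = c(1, 9001),
                       end = c(2000, 10000),
                       nMajor = c(2, 3), nMinor = c(1, 1))
  pg <- SectorProfile("S1", segGap, purity = 0.8)
  fc <- mapToFeatures(pg, feat(1801, 12000, "sparse"))  # 200/10200, 1000/10200
  expect_false(fc$assigned)
  expect_true(is.na(fc$totalCN))
  # a single overlapping segment assigns regardless of the 25% rule
  fc <- mapToFeatures(pg, feat(1991, 8000, "single"))
  expect_true(fc$assigned)
  expect_equal(fc$totalCN, 3L)
})

test_that("LOH requires zero minor copies with at least one copy left", {
  p <- toyProfile(c(2, 1, 1, 2), c(0, 1, 0, 2), w = rep(2.5e6, 4))
  res <- detectLoh(p)
  expect_equal(res$segments$loh, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$fraction, 0.5)
  # quarter of the genome at minor zero
  p <- toyProfile(c(2, 1, 1, 1), c(0, 1, 1, 1))
  expect_equal(detectLoh(p)$fraction, 0.25)
})

test_that("SCNA-ITH separates truncal from late alterations", {
  fc <- function(cn) data.frame(feature = paste0("f", seq_along(cn)),
                                totalCN = cn, stringsAsFactors = FALSE)
  # f1 gained everywhere (truncal), f2 gained in 2/3 (late),
  # f3 conflicting directions (late), f4 neutral everywhere (unaltered)
  res <- scnaIth(list(fc(c(3, 3, 3, 2)), fc(c(3, 3, 1, 2)),
                      fc(c(3, 2, 3, 2))),
                 ploidies = c(2, 2, 2))
  expect_equal(res$labels$label, c("truncal", "late", "late", "unaltered"))
  expect_equal(res$lateFraction, 0.5)
  expect_error(scnaIth(list(fc(2), fc(2)), ploidies = c(2, 2)),
               ">= 3 profiled sectors")
})
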