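test_that("presence matrices follow the configured detection rule", {
  mkDec <- function(key, sector, assay, passed) {
    data.frame(key = key, patient_id = "P01", sector_id = sector,
               assay = assay, passed = passed, stringsAsFactors = FALSE)
  }
  dec <- rbind(
    mkDec("1:10:C:T", c("S1", "S2", "S3"), "deepseq", c(TRUE, TRUE, FALSE)),
    mkDec("1:20:C:T", c("S1", "S2", "S3"), "deepseq", FALSE),
    mkDec("1:30:C:T", c("S1", "S2", "S3"), "deepseq", TRUE)
  )
  pm <- buildPresenceMatrix(dec)
  m <- presence(pm)
  expect_equal(dim(m), c(2L, 3L))          # the all-fail mutation is dropped
  expect_equal(unname(m["1:10:C:T", ]), c(TRUE, TRUE, FALSE))
  expect_false("1:20:C:T" %in% rownames(m))

  # exome fallback only where no deep-seq decision exists for that sector
  dec2 <- rbind(
    mkDec("1:10:C:T", c("S1", "S2"), "deepseq", c(TRUE, FALSE)),
    mkDec("1:10:C:T", c("S2", "S3"), "exome", TRUE)
  )
  m2 <- presence(buildPresenceMatrix(dec2, sectors = c("S1", "S2", "S3")))
  expect_equal(unname(m2["1:10:C:T", ]), c(TRUE, FALSE, TRUE))

  expect_error(buildPresenceMatrix(mkDec("1:10:C:T", "S1", "deepseq", TRUE)),
               ">= 2 sectors")
})

test_that("trunk/branch/private labels follow presence counts", {
  m <- rbind(
    matrix(TRUE, 6, 4),                          # trunk
    matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 4, byrow = TRUE),
    matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 4, byrow = TRUE),  # branch
    matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 4, byrow = TRUE)  # private
  )
  cls <- classifyMutations(toyPresence(m))
  expect_equal(unname(cls$counts), c(6L, 4L, 2L))
  expect_equal(sum(cls$counts), nrow(m))
  expect_equal(as.character(cls$labels[1]), "trunk")
  expect_equal(as.character(cls$labels[11]), "private")
  expect_equal(computePith(cls), 50)
})

test_that("pITH identities hold: all-trunk 0, no-trunk 100, complements", {
  allTrunk <- toyPresence(matrix(TRUE, 5, 3))
  expect_equal(computePith(allTrunk), 0)
  noTrunk <- toyPresence(rbind(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE)))
  expect_equal(computePith(noTrunk), 100)
  set.seed(21)
  for (i in 1:25) {
    pm <- randomPresence(30, sample(2:8, 1))
    cls <- classifyMutations(pm)
    trunkPct <- 100 * cls$counts[["n_trunk"]] / sum(cls$counts)
    expect_identical(computePith(cls) + trunkPct, 100)
  }
})

test_that("Hamming distances count discordant mutations; normal = burden", {
  m <- rbind(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE))
  pm <- toyPresence(m)
  d <- hammingDistances(pm, includeNormal = FALSE)
  expect_equal(unname(diag(d)), c(0L, 0L, 0L))
  expect_equal(d["S2", "S3"], 2L)          # S2 has row1 only, S3 row2 only
  dn <- hammingDistances(pm, includeNormal = TRUE)
  expect_equal(unname(dn["normal", c("S1", "S2", "S3")]),
               unname(colSums(m)))
  # identical sectors at distance zero
  dup <- toyPresence(cbind(m, m[, 1]))
  expect_equal(hammingDistances(dup, FALSE)["S1", "S4"], 0L)
  # metric property on random matrices
  set.seed(5)
  for (i in 1:10) {
    d <- hammingDistances(randomPresence(25, 5))
    for (a in 1:5) for (b in 1:5) for (cc in 1:5) {
      expect_true(d[a, b] <= d[a, cc] + d[cc, b])
    }
  }
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  # terminal branch lengths: a = (dAB + dAC - dBC)/2 = 2, b = 3, c = 7
  lens <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                        tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[c("A", "B", "C")], c(A = 2, B = 3, C = 7))
})

test_that("NJ recovers additive trees and agrees with the reference", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n)
    d <- ape::cophenetic.phylo(gen)
    mine <- neighborJoining(d)
    expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(mine)), 0,
                 ignore_attr = TRUE)
    ref <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(mine)), 0,
                 ignore_attr = TRUE)
    # branch lengths reproduce the additive distances
    expect_equal(ape::cophenetic.phylo(mine)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("degenerate NJ inputs: all-zero distances and two taxa", {
  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighborJoining(d0)
  expect_true(all(tr$edge.length == 0))
  expect_setequal(tr$tip.label, letters[1:4])
  expect_warning(neighborJoining(matrix(c(0, 2, 2, 0), 2,
                                        dimnames = list(c("A", "B"), NULL))),
                 "degenerate")
  expect_error(neighborJoining(matrix(0, 1, 1)), ">= 2 taxa")
})

test_that("subsampled trunk ratio matches enumeration and edge cases", {
  set.seed(41)
  m <- presence(randomPresence(40, 5))
  # k = n: equals the full-matrix trunk proportion with zero variance
  full <- sum(rowSums(m) == 5) / nrow(m)
  expect_equal(subsampleTrunkRatio(toyPresence(m), k = 5, nIter = 5,
                                   seed = 1), full)
  # all-trunk matrix gives 1 for any k
  at <- toyPresence(matrix(TRUE, 10, 4))
  for (k in 2:4) expect_equal(subsampleTrunkRatio(at, k, seed = 1), 1)
  expect_error(subsampleTrunkRatio(at, k = 5), "exceeds")
  # Monte-Carlo mean close to exhaustive enumeration (many iterations)
  pm <- toyPresence(m)
  mc <- subsampleTrunkRatio(pm, k = 2, nIter = 4000, seed = 2)
  expect_equal(mc, enumTrunkRatio(m, 2), tolerance = 0.02)
})

test_that("burden gain matches enumeration and is 0 for clonal tumors", {
  at <- toyPresence(matrix(TRUE, 10, 4))
  for (k in 2:4) expect_equal(burdenGain(at, k, seed = 1), 0)
  expect_equal(burdenGain(at, k = 1), 0)
  set.seed(51)
  m <- presence(randomPresence(40, 5))
  mc <- burdenGain(toyPresence(m), k = 3, nIter = 4000, seed = 3)
  expect_equal(mc, enumBurdenGain(m, 3), tolerance = 1.5)
})

test_that("expected trunk ratio shrinks (weakly) as more sectors are drawn", {
  set.seed(61)
  for (i in 1:10) {
    m <- presence(randomPresence(50, 6))
    ratios <- vapply(2:6, function(k) enumTrunkRatio(m, k), numeric(1))
    expect_true(all(diff(ratios) <= 1e-12))
  }
})
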