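smallCfg <- function(...) {
  simConfig(nPatients = 3, sectorRange = c(3, 5), mutationsPerTumor = 40,
            scnaCoverage = 1, ...)
}

test_that("simulated tumors respect the configured structure", {
  cfg <- smallCfg()
  tm <- simulateTumor(cfg, 2, seed = 7)
  tr <- tm$truth
  n <- nrow(tr$sectors)
  expect_true(n >= 3 && n <= 5)
  expect_equal(tm$patient_id, "P02")
  # clade labels consistent with carrier sector counts
  carriers <- strsplit(tr$mutations$sectors, ";")
  sizes <- lengths(carriers)
  expect_true(all(sizes[tr$mutations$clade == "trunk"] == n))
  expect_true(all(sizes[tr$mutations$clade == "private"] == 1))
  br <- sizes[tr$mutations$clade == "branch"]
  expect_true(all(br > 1 & br < n))
  # purity within the configured range
  expect_true(all(tr$sectors$purity >= 0.4 & tr$sectors$purity <= 0.9))
  # an EGFR truncal driver is always planted
  eg <- tr$mutations[tr$mutations$gene == "EGFR", ]
  expect_equal(nrow(eg), 1L)
  expect_equal(eg$clade, "trunk")
})

test_that("emitted tables pass core validation and are key-consistent", {
  tm <- simulateTumor(smallCfg(), 1, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeVariants(tm$variants, f)
  v2 <- readVariants(f)                        # full column validation
  expect_equal(nrow(v2), nrow(tm$variants))
  expect_setequal(unique(variantKey(tm$variants)), tm$truth$mutations$key)
  fs <- withr::local_tempfile(); fp <- withr::local_tempfile()
  writeSegments(tm$profiles, fs, fp)
  profs <- readSegments(fs, fp)                # overlap / allele validation
  expect_equal(length(profs), length(tm$profiles))
})

test_that("cohort generation is deterministic and order-independent", {
  cfg <- smallCfg()
  c1 <- simulateCohort(cfg, seed = 5)
  c2 <- simulateCohort(cfg, seed = 5)
  expect_identical(c1$P02$variants, c2$P02$variants)
  # a patient's stream depends only on the master seed and its id
  solo <- simulateTumor(cfg, 2, seed = clonarch:::.patientSeed(5, "P02"))
  expect_identical(solo$variants, c1$P02$variants)
  c3 <- simulateCohort(cfg, seed = 6)
  expect_false(identical(c1$P01$variants$t_alt, c3$P01$variants$t_alt))
})

test_that("read counts converge to the analytic VAF at extreme depth", {
  cfg <- smallCfg(deepseqDepth = 1e5)
  tm <- simulateTumor(cfg, 1, seed = 11)
  tr <- tm$truth
  v <- tm$variants[tm$variants$assay == "deepseq", ]
  # check truncal SNVs sector by sector against the closed-form VAF
  tmut <- tr$mutations[tr$mutations$clade == "trunk" &
                       tr$mutations$variant_class == "SNV", ]
  for (s in seq_len(nrow(tr$sectors))) {
    sid <- tr$sectors$sector_id[s]
    p <- tr$sectors$purity[s]
    prof <- tr$profilesAll[[sid]]
    mc <- S4Vectors::mcols(cnSegments(prof))
    vs <- v[v$sector_id == sid, ]
    vaf <- tumorVAF(vs)[match(tmut$key, variantKey(vs))]
    cnt <- (mc$nMajor + mc$nMinor)[tmut$seg_index]
    mEff <- pmin(tmut$multiplicity, pmax(mc$nMajor[tmut$seg_index], 1))
    expected <- p * mEff / (p * cnt + 2 * (1 - p))
    expect_equal(vaf, expected, tolerance = 0.02)
  }
})

test_that("single-clone configurations give zero heterogeneity", {
  cfg <- simConfig(nPatients = 1, sectorRange = c(4, 4),
                   mutationsPerTumor = 50, trunkShape1 = 1e6,
                   trunkShape2 = 1e-3, branchShare = 0)
  tm <- simulateTumor(cfg, 1, seed = 2)
  expect_true(all(tm$truth$mutations$clade == "trunk"))
  expect_equal(computePith(truePresenceMatrix(tm)), 0)
})

test_that("WGD tumors are detected and carry doubled truncal multiplicity", {
  cfg <- smallCfg(wgdProb = 1, preWgdFraction = 1)
  tm <- simulateTumor(cfg, 1, seed = 13)
  expect_true(tm$truth$wgd)
  r <- wgdTest(tm$profiles[[1]], nSim = 1000, seed = 1)
  expect_true(r$doubled)
  pre <- tm$truth$mutations$pre_wgd
  expect_true(all(tm$truth$mutations$multiplicity[pre] == 2L))
  expect_true(all(tm$truth$mutations$clade[pre] == "trunk"))
})

test_that("dominance cohorts realize the planted co-occurrence spec", {
  spec <- data.frame(gene = c("DOM", "NEEDY"), carriers = c(10, 10),
                     coDrivers = c(0, 2))
  sim <- simulateCohortForDominance(spec, nPatients = 40, seed = 3)
  tab <- dominanceScores(sim$mutations, sim$catalog, minCarriers = 5)
  expect_equal(tab$dominance[tab$gene == "DOM"], 1)
  expect_equal(tab$dominance[tab$gene == "NEEDY"], 1 / 3)
  expect_equal(sort(unique(table(sim$mutations$patient_id[
    sim$mutations$gene == "DOM"]))), 1)
  # infeasible spec rejected
  expect_error(simulateCohortForDominance(
    data.frame(gene = "X", carriers = 50, coDrivers = 0), nPatients = 10),
    "infeasible")
})
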