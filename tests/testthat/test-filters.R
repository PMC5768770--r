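test_that("exome SNV rules match the published thresholds", {
  # below the 6-read tumor support floor
  d <- filterExomeSnv(toyVariants(t_alt = 5, t_ref = 45, n_alt = 0))
  expect_false(d$passed)
  expect_match(d$failed_rules, "min_alt_reads")
  # low-VAF call with only 5x the normal frequency (10x required)
  d <- filterExomeSnv(toyVariants(t_alt = 10, t_ref = 90,
                                  n_alt = 2, n_ref = 98))
  expect_false(d$passed)
  expect_match(d$failed_rules, "tumor_normal_ratio")
  # clean high-VAF somatic call
  d <- filterExomeSnv(toyVariants(t_alt = 50, t_ref = 50, n_alt = 0))
  expect_true(d$passed)
  expect_identical(d$failed_rules, "")
  # normal support above 5 reads or 0.05 frequency
  d <- filterExomeSnv(toyVariants(t_alt = 50, t_ref = 50,
                                  n_alt = 6, n_ref = 54))
  expect_false(d$passed)
  expect_match(d$failed_rules, "normal_alt_reads")
  expect_match(d$failed_rules, "normal_vaf")
})

test_that("exome indel rules require >4 reads and VAF >= 0.1", {
  expect_false(filterExomeIndel(
    toyVariants(t_alt = 4, t_ref = 6, variant_class = "INS"))$passed)
  expect_true(filterExomeIndel(
    toyVariants(t_alt = 5, t_ref = 37, variant_class = "INS"))$passed)
  expect_false(filterExomeIndel(
    toyVariants(t_alt = 20, t_ref = 203, variant_class = "DEL"))$passed)
})

test_that("deep-seq SNV validation matches the published thresholds", {
  mk <- function(...) toyVariants(..., assay = "deepseq")
  # fewer than 10 alternate reads
  expect_false(validateDeepseqSnv(mk(t_alt = 9, t_ref = 2000), TRUE)$passed)
  # VAF < 0.05 needs >= 15 alternate reads
  expect_false(validateDeepseqSnv(
    mk(t_alt = 12, t_ref = 288), TRUE)$passed)       # VAF 0.04, 12 reads
  expect_true(validateDeepseqSnv(
    mk(t_alt = 16, t_ref = 384), TRUE)$passed)       # VAF 0.04, 16 reads
  # tumor VAF must be 5x the normal VAF (here only 4x)
  expect_false(validateDeepseqSnv(
    mk(t_alt = 200, t_ref = 800, n_alt = 5, n_ref = 95), TRUE)$passed)
  # exome membership is mandatory
  expect_false(validateDeepseqSnv(mk(t_alt = 200, t_ref = 800),
                                  FALSE)$passed)
  expect_error(validateDeepseqSnv(mk(t_alt = 200, t_ref = 800), NA),
               "exome-membership")
})

test_that("deep-seq indel validation enforces strand balance and floors", {
  mk <- function(...) toyVariants(..., assay = "deepseq",
                                  variant_class = "INS")
  # 95% of alternate reads on one strand
  expect_match(validateDeepseqIndel(
    mk(t_alt = 20, t_ref = 180, alt_fwd = 19, alt_rev = 1))$failed_rules,
    "strand_bias")
  # balanced, 10 reads, VAF 0.05, normal VAF 0.005: passes
  expect_true(validateDeepseqIndel(
    mk(t_alt = 10, t_ref = 190, n_alt = 1, n_ref = 199,
       alt_fwd = 5, alt_rev = 5))$passed)
  # VAF below the 0.03 floor
  expect_match(validateDeepseqIndel(
    mk(t_alt = 50, t_ref = 2450, alt_fwd = 25, alt_rev = 25))$failed_rules,
    "min_vaf")
  # zero alternate reads: strand fraction undefined, fails (not crashes)
  d <- validateDeepseqIndel(mk(t_alt = 0, t_ref = 200,
                               alt_fwd = 0, alt_rev = 0))
  expect_false(d$passed)
  expect_match(d$failed_rules, "strand_bias")
})

test_that("pass status increases monotonically with alt-read support", {
  # raising t_alt at fixed depth can only turn fail into pass
  for (assay in c("exome", "deepseq")) {
    depth <- if (assay == "exome") 100L else 1000L
    tAlt <- seq(0L, depth, by = if (assay == "exome") 2L else 20L)
    tAlt <- tAlt[tAlt < depth]
    v <- toyVariants(t_alt = tAlt, t_ref = depth - tAlt, assay = assay,
                     pos = seq_along(tAlt))
    passed <- if (assay == "exome") filterExomeSnv(v)$passed else
      validateDeepseqSnv(v, TRUE)$passed
    expect_true(all(diff(passed) >= 0), info = assay)
  }
})

test_that("decisions are order-independent and name every failed rule", {
  set.seed(11)
  n <- 40
  v <- toyVariants(
    t_alt = sample(0:60, n, TRUE), t_ref = sample(40:200, n, TRUE),
    n_alt = sample(0:8, n, TRUE), n_ref = 100,
    variant_class = sample(c("SNV", "INS", "DEL"), n, TRUE),
    assay = sample(c("exome", "deepseq"), n, TRUE),
    pos = seq_len(n)
  )
  v$alt_fwd <- rbinom(n, v$t_alt, 0.5)
  v$alt_rev <- v$t_alt - v$alt_fwd
  d1 <- filterVariants(v)
  perm <- sample(n)
  d2 <- filterVariants(v[perm, ])
  expect_equal(d2$passed, d1$passed[perm])
  expect_equal(d2$failed_rules, d1$failed_rules[perm])
  # passed <=> no failed rule named
  expect_identical(d1$passed, !nzchar(d1$failed_rules))
})

test_that("germline-blacklisted keys are failed with a named rule", {
  v <- toyVariants(t_alt = c(50, 50), t_ref = c(50, 50))
  bl <- variantKey(v)[1]
  d <- filterVariants(v, germlineBlacklist = bl)
  expect_false(d$passed[1])
  expect_match(d$failed_rules[1], "germline")
  expect_true(d$passed[2])
})

test_that("validation rates are validated/attempted per variant class", {
  # 20 exome SNVs, 17 validated
  ex <- toyVariants(t_alt = rep(50, 20), t_ref = 50, pos = 1:20)
  dd <- data.frame(key = variantKey(ex), passed = rep(c(TRUE, FALSE),
                                                      c(17, 3)),
                   variant_class = "SNV")
  r <- validationRate(ex, dd)
  expect_equal(r$snv_rate, 0.85)
  expect_true(is.na(r$indel_rate))
  dd$passed <- TRUE
  expect_equal(validationRate(ex, dd)$snv_rate, 1.0)
})

test_that("zero tumor depth is an error for SNV filters", {
  expect_error(filterExomeSnv(toyVariants(t_alt = 0, t_ref = 0)),
               "zero tumor depth")
})
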