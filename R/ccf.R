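## Cancer cell fraction (CCF), mutation multiplicity and mutation timing
## relative to copy gains / genome doubling.

#' Cancer cell fraction and mutant allele copy number
#'
#' For each mutation the mutant allele copy number is
#' `n_mut = VAF / purity * (purity * CNt + 2 * (1 - purity))`,
#' where `CNt` is the local total copy number. The integer multiplicity is
#' `m = clamp(round(n_mut), 1, nMajor)` (a mutation cannot sit on more
#' copies than the larger haplotype carries) and `ccf = n_mut / m`, not
#' forcibly capped at 1. A 95% Clopper–Pearson interval on the VAF is
#' propagated through the same linear map (at the fixed `m`) to give the
#' CCF interval; a mutation is clonal when that interval spans 1.
#'
#' @param tAlt,tRef tumor alternate/reference read counts (vectors). Zero
#'   depth is an error.
#' @param purity tumor purity in (0, 1] (scalar or vector).
#' @param cnTotal local total copy number per mutation; 0 makes the
#'   mutation not evaluable (all estimates NA).
#' @param cnMajor local major allele copy number per mutation (multiplicity
#'   cap).
#' @param conf confidence level for the VAF interval (default 0.95).
#' @return data.frame: `vaf`, `n_mut`, `multiplicity`, `ccf`, `ci_low`,
#'   `ci_high`, `clonal`.
#' @examples
#' ccfEstimate(tAlt = 25, tRef = 75, purity = 0.5, cnTotal = 2, cnMajor = 1)
#' @export
ccfEstimate <- function(tAlt, tRef, purity, cnTotal, cnMajor, conf = 0.95) {
  depth <- tAlt + tRef
  if (any(depth == 0)) stop("zero tumor depth: VAF undefined")
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  n <- length(tAlt)
  purity <- rep_len(purity, n)
  cnTotal <- rep_len(cnTotal, n)
  cnMajor <- rep_len(cnMajor, n)
  vaf <- tAlt / depth
  scale <- (purity * cnTotal + 2 * (1 - purity)) / purity
  nMut <- vaf * scale
  m <- pmin(pmax(round(nMut), 1), pmax(cnMajor, 1))
  ccf <- nMut / m
  alpha <- 1 - conf
  vLo <- ifelse(tAlt == 0, 0, stats::qbeta(alpha / 2, tAlt, tRef + 1))
  vHi <- ifelse(tRef == 0, 1, stats::qbeta(1 - alpha / 2, tAlt + 1, tRef))
  ciLo <- vLo * scale / m
  ciHi <- vHi * scale / m
  clonal <- ciLo <= 1 & ciHi >= 1
  evaluable <- cnTotal >= 1
  out <- data.frame(vaf = vaf, n_mut = nMut, multiplicity = as.integer(m),
                    ccf = ccf, ci_low = ciLo, ci_high = ciHi,
                    clonal = clonal)
  out[!evaluable, c("n_mut", "multiplicity", "ccf", "ci_low", "ci_high",
                    "clonal")] <- NA
  out
}

#' Timing of mutations relative to copy gains / genome doubling
#'
#' Indels, regions without copy-number alteration (`nMajor = nMinor = 1`),
#' and single-copy regions (total CN = 1) cannot be timed and are
#' `not_evaluable`. A mutation is `early` (preceding the local gain or
#' doubling) only when it is clonal and its rounded mutant allele copy
#' number is at least 2; otherwise it is `late`.
#'
#' @param est data.frame from [ccfEstimate()].
#' @param variantClass per-mutation class (`"SNV"`, `"INS"`, `"DEL"`).
#' @param cnMajor,cnMinor local allele-specific copy numbers per mutation.
#' @return character vector of labels in
#'   `c("early", "late", "not_evaluable")`.
#' @export
mutationTiming <- function(est, variantClass, cnMajor, cnMinor) {
  n <- nrow(est)
  variantClass <- rep_len(variantClass, n)
  cnMajor <- rep_len(cnMajor, n)
  cnMinor <- rep_len(cnMinor, n)
  notEval <- variantClass != "SNV" |
    (cnMajor == 1L & cnMinor == 1L) |
    (cnMajor + cnMinor) <= 1L |
    is.na(est$ccf)
  early <- !notEval & est$clonal & round(est$n_mut) >= 2
  ifelse(notEval, "not_evaluable", ifelse(early, "early", "late"))
}

#' CCF and timing for all validated mutations of one sector
#'
#' Joins a sector's variants to its copy-number profile by position, runs
#' [ccfEstimate()] with the sector purity and local allele-specific copy
#' numbers, and appends the [mutationTiming()] label. Mutations falling
#' outside every segment are not evaluable.
#'
#' @param variants variant data.frame for one sector (deep-seq rows
#'   recommended).
#' @param profile the sector's [SectorProfile-class].
#' @return data.frame: variant key columns plus the [ccfEstimate()] fields
#'   and `timing`.
#' @export
sectorCcfTable <- function(variants, profile) {
  gr <- cnSegments(profile)
  mc <- S4Vectors::mcols(gr)
  vgr <- GenomicRanges::GRanges(
    seqnames = sub("^chr", "", as.character(variants$chrom)),
    ranges = IRanges::IRanges(start = variants$pos, width = 1L)
  )
  hit <- GenomicRanges::findOverlaps(vgr, gr, select = "first")
  cnMajor <- ifelse(is.na(hit), NA_integer_, mc$nMajor[hit])
  cnMinor <- ifelse(is.na(hit), NA_integer_, mc$nMinor[hit])
  cnTotal <- cnMajor + cnMinor
  est <- ccfEstimate(variants$t_alt, variants$t_ref, purity(profile),
                     ifelse(is.na(cnTotal), 0L, cnTotal),
                     ifelse(is.na(cnMajor), 1L, cnMajor))
  est$ccf[is.na(hit)] <- NA_real_
  timing <- mutationTiming(est, variants$variant_class,
                           ifelse(is.na(cnMajor), 1L, cnMajor),
                           ifelse(is.na(cnMinor), 1L, cnMinor))
  timing[is.na(hit)] <- "not_evaluable"
  cbind(
    data.frame(key = variantKey(variants), sector_id = variants$sector_id,
               gene = variants$gene, stringsAsFactors = FALSE),
    est, cnMajor = cnMajor, cnMinor = cnMinor,
    timing = timing, stringsAsFactors = FALSE
  )
}
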