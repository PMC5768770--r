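## Somatic copy-number analysis: median integer ploidy, relative gain/loss
## calls, genomic instability indices (GII, adGII), feature-level copy
## assignment with the 25%-overlap rule, LOH detection, and SCNA-level
## intra-tumor heterogeneity (truncal vs late alterations).
##
## Genome-fraction denominators use autosomes only by default (configurable
## via includeX) to avoid sex-chromosome ploidy ambiguity; the denominator
## is the total segmented (covered) length of the included chromosomes.

.AUTOSOMES <- as.character(1:22)

.includedSeg <- function(profile, includeX = FALSE) {
  gr <- cnSegments(profile)
  chroms <- sub("^chr", "", as.character(GenomicRanges::seqnames(gr)))
  keep <- chroms %in% if (includeX) c(.AUTOSOMES, "X") else .AUTOSOMES
  gr[keep]
}

#' Median integer ploidy of a sector
#'
#' The weighted median of per-segment total copy number (`nMajor + nMinor`),
#' weighted by the number of supporting array SNPs when every segment
#' carries one, otherwise by segment length. Ties resolve to the lower
#' integer. This is the reference against which gains and losses are called.
#'
#' @param profile a [SectorProfile-class].
#' @param includeX include chromosome X in the computation (default FALSE).
#' @return integer ploidy (>= 0).
#' @examples
#' p <- SectorProfile("S", data.frame(chrom = "1", start = 1, end = 100,
#'                                    nMajor = 1, nMinor = 1), purity = 0.7)
#' medianIntegerPloidy(p)  # 2
#' @export
medianIntegerPloidy <- function(profile, includeX = FALSE) {
  gr <- .includedSeg(profile, includeX)
  if (length(gr) == 0L) stop("profile has no segments on included chromosomes")
  mc <- S4Vectors::mcols(gr)
  tcn <- mc$nMajor + mc$nMinor
  w <- if ("nSNPs" %in% colnames(mc) && !anyNA(mc$nSNPs)) {
    as.numeric(mc$nSNPs)
  } else {
    as.numeric(GenomicRanges::width(gr))
  }
  ord <- order(tcn)
  tcn <- tcn[ord]; w <- w[ord]
  cw <- cumsum(w)
  as.integer(tcn[which(cw >= sum(w) / 2)[1]])
}

#' Relative copy-number calls against the sector's ploidy
#'
#' Each segment's deviation `delta = total CN - ploidy` is classified as
#' `loss2` (delta <= -2), `loss1` (-1), `neutral` (0), `gain1` (+1) or
#' `gain2plus` (delta >= 2).
#'
#' @inheritParams medianIntegerPloidy
#' @param refPloidy reference ploidy; the profile's cached median integer
#'   ploidy when `NULL`.
#' @return data.frame with one row per segment: `chrom`, `start`, `end`,
#'   `width`, `nMajor`, `nMinor`, `delta`, `class`.
#' @export
relativeCalls <- function(profile, refPloidy = NULL) {
  gr <- cnSegments(profile)
  mc <- S4Vectors::mcols(gr)
  if (is.null(refPloidy)) refPloidy <- ploidy(profile)
  delta <- mc$nMajor + mc$nMinor - refPloidy
  cls <- cut(delta, breaks = c(-Inf, -2, -1, 0, 1, Inf),
             labels = c("loss2", "loss1", "neutral", "gain1", "gain2plus"),
             right = TRUE)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    width = GenomicRanges::width(gr),
    nMajor = mc$nMajor, nMinor = mc$nMinor,
    delta = as.integer(delta), class = as.character(cls),
    stringsAsFactors = FALSE
  )
}

#' Genomic instability indices GII and adGII
#'
#' GII is the fraction of the (covered, included) genome whose total copy
#' number deviates by at least 1 from the sector's median integer ploidy;
#' adGII is the fraction deviating by at least 2 (amplifications and
#' deletions). Deviations are on total copy number, so copy-neutral LOH does
#' not contribute. By construction `gii >= adgii`.
#'
#' @inheritParams medianIntegerPloidy
#' @return data.frame row: `sector_id`, `ploidy`, `gii`, `adgii`.
#' @export
instabilityScores <- function(profile, includeX = FALSE) {
  gr <- .includedSeg(profile, includeX)
  if (length(gr) == 0L) stop("profile has no segments on included chromosomes")
  mc <- S4Vectors::mcols(gr)
  pl <- ploidy(profile)
  delta <- mc$nMajor + mc$nMinor - pl
  w <- as.numeric(GenomicRanges::width(gr))
  W <- sum(w)
  data.frame(
    sector_id = sectorId(profile),
    ploidy = pl,
    gii = sum(w[abs(delta) >= 1]) / W,
    adgii = sum(w[abs(delta) >= 2]) / W,
    stringsAsFactors = FALSE
  )
}

#' Assign segment copy numbers to genes or cytobands
#'
#' A feature overlapped by a single segment takes that segment's copy
#' number. When several segments overlap a feature, only segments covering
#' at least `minOverlap` (default 25%) of the feature's length are eligible
#' and the one with the largest overlap wins; a feature with no eligible
#' segment stays unassigned.
#'
#' @param profile a [SectorProfile-class].
#' @param features `GRanges` of features with a `name` metadata column (see
#'   [readCytoband()], [readGeneBed()]).
#' @param minOverlap minimum fraction of the feature that an eligible
#'   segment must cover.
#' @return data.frame: `feature`, `sector_id`, `totalCN`, `nMajor`,
#'   `nMinor`, `assigned`.
#' @export
mapToFeatures <- function(profile, features, minOverlap = 0.25) {
  gr <- cnSegments(profile)
  mc <- S4Vectors::mcols(gr)
  hits <- GenomicRanges::findOverlaps(features, gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(features)[q], GenomicRanges::ranges(gr)[s]))
  frac <- ov / GenomicRanges::width(features)[q]
  nHits <- tabulate(q, nbins = length(features))
  # single-overlap features are assigned regardless of the 25% rule
  eligible <- nHits[q] == 1L | frac >= minOverlap
  q <- q[eligible]; s <- s[eligible]; ov <- ov[eligible]
  best <- rep(NA_integer_, length(features))
  if (length(q)) {
    ord <- order(q, -ov, s)
    q <- q[ord]; s <- s[ord]
    best[q[!duplicated(q)]] <- s[!duplicated(q)]
  }
  assigned <- !is.na(best)
  data.frame(
    feature = S4Vectors::mcols(features)$name,
    sector_id = sectorId(profile),
    totalCN = ifelse(assigned, mc$nMajor[best] + mc$nMinor[best], NA_integer_),
    nMajor = ifelse(assigned, mc$nMajor[best], NA_integer_),
    nMinor = ifelse(assigned, mc$nMinor[best], NA_integer_),
    assigned = assigned,
    stringsAsFactors = FALSE
  )
}

#' Loss of heterozygosity per segment
#'
#' A segment is under LOH when its minor allele copy number is zero while at
#' least one copy remains (`nMinor = 0`, total CN >= 1); this includes
#' copy-neutral LOH. Also reports the LOH fraction of the covered included
#' genome.
#'
#' @inheritParams medianIntegerPloidy
#' @return list with `segments` (the [relativeCalls()] table plus an `loh`
#'   flag) and `fraction` (genome LOH fraction).
#' @export
detectLoh <- function(profile, includeX = FALSE) {
  calls <- relativeCalls(profile)
  calls$loh <- calls$nMinor == 0L & (calls$nMajor + calls$nMinor) >= 1L
  gr <- .includedSeg(profile, includeX)
  mc <- S4Vectors::mcols(gr)
  w <- as.numeric(GenomicRanges::width(gr))
  lohIn <- mc$nMinor == 0L & (mc$nMajor + mc$nMinor) >= 1L
  list(segments = calls, fraction = sum(w[lohIn]) / sum(w))
}

#' SCNA intra-tumor heterogeneity: truncal vs late alterations
#'
#' For each feature, the per-sector alteration direction is
#' `sign(totalCN - sector ploidy)`. A feature is `truncal` when every sector
#' shows the same non-zero direction, `late` when altered in at least one
#' but not all sectors (or with conflicting directions), and `unaltered`
#' when no sector deviates. Only features assigned a copy number in every
#' sector are evaluated. Patients with fewer than `minSectors` profiled
#' sectors are rejected.
#'
#' @param featureCN list (one element per sector) of [mapToFeatures()]
#'   tables.
#' @param ploidies integer vector of sector ploidies, aligned with
#'   `featureCN`.
#' @param minSectors minimum number of profiled sectors (default 3).
#' @return list with `labels` (data.frame `feature`, `label`) and
#'   `lateFraction` (late / assigned features).
#' @export
scnaIth <- function(featureCN, ploidies, minSectors = 3) {
  if (length(featureCN) < minSectors) {
    stop(sprintf("SCNA-ITH needs >= %d profiled sectors, got %d",
                 minSectors, length(featureCN)))
  }
  stopifnot(length(ploidies) == length(featureCN))
  feats <- featureCN[[1]]$feature
  dirs <- vapply(seq_along(featureCN), function(i) {
    fc <- featureCN[[i]]
    sign(fc$totalCN[match(feats, fc$feature)] - ploidies[i])
  }, numeric(length(feats)))
  dirs <- matrix(dirs, nrow = length(feats))
  ok <- rowSums(is.na(dirs)) == 0L
  nAlt <- rowSums(dirs != 0)
  sameDir <- apply(dirs, 1, function(x) length(unique(x)) == 1L)
  label <- ifelse(!ok, NA_character_,
           ifelse(nAlt == 0, "unaltered",
           ifelse(nAlt == ncol(dirs) & sameDir, "truncal", "late")))
  lateFraction <- sum(label == "late", na.rm = TRUE) / sum(ok)
  list(labels = data.frame(feature = feats, label = label,
                           stringsAsFactors = FALSE),
       lateFraction = lateFraction)
}
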