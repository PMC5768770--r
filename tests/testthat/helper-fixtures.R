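# Fixture builders and independent oracles used across the suite.

# one-row (or vectorized) variant table with sensible defaults
toyVariants <- function(t_alt, t_ref, n_alt = 0, n_ref = 60,
                        variant_class = "SNV", assay = "exome",
                        alt_fwd = NULL, alt_rev = NULL,
                        patient_id = "P01", sector_id = "S1",
                        chrom = "1", pos = NULL, gene = "",
                        effect = "non_silent") {
  n <- max(lengths(list(t_alt, t_ref, n_alt, n_ref)))
  if (is.null(pos)) pos <- seq_len(n) * 100L
  df <- data.frame(
    patient_id = patient_id, sector_id = sector_id, chrom = chrom,
    pos = pos, ref = "C", alt = "T", variant_class = variant_class,
    gene = gene, effect = effect, assay = assay,
    t_ref = t_ref, t_alt = t_alt, n_ref = n_ref, n_alt = n_alt,
    stringsAsFactors = FALSE
  )
  if (!is.null(alt_fwd)) {
    df$alt_fwd <- alt_fwd
    df$alt_rev <- alt_rev
  }
  df
}

# profile with one segment per (recycled) autosome, equal or given lengths
toyProfile <- function(nMajor, nMinor, w = NULL, purity = 0.7,
                       sectorId = "S1", nSNPs = NULL) {
  n <- length(nMajor)
  if (is.null(w)) w <- rep(1e6, n)
  chrom <- as.character(rep(1:22, length.out = n))
  start <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    start[idx] <- cumsum(c(1, w[idx][-length(idx)] + 1))[seq_along(idx)]
  }
  df <- data.frame(chrom = chrom, start = start, end = start + w - 1,
                   nMajor = nMajor, nMinor = nMinor)
  if (!is.null(nSNPs)) df$nSNPs <- nSNPs
  SectorProfile(sectorId, df, purity = purity)
}

toyPresence <- function(mat, patientId = "P01") {
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("S%d", seq_len(ncol(mat)))
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("1:%d:C:T", seq_len(nrow(mat)) * 10L)
  }
  PresenceMatrix(mat, patientId)
}

randomPresence <- function(nMut, nSect) {
  repeat {
    m <- matrix(stats::runif(nMut * nSect) < stats::runif(1, 0.2, 0.8),
                nMut, nSect)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) >= 2) break
  }
  toyPresence(m)
}

# exhaustive enumeration oracles over all C(n, k) sector subsets,
# independent of the package's sampling implementation
enumTrunkRatio <- function(m, k) {
  subs <- utils::combn(ncol(m), k, simplify = FALSE)
  mean(vapply(subs, function(cols) {
    sub <- m[, cols, drop = FALSE]
    ns <- rowSums(sub)
    sum(ns == k) / sum(ns > 0)
  }, numeric(1)), na.rm = TRUE)
}

enumBurdenGain <- function(m, k) {
  subs <- utils::combn(ncol(m), k, simplify = FALSE)
  mean(vapply(subs, function(cols) {
    sub <- m[, cols, drop = FALSE]
    single <- mean(colSums(sub))
    if (single == 0) return(NA_real_)
    (sum(rowSums(sub) > 0) - single) / single * 100
  }, numeric(1)), na.rm = TRUE)
}

# Monte-Carlo standard error of a subset statistic, for the 3-SE bands
mcSE <- function(values) stats::sd(values) / sqrt(length(values))

# uniformly doubled / diploid profiles with scattered single-copy gains
nullDiploidProfile <- function(gainFrac = 0.1, nSeg = 40, sectorId = "S") {
  nMajor <- rep(1L, nSeg)
  gained <- sample(nSeg, round(gainFrac * nSeg))
  nMajor[gained] <- 2L
  toyProfile(nMajor, rep(1L, nSeg), sectorId = sectorId)
}

doubledProfile <- function(devFrac = 0.1, nSeg = 40, sectorId = "S") {
  nMajor <- rep(2L, nSeg)
  nMinor <- rep(2L, nSeg)
  dev <- sample(nSeg, round(devFrac * nSeg))
  up <- stats::runif(length(dev)) < 0.5
  nMajor[dev[up]] <- 3L
  nMinor[dev[!up]] <- 1L
  toyProfile(nMajor, nMinor, sectorId = sectorId)
}
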