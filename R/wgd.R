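## Simulation-based whole-genome-doubling (WGD) test.
##
## The observed statistic is the length fraction of the included genome
## whose major allele copy number is >= 2 (a doubled genome retains two
## copies of both haplotypes almost everywhere). The null model asks how
## much of that fraction could arise without a doubling event: starting
## from the non-doubled unit state (nMajor = nMinor = 1) on the sample's
## own segment structure, each segment independently gains a single copy
## with probability equal to the observed genome-wide gain rate (length
## fraction with total CN above the median integer ploidy) or loses one at
## the observed loss rate. Single-copy events from the unit state can raise
## the major allele to 2 only through gains, so the simulated statistic is
## the gained length fraction. Event rates are measured relative to the
## median integer ploidy, consistent with how gains and losses are called
## everywhere else in the pipeline; all null parameters are arguments.

#' Whole-genome-doubling test for one sector
#'
#' Computes `T_obs`, the length fraction of the included genome with major
#' allele copy number >= 2, and a permutation-style p-value
#' `(1 + #\{T_sim >= T_obs\}) / (1 + nSim)` under the no-doubling null
#' described above. The doubling call uses ploidy-dependent thresholds: for
#' median integer ploidy <= 3 the sample is doubled when `p < 0.001`; for
#' ploidy 4, `p < 0.05` (avoiding under-calling in high-ploidy samples);
#' ploidy above 4 is called doubled unconditionally.
#'
#' @param profile a [SectorProfile-class].
#' @param nSim number of null simulations (default 10000).
#' @param seed optional RNG seed.
#' @param includeX include chromosome X (default FALSE).
#' @param pGain,pLoss override the observed per-segment event rates
#'   (defaults estimated from the profile).
#' @return data.frame row: `sector_id`, `ploidy`, `t_obs`, `p_value`,
#'   `n_sim`, `doubled`.
#' @examples
#' seg <- data.frame(chrom = as.character(1:22), start = 1, end = 1e8,
#'                   nMajor = 2, nMinor = 2)
#' wgdTest(SectorProfile("S", seg, purity = 0.8), nSim = 1000, seed = 1)
#' @export
wgdTest <- function(profile, nSim = 10000, seed = NULL, includeX = FALSE,
                    pGain = NULL, pLoss = NULL) {
  gr <- .includedSeg(profile, includeX)
  if (length(gr) == 0L) stop("profile has no segments on included chromosomes")
  if (!is.null(seed)) set.seed(seed)
  mc <- S4Vectors::mcols(gr)
  w <- as.numeric(GenomicRanges::width(gr))
  W <- sum(w)
  pl <- ploidy(profile)
  tcn <- mc$nMajor + mc$nMinor
  tObs <- sum(w[mc$nMajor >= 2L]) / W
  if (is.null(pGain)) pGain <- sum(w[tcn > pl]) / W
  if (is.null(pLoss)) pLoss <- sum(w[tcn < pl]) / W
  # each row of U is one simulated genome; a segment is gained when its
  # uniform draw falls in [0, pGain) (losses occupy [pGain, pGain+pLoss)
  # and never produce major CN >= 2 from the 1+1 state)
  U <- matrix(stats::runif(nSim * length(gr)), nrow = nSim)
  tSim <- as.vector((U < pGain) %*% w) / W
  p <- (1 + sum(tSim >= tObs)) / (1 + nSim)
  doubled <- if (pl > 4L) TRUE else if (pl == 4L) p < 0.05 else p < 0.001
  data.frame(
    sector_id = sectorId(profile), ploidy = pl,
    t_obs = tObs, p_value = p, n_sim = as.integer(nSim),
    doubled = doubled, stringsAsFactors = FALSE
  )
}
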