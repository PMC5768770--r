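## Synthetic multi-sector tumor cohorts with known ground truth.
##
## The generator emulates the structure of a multi-region study of
## oncogene-driven lung adenocarcinoma: a cohort of tumors each sampled in
## several spatially distinct sectors, a clonal tree per tumor whose root
## edge carries the truncal mutations, allele-specific copy-number profiles
## with optional early whole-genome doubling, and per-sector read counts at
## exome and targeted deep-sequencing depths. Every observable table is
## paired with the generating truth (clade labels, true profiles, WGD
## status, pre/post-WGD multiplicity, planted drivers) so each pipeline
## stage can be scored against it.

# hg19 autosome lengths (Mb), the genome over which segments are laid out
.CHROM_MB <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136,
               135, 134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

#' Simulation configuration
#'
#' Default values reproduce the study conditions the generator emulates:
#' 16 patients with 3-11 sectors each, about 95 confirmed mutations per
#' tumor (1521 across 16 tumors), a trunk fraction drawn from
#' Beta(4.9, 8.1) (mean 0.377, so cohort pITH centers on ~62% with a
#' realistic 30-80% spread), an indel fraction of 71/1521, exome depth
#' 114X and targeted deep-seq depth 3860X, whole-genome doubling in 12/16
#' tumors, a per-sector altered genome fraction of 0.48 of which 0.072 is
#' high-amplitude (|delta| >= 2), copy-number profiling for 61/79 of
#' sectors, and purity uniform on (0.4, 0.9).
#'
#' @param nPatients number of tumors.
#' @param sectorRange inclusive range of sectors per tumor.
#' @param mutationsPerTumor Poisson mean of confirmed mutations per tumor.
#' @param trunkShape1,trunkShape2 Beta parameters for the per-tumor trunk
#'   fraction.
#' @param branchShare fraction of non-trunk mutations assigned to branch
#'   (vs private) clades.
#' @param indelFraction fraction of mutations that are indels.
#' @param exomeDepth,deepseqDepth mean sequencing depths (Poisson).
#' @param purityRange per-sector purity range (uniform draw).
#' @param wgdProb probability that a tumor carries a (truncal) whole-genome
#'   doubling.
#' @param preWgdFraction fraction of truncal mutations placed before the
#'   doubling (multiplicity 2) in WGD tumors.
#' @param nSegments number of copy-number segments in the genome template.
#' @param giiTarget expected per-sector altered genome fraction (relative
#'   to ploidy).
#' @param adgiiShare fraction of altered length that is high-amplitude
#'   (|delta| >= 2).
#' @param truncalScnaShare fraction of the altered genome shared by all
#'   sectors (the rest is sector-private).
#' @param scnaCoverage fraction of sectors with a copy-number profile in
#'   the observable output (truth keeps all).
#' @param errorRate symmetric per-read sequencing error floor (default 0;
#'   used for filter stress tests).
#' @param tp53Prob probability of planting a truncal TP53 driver mutation
#'   (an EGFR truncal driver is always planted).
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(nPatients = 16,
                      sectorRange = c(3, 11),
                      mutationsPerTumor = 95,
                      trunkShape1 = 4.9,
                      trunkShape2 = 8.1,
                      branchShare = 0.6,
                      indelFraction = 71 / 1521,
                      exomeDepth = 114,
                      deepseqDepth = 3860,
                      purityRange = c(0.4, 0.9),
                      wgdProb = 12 / 16,
                      preWgdFraction = 0.8,
                      nSegments = 40,
                      giiTarget = 0.48,
                      adgiiShare = 0.072 / 0.48,
                      truncalScnaShare = 0.6,
                      scnaCoverage = 61 / 79,
                      errorRate = 0,
                      tp53Prob = 9 / 16) {
  cfg <- as.list(environment())
  stopifnot(
    nPatients >= 1, sectorRange[1] >= 2, sectorRange[2] >= sectorRange[1],
    mutationsPerTumor > 0, branchShare >= 0, branchShare <= 1,
    indelFraction >= 0, indelFraction < 1,
    exomeDepth > 0, deepseqDepth > 0,
    purityRange[1] > 0, purityRange[2] <= 1,
    wgdProb >= 0, wgdProb <= 1, nSegments >= 22,
    giiTarget >= 0, giiTarget < 0.5, adgiiShare >= 0, adgiiShare <= 1,
    scnaCoverage >= 0, scnaCoverage <= 1, errorRate >= 0, errorRate < 0.5
  )
  structure(cfg, class = "simConfig")
}

# genome template: segments tiled over the 22 autosomes; the longest
# chromosomes are split into two segments at a random interior point
.segmentTemplate <- function(nSegments) {
  lenBp <- .CHROM_MB * 1e6
  nExtra <- nSegments - 22L
  splitChrom <- order(lenBp, decreasing = TRUE)[seq_len(nExtra)]
  rows <- lapply(1:22, function(ch) {
    if (ch %in% splitChrom) {
      bp <- round(lenBp[ch] * stats::runif(1, 0.3, 0.7))
      data.frame(chrom = as.character(ch), start = c(1, bp + 1),
                 end = c(bp, lenBp[ch]))
    } else {
      data.frame(chrom = as.character(ch), start = 1, end = lenBp[ch])
    }
  })
  do.call(rbind, rows)
}

# random rooted clonal topology over sectors; returns the list of edges,
# each edge being the set of sector indices below it (root edge first)
.cloneEdges <- function(sectors) {
  edges <- list(sectors)
  recurse <- function(s) {
    if (length(s) < 2L) return(invisible())
    nLeft <- sample(length(s) - 1L, 1L)
    left <- sample(s, nLeft)
    right <- setdiff(s, left)
    edges[[length(edges) + 1L]] <<- left
    edges[[length(edges) + 1L]] <<- right
    recurse(left)
    recurse(right)
  }
  recurse(sectors)
  edges
}

# apply a signed copy change to one allele pair: gains add to the major
# allele; losses strip the minor allele first, then the major (floor 0)
.applyDelta <- function(nMajor, nMinor, delta) {
  if (delta >= 0) {
    nMajor <- nMajor + delta
  } else {
    take <- min(-delta, nMinor)
    nMinor <- nMinor - take
    nMajor <- max(nMajor - (-delta - take), 0L)
  }
  c(nMajor, nMinor)
}

#' Simulate one multi-sector tumor
#'
#' Builds a random clonal topology over the tumor's sectors, assigns trunk
#' (root edge), branch (internal edge) and private (leaf edge) mutations,
#' lays out allele-specific copy-number profiles on a shared segment
#' template (doubling all alleles when the tumor carries a WGD, with
#' truncal/private gains and losses applied relative to the doubled
#' state), and draws tumor read counts binomially around the expected VAF
#' `purity * m * CCF / (purity * CNt + 2 (1 - purity))` at both assay
#' depths (Poisson depth). Normal counts carry no somatic signal beyond
#' the configured error floor. Each mutation is clonal within the sectors
#' that carry it.
#'
#' @param config a [simConfig()].
#' @param patientIdx patient index (used for the identifier `P<idx>`).
#' @param seed RNG seed for this tumor.
#' @return list with `patient_id`, `variants` (exome + deepseq rows),
#'   `profiles` (observed [SectorProfile-class] list, possibly a subset of
#'   sectors), and `truth` (mutation clade labels, multiplicities and
#'   pre-WGD flags; per-sector purity/ploidy/WGD; full profile set).
#' @export
simulateTumor <- function(config, patientIdx = 1, seed = 1) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(seed)
  pid <- sprintf("P%02d", patientIdx)
  sectorChoices <- seq(config$sectorRange[1], config$sectorRange[2])
  nSectors <- if (length(sectorChoices) == 1L) sectorChoices else
    sample(sectorChoices, 1)
  sectors <- sprintf("%s-S%02d", pid, seq_len(nSectors))

  ## clonal topology and mutation clade assignment
  edges <- .cloneEdges(seq_len(nSectors))
  sizes <- lengths(edges)
  trunkEdge <- 1L
  branchEdges <- which(sizes >= 2L & sizes < nSectors)
  leafEdges <- lapply(seq_len(nSectors), identity)

  nMut <- max(stats::rpois(1, config$mutationsPerTumor), 5L)
  trunkFrac <- stats::rbeta(1, config$trunkShape1, config$trunkShape2)
  nTrunk <- round(nMut * trunkFrac)
  nBranch <- if (length(branchEdges)) {
    round((nMut - nTrunk) * config$branchShare)
  } else 0L
  nPrivate <- nMut - nTrunk - nBranch
  if (nPrivate > 0L && nSectors < 2L) {
    stop("private mutations are infeasible with a single sector")
  }
  mutEdge <- c(
    rep(trunkEdge, nTrunk),
    if (nBranch > 0) branchEdges[sample.int(length(branchEdges), nBranch,
                                            replace = TRUE)],
    if (nPrivate > 0) -sample.int(nSectors, nPrivate, replace = TRUE)
  )
  clade <- rep(c("trunk", "branch", "private"),
               c(nTrunk, nBranch, nPrivate))
  carrier <- lapply(seq_len(nMut), function(i) {
    if (mutEdge[i] < 0) -mutEdge[i] else edges[[mutEdge[i]]]
  })

  ## copy-number profiles
  template <- .segmentTemplate(config$nSegments)
  segW <- template$end - template$start + 1
  W <- sum(segW)
  wgd <- stats::runif(1) < config$wgdProb
  base <- if (wgd) 2L else 1L
  pickAltered <- function(targetFrac, exclude = integer()) {
    # random segments until the altered length fraction reaches the target
    ord <- setdiff(sample(nrow(template)), exclude)
    ord[cumsum(segW[ord]) <= targetFrac * W]
  }
  truncalAlt <- pickAltered(config$giiTarget * config$truncalScnaShare)
  deltaOf <- function(k) {
    mag <- ifelse(stats::runif(k) < config$adgiiShare, 2L, 1L)
    sgn <- ifelse(stats::runif(k) < 0.5, 1L, -1L)
    mag * sgn
  }
  truncalDelta <- deltaOf(length(truncalAlt))
  profilesAll <- vector("list", nSectors)
  segCN <- array(0L, dim = c(nrow(template), 2L, nSectors))
  purities <- stats::runif(nSectors, config$purityRange[1],
                           config$purityRange[2])
  for (s in seq_len(nSectors)) {
    nMaj <- rep(base, nrow(template))
    nMin <- rep(base, nrow(template))
    privAlt <- pickAltered(config$giiTarget * (1 - config$truncalScnaShare),
                           exclude = truncalAlt)
    privDelta <- deltaOf(length(privAlt))
    idx <- c(truncalAlt, privAlt)
    dlt <- c(truncalDelta, privDelta)
    for (t in seq_along(idx)) {
      mm <- .applyDelta(nMaj[idx[t]], nMin[idx[t]], dlt[t])
      nMaj[idx[t]] <- mm[1]; nMin[idx[t]] <- mm[2]
    }
    segCN[, 1, s] <- nMaj
    segCN[, 2, s] <- nMin
    df <- cbind(template, nMajor = nMaj, nMinor = nMin)
    profilesAll[[s]] <- SectorProfile(sectors[s], df, purity = purities[s])
  }

  ## mutation placement and multiplicity; homozygously deleted loci carry
  ## no detectable alleles anywhere, so mutations are placed on segments
  ## retaining at least one copy in every sector (keeps the emitted truth
  ## consistent with what any assay could observe)
  okSeg <- which(apply(segCN[, 1, , drop = FALSE] +
                       segCN[, 2, , drop = FALSE], 1, min) >= 1L)
  mutSeg <- okSeg[sample(length(okSeg), nMut, replace = TRUE,
                         prob = segW[okSeg])]
  mutPos <- template$start[mutSeg] +
    floor(stats::runif(nMut) * segW[mutSeg])
  bases <- c("A", "C", "G", "T")
  refB <- sample(bases, nMut, replace = TRUE)
  altB <- vapply(refB, function(b) sample(setdiff(bases, b), 1), "")
  isIndel <- stats::runif(nMut) < config$indelFraction
  vclass <- ifelse(!isIndel, "SNV",
                   ifelse(stats::runif(nMut) < 0.5, "INS", "DEL"))
  ref <- ifelse(vclass == "DEL", paste0(refB, altB), refB)
  alt <- ifelse(vclass == "INS", paste0(refB, altB), altB)
  alt[vclass == "DEL"] <- refB[vclass == "DEL"]
  preWgd <- wgd & clade == "trunk" & !isIndel &
    stats::runif(nMut) < config$preWgdFraction
  mult <- ifelse(preWgd, 2L, 1L)

  gene <- sprintf("%s_G%03d", pid, seq_len(nMut))
  effect <- ifelse(stats::runif(nMut) < 0.7, "non_silent", "silent")
  trunkSnv <- which(clade == "trunk" & vclass == "SNV")
  if (length(trunkSnv)) {
    gene[trunkSnv[1]] <- "EGFR"
    effect[trunkSnv[1]] <- "non_silent"
    if (length(trunkSnv) > 1L && stats::runif(1) < config$tp53Prob) {
      gene[trunkSnv[2]] <- "TP53"
      effect[trunkSnv[2]] <- "non_silent"
    }
  }

  ## read counts per sector and assay
  rows <- vector("list", nSectors * 2L)
  k <- 0L
  for (s in seq_len(nSectors)) {
    present <- vapply(carrier, function(cc) s %in% cc, logical(1))
    nMajLoc <- segCN[mutSeg, 1, s]
    cnt <- segCN[mutSeg, 1, s] + segCN[mutSeg, 2, s]
    mEff <- pmin(mult, pmax(nMajLoc, 1L))
    p <- purities[s]
    expVaf <- ifelse(present & cnt > 0,
                     p * mEff / (p * cnt + 2 * (1 - p)),
                     config$errorRate)
    for (assay in c("exome", "deepseq")) {
      depthMean <- if (assay == "exome") config$exomeDepth else
        config$deepseqDepth
      depth <- stats::rpois(nMut, depthMean) + 1L
      tAlt <- stats::rbinom(nMut, depth, pmin(expVaf, 1))
      nDepth <- stats::rpois(nMut, depthMean) + 1L
      nAlt <- stats::rbinom(nMut, nDepth, config$errorRate)
      altFwd <- ifelse(vclass != "SNV" & assay == "deepseq",
                       stats::rbinom(nMut, tAlt, 0.5), NA_integer_)
      k <- k + 1L
      rows[[k]] <- data.frame(
        patient_id = pid, sector_id = sectors[s],
        chrom = template$chrom[mutSeg], pos = mutPos,
        ref = ref, alt = alt, variant_class = vclass,
        gene = gene, effect = effect, assay = assay,
        t_ref = depth - tAlt, t_alt = tAlt,
        n_ref = nDepth - nAlt, n_alt = nAlt,
        alt_fwd = altFwd,
        alt_rev = ifelse(is.na(altFwd), NA_integer_, tAlt - altFwd),
        stringsAsFactors = FALSE
      )
    }
  }
  variants <- do.call(rbind, rows)

  profiled <- sort(sample(nSectors, round(nSectors * config$scnaCoverage)))
  key <- paste(template$chrom[mutSeg], mutPos, ref, alt, sep = ":")
  truth <- list(
    mutations = data.frame(
      key = key, variant_class = vclass, gene = gene, effect = effect,
      clade = clade,
      sectors = vapply(carrier, function(cc)
        paste(sectors[cc], collapse = ";"), ""),
      pre_wgd = preWgd, multiplicity = mult, seg_index = mutSeg,
      stringsAsFactors = FALSE
    ),
    sectors = data.frame(
      sector_id = sectors, purity = purities,
      ploidy = vapply(profilesAll, ploidy, integer(1)),
      wgd = wgd, profiled = seq_len(nSectors) %in% profiled,
      stringsAsFactors = FALSE
    ),
    wgd = wgd,
    profilesAll = stats::setNames(profilesAll, sectors)
  )
  list(
    patient_id = pid,
    variants = variants,
    profiles = stats::setNames(profilesAll[profiled], sectors[profiled]),
    truth = truth
  )
}

#' Simulate a cohort of multi-sector tumors
#'
#' Per-patient RNG streams are derived from the master seed and a hash of
#' the patient identifier, so a patient's data does not depend on the
#' order in which the cohort is generated.
#'
#' @param config a [simConfig()].
#' @param seed master seed.
#' @return list of class `simCohort`: one [simulateTumor()] result per
#'   patient.
#' @export
simulateCohort <- function(config = simConfig(), seed = 1) {
  tumors <- lapply(seq_len(config$nPatients), function(i) {
    simulateTumor(config, i, seed = .patientSeed(seed, sprintf("P%02d", i)))
  })
  names(tumors) <- vapply(tumors, `[[`, "", "patient_id")
  structure(tumors, class = "simCohort")
}

.patientSeed <- function(masterSeed, pid) {
  h <- 0
  for (ch in utf8ToInt(pid)) h <- (h * 31 + ch) %% 1e6
  as.integer((masterSeed * 1009 + h) %% 2147483629)
}

#' True presence matrix of a simulated tumor
#'
#' Builds the [PresenceMatrix-class] directly from the generating truth
#' (noiseless detection): a mutation is present exactly in the sectors of
#' its clade.
#'
#' @param tumor a [simulateTumor()] result.
#' @return a [PresenceMatrix-class].
#' @export
truePresenceMatrix <- function(tumor) {
  tm <- tumor$truth$mutations
  sectors <- tumor$truth$sectors$sector_id
  m <- matrix(FALSE, nrow(tm), length(sectors),
              dimnames = list(tm$key, sectors))
  for (i in seq_len(nrow(tm))) {
    m[i, strsplit(tm$sectors[i], ";")[[1]]] <- TRUE
  }
  PresenceMatrix(m, tumor$patient_id)
}

#' Simulate a cohort mutation table with planted driver co-occurrence
#'
#' Each row of `spec` plants one driver gene in `carriers` patients, each
#' carrier additionally receiving `coDrivers` patient-unique filler driver
#' genes, so the planted gene's expected dominance is
#' `1 / (1 + coDrivers)`. Spec genes are assigned to disjoint patient
#' sets; a spec requesting more carriers than patients is rejected as
#' infeasible. With `poisson = TRUE` the filler count is drawn as
#' Poisson(`coDrivers`) per carrier instead of being exact.
#'
#' @param spec data.frame with columns `gene`, `carriers`, `coDrivers`.
#' @param nPatients cohort size.
#' @param seed RNG seed.
#' @param poisson draw filler counts stochastically (default FALSE).
#' @return list with `mutations` (columns `patient_id`, `gene`, `effect`),
#'   `catalog` (all driver genes involved) and `truth` (spec plus
#'   `expected_dominance`).
#' @export
simulateCohortForDominance <- function(spec, nPatients = 60, seed = 1,
                                       poisson = FALSE) {
  stopifnot(all(c("gene", "carriers", "coDrivers") %in% names(spec)))
  if (sum(spec$carriers) > nPatients) {
    stop("infeasible co-occurrence spec: more carriers than patients")
  }
  set.seed(seed)
  patients <- sprintf("C%03d", seq_len(nPatients))
  pool <- sample(patients)
  rows <- list()
  fillers <- character()
  offset <- 0L
  for (g in seq_len(nrow(spec))) {
    carr <- pool[offset + seq_len(spec$carriers[g])]
    offset <- offset + spec$carriers[g]
    for (p in carr) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p, gene = spec$gene[g], effect = "non_silent",
        stringsAsFactors = FALSE
      )
      nCo <- if (poisson) stats::rpois(1, spec$coDrivers[g]) else
        spec$coDrivers[g]
      if (nCo > 0L) {
        fg <- sprintf("FILLER_%s_%02d", p, seq_len(nCo))
        fillers <- union(fillers, fg)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p, gene = fg, effect = "non_silent",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  mutations <- do.call(rbind, rows)
  truth <- spec
  truth$expected_dominance <- 1 / (1 + spec$coDrivers)
  list(
    mutations = mutations,
    catalog = union(spec$gene, fillers),
    truth = truth
  )
}
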