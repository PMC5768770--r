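## Per-patient presence/absence matrices, trunk/branch/private
## classification, pITH, Hamming-distance neighbor-joining trees, and the
## sector-subsampling statistics (trunk ratio calibration, mutation-burden
## gain) used to compare cohorts with different sector counts.

#' Build a presence matrix from validated variant decisions
#'
#' A mutation is present in a sector when it passes the configured detection
#' rule there. The default rule uses the targeted deep-sequencing validation
#' decision when one exists for that mutation/sector, and falls back to the
#' exome filter decision otherwise, reflecting that only validated variants
#' feed the phylogenies. Mutations detected in no sector are dropped;
#' sector/mutation pairs without any decision row are imputed absent.
#'
#' @param decisions decision data.frame from [filterVariants()] (columns
#'   `key`, `patient_id`, `sector_id`, `assay`, `passed`).
#' @param sectors sector ids (columns); defaults to all sectors seen in
#'   `decisions`. Fewer than 2 sectors is an error.
#' @param rule presence rule: `"deepseq_fallback_exome"` (default),
#'   `"deepseq"` (deep-seq decisions only) or `"exome"`.
#' @return a [PresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(decisions, sectors = NULL,
                                rule = c("deepseq_fallback_exome", "deepseq",
                                         "exome")) {
  rule <- match.arg(rule)
  pid <- unique(decisions$patient_id)
  if (length(pid) != 1L) {
    stop("decisions must come from exactly one patient")
  }
  if (is.null(sectors)) sectors <- sort(unique(decisions$sector_id))
  if (length(sectors) < 2L) stop("a presence matrix needs >= 2 sectors")
  use <- switch(rule,
    deepseq = decisions[decisions$assay == "deepseq", , drop = FALSE],
    exome = decisions[decisions$assay == "exome", , drop = FALSE],
    deepseq_fallback_exome = decisions
  )
  keys <- sort(unique(use$key))
  m <- matrix(FALSE, nrow = length(keys), ncol = length(sectors),
              dimnames = list(keys, sectors))
  if (rule == "deepseq_fallback_exome") {
    ds <- use[use$assay == "deepseq", , drop = FALSE]
    ex <- use[use$assay == "exome", , drop = FALSE]
    hasDeep <- paste(ex$key, ex$sector_id) %in% paste(ds$key, ds$sector_id)
    use <- rbind(ds, ex[!hasDeep, , drop = FALSE])
  }
  hit <- use[use$passed, , drop = FALSE]
  hit <- hit[hit$sector_id %in% sectors, , drop = FALSE]
  m[cbind(match(hit$key, keys), match(hit$sector_id, sectors))] <- TRUE
  m <- m[rowSums(m) > 0L, , drop = FALSE]
  PresenceMatrix(m, pid)
}

#' Classify mutations as trunk, branch or private
#'
#' Trunk mutations are present in every sector of the tumor, private
#' mutations in exactly one, and branch mutations in more than one but not
#' all sectors.
#'
#' @param pm a [PresenceMatrix-class].
#' @return list of class `cladeClassification` with `labels` (named factor
#'   over mutation keys, levels trunk/branch/private) and `counts` (named
#'   integer vector `n_trunk`, `n_branch`, `n_private`).
#' @examples
#' m <- rbind(a = c(TRUE, TRUE), b = c(TRUE, FALSE))
#' colnames(m) <- c("S1", "S2")
#' classifyMutations(PresenceMatrix(m, "P"))$counts
#' @export
classifyMutations <- function(pm) {
  m <- presence(pm)
  ns <- rowSums(m)
  lab <- factor(ifelse(ns == ncol(m), "trunk",
                ifelse(ns == 1L, "private", "branch")),
                levels = c("trunk", "branch", "private"))
  names(lab) <- rownames(m)
  counts <- c(n_trunk = sum(lab == "trunk"),
              n_branch = sum(lab == "branch"),
              n_private = sum(lab == "private"))
  structure(list(patient_id = patientId(pm), labels = lab, counts = counts),
            class = "cladeClassification")
}

#' @export
print.cladeClassification <- function(x, ...) {
  cat("Clade classification for", x$patient_id, "-",
      sum(x$counts), "mutations:\n")
  print(x$counts)
  invisible(x)
}

#' Proportional intra-tumor heterogeneity (pITH)
#'
#' The percentage of a tumor's mutations that are branch or private, i.e.
#' `100 * (n_branch + n_private) / total`. Complements the trunk percentage
#' exactly (`pITH + trunk% = 100`). Undefined (NA) for zero mutations.
#'
#' @param cls a `cladeClassification` from [classifyMutations()], or a
#'   [PresenceMatrix-class].
#' @return pITH percentage in \[0, 100\], or `NA` when no mutations.
#' @export
computePith <- function(cls) {
  if (is(cls, "PresenceMatrix")) cls <- classifyMutations(cls)
  total <- sum(cls$counts)
  if (total == 0L) return(NA_real_)
  100 * (cls$counts[["n_branch"]] + cls$counts[["n_private"]]) / total
}

#' Pairwise Hamming distances between sector mutation profiles
#'
#' The distance between two sectors is the number of mutations present in
#' one but not the other. With `includeNormal = TRUE` an all-absent "normal"
#' profile is appended, whose distance to a sector equals that sector's
#' mutation burden; the trunk of the NJ tree is the edge from normal to the
#' first internal node.
#'
#' @param pm a [PresenceMatrix-class].
#' @param includeNormal append the all-absent normal outgroup (default TRUE).
#' @param normalLabel taxon label for the outgroup.
#' @return symmetric integer distance matrix with zero diagonal.
#' @export
hammingDistances <- function(pm, includeNormal = TRUE,
                             normalLabel = "normal") {
  m <- presence(pm)
  prof <- t(m) * 1L
  if (includeNormal) {
    prof <- rbind(prof, matrix(0L, 1, ncol(prof),
                               dimnames = list(normalLabel, NULL)))
  }
  d <- as.matrix(stats::dist(prof, method = "manhattan"))
  storage.mode(d) <- "integer"
  d
}

#' Neighbor-joining tree reconstruction
#'
#' Standard Saitou–Nei neighbor joining on a distance matrix: iteratively
#' join the pair minimizing the Q criterion
#' `Q(i,j) = (N-2) d(i,j) - r_i - r_j`, attach the pair at branch lengths
#' `d(i,j)/2 +- (r_i - r_j)/(2(N-2))`, and reduce the matrix with
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j))/2`. The final three nodes are
#' resolved with the three-point formulas. Negative branch lengths are
#' clamped to zero. For additive distances the generating topology is
#' recovered exactly. Two taxa give a degenerate two-tip tree with a
#' warning.
#'
#' @param d distance matrix (or `dist`) with taxon labels.
#' @return an unrooted [ape::phylo] tree with branch lengths.
#' @examples
#' m <- rbind(a = c(TRUE, TRUE, FALSE), b = c(TRUE, FALSE, TRUE))
#' colnames(m) <- c("S1", "S2", "S3")
#' neighborJoining(hammingDistances(PresenceMatrix(m, "P")))
#' @export
neighborJoining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("neighbor joining needs >= 2 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  if (n == 2L) {
    warning("fewer than 3 taxa: returning degenerate two-taxon tree")
    txt <- sprintf("(%s:%s,%s:%s);", labs[1], fmt(d[1, 2] / 2),
                   labs[2], fmt(d[1, 2] / 2))
    return(ape::read.tree(text = txt))
  }
  node <- labs  # current Newick representation of each active cluster
  dm <- d
  while (length(node) > 3L) {
    N <- length(node)
    r <- rowSums(dm)
    Q <- (N - 2) * dm - outer(r, r, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    li <- dm[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- dm[i, j] - li
    sub <- sprintf("(%s:%s,%s:%s)", node[i], fmt(li), node[j], fmt(lj))
    dnew <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node <- c(node[keep], sub)
  }
  d12 <- dm[1, 2]; d13 <- dm[1, 3]; d23 <- dm[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[1], fmt(l1), node[2], fmt(l2), node[3], fmt(l3))
  ape::read.tree(text = txt)
}

#' Per-patient NJ tree over sectors plus the normal outgroup
#'
#' Convenience wrapper: Hamming distances with the all-absent normal
#' profile, then [neighborJoining()].
#'
#' @inheritParams hammingDistances
#' @return an [ape::phylo] tree whose leaves are the sectors plus `normal`.
#' @export
sectorTree <- function(pm, includeNormal = TRUE, normalLabel = "normal") {
  neighborJoining(hammingDistances(pm, includeNormal, normalLabel))
}

.trunkRatioOf <- function(m, cols) {
  sub <- m[, cols, drop = FALSE]
  ns <- rowSums(sub)
  detected <- ns > 0L
  if (!any(detected)) return(NA_real_)
  sum(ns == length(cols)) / sum(detected)
}

#' Mean trunk proportion under random sector subsampling
#'
#' To compare trunk ratios across tumors with different numbers of sectors,
#' `k` sectors are drawn without replacement `nIter` times; in each draw the
#' trunk is recomputed as the mutations present in all `k` drawn sectors,
#' over the mutations present in at least one of them. Returns the mean
#' across iterations. With `k` equal to the number of sectors this equals
#' the full-matrix trunk proportion with zero variance.
#'
#' @param pm a [PresenceMatrix-class].
#' @param k number of sectors to draw (2 <= k <= n sectors).
#' @param nIter number of random draws (default 20).
#' @param seed optional RNG seed for reproducibility.
#' @return mean trunk proportion in \[0, 1\].
#' @export
subsampleTrunkRatio <- function(pm, k, nIter = 20, seed = NULL) {
  m <- presence(pm)
  if (k > ncol(m)) stop("k exceeds the number of sectors")
  if (k < 2L) stop("k must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(nIter), function(i) {
    .trunkRatioOf(m, sample(ncol(m), k))
  }, numeric(1)), na.rm = TRUE)
}

#' Mutation-burden gain from sequencing multiple sectors
#'
#' Per iteration, `k` sectors are drawn without replacement; the gain is the
#' union mutation burden of the drawn sectors over their mean single-sector
#' burden, minus one, as a percentage. The mean over `nIter` draws is
#' returned. An all-trunk tumor gains 0% for any `k`; `k = 1` is 0% by
#' definition.
#'
#' @inheritParams subsampleTrunkRatio
#' @param k number of sectors to draw (default 3).
#' @param baseline denominator choice: mean single-sector burden of the same
#'   `k` drawn sectors (default), the first drawn sector's burden, or the
#'   patient-wide mean single-sector burden.
#' @return mean percentage gain.
#' @export
burdenGain <- function(pm, k = 3, nIter = 20, seed = NULL,
                       baseline = c("mean_of_k", "first_sector",
                                    "patient_mean")) {
  baseline <- match.arg(baseline)
  m <- presence(pm)
  if (k > ncol(m)) stop("k exceeds the number of sectors")
  if (k == 1L) return(0)
  if (!is.null(seed)) set.seed(seed)
  patientMean <- mean(colSums(m))
  mean(vapply(seq_len(nIter), function(i) {
    cols <- sample(ncol(m), k)
    sub <- m[, cols, drop = FALSE]
    denom <- switch(baseline,
      mean_of_k = mean(colSums(sub)),
      first_sector = sum(sub[, 1]),
      patient_mean = patientMean
    )
    if (denom == 0) return(NA_real_)
    (sum(rowSums(sub) > 0L) - denom) / denom * 100
  }, numeric(1)), na.rm = TRUE)
}
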