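## Driver-gene dominance (self-sufficiency) scoring. A driver that tends to
## occur with few co-occurring drivers across a cohort scores near 1; one
## that always needs company scores near 1/mean(co-driver count).

#' Per-patient driver-mutation burden
#'
#' `d_j` is the number of catalog driver genes carrying at least one
#' non-silent mutation in patient `j` (gene-level counting by default: two
#' mutations in the same gene count once; `countBy = "event"` counts
#' mutation events instead).
#'
#' @param mutations cohort mutation data.frame with columns `patient_id`,
#'   `gene`, `effect`.
#' @param catalog driver catalog from [readDriverCatalog()] (list with
#'   `luad`/`extended` character vectors), or a plain character vector.
#' @param geneSet which catalog to use: `"luad"` (default) or `"extended"`.
#' @param countBy `"gene"` (default) or `"event"`.
#' @return named integer vector of burdens for patients with at least one
#'   driver mutation.
#' @export
driverBurden <- function(mutations, catalog, geneSet = c("luad", "extended"),
                         countBy = c("gene", "event")) {
  geneSet <- match.arg(geneSet)
  countBy <- match.arg(countBy)
  drivers <- if (is.list(catalog)) catalog[[geneSet]] else catalog
  hit <- mutations[mutations$effect == "non_silent" &
                   mutations$gene %in% drivers, , drop = FALSE]
  if (countBy == "gene") hit <- unique(hit[, c("patient_id", "gene")])
  tab <- table(hit$patient_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Driver dominance scores
#'
#' For each driver gene `i` mutated (non-silently) in `N_i` patients, the
#' dominance score is the mean reciprocal driver burden of its carriers,
#' `D_i = (sum over carriers j of 1/d_j) / N_i`, where `d_j` is the
#' patient's driver burden from [driverBurden()]. `D_i` is 1 when the gene
#' always occurs as the sole driver and decreases toward 0 as carriers
#' accumulate co-drivers. Genes mutated in fewer than `minCarriers`
#' patients (default 5) are excluded. Ranking is by descending `D_i`, ties
#' broken by descending `N_i` then gene name.
#'
#' @inheritParams driverBurden
#' @param minCarriers minimum carrier count for inclusion.
#' @return data.frame: `gene`, `n_carriers`, `dominance`, `rank`, ordered
#'   by rank.
#' @examples
#' muts <- data.frame(
#'   patient_id = c("P1", "P2", "P2", "P3"),
#'   gene = c("A", "A", "B", "A"),
#'   effect = "non_silent"
#' )
#' dominanceScores(muts, c("A", "B"), minCarriers = 1)
#' @export
dominanceScores <- function(mutations, catalog,
                            geneSet = c("luad", "extended"),
                            minCarriers = 5, countBy = c("gene", "event")) {
  geneSet <- match.arg(geneSet)
  countBy <- match.arg(countBy)
  drivers <- if (is.list(catalog)) catalog[[geneSet]] else catalog
  d <- driverBurden(mutations, drivers, countBy = countBy)
  hit <- unique(mutations[mutations$effect == "non_silent" &
                          mutations$gene %in% drivers,
                          c("patient_id", "gene"), drop = FALSE])
  if (nrow(hit) == 0L) {
    return(data.frame(gene = character(), n_carriers = integer(),
                      dominance = numeric(), rank = integer()))
  }
  byGene <- split(hit$patient_id, hit$gene)
  tab <- data.frame(
    gene = names(byGene),
    n_carriers = vapply(byGene, length, integer(1)),
    dominance = vapply(byGene, function(pj) mean(1 / d[pj]), numeric(1)),
    stringsAsFactors = FALSE
  )
  tab <- tab[tab$n_carriers >= minCarriers, , drop = FALSE]
  tab <- tab[order(-tab$dominance, -tab$n_carriers, tab$gene), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
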