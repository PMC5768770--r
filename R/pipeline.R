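## End-to-end orchestration: filter/validate variants, build presence
## matrices and trees, compute pITH and subsampling statistics, per-sector
## instability scores, WGD status, CCF/timing tables and the cohort
## dominance ranking, writing JSON + flat TSV twins (and Newick trees) when
## an output directory is given. Sectors without a copy-number profile are
## allowed: SCNA/WGD/timing stages skip them and the report records the
## absence; mutation stages still use them.

#' Run the full multi-region analysis pipeline
#'
#' Inputs are either a simulated cohort ([simulateCohort()]), or file paths
#' to a variant table and (optionally) segment + purity tables. All stage
#' parameters default to the study-condition values; identical
#' configuration and seed give identical outputs.
#'
#' @param cohort a `simCohort` object, or `NULL` to read from files.
#' @param variantsFile,segmentsFile,purityFile input TSV paths (used when
#'   `cohort` is `NULL`; segments optional).
#' @param outDir output directory; created if needed. `NULL` suppresses
#'   file output.
#' @param seed seed for the subsampling and WGD simulation stages.
#' @param features optional `GRanges` of cytobands/genes for feature-level
#'   copy assignment and SCNA-ITH.
#' @param catalog driver catalog (list with `luad`/`extended`, or character
#'   vector); defaults to the catalog shipped with the package.
#' @param kSubsample,nIter sector subsampling parameters.
#' @param nSimWgd WGD null simulations per sector.
#' @param minCarriers dominance carrier threshold.
#' @param minSectorsScna minimum profiled sectors for SCNA-ITH.
#' @param includeX include chromosome X in genome fractions.
#' @return (invisibly when writing) list with per-patient results and a
#'   cohort summary.
#' @export
runPipeline <- function(cohort = NULL, variantsFile = NULL,
                        segmentsFile = NULL, purityFile = NULL,
                        outDir = NULL, seed = 1, features = NULL,
                        catalog = NULL, kSubsample = 3, nIter = 20,
                        nSimWgd = 10000, minCarriers = 5,
                        minSectorsScna = 3, includeX = FALSE) {
  if (is.null(cohort)) {
    if (is.null(variantsFile)) {
      stop("either a cohort object or a variants file is required")
    }
    variants <- readVariants(variantsFile)
    profiles <- if (!is.null(segmentsFile)) {
      readSegments(segmentsFile, purityFile)
    } else {
      list()
    }
    pids <- unique(variants$patient_id)
    cohort <- lapply(pids, function(p) {
      v <- variants[variants$patient_id == p, , drop = FALSE]
      sect <- unique(v$sector_id)
      list(patient_id = p, variants = v,
           profiles = profiles[intersect(names(profiles), sect)])
    })
    names(cohort) <- pids
  }
  if (is.null(catalog)) {
    catalog <- readDriverCatalog(
      system.file("extdata", "luad_drivers.txt", package = "clonarch"),
      system.file("extdata", "extended_drivers.txt", package = "clonarch")
    )
  }

  patientResults <- lapply(cohort, function(tumor) {
    .analyzePatient(tumor, seed = .patientSeed(seed, tumor$patient_id),
                    features = features, kSubsample = kSubsample,
                    nIter = nIter, nSimWgd = nSimWgd,
                    minSectorsScna = minSectorsScna, includeX = includeX)
  })

  cohortMutations <- do.call(rbind, lapply(patientResults, `[[`,
                                           "driverMutations"))
  dominance <- dominanceScores(cohortMutations, catalog,
                               minCarriers = minCarriers)
  ith <- do.call(rbind, lapply(patientResults, `[[`, "ith"))
  rownames(ith) <- NULL
  scna <- do.call(rbind, lapply(patientResults, function(r) r$scna))
  wgd <- do.call(rbind, lapply(patientResults, function(r) r$wgd))
  summary <- list(
    n_patients = length(patientResults),
    pith_median = stats::median(ith$pith, na.rm = TRUE),
    burden_gain_mean = mean(ith$burden_gain, na.rm = TRUE),
    gii_median = if (!is.null(scna)) stats::median(scna$gii) else NA,
    adgii_median = if (!is.null(scna)) stats::median(scna$adgii) else NA,
    n_wgd_tumors = if (!is.null(wgd)) {
      sum(vapply(split(wgd$doubled, wgd$patient_id), any, logical(1)))
    } else NA
  )
  result <- list(patients = patientResults, ith = ith, scna = scna,
                 wgd = wgd, dominance = dominance, summary = summary)
  if (!is.null(outDir)) {
    .writeReports(result, outDir)
    return(invisible(result))
  }
  result
}

.analyzePatient <- function(tumor, seed, features, kSubsample, nIter,
                            nSimWgd, minSectorsScna, includeX) {
  v <- tumor$variants
  pid <- tumor$patient_id
  decisions <- filterVariants(v)
  sectors <- sort(unique(v$sector_id))
  pm <- buildPresenceMatrix(decisions, sectors = sectors)
  cls <- classifyMutations(pm)
  tree <- sectorTree(pm)
  k <- min(kSubsample, ncol(presence(pm)))
  trunkRatio <- subsampleTrunkRatio(pm, k = k, nIter = nIter, seed = seed)
  gain <- burdenGain(pm, k = k, nIter = nIter, seed = seed + 1L)

  exomePass <- decisions$assay == "exome" & decisions$passed
  exomeCalls <- v[exomePass, , drop = FALSE]
  vr <- validationRate(exomeCalls,
                       decisions[decisions$assay == "deepseq", , drop = FALSE])

  profiles <- tumor$profiles
  scna <- NULL; wgd <- NULL; timing <- NULL; scnaIthRes <- NULL
  if (length(profiles)) {
    scna <- do.call(rbind, lapply(profiles, instabilityScores,
                                  includeX = includeX))
    scna <- cbind(patient_id = pid, scna)
    rownames(scna) <- NULL
    wgd <- do.call(rbind, lapply(seq_along(profiles), function(i) {
      wgdTest(profiles[[i]], nSim = nSimWgd, seed = seed + 100L + i,
              includeX = includeX)
    }))
    wgd <- cbind(patient_id = pid, wgd)
    rownames(wgd) <- NULL
    validated <- decisions$assay == "deepseq" & decisions$passed
    vv <- v[validated, , drop = FALSE]
    timing <- do.call(rbind, lapply(profiles, function(p) {
      vs <- vv[vv$sector_id == sectorId(p), , drop = FALSE]
      if (!nrow(vs)) return(NULL)
      sectorCcfTable(vs, p)
    }))
    if (!is.null(timing)) rownames(timing) <- NULL
    if (!is.null(features) && length(profiles) >= minSectorsScna) {
      featureCN <- lapply(profiles, mapToFeatures, features = features)
      scnaIthRes <- scnaIth(featureCN,
                            vapply(profiles, ploidy, integer(1)),
                            minSectors = minSectorsScna)
    }
  }

  # decisions are returned in input row order, so this subsets v directly
  vOk <- v[decisions$passed, , drop = FALSE]
  driverMutations <- unique(vOk[, c("patient_id", "gene", "effect")])
  ith <- data.frame(
    patient_id = pid,
    n_sectors = length(sectors),
    n_trunk = cls$counts[["n_trunk"]],
    n_branch = cls$counts[["n_branch"]],
    n_private = cls$counts[["n_private"]],
    pith = computePith(cls),
    trunk_ratio_k = trunkRatio,
    burden_gain = gain,
    snv_validation = vr$snv_rate,
    indel_validation = vr$indel_rate,
    stringsAsFactors = FALSE
  )
  list(patient_id = pid, ith = ith, classification = cls, tree = tree,
       scna = scna, wgd = wgd, timing = timing, scnaIth = scnaIthRes,
       driverMutations = driverMutations,
       scnaAbsent = length(profiles) == 0L)
}

.writeReports <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "trees"), showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(outDir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(result$ith, "ith.tsv")
  wt(result$scna, "scna.tsv")
  wt(result$wgd, "wgd.tsv")
  wt(result$dominance, "dominance.tsv")
  timing <- do.call(rbind, lapply(result$patients, `[[`, "timing"))
  wt(timing, "timing.tsv")
  for (p in result$patients) {
    writeNewick(p$tree, file.path(outDir, "trees",
                                  paste0(p$patient_id, ".nwk")))
  }
  report <- list(
    summary = result$summary,
    patients = lapply(result$patients, function(p) {
      list(
        patient_id = p$patient_id,
        pith = p$ith$pith,
        counts = as.list(p$classification$counts),
        tree = writeNewick(p$tree),
        scna = if (p$scnaAbsent) "absent" else "present",
        late_scna_fraction = if (is.null(p$scnaIth)) NULL else
          p$scnaIth$lateFraction
      )
    })
  )
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
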