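## Post-caller somatic filter rules for exome calls and targeted
## deep-sequencing validation rules. All functions are vectorized over the
## rows of a variant data.frame and return one decision per row; a decision
## fails iff at least one named rule fails, so `passed` and `failed_rules`
## are always consistent and rule order never matters.

.decision <- function(v, ruleFails) {
  # ruleFails: named list of logical vectors (TRUE = rule failed)
  failed <- vapply(seq_len(nrow(v)), function(i) {
    paste(names(ruleFails)[vapply(ruleFails, `[`, logical(1), i)],
          collapse = ";")
  }, character(1))
  data.frame(
    key = variantKey(v),
    patient_id = v$patient_id,
    sector_id = v$sector_id,
    passed = !nzchar(failed),
    failed_rules = failed,
    stringsAsFactors = FALSE
  )
}

.checkDepth <- function(v) {
  bad <- which(v$t_alt + v$t_ref == 0L)
  if (length(bad)) {
    stop(sprintf("zero tumor depth (undefined VAF) for variant %s in %s",
                 variantKey(v)[bad[1]], v$sector_id[bad[1]]))
  }
}

#' Exome somatic SNV filter
#'
#' Post-caller rules applied to exome SNV calls: at most 5 reads supporting
#' the variant in the normal at up to 0.05 normal allele frequency, at least
#' 6 tumor reads supporting the variant, and tumor VAF either at least
#' `lowVafCut` (default 0.2) or at least 10 times the normal VAF (the
#' low-frequency rescue rule). The normal-VAF ratio rule passes when the
#' normal VAF is 0 (the limit of the ratio test).
#'
#' @param v variant data.frame (exome SNV rows); zero tumor depth is an
#'   error.
#' @param lowVafCut tumor VAF above which the 10x normal-ratio rule is not
#'   required.
#' @param lowVafInclusive whether the `lowVafCut` boundary passes (`>=`,
#'   default) or requires strict excess (`>`).
#' @return decision data.frame: `key`, `patient_id`, `sector_id`, `passed`,
#'   `failed_rules` (semicolon-joined rule ids; empty iff passed).
#' @examples
#' v <- data.frame(patient_id = "P", sector_id = "S", chrom = "7",
#'                 pos = 100, ref = "C", alt = "T", t_alt = 50, t_ref = 50,
#'                 n_alt = 0, n_ref = 60)
#' filterExomeSnv(v)
#' @export
filterExomeSnv <- function(v, lowVafCut = 0.2, lowVafInclusive = TRUE) {
  .checkDepth(v)
  tv <- tumorVAF(v)
  nv <- normalVAF(v)
  nv[is.na(nv)] <- 0
  highVaf <- if (lowVafInclusive) tv >= lowVafCut else tv > lowVafCut
  .decision(v, list(
    normal_alt_reads = v$n_alt > 5L,
    normal_vaf = nv > 0.05,
    min_alt_reads = v$t_alt < 6L,
    tumor_normal_ratio = !(highVaf | tv >= 10 * nv)
  ))
}

#' Exome somatic indel filter
#'
#' More than 4 reads supporting the indel with tumor VAF at least 0.1
#' (mapping-quality filtering is assumed upstream of the count table).
#'
#' @inheritParams filterExomeSnv
#' @return decision data.frame (see [filterExomeSnv()]).
#' @export
filterExomeIndel <- function(v) {
  .checkDepth(v)
  tv <- tumorVAF(v)
  .decision(v, list(
    min_alt_reads = v$t_alt <= 4L,
    min_vaf = tv < 0.1
  ))
}

#' Targeted deep-sequencing SNV validation
#'
#' Validation rules for deep-sequenced SNVs: the variant must have been
#' called in the exome assay (`exomeCalled`), carry at least 10 alternate
#' reads (at least 15 when the tumor VAF is below 0.05), have tumor VAF at
#' least 5 times the normal VAF, and tumor VAF at least 0.01 (the caller's
#' minimum variant frequency). A zero normal VAF passes the ratio rule.
#'
#' @inheritParams filterExomeSnv
#' @param exomeCalled logical vector (or single value) flagging exome
#'   membership per row; missing values are an error.
#' @return decision data.frame (see [filterExomeSnv()]).
#' @export
validateDeepseqSnv <- function(v, exomeCalled) {
  .checkDepth(v)
  exomeCalled <- rep_len(exomeCalled, nrow(v))
  if (anyNA(exomeCalled)) {
    stop("exome-membership flag is required for every deep-seq SNV")
  }
  tv <- tumorVAF(v)
  nv <- normalVAF(v)
  nv[is.na(nv)] <- 0
  .decision(v, list(
    not_exome_called = !exomeCalled,
    min_alt_reads = v$t_alt < 10L,
    low_vaf_support = tv < 0.05 & v$t_alt < 15L,
    tumor_normal_ratio = tv < 5 * nv,
    min_vaf = tv < 0.01
  ))
}

#' Targeted deep-sequencing indel validation
#'
#' Validation rules for deep-sequenced indels: no more than 90% of
#' alternate reads from one strand, at least 10 alternate reads, tumor VAF
#' at least 0.03, and tumor VAF at least 5 times the normal VAF. Rows with
#' `t_alt = 0` fail the strand rule (fraction undefined) rather than
#' erroring.
#'
#' @inheritParams filterExomeSnv
#' @return decision data.frame (see [filterExomeSnv()]).
#' @export
validateDeepseqIndel <- function(v) {
  .checkDepth(v)
  if (!all(c("alt_fwd", "alt_rev") %in% names(v))) {
    stop("deep-seq indel validation needs strand-split counts alt_fwd/alt_rev")
  }
  tv <- tumorVAF(v)
  nv <- normalVAF(v)
  nv[is.na(nv)] <- 0
  strandFrac <- ifelse(v$t_alt > 0,
                       pmax(v$alt_fwd, v$alt_rev) / v$t_alt, NA_real_)
  .decision(v, list(
    strand_bias = is.na(strandFrac) | strandFrac > 0.9,
    min_alt_reads = v$t_alt < 10L,
    min_vaf = tv < 0.03,
    tumor_normal_ratio = tv < 5 * nv
  ))
}

#' Apply the assay- and class-appropriate filter to a mixed variant table
#'
#' Dispatches each row to [filterExomeSnv()], [filterExomeIndel()],
#' [validateDeepseqSnv()] or [validateDeepseqIndel()] by its `assay` and
#' `variant_class`, optionally removing germline-blacklisted keys first.
#'
#' @param v variant data.frame with `assay` and `variant_class` columns.
#' @param exomeCalled exome-membership flags for deep-seq SNV rows (recycled;
#'   default `TRUE`, appropriate when the deep-seq panel was designed from
#'   the exome calls).
#' @param germlineBlacklist optional character vector of mutation keys
#'   (`chrom:pos:ref:alt`) to fail with rule `germline`.
#' @return decision data.frame in the input row order.
#' @export
filterVariants <- function(v, exomeCalled = TRUE, germlineBlacklist = NULL) {
  isSnv <- v$variant_class == "SNV"
  isExome <- v$assay == "exome"
  idx <- list(
    which(isExome & isSnv), which(isExome & !isSnv),
    which(!isExome & isSnv), which(!isExome & !isSnv)
  )
  exomeCalled <- rep_len(exomeCalled, nrow(v))
  parts <- list(
    if (length(idx[[1]])) filterExomeSnv(v[idx[[1]], , drop = FALSE]),
    if (length(idx[[2]])) filterExomeIndel(v[idx[[2]], , drop = FALSE]),
    if (length(idx[[3]])) validateDeepseqSnv(v[idx[[3]], , drop = FALSE],
                                             exomeCalled[idx[[3]]]),
    if (length(idx[[4]])) validateDeepseqIndel(v[idx[[4]], , drop = FALSE])
  )
  keep <- !vapply(parts, is.null, logical(1))
  out <- do.call(rbind, parts[keep])
  out <- out[order(unlist(idx[keep])), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(germlineBlacklist)) {
    hit <- out$key %in% germlineBlacklist
    out$failed_rules[hit] <- ifelse(nzchar(out$failed_rules[hit]),
                                    paste0(out$failed_rules[hit], ";germline"),
                                    "germline")
    out$passed <- out$passed & !hit
  }
  out$assay <- v$assay
  out$variant_class <- v$variant_class
  out
}

#' Deep-sequencing validation rate
#'
#' Fraction of exome-called mutations confirmed by targeted deep sequencing,
#' reported separately for SNVs and indels. A mutation is attempted when at
#' least one deep-seq decision covers its key, and validated when it passes
#' in at least one sector. Classes with zero attempted mutations are
#' reported as `NA`.
#'
#' @param exomeCalls data.frame of exome-passed variants (needs `chrom`,
#'   `pos`, `ref`, `alt`, `variant_class`).
#' @param deepseqDecisions decision data.frame from the deep-seq validators,
#'   with `key`, `passed` and `variant_class` columns.
#' @return list with elements `snv_rate` and `indel_rate` in \[0, 1\] or `NA`.
#' @export
validationRate <- function(exomeCalls, deepseqDecisions) {
  keys <- variantKey(exomeCalls)
  rateFor <- function(classes) {
    attempted <- unique(keys[exomeCalls$variant_class %in% classes])
    dd <- deepseqDecisions[deepseqDecisions$key %in% attempted, , drop = FALSE]
    attempted <- intersect(attempted, dd$key)
    if (!length(attempted)) return(NA_real_)
    validated <- unique(dd$key[dd$passed])
    length(validated) / length(attempted)
  }
  list(
    snv_rate = rateFor("SNV"),
    indel_rate = rateFor(c("INS", "DEL"))
  )
}
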