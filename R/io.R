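## Readers and writers for the plain-text formats the pipeline consumes:
## MAF-like variant TSVs with tumor/normal read counts, SEG-like allele-
## specific copy-number tables with a companion purity table, UCSC
## cytoBand.txt, gene BED, plain driver-gene lists, and Newick trees.
## Coordinates are 1-based inclusive internally; BED is converted on read.

.VARIANT_COLS <- c(
  "patient_id", "sector_id", "chrom", "pos", "ref", "alt",
  "variant_class", "gene", "effect", "assay",
  "t_ref", "t_alt", "n_ref", "n_alt"
)
.VARIANT_CLASSES <- c("SNV", "INS", "DEL")
.EFFECTS <- c("non_silent", "silent", "other")
.ASSAYS <- c("exome", "deepseq")

#' Mutation key
#'
#' `chrom:pos:ref:alt` identifies a mutation within a patient.
#'
#' @param v variant data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of keys.
#' @export
variantKey <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Read a somatic variant table
#'
#' Reads a MAF-like TSV of per-sector somatic SNV/indel observations with
#' tumor/normal reference/alternate read counts. Required columns:
#' `patient_id`, `sector_id`, `chrom`, `pos`, `ref`, `alt`, `variant_class`
#' (SNV/INS/DEL), `gene`, `effect` (non_silent/silent/other), `assay`
#' (exome/deepseq), `t_ref`, `t_alt`, `n_ref`, `n_alt`; optional strand-split
#' alternate counts `alt_fwd`/`alt_rev` (indels). Malformed rows raise an
#' error naming the offending data row.
#'
#' @param path TSV file with header.
#' @param assay if given, overrides/fills the `assay` column
#'   (`"exome"` or `"deepseq"`).
#' @return data.frame of variant records.
#' @seealso [writeVariants()], [tumorVAF()]
#' @export
readVariants <- function(path, assay = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", comment.char = "")
  if (!is.null(assay)) {
    assay <- match.arg(assay, .ASSAYS)
    df$assay <- assay
  }
  miss <- setdiff(.VARIANT_COLS, names(df))
  if (length(miss)) {
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  }
  countCols <- c("pos", "t_ref", "t_alt", "n_ref", "n_alt",
                 intersect(c("alt_fwd", "alt_rev"), names(df)))
  for (cc in countCols) {
    raw <- df[[cc]]
    missingOk <- cc %in% c("alt_fwd", "alt_rev")  # strand counts optional
    isMiss <- is.na(raw) | raw %in% c("", "NA")
    val <- suppressWarnings(as.numeric(raw))
    bad <- which((!isMiss & (is.na(val) | val < 0 | val != round(val))) |
                 (isMiss & !missingOk))
    if (length(bad)) {
      stop(sprintf("invalid value '%s' in column '%s' at data row %d",
                   raw[bad[1]], cc, bad[1]))
    }
    df[[cc]] <- as.integer(round(val))
  }
  bad <- which(!df$variant_class %in% .VARIANT_CLASSES)
  if (length(bad)) {
    stop(sprintf("invalid variant_class '%s' at data row %d",
                 df$variant_class[bad[1]], bad[1]))
  }
  bad <- which(!df$assay %in% .ASSAYS)
  if (length(bad)) {
    stop(sprintf("invalid assay '%s' at data row %d", df$assay[bad[1]], bad[1]))
  }
  bad <- which(!df$effect %in% .EFFECTS)
  if (length(bad)) {
    stop(sprintf("invalid effect '%s' at data row %d", df$effect[bad[1]], bad[1]))
  }
  if (all(c("alt_fwd", "alt_rev") %in% names(df))) {
    both <- !is.na(df$alt_fwd) & !is.na(df$alt_rev)
    bad <- which(both & df$alt_fwd + df$alt_rev != df$t_alt)
    if (length(bad)) {
      stop(sprintf("alt_fwd + alt_rev != t_alt at data row %d", bad[1]))
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a somatic variant table
#'
#' @param variants data.frame as returned by [readVariants()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Tumor and normal variant allele frequencies
#'
#' VAF uses the modeled counts only: `alt / (alt + ref)`. Zero-depth
#' observations give `NA`.
#'
#' @param v variant data.frame.
#' @return numeric vector of tumor (resp. normal) VAFs.
#' @export
tumorVAF <- function(v) {
  depth <- v$t_alt + v$t_ref
  ifelse(depth > 0, v$t_alt / depth, NA_real_)
}

#' @rdname tumorVAF
#' @export
normalVAF <- function(v) {
  depth <- v$n_alt + v$n_ref
  ifelse(depth > 0, v$n_alt / depth, NA_real_)
}

#' Read allele-specific copy-number segments and purity
#'
#' Reads a SEG-like TSV (`sector`, `chrom`, `start`, `end`, `nMajor`,
#' `nMinor`, optional `nSNPs`; 1-based inclusive coordinates) together with a
#' companion purity table (`sector`, `purity`), and returns one
#' [SectorProfile-class] per sector. Overlapping segments within a sector and
#' `nMinor > nMajor` rows are rejected.
#'
#' @param segPath segment TSV path.
#' @param purityPath purity TSV path.
#' @return named list of `SectorProfile` objects.
#' @seealso [writeSegments()]
#' @export
readSegments <- function(segPath, purityPath) {
  seg <- utils::read.table(segPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("sector", "chrom", "start", "end", "nMajor", "nMinor")
  miss <- setdiff(req, names(seg))
  if (length(miss)) {
    stop("segment table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(seg$start > seg$end)
  if (length(bad)) stop(sprintf("start > end at data row %d", bad[1]))
  bad <- which(seg$nMinor > seg$nMajor)
  if (length(bad)) {
    stop(sprintf("nMinor > nMajor (swapped alleles?) at data row %d", bad[1]))
  }
  pur <- utils::read.table(purityPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sector", "purity") %in% names(pur))) {
    stop("purity table needs columns: sector, purity")
  }
  sectors <- unique(seg$sector)
  missP <- setdiff(sectors, pur$sector)
  if (length(missP)) {
    stop("no purity for sector(s): ", paste(missP, collapse = ", "))
  }
  out <- lapply(sectors, function(s) {
    df <- seg[seg$sector == s, , drop = FALSE]
    df$sector <- NULL
    SectorProfile(s, df, purity = pur$purity[match(s, pur$sector)])
  })
  names(out) <- sectors
  out
}

#' Write segment profiles
#'
#' @param profiles list of [SectorProfile-class] objects.
#' @param segPath output segment TSV path.
#' @param purityPath output purity TSV path.
#' @return `segPath`, invisibly.
#' @export
writeSegments <- function(profiles, segPath, purityPath) {
  segs <- do.call(rbind, lapply(profiles, function(p) {
    gr <- cnSegments(p)
    df <- data.frame(
      sector = sectorId(p),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      nMajor = S4Vectors::mcols(gr)$nMajor,
      nMinor = S4Vectors::mcols(gr)$nMinor,
      stringsAsFactors = FALSE
    )
    if ("nSNPs" %in% colnames(S4Vectors::mcols(gr))) {
      df$nSNPs <- S4Vectors::mcols(gr)$nSNPs
    }
    df
  }))
  utils::write.table(segs, segPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pur <- data.frame(
    sector = vapply(profiles, sectorId, character(1)),
    purity = vapply(profiles, purity, numeric(1))
  )
  utils::write.table(pur, purityPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(segPath)
}

#' Read a UCSC cytoBand.txt feature table
#'
#' cytoBand.txt is headerless, tab-separated (`chrom`, `chromStart`,
#' `chromEnd`, `name`, `gieStain`) with 0-based half-open coordinates, which
#' are converted to 1-based inclusive. Feature names are `chrom` stripped of
#' the `chr` prefix pasted to the band name (e.g. `9p21.3`).
#'
#' @param path cytoBand.txt path.
#' @return `GRanges` with metadata columns `name` and `kind = "cytoband"`.
#' @export
readCytoband <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "chromStart", "chromEnd",
                                        "name", "gieStain"))
  chrom <- sub("^chr", "", df$chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = df$chromStart + 1L, end = df$chromEnd)
  )
  S4Vectors::mcols(gr)$name <- paste0(chrom, df$name)
  S4Vectors::mcols(gr)$kind <- "cytoband"
  gr
}

#' Read a gene BED file
#'
#' BED is 0-based half-open; coordinates are converted to 1-based inclusive
#' on read (via `rtracklayer` when available, otherwise a minimal 4-column
#' reader).
#'
#' @param path BED path (>= 4 columns: chrom, start, end, name).
#' @return `GRanges` with metadata columns `name` and `kind = "gene"`.
#' @export
readGeneBed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    GenomeInfoDb::seqlevels(gr) <- sub("^chr", "",
                                       GenomeInfoDb::seqlevels(gr))
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::IRanges(GenomicRanges::start(gr),
                                                   GenomicRanges::end(gr)))
    S4Vectors::mcols(out)$name <- S4Vectors::mcols(gr)$name
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("gene BED needs >= 4 columns")
    out <- GenomicRanges::GRanges(
      seqnames = sub("^chr", "", df[[1]]),
      ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]])
    )
    S4Vectors::mcols(out)$name <- df[[4]]
  }
  S4Vectors::mcols(out)$kind <- "gene"
  out
}

#' Read driver-gene catalogs
#'
#' Plain one-gene-per-line lists (blank lines and `#` comments ignored). The
#' extended catalog is unioned with the primary list so the containment
#' invariant (primary subset of extended) always holds.
#'
#' @param luadPath path to the tumor-type-specific driver list.
#' @param extendedPath optional path to the pan-cancer extension.
#' @return list with character vectors `luad` and `extended`.
#' @export
readDriverCatalog <- function(luadPath, extendedPath = NULL) {
  readList <- function(p) {
    x <- trimws(readLines(p, warn = FALSE))
    x <- x[nzchar(x) & !startsWith(x, "#")]
    unique(x)
  }
  luad <- readList(luadPath)
  extended <- if (is.null(extendedPath)) luad else {
    union(luad, readList(extendedPath))
  }
  list(luad = luad, extended = extended)
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] tree (e.g. from [neighborJoining()]).
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when `path` is given).
#' @export
writeNewick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$tip.label) || length(tree$tip.label) < 2L) {
    stop("cannot serialize a tree with fewer than 2 taxa")
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#'
#' @param path file containing one Newick string, or the string itself.
#' @return an [ape::phylo] tree.
#' @export
readNewick <- function(path) {
  if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
}
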