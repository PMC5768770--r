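#' @import methods
#' @importFrom GenomicRanges GRanges findOverlaps width seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

#' SectorProfile: purity and allele-specific copy number for one tumor sector
#'
#' A `SectorProfile` holds the ASCAT-style allele-specific integer copy-number
#' segmentation of a single tumor sector together with its estimated purity
#' (aberrant cell fraction) and cached median integer ploidy. Segments are
#' stored as a [GenomicRanges::GRanges] (1-based, inclusive coordinates) with
#' metadata columns `nMajor`, `nMinor` and optionally `nSNPs` (the number of
#' array SNPs supporting the segment, used as the ploidy weight when present).
#'
#' Validity requires purity in (0, 1], integer `nMajor >= nMinor >= 0`, and
#' non-overlapping segments within the sector.
#'
#' @slot sectorId single sector identifier.
#' @slot purity tumor purity in (0, 1].
#' @slot segments `GRanges` of segments with `nMajor`/`nMinor` (and optional
#'   `nSNPs`) metadata columns.
#' @slot ploidy cached median integer ploidy (see [medianIntegerPloidy()]).
#'
#' @seealso [SectorProfile()] constructor, [instabilityScores()], [wgdTest()]
#' @exportClass SectorProfile
setClass("SectorProfile",
  slots = c(
    sectorId = "character",
    purity = "numeric",
    segments = "GRanges",
    ploidy = "integer"
  )
)

setValidity("SectorProfile", function(object) {
  msg <- character()
  if (length(object@sectorId) != 1L || is.na(object@sectorId) ||
      !nzchar(object@sectorId)) {
    msg <- c(msg, "sectorId must be a single non-empty string")
  }
  if (length(object@purity) != 1L || is.na(object@purity) ||
      object@purity <= 0 || object@purity > 1) {
    msg <- c(msg, "purity must be a single value in (0, 1]")
  }
  seg <- object@segments
  mc <- S4Vectors::mcols(seg)
  if (!all(c("nMajor", "nMinor") %in% colnames(mc))) {
    msg <- c(msg, "segments must carry nMajor and nMinor metadata columns")
  } else {
    nMaj <- mc$nMajor
    nMin <- mc$nMinor
    if (any(is.na(nMaj)) || any(is.na(nMin)) ||
        any(nMaj != round(nMaj)) || any(nMin != round(nMin))) {
      msg <- c(msg, "nMajor/nMinor must be non-missing integers")
    } else {
      if (any(nMin < 0)) msg <- c(msg, "nMinor must be >= 0")
      if (any(nMaj < nMin)) {
        msg <- c(msg, "nMajor must be >= nMinor (allele labels swapped?)")
      }
    }
    if (length(seg) > 1L) {
      hits <- GenomicRanges::findOverlaps(seg, drop.self = TRUE,
                                          drop.redundant = TRUE)
      if (length(hits) > 0L) {
        msg <- c(msg, "segments within a sector must not overlap")
      }
    }
  }
  if (length(object@ploidy) != 1L || is.na(object@ploidy) ||
      object@ploidy < 1L) {
    msg <- c(msg, "ploidy must be a single integer >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SectorProfile
#'
#' @param sectorId sector identifier.
#' @param segments `GRanges` with `nMajor`/`nMinor` (optional `nSNPs`)
#'   metadata columns, or a data.frame with columns `chrom`, `start`, `end`,
#'   `nMajor`, `nMinor` (optional `nSNPs`).
#' @param purity tumor purity in (0, 1].
#' @param ploidy median integer ploidy; computed with [medianIntegerPloidy()]
#'   when `NULL`.
#' @return A [SectorProfile-class] object.
#' @examples
#' seg <- data.frame(chrom = "1", start = 1, end = 1e6, nMajor = 1, nMinor = 1)
#' SectorProfile("S1", seg, purity = 0.7)
#' @export
SectorProfile <- function(sectorId, segments, purity, ploidy = NULL) {
  if (is.data.frame(segments)) {
    segments <- .segmentsAsGRanges(segments)
  }
  obj <- new("SectorProfile",
    sectorId = as.character(sectorId),
    purity = as.numeric(purity),
    segments = segments,
    ploidy = 1L
  )
  obj@ploidy <- if (is.null(ploidy)) {
    medianIntegerPloidy(obj)
  } else {
    as.integer(ploidy)
  }
  validObject(obj)
  obj
}

.segmentsAsGRanges <- function(df) {
  req <- c("chrom", "start", "end", "nMajor", "nMinor")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("segment table missing column(s): ", paste(miss, collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
  S4Vectors::mcols(gr)$nMajor <- as.integer(df$nMajor)
  S4Vectors::mcols(gr)$nMinor <- as.integer(df$nMinor)
  if ("nSNPs" %in% names(df)) {
    S4Vectors::mcols(gr)$nSNPs <- as.integer(df$nSNPs)
  }
  gr
}

#' PresenceMatrix: binary mutation detection across the sectors of one tumor
#'
#' Rows are mutation keys (`chrom:pos:ref:alt`), columns are sector
#' identifiers, and entries record whether the mutation was detected
#' (validated) in that sector. The matrix is the substrate for
#' trunk/branch/private classification, pITH, and Hamming-distance
#' phylogenies. Validity requires at least two sectors, logical entries, and
#' no all-absent row (a mutation detected nowhere carries no signal).
#'
#' @slot patientId patient identifier.
#' @slot mat logical matrix, mutations x sectors, with dimnames.
#'
#' @seealso [PresenceMatrix()], [buildPresenceMatrix()], [classifyMutations()]
#' @exportClass PresenceMatrix
setClass("PresenceMatrix",
  slots = c(patientId = "character", mat = "matrix")
)

setValidity("PresenceMatrix", function(object) {
  msg <- character()
  m <- object@mat
  if (length(object@patientId) != 1L || !nzchar(object@patientId)) {
    msg <- c(msg, "patientId must be a single non-empty string")
  }
  if (!is.logical(m)) msg <- c(msg, "entries must be logical")
  if (ncol(m) < 2L) msg <- c(msg, "a presence matrix needs >= 2 sectors")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    msg <- c(msg, "mutation keys (rownames) and sector ids (colnames) required")
  } else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate mutation keys")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate sector ids")
  }
  if (nrow(m) > 0L && is.logical(m) && any(rowSums(m) == 0L)) {
    msg <- c(msg, "all-absent mutation rows are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PresenceMatrix
#'
#' @param mat logical (or 0/1) matrix, mutations x sectors, with mutation keys
#'   as rownames and sector ids as colnames.
#' @param patientId patient identifier.
#' @return A [PresenceMatrix-class] object.
#' @examples
#' m <- rbind(m1 = c(1, 1, 1), m2 = c(1, 0, 0))
#' colnames(m) <- c("S1", "S2", "S3")
#' PresenceMatrix(m, "P01")
#' @export
PresenceMatrix <- function(mat, patientId) {
  storage.mode(mat) <- "logical"
  obj <- new("PresenceMatrix", patientId = as.character(patientId), mat = mat)
  validObject(obj)
  obj
}

## ---- generics & accessors ----

#' @rdname SectorProfile-class
#' @param x,object a `SectorProfile` or `PresenceMatrix`.
#' @export
setGeneric("sectorId", function(x) standardGeneric("sectorId"))

#' @rdname SectorProfile-class
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))

#' @rdname SectorProfile-class
#' @export
setGeneric("cnSegments", function(x) standardGeneric("cnSegments"))

#' @rdname SectorProfile-class
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname SectorProfile-class
#' @export
setMethod("sectorId", "SectorProfile", function(x) x@sectorId)

#' @rdname SectorProfile-class
#' @export
setMethod("purity", "SectorProfile", function(x) x@purity)

#' @rdname SectorProfile-class
#' @export
setMethod("cnSegments", "SectorProfile", function(x) x@segments)

#' @rdname SectorProfile-class
#' @export
setMethod("ploidy", "SectorProfile", function(x) x@ploidy)

#' @rdname PresenceMatrix-class
#' @export
setMethod("patientId", "PresenceMatrix", function(x) x@patientId)

#' @rdname PresenceMatrix-class
#' @export
setMethod("presence", "PresenceMatrix", function(x) x@mat)

#' @rdname PresenceMatrix-class
#' @export
setMethod("sectorId", "PresenceMatrix", function(x) colnames(x@mat))

setMethod("show", "SectorProfile", function(object) {
  seg <- object@segments
  tcn <- S4Vectors::mcols(seg)$nMajor + S4Vectors::mcols(seg)$nMinor
  cat("SectorProfile", object@sectorId, "\n")
  cat("  purity:", format(object@purity, digits = 3),
      " ploidy:", object@ploidy, "\n")
  cat("  segments:", length(seg), "on",
      length(unique(as.character(GenomicRanges::seqnames(seg)))),
      "chromosome(s); total CN range",
      if (length(seg)) paste(range(tcn), collapse = "-") else "NA", "\n")
  invisible(object)
})

setMethod("show", "PresenceMatrix", function(object) {
  m <- object@mat
  cat("PresenceMatrix for patient", object@patientId, "\n")
  cat("  ", nrow(m), "mutations x", ncol(m), "sectors\n")
  if (nrow(m)) {
    ns <- rowSums(m)
    cat("  trunk:", sum(ns == ncol(m)),
        " private:", sum(ns == 1L),
        " branch:", sum(ns > 1L & ns < ncol(m)), "\n")
  }
  invisible(object)
})

#' @rdname PresenceMatrix-class
#' @export
setMethod("dim", "PresenceMatrix", function(x) dim(x@mat))
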