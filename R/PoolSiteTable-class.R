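#' @import methods
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps reduce setdiff intersect sort
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' Container for biallelic pooled SNP sites
#'
#' A \code{PoolSiteTable} holds the biallelic SNP sites of a pooled-sequencing
#' cohort: one row per site (a width-1 \code{GRanges} with \code{ref}/\code{alt}
#' alleles) and one column per pooled isofemale line, with assays \code{refDepth}
#' and \code{altDepth} carrying per-line read counts supporting each allele and
#' \code{qual} carrying per-line genotyping quality. Column data must contain a
#' \code{slope} factor with levels \code{NFS}/\code{SFS}.
#'
#' @seealso [PoolSiteTable()] for construction, [siteFrequency()],
#'   [windowStats()], [decodeSweepHmm()].
#' @export
setClass("PoolSiteTable", contains = "RangedSummarizedExperiment")

setValidity("PoolSiteTable", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("refDepth", "altDepth") %in% an))
    msg <- c(msg, "assays 'refDepth' and 'altDepth' are required")
  rr <- rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  if (!all(c("ref", "alt") %in% colnames(mc))) {
    msg <- c(msg, "rowRanges need 'ref' and 'alt' allele columns")
  } else {
    ok <- mc$ref %in% c("A", "C", "G", "T") & mc$alt %in% c("A", "C", "G", "T") &
      mc$ref != mc$alt
    if (!all(ok)) msg <- c(msg, "alleles must be single distinct nucleotides (biallelic SNPs)")
  }
  if (any(width(rr) != 1L)) msg <- c(msg, "sites must have width 1")
  if (!"slope" %in% colnames(colData(object))) {
    msg <- c(msg, "colData must contain a 'slope' column")
  } else if (!all(colData(object)$slope %in% c("NFS", "SFS"))) {
    msg <- c(msg, "slope labels must be 'NFS' or 'SFS'")
  }
  if (length(an) && nrow(object)) {
    if (any(assay(object, "refDepth") < 0, na.rm = TRUE) ||
        any(assay(object, "altDepth") < 0, na.rm = TRUE))
      msg <- c(msg, "read counts must be non-negative")
  }
  # strictly increasing positions within chromosome
  sp <- split(start(rr), as.character(seqnames(rr)))
  if (any(vapply(sp, function(p) is.unsorted(p, strictly = TRUE), logical(1))))
    msg <- c(msg, "positions must be strictly increasing within each chromosome")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PoolSiteTable
#'
#' @param chrom Character vector of chromosome names, one per site.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Single-nucleotide reference and alternate alleles.
#' @param refDepth,altDepth Integer matrices (sites x lines) of read counts
#'   supporting the reference / alternate allele.
#' @param qual Numeric matrix of per-line phred-scaled genotyping qualities;
#'   defaults to a constant 99 (synthetic data carry no meaningful quality).
#' @param lineId Character vector of line identifiers (one per column).
#' @param slope Character vector of slope labels, \code{"NFS"} or \code{"SFS"}.
#' @return A [PoolSiteTable-class] object, sites sorted by position.
#' @examples
#' st <- PoolSiteTable(chrom = "2R", pos = c(100L, 200L), ref = c("A", "T"),
#'   alt = c("G", "C"), refDepth = matrix(30L, 2, 2),
#'   altDepth = matrix(10L, 2, 2), lineId = c("n1", "s1"),
#'   slope = c("NFS", "SFS"))
#' siteFrequency(st)
#' @export
PoolSiteTable <- function(chrom, pos, ref, alt, refDepth, altDepth,
                          qual = NULL, lineId, slope) {
  refDepth <- as.matrix(refDepth)
  altDepth <- as.matrix(altDepth)
  slope <- .checkSlopes(slope)
  if (is.null(qual)) qual <- matrix(99, nrow(refDepth), ncol(refDepth))
  qual <- as.matrix(qual)
  # line identity comes from lineId; incidental matrix dimnames are dropped
  dimnames(refDepth) <- dimnames(altDepth) <- dimnames(qual) <- NULL
  chrom <- rep(as.character(chrom), length.out = length(pos))
  ord <- order(chrom, pos)
  rr <- GRanges(as.character(chrom)[ord], IRanges(pos[ord], width = 1L),
                ref = as.character(ref)[ord], alt = as.character(alt)[ord])
  se <- SummarizedExperiment(
    assays = list(refDepth = refDepth[ord, , drop = FALSE],
                  altDepth = altDepth[ord, , drop = FALSE],
                  qual = as.matrix(qual)[ord, , drop = FALSE]),
    rowRanges = rr,
    colData = DataFrame(lineId = lineId, slope = slope, row.names = lineId))
  new("PoolSiteTable", se)
}

#' @describeIn PoolSiteTable Reference-allele read depth matrix.
#' @param x A \code{PoolSiteTable}.
#' @export
refDepth <- function(x) assay(x, "refDepth")

#' @describeIn PoolSiteTable Alternate-allele read depth matrix.
#' @export
altDepth <- function(x) assay(x, "altDepth")

#' @describeIn PoolSiteTable Total read depth matrix (ref + alt).
#' @export
totalDepth <- function(x) assay(x, "refDepth") + assay(x, "altDepth")

#' @describeIn PoolSiteTable Slope label of each pooled line.
#' @export
slopes <- function(x) as.character(colData(x)$slope)

#' @describeIn PoolSiteTable Line identifiers.
#' @export
lineIds <- function(x) as.character(colData(x)$lineId)

setMethod("show", "PoolSiteTable", function(object) {
  sl <- table(slopes(object))
  cat("PoolSiteTable with", nrow(object), "biallelic sites x",
      ncol(object), "pooled lines\n")
  cat("  slopes:", paste(names(sl), sl, sep = "=", collapse = ", "), "\n")
  cat("  chromosomes:",
      paste(unique(as.character(seqnames(rowRanges(object)))), collapse = ", "),
      "\n")
})
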