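#' Does a gene fall within a line's sweep regions?
#'
#' A gene counts as "within" a sweep region when its span overlaps any region
#' by at least 1 bp (permissive overlap semantics; set
#' \code{containment = TRUE} to require the whole gene inside one region).
#'
#' @param genes \code{GRanges} of gene spans.
#' @param regions \code{GRanges} of one line's sweep regions.
#' @param containment Require full containment instead of >= 1 bp overlap.
#' @return Logical vector, one per gene.
#' @export
geneInRegion <- function(genes, regions, containment = FALSE) {
  type <- if (containment) "within" else "any"
  IRanges::overlapsAny(genes, regions, type = type, ignore.strand = TRUE)
}

#' Differential sweep scores per gene
#'
#' For each gene, \code{N} is the number of NFS lines whose sweep regions
#' contain the gene and \code{S} the analogous SFS count; the differential
#' sweep score is \code{N - S}. With 9 lines per slope the attainable range is
#' -9..9; positive scores mark NFS-prevalent sweeps.
#'
#' @param genes \code{GRanges} of gene spans with a \code{gene_id} column.
#' @param regionsByLine Named list of per-line sweep \code{GRanges}.
#' @param slope Named character vector mapping line ids to \code{NFS}/\code{SFS}.
#' @param geneStats Optional output of [geneStats()]; when given, its
#'   \code{deltaTajimaD} and \code{meanHet} columns are joined by gene id.
#' @param containment Passed to [geneInRegion()].
#' @return data.frame with columns \code{gene_id}, \code{N}, \code{S},
#'   \code{score} (and the joined statistics when available).
#' @export
differentialScore <- function(genes, regionsByLine, slope, geneStats = NULL,
                              containment = FALSE) {
  if (is.null(names(regionsByLine)) ||
      !all(names(regionsByLine) %in% names(slope)))
    stop("every line in regionsByLine needs a slope label")
  slope <- .checkSlopes(slope[names(regionsByLine)])
  names(slope) <- names(regionsByLine)
  hits <- vapply(regionsByLine, function(rg)
    geneInRegion(genes, rg, containment = containment),
    logical(length(genes)))
  hits <- matrix(hits, nrow = length(genes))
  N <- rowSums(hits[, slope == "NFS", drop = FALSE])
  S <- rowSums(hits[, slope == "SFS", drop = FALSE])
  out <- data.frame(gene_id = genes$gene_id, N = as.integer(N),
                    S = as.integer(S), score = as.integer(N - S))
  if (!is.null(geneStats)) {
    m <- match(out$gene_id, geneStats$gene_id)
    out$deltaTajimaD <- geneStats$deltaTajimaD[m]
    out$meanHet <- geneStats$meanHet[m]
  }
  out
}

#' Slope-prevalent gene lists at a score threshold
#'
#' @param scores Output of [differentialScore()].
#' @param threshold Minimum absolute score (default 6, the conventional
#'   cutoff for a 9+9-line design).
#' @return List with character vectors \code{NFS} (score >= threshold) and
#'   \code{SFS} (score <= -threshold).
#' @export
prevalentGenes <- function(scores, threshold = 6L) {
  list(NFS = as.character(scores$gene_id[scores$score >= threshold]),
       SFS = as.character(scores$gene_id[scores$score <= -threshold]))
}

#' Spearman correlations of the sweep score with gene statistics
#'
#' Rank correlation (ties mid-ranked) of the differential sweep score against
#' the per-gene interslope difference in Tajima's D and against mean
#' heterozygosity, with two-sided p-values. Sweeps depress Tajima's D on the
#' slope where they are prevalent, so a genuine slope contrast shows up as a
#' negative correlation with \code{deltaTajimaD = D_NFS - D_SFS}.
#'
#' @param scores Output of [differentialScore()] including \code{deltaTajimaD}
#'   and \code{meanHet}.
#' @return data.frame with rows \code{deltaTajimaD} and \code{meanHet} and
#'   columns \code{rho}, \code{p}, \code{n}.
#' @export
scoreCorrelations <- function(scores) {
  one <- function(y, label) {
    ok <- !is.na(scores$score) & !is.na(y)
    if (sum(ok) < 10L)
      stop("need >= 10 genes with defined statistics (got ", sum(ok), ")")
    if (stats::sd(scores$score[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(stat = label, rho = NA_real_, p = NA_real_,
                        n = sum(ok), note = "constant vector"))
    ct <- suppressWarnings(
      stats::cor.test(scores$score[ok], y[ok], method = "spearman",
                      exact = FALSE))
    data.frame(stat = label, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), note = "")
  }
  rbind(one(scores$deltaTajimaD, "deltaTajimaD"),
        one(scores$meanHet, "meanHet"))
}
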