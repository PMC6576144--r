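#' Pooled allele frequencies per line or per slope
#'
#' Allele frequencies are estimated from read counts: per line
#' \eqn{\hat p = alt/(ref+alt)}; the slope-level frequency is the depth-weighted
#' mean over that slope's lines (equivalently, pooled alt reads over pooled
#' depth), or the unweighted mean of line frequencies when
#' \code{weighted = FALSE}.
#'
#' @param x A [PoolSiteTable-class].
#' @param by \code{"line"} for a sites x lines matrix, \code{"slope"} for a
#'   sites x 2 matrix with columns \code{NFS}, \code{SFS}.
#' @param weighted Depth-weight line frequencies when aggregating by slope.
#' @return Numeric matrix of alternate-allele frequencies; \code{NA} where the
#'   relevant depth is zero.
#' @export
siteFrequency <- function(x, by = c("line", "slope"), weighted = TRUE) {
  by <- match.arg(by)
  rd <- refDepth(x); ad <- altDepth(x)
  if (by == "line") {
    d <- rd + ad
    f <- ad / d
    f[d == 0] <- NA_real_
    dimnames(f) <- list(NULL, lineIds(x))
    return(f)
  }
  sl <- slopes(x)
  out <- matrix(NA_real_, nrow(x), 2L, dimnames = list(NULL, c("NFS", "SFS")))
  for (s in c("NFS", "SFS")) {
    idx <- sl == s
    if (!any(idx)) next
    if (weighted) {
      num <- rowSums(ad[, idx, drop = FALSE])
      den <- rowSums(rd[, idx, drop = FALSE] + ad[, idx, drop = FALSE])
      f <- num / den
      f[den == 0] <- NA_real_
    } else {
      d <- rd[, idx, drop = FALSE] + ad[, idx, drop = FALSE]
      fl <- ad[, idx, drop = FALSE] / d
      fl[d == 0] <- NA
      f <- rowMeans(fl, na.rm = TRUE)
      f[!is.finite(f)] <- NA_real_
    }
    out[, s] <- f
  }
  out
}

#' Expected heterozygosity of pooled frequencies
#'
#' Per-SNP expected heterozygosity \eqn{2\hat p(1-\hat p)\,n/(n-1)}, with the
#' small-sample factor for \code{nHaploids} genomes per pool.
#'
#' @param p Alternate-allele frequencies.
#' @param nHaploids Haploid genomes per pool (default 40).
#' @return Per-site heterozygosity values in \[0, n/(n-1)/2\].
#' @export
expectedHet <- function(p, nHaploids = 40L) {
  2 * p * (1 - p) * nHaploids / (nHaploids - 1)
}

#' Mean heterozygosity of a set of SNPs (e.g. one window)
#'
#' @param p Frequencies of the SNPs falling in the window; fixed sites
#'   (\eqn{p \in \{0,1\}}) contribute zero. Returns \code{NA} when no SNPs.
#' @inheritParams expectedHet
#' @export
windowHeterozygosity <- function(p, nHaploids = 40L) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  mean(expectedHet(p, nHaploids))
}

#' Watterson's theta per site
#'
#' \eqn{\theta_W = S / (a_n L)} with \eqn{a_n = \sum_{i=1}^{n-1} 1/i},
#' \code{S} segregating sites and \code{L} the window length in bp.
#'
#' @param nSnps Segregating sites in the window.
#' @param nHaploids Haploid sample size.
#' @param windowBp Window length in bp.
#' @export
wattersonTheta <- function(nSnps, nHaploids = 40L, windowBp) {
  nSnps / (harmonicNumber(nHaploids) * windowBp)
}

#' Tajima's D from pooled frequencies
#'
#' Classical Tajima's D contrasting pairwise diversity with Watterson's
#' estimator: \eqn{D = (\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} where
#' \eqn{\pi = \sum 2\hat p(1-\hat p)\,n/(n-1)} over the window's SNPs and the
#' constants \eqn{a_1,a_2,b_1,b_2,c_1,c_2,e_1,e_2} follow the standard
#' derivation for \code{n} haploid genomes. Negative values indicate an excess
#' of rare variants, the footprint of a selective sweep.
#'
#' @param p Frequencies of the SNPs in the window (fixed sites contribute
#'   nothing and are not counted as segregating).
#' @param nHaploids Haploid sample size.
#' @return D, or \code{NA} when fewer than 3 segregating sites.
#' @export
tajimaD <- function(p, nHaploids = 40L) {
  p <- p[!is.na(p)]
  seg <- p > 0 & p < 1
  S <- sum(seg)
  if (S < 3L) return(NA_real_)
  n <- nHaploids
  piSum <- sum(expectedHet(p[seg], n))
  a1 <- harmonicNumber(n)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piSum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Per-SNP fixation index between the two slopes
#'
#' \eqn{F_{ST} = (H_T - \bar H_S)/H_T} with \eqn{H_T = 2\bar p(1-\bar p)},
#' \eqn{\bar p = (p_1+p_2)/2} and \eqn{\bar H_S} the mean within-slope
#' expected heterozygosity. Sites monomorphic in both slopes return \code{NA}.
#' Values are reported as computed (they can be negative); no clipping.
#'
#' @param p1,p2 Slope-level allele frequencies (vectors).
#' @return Per-SNP FST values.
#' @export
fstPerSnp <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  out <- (ht - hs) / ht
  out[ht == 0] <- NA_real_
  out
}

#' Windowed diversity and differentiation statistics
#'
#' Tiles each chromosome into non-overlapping windows (default 5 kb) and
#' reports, per slope, the number of segregating SNPs, mean per-SNP expected
#' heterozygosity, Watterson's theta per site and Tajima's D, plus the mean
#' per-SNP interslope FST.
#'
#' @param x A [PoolSiteTable-class].
#' @param windowSize Window width in bp (default 5000; 100 for fine-scale
#'   reanalysis).
#' @param nHaploids Haploid genomes per pool.
#' @param weighted Depth-weight slope frequencies (see [siteFrequency()]).
#' @param chromLengths Optional named vector of chromosome lengths; defaults to
#'   the seqlengths of \code{x} or, failing that, the last site per chromosome.
#' @return A data.frame with one row per window: \code{chrom,start,end},
#'   \code{nSnps_NFS,het_NFS,thetaW_NFS,tajimaD_NFS}, the same for SFS, and
#'   \code{fst}.
#' @export
windowStats <- function(x, windowSize = 5000L, nHaploids = 40L,
                        weighted = TRUE, chromLengths = NULL) {
  rr <- rowRanges(x)
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  if (is.null(chromLengths)) {
    sl <- GenomeInfoDb::seqlengths(rr)
    if (all(!is.na(sl))) chromLengths <- sl
    else chromLengths <- tapply(pos, chrom, max)
  }
  fr <- siteFrequency(x, by = "slope", weighted = weighted)
  fst <- fstPerSnp(fr[, "NFS"], fr[, "SFS"])
  res <- list()
  for (ch in names(chromLengths)) {
    L <- as.integer(chromLengths[[ch]])
    starts <- seq.int(1L, L, by = windowSize)
    ends <- pmin(starts + windowSize - 1L, L)
    idx <- which(chrom == ch)
    bin <- findInterval(pos[idx], starts)
    perSlope <- lapply(c(NFS = "NFS", SFS = "SFS"), function(s) {
      f <- fr[idx, s]
      nS <- het <- thw <- td <- rep(NA_real_, length(starts))
      for (b in unique(bin)) {
        pb <- f[bin == b]
        pb <- pb[!is.na(pb)]
        nS[b] <- sum(pb > 0 & pb < 1)
        het[b] <- windowHeterozygosity(pb, nHaploids)
        thw[b] <- wattersonTheta(nS[b], nHaploids, ends[b] - starts[b] + 1L)
        td[b] <- tajimaD(pb, nHaploids)
      }
      nS[is.na(nS)] <- 0
      data.frame(nSnps = nS, het = het, thetaW = thw, tajimaD = td)
    })
    mfst <- rep(NA_real_, length(starts))
    agg <- tapply(fst[idx], bin, mean, na.rm = TRUE)
    mfst[as.integer(names(agg))] <- as.numeric(agg)
    mfst[is.nan(mfst)] <- NA_real_
    res[[ch]] <- data.frame(
      chrom = ch, start = starts, end = ends,
      nSnps_NFS = perSlope$NFS$nSnps, het_NFS = perSlope$NFS$het,
      thetaW_NFS = perSlope$NFS$thetaW, tajimaD_NFS = perSlope$NFS$tajimaD,
      nSnps_SFS = perSlope$SFS$nSnps, het_SFS = perSlope$SFS$het,
      thetaW_SFS = perSlope$SFS$thetaW, tajimaD_SFS = perSlope$SFS$tajimaD,
      fst = mfst)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-gene diversity and differentiation statistics
#'
#' A gene's statistics are computed from its own sites (those whose position
#' falls within the gene span), not from window means.
#'
#' @param x A [PoolSiteTable-class].
#' @param genes \code{GRanges} of gene spans with a \code{gene_id} column.
#' @inheritParams windowStats
#' @return data.frame with one row per gene: per-slope het / Tajima's D,
#'   interslope differences \code{deltaTajimaD} (NFS - SFS), \code{meanHet}
#'   (average of the two slopes), and mean per-SNP \code{fst}.
#' @export
geneStats <- function(x, genes, nHaploids = 40L, weighted = TRUE) {
  fr <- siteFrequency(x, by = "slope", weighted = weighted)
  fst <- fstPerSnp(fr[, "NFS"], fr[, "SFS"])
  ov <- findOverlaps(rowRanges(x), genes, ignore.strand = TRUE)
  bySite <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  n <- length(genes)
  out <- data.frame(
    gene_id = genes$gene_id,
    het_NFS = NA_real_, het_SFS = NA_real_,
    tajimaD_NFS = NA_real_, tajimaD_SFS = NA_real_,
    fst = NA_real_)
  for (j in names(bySite)) {
    i <- as.integer(j)
    idx <- bySite[[j]]
    out$het_NFS[i] <- windowHeterozygosity(fr[idx, "NFS"], nHaploids)
    out$het_SFS[i] <- windowHeterozygosity(fr[idx, "SFS"], nHaploids)
    out$tajimaD_NFS[i] <- tajimaD(fr[idx, "NFS"], nHaploids)
    out$tajimaD_SFS[i] <- tajimaD(fr[idx, "SFS"], nHaploids)
    fv <- fst[idx]
    out$fst[i] <- if (all(is.na(fv))) NA_real_ else mean(fv, na.rm = TRUE)
  }
  out$deltaTajimaD <- out$tajimaD_NFS - out$tajimaD_SFS
  out$meanHet <- (out$het_NFS + out$het_SFS) / 2
  out
}

#' Per-chromosome summary in the layout of a diversity table
#'
#' Means of windowed Tajima's D, heterozygosity (per slope) and FST per
#' chromosome arm.
#'
#' @param ws Output of [windowStats()].
#' @export
chromSummary <- function(ws) {
  agg <- function(col) tapply(ws[[col]], ws$chrom, mean, na.rm = TRUE)
  data.frame(
    chrom = sort(unique(ws$chrom)),
    tajimaD_NFS = as.numeric(agg("tajimaD_NFS")),
    tajimaD_SFS = as.numeric(agg("tajimaD_SFS")),
    het_NFS = as.numeric(agg("het_NFS")),
    het_SFS = as.numeric(agg("het_SFS")),
    fst = as.numeric(agg("fst")))
}
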