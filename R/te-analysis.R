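#' Collapse TE insertion records to insertion sites
#'
#' Insertions of the same family on the same chromosome within
#' \code{mergeWindow} bp of each other (across lines) are treated as one
#' insertion site; the default \code{mergeWindow = 0} requires exact position
#' matches, appropriate for synthetic calls (real callers have positional
#' jitter; widen the window for those).
#'
#' @param records data.frame with columns \code{family}, \code{chrom},
#'   \code{pos}, \code{line}, \code{slope}.
#' @param mergeWindow Merge radius in bp.
#' @return data.frame with one row per (site, line): \code{family},
#'   \code{chrom}, \code{pos} (site anchor = smallest member position),
#'   \code{line}, \code{slope}, \code{siteId}.
#' @export
collapseTeSites <- function(records, mergeWindow = 0L) {
  stopifnot(all(c("family", "chrom", "pos", "line", "slope") %in%
                  colnames(records)))
  records$slope <- .checkSlopes(records$slope)
  records <- records[!duplicated(records[c("family", "chrom", "pos", "line")]), ]
  out <- lapply(split(records, list(records$family, records$chrom),
                      drop = TRUE), function(d) {
    d <- d[order(d$pos), ]
    upos <- sort(unique(d$pos))
    grp <- cumsum(c(1L, as.integer(diff(upos) > mergeWindow)))
    anchor <- tapply(upos, grp, min)
    d$pos <- as.integer(anchor[as.character(grp[match(d$pos, upos)])])
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$siteId <- paste(out$family, out$chrom, out$pos, sep = ":")
  out[order(out$family, out$chrom, out$pos, out$line), ]
}

#' Per-family sharing statistics
#'
#' A site is shared when it has at least one carrier line on each slope.
#'
#' @param sites Output of [collapseTeSites()].
#' @param family Family name (must be present).
#' @return List: \code{family}, \code{nSitesTotal}, \code{nSitesShared},
#'   \code{pctShared} (percentage, rounded to integer for display parity with
#'   published tables), \code{abundanceNFS}, \code{abundanceSFS} (insertion
#'   records per slope).
#' @export
familySharing <- function(sites, family) {
  d <- sites[sites$family == family, ]
  if (!nrow(d)) stop("unknown family: ", family)
  bySite <- split(d$slope, d$siteId)
  shared <- vapply(bySite, function(s) all(c("NFS", "SFS") %in% s), logical(1))
  list(family = family,
       nSitesTotal = length(bySite),
       nSitesShared = sum(shared),
       pctShared = round(100 * sum(shared) / length(bySite)),
       abundanceNFS = sum(d$slope == "NFS"),
       abundanceSFS = sum(d$slope == "SFS"))
}

#' Fisher test for interslope TE abundance of one family
#'
#' Two-sided Fisher's exact test on
#' \code{[[c1, T1-c1], [c2, T2-c2]]}: the family's insertion count on each
#' slope against the slope's total insertion count. Two-sidedness follows the
#' usual convention of summing the probabilities of all tables no more likely
#' than the observed one.
#'
#' @param c1,c2 Family insertion counts (NFS, SFS).
#' @param t1,t2 Slope total insertion counts.
#' @return Two-sided p-value.
#' @export
teAbundanceTest <- function(c1, c2, t1, t2) {
  stopifnot(c1 <= t1, c2 <= t2)
  tab <- matrix(c(c1, t1 - c1, c2, t2 - c2), 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Fisher test for a family's sharing rate against the background
#'
#' Compares a family's shared/total site counts with the sharing of all other
#' families pooled: table \code{[[s, t-s], [S-s, (T-t)-(S-s)]]}.
#'
#' @param s,t Family shared and total site counts.
#' @param S,T Background (all families) shared and total site counts,
#'   including this family.
#' @return Two-sided p-value.
#' @export
teSharingTest <- function(s, t, S, T) {
  stopifnot(s <= t, S <= T, s <= S, t <= T)
  tab <- matrix(c(s, t - s, S - s, (T - t) - (S - s)), 2L, byrow = TRUE)
  if (any(tab < 0)) stop("inconsistent counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Full per-family TE sharing/abundance table
#'
#' @param sites Output of [collapseTeSites()].
#' @return data.frame, one row per family: sharing counts and percentages,
#'   per-slope abundance, \code{fisherPAbundance} and \code{fisherPSharing}.
#' @export
teFamilyTable <- function(sites) {
  fams <- sort(unique(sites$family))
  rows <- lapply(fams, function(f) as.data.frame(familySharing(sites, f)))
  out <- do.call(rbind, rows)
  T1 <- sum(out$abundanceNFS); T2 <- sum(out$abundanceSFS)
  Sh <- sum(out$nSitesShared); To <- sum(out$nSitesTotal)
  out$fisherPAbundance <- mapply(teAbundanceTest, out$abundanceNFS,
                                 out$abundanceSFS, T1, T2)
  out$fisherPSharing <- mapply(teSharingTest, out$nSitesShared,
                               out$nSitesTotal, Sh, To)
  out
}

#' TE insertion-site density per window and slope
#'
#' Counts distinct insertion sites per non-overlapping window (default
#' 100 kb), per slope; a site counts for a slope when it has at least one
#' carrier there.
#'
#' @param sites Output of [collapseTeSites()].
#' @param chromLengths Named vector of chromosome lengths.
#' @param windowSize Window width in bp.
#' @return data.frame \code{chrom,start,end,nNFS,nSFS}.
#' @export
teDensity <- function(sites, chromLengths, windowSize = 100000L) {
  res <- list()
  u <- unique(sites[c("siteId", "chrom", "pos")])
  slopeOf <- split(sites$slope, sites$siteId)
  u$hasNFS <- vapply(slopeOf[u$siteId], function(s) "NFS" %in% s, logical(1))
  u$hasSFS <- vapply(slopeOf[u$siteId], function(s) "SFS" %in% s, logical(1))
  for (ch in names(chromLengths)) {
    L <- as.integer(chromLengths[[ch]])
    starts <- seq.int(1L, L, by = windowSize)
    ends <- pmin(starts + windowSize - 1L, L)
    d <- u[u$chrom == ch, ]
    bin <- findInterval(d$pos, starts)
    nN <- nS <- integer(length(starts))
    tn <- tapply(d$hasNFS, bin, sum); ts <- tapply(d$hasSFS, bin, sum)
    nN[as.integer(names(tn))] <- as.integer(tn)
    nS[as.integer(names(ts))] <- as.integer(ts)
    res[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            nNFS = nN, nSFS = nS)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' TE insertions disrupting coding sequence
#'
#' An insertion disrupts a CDS when its position falls within a CDS interval
#' (1-based inclusive at both ends).
#'
#' @param sites Output of [collapseTeSites()].
#' @param cds \code{GRanges} of CDS intervals with a \code{gene_id} column.
#' @return data.frame \code{family, chrom, pos, line, slope, gene_id}.
#' @export
teCdsDisruption <- function(sites, cds) {
  gr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  ov <- findOverlaps(gr, cds, ignore.strand = TRUE)
  out <- sites[S4Vectors::queryHits(ov),
               c("family", "chrom", "pos", "line", "slope")]
  out$gene_id <- cds$gene_id[S4Vectors::subjectHits(ov)]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Interslope divergence score per TE site
#'
#' Same construction as the gene sweep score: NFS carrier lines minus SFS
#' carrier lines per insertion site.
#'
#' @param sites Output of [collapseTeSites()].
#' @return data.frame \code{siteId, family, chrom, pos, nNFS, nSFS, score}.
#' @export
teDivergenceScore <- function(sites) {
  sp <- split(sites, sites$siteId)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(siteId = d$siteId[1L], family = d$family[1L],
               chrom = d$chrom[1L], pos = d$pos[1L],
               nNFS = sum(d$slope == "NFS"), nSFS = sum(d$slope == "SFS"))
  }))
  out$score <- out$nNFS - out$nSFS
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), ]
}
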