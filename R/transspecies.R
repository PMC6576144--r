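#' Map polymorphic sites shared between two species
#'
#' A site is transspecies when both species are polymorphic at corresponding
#' coordinates with the same two alleles (ref/alt labels may be swapped;
#' species-B frequencies are re-expressed on species A's alt allele). The
#' coordinate map is one-to-one; the identity map (same chrom/pos) is the
#' default, appropriate for synthetic cohorts.
#'
#' @param sitesA,sitesB [PoolSiteTable-class] objects for the two species.
#' @param coordMap Optional data.frame \code{chromA,posA,chromB,posB}; default
#'   identity. Many-to-one maps are rejected.
#' @param weighted Depth-weighting for slope frequencies.
#' @return data.frame of shared sites: coordinates in both species, alleles
#'   (A's labels), overall and per-slope alt-allele frequencies in both
#'   species (\code{fA,fB,fA_NFS,fA_SFS,fB_NFS,fB_SFS}), major-allele bases
#'   \code{majorA,majorB}, and row indices \code{idxA,idxB}.
#' @export
mapSharedSites <- function(sitesA, sitesB, coordMap = NULL, weighted = TRUE) {
  rrA <- rowRanges(sitesA); rrB <- rowRanges(sitesB)
  keyA <- paste(as.character(seqnames(rrA)), start(rrA))
  if (is.null(coordMap)) {
    keyAmapped <- keyA
  } else {
    mk <- paste(coordMap$chromA, coordMap$posA)
    if (anyDuplicated(mk) || anyDuplicated(paste(coordMap$chromB, coordMap$posB)))
      stop("coordMap must be one-to-one")
    m <- match(keyA, mk)
    keyAmapped <- ifelse(is.na(m), NA_character_,
                         paste(coordMap$chromB, coordMap$posB)[m])
  }
  keyB <- paste(as.character(seqnames(rrB)), start(rrB))
  idxB <- match(keyAmapped, keyB)
  idxA <- which(!is.na(idxB))
  idxB <- idxB[idxA]
  # same allele pair (order-free)
  sameDir <- rrA$ref[idxA] == rrB$ref[idxB] & rrA$alt[idxA] == rrB$alt[idxB]
  swapped <- rrA$ref[idxA] == rrB$alt[idxB] & rrA$alt[idxA] == rrB$ref[idxB]
  keep <- sameDir | swapped
  idxA <- idxA[keep]; idxB <- idxB[keep]; swapped <- swapped[keep]
  fA <- siteFrequency(sitesA, by = "slope", weighted = weighted)[idxA, , drop = FALSE]
  fB <- siteFrequency(sitesB, by = "slope", weighted = weighted)[idxB, , drop = FALSE]
  # express B on A's alt allele
  if (any(swapped)) fB[swapped, ] <- 1 - fB[swapped, ]
  qA <- rowMeans(fA); qB <- rowMeans(fB)
  out <- data.frame(
    chromA = as.character(seqnames(rrA))[idxA], posA = start(rrA)[idxA],
    chromB = as.character(seqnames(rrB))[idxB], posB = start(rrB)[idxB],
    ref = rrA$ref[idxA], alt = rrA$alt[idxA],
    fA = qA, fB = qB,
    fA_NFS = fA[, "NFS"], fA_SFS = fA[, "SFS"],
    fB_NFS = fB[, "NFS"], fB_SFS = fB[, "SFS"],
    majorA = ifelse(qA > 0.5, rrA$alt[idxA], rrA$ref[idxA]),
    majorB = ifelse(qB > 0.5, rrA$alt[idxA], rrA$ref[idxA]),
    idxA = idxA, idxB = idxB)
  rownames(out) <- NULL
  out
}

#' Major allele of every site in a species
#' @param x A [PoolSiteTable-class].
#' @param weighted Depth-weighting for the overall frequency.
#' @return Character vector of major-allele bases (ties at 0.5 go to ref).
#' @keywords internal
.majorBase <- function(x, weighted = TRUE) {
  f <- siteFrequency(x, by = "slope", weighted = weighted)
  q <- rowMeans(f, na.rm = TRUE)
  rr <- rowRanges(x)
  ifelse(q > 0.5, rr$alt, rr$ref)
}

#' Major-allele co-occurrence enrichment at transspecies sites
#'
#' Observed: the fraction of shared sites at which the same nucleotide is the
#' major allele in both species. Expected: the chance that two independently
#' drawn non-shared sites (one from each species' private sites) carry the
#' same major nucleotide, \eqn{\sum_b f_A(b) f_B(b)} over bases, computed from
#' the major-base composition of each species' non-shared sites. The fold
#' enrichment is observed / expected; optional strata (e.g. CDS or
#' nonsynonymous subsets) reuse the same background.
#'
#' @param shared Output of [mapSharedSites()].
#' @param sitesA,sitesB The two species' site tables (backgrounds are their
#'   sites not in \code{shared}).
#' @param strata Optional factor over rows of \code{shared}.
#' @return data.frame with rows per stratum (plus \code{all}): \code{observed},
#'   \code{expected}, \code{fold}, \code{n}.
#' @export
majorAlleleCooccurrence <- function(shared, sitesA, sitesB, strata = NULL) {
  if (nrow(shared) < 100L)
    warning("fewer than 100 shared sites; the enrichment ratio is unstable")
  majA <- .majorBase(sitesA); majB <- .majorBase(sitesB)
  bgA <- majA[-shared$idxA]; bgB <- majB[-shared$idxB]
  if (!length(bgA) || !length(bgB)) stop("no non-shared background sites")
  bases <- c("A", "C", "G", "T")
  fa <- tabulate(factor(bgA, bases), 4L) / length(bgA)
  fb <- tabulate(factor(bgB, bases), 4L) / length(bgB)
  expected <- sum(fa * fb)
  co <- shared$majorA == shared$majorB
  one <- function(sel, label) {
    if (!sum(sel)) return(data.frame(stratum = label, observed = NA_real_,
                                     expected = expected, fold = NA_real_,
                                     n = 0L))
    data.frame(stratum = label, observed = mean(co[sel]), expected = expected,
               fold = mean(co[sel]) / expected, n = sum(sel))
  }
  out <- one(rep(TRUE, nrow(shared)), "all")
  if (!is.null(strata)) {
    for (s in levels(factor(strata)))
      out <- rbind(out, one(strata == s, s))
  }
  out
}

#' Interspecies correlation of interslope frequency differences
#'
#' Spearman rank correlation between the interslope difference
#' \eqn{p_{NFS} - p_{SFS}} in species A and the same quantity in species B
#' over transspecies sites. Near-zero values indicate no convergent
#' slope-specific allele-frequency shifts.
#'
#' @param shared Output of [mapSharedSites()].
#' @param strata Optional factor over rows for stratified estimates.
#' @return data.frame \code{stratum, rho, p, n}.
#' @export
interslopeDiffCorrelation <- function(shared, strata = NULL) {
  dA <- shared$fA_NFS - shared$fA_SFS
  dB <- shared$fB_NFS - shared$fB_SFS
  one <- function(sel, label) {
    ok <- sel & !is.na(dA) & !is.na(dB)
    if (sum(ok) < 3L || stats::sd(dA[ok]) == 0 || stats::sd(dB[ok]) == 0)
      return(data.frame(stratum = label, rho = NA_real_, p = NA_real_,
                        n = sum(ok)))
    ct <- suppressWarnings(stats::cor.test(dA[ok], dB[ok], method = "spearman",
                                           exact = FALSE))
    data.frame(stratum = label, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  }
  out <- one(rep(TRUE, nrow(shared)), "all")
  if (!is.null(strata)) {
    for (s in levels(factor(strata)))
      out <- rbind(out, one(strata == s, s))
  }
  out
}

#' Annotate the coding effect of SNPs
#'
#' Substitutes the alt allele into its codon (strand-aware) and compares the
#' translated amino acids under the standard nuclear code. Sites outside all
#' CDS are \code{noncoding}. Assumes each gene's CDS intervals are in frame
#' (total length divisible by 3, phase 0 at the 5' end), as the synthetic
#' gene models guarantee; a mismatch between the stated reference allele and
#' the genome sequence is flagged as an error.
#'
#' @param x A [PoolSiteTable-class] (or GRanges with \code{ref}/\code{alt}).
#' @param cds \code{GRanges} of CDS intervals with \code{gene_id} and strand.
#' @param genome Named \code{DNAStringSet} of reference chromosomes.
#' @return Character vector per site: \code{"synonymous"},
#'   \code{"nonsynonymous"} or \code{"noncoding"}.
#' @export
annotateEffect <- function(x, cds, genome) {
  rr <- if (is(x, "PoolSiteTable")) rowRanges(x) else x
  effect <- rep("noncoding", length(rr))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gc <- Biostrings::GENETIC_CODE
  for (gid in unique(cds$gene_id)) {
    ivs <- cds[cds$gene_id == gid]
    str <- as.character(strand(ivs))[1L]
    ivs <- ivs[order(start(ivs), decreasing = (str == "-"))]
    ch <- as.character(seqnames(ivs))[1L]
    pieces <- vapply(seq_along(ivs), function(k)
      as.character(subseq(genome[[ch]], start(ivs)[k], end(ivs)[k])),
      character(1))
    if (str == "-")
      pieces <- vapply(pieces, function(p)
        as.character(reverseComplement(Biostrings::DNAString(p))),
        character(1), USE.NAMES = FALSE)
    spliced <- paste(pieces, collapse = "")
    if (nchar(spliced) %% 3L != 0L)
      warning("CDS length of ", gid, " not a multiple of 3; trailing bases ignored")
    ov <- findOverlaps(rr, ivs, ignore.strand = TRUE)
    if (!length(ov)) next
    offs <- c(0L, cumsum(nchar(pieces)))[seq_along(ivs)]
    for (h in seq_along(ov)) {
      si <- S4Vectors::queryHits(ov)[h]
      k <- S4Vectors::subjectHits(ov)[h]
      p <- start(rr)[si]
      within <- if (str == "+") p - start(ivs)[k] else end(ivs)[k] - p
      cdsPos <- offs[k] + within          # 0-based position in spliced CDS
      codonIdx <- cdsPos %/% 3L
      inCodon <- cdsPos %% 3L
      codon <- substr(spliced, codonIdx * 3L + 1L, codonIdx * 3L + 3L)
      if (nchar(codon) < 3L) next
      refB <- rr$ref[si]; altB <- rr$alt[si]
      if (str == "-") { refB <- comp[[refB]]; altB <- comp[[altB]] }
      if (substr(codon, inCodon + 1L, inCodon + 1L) != refB)
        stop("reference allele mismatch at ", ch, ":", p, " in ", gid)
      mut <- codon
      substr(mut, inCodon + 1L, inCodon + 1L) <- altB
      effect[si] <- if (gc[[codon]] == gc[[mut]]) "synonymous" else "nonsynonymous"
    }
  }
  effect
}

#' Filter transspecies SNPs that are nonsynonymous and slope-divergent
#'
#' Retains shared sites that are (i) nonsynonymous, (ii) in each species have
#' different major alleles on the two slopes ("alternative alleles predominant
#' on opposing slopes"; frequencies exactly 0.5 are excluded as ties), and
#' (iii) have the same allele major on the same slope in both species. A
#' two-sided Fisher's exact test on the interslope allele-count table is
#' attached per species, with haploid-equivalent counts
#' \code{round(freq * 2 * nLinesPerSlope)} (pooled read counts overstate the
#' effective sample, so counts are scaled to sampled genomes per slope).
#'
#' @param shared Output of [mapSharedSites()].
#' @param effect Effect annotation per row of \code{shared} (from
#'   [annotateEffect()] on the species-A sites).
#' @param nLinesPerSlope Lines per slope used for haploid-equivalent counts.
#' @return Subset of \code{shared} with columns \code{effect},
#'   \code{fisherPA}, \code{fisherPB} added.
#' @export
slopeDivergentFilter <- function(shared, effect, nLinesPerSlope = 9L) {
  stopifnot(length(effect) == nrow(shared))
  divergent <- function(fN, fS) (fN - 0.5) * (fS - 0.5) < 0
  condNs <- effect == "nonsynonymous"
  condDivA <- divergent(shared$fA_NFS, shared$fA_SFS)
  condDivB <- divergent(shared$fB_NFS, shared$fB_SFS)
  condSame <- (shared$fA_NFS > 0.5) == (shared$fB_NFS > 0.5)
  keep <- which(condNs & condDivA & condDivB & condSame)
  out <- shared[keep, , drop = FALSE]
  out$effect <- effect[keep]
  nHap <- 2L * nLinesPerSlope
  fp <- function(fN, fS) {
    cN <- round(fN * nHap); cS <- round(fS * nHap)
    stats::fisher.test(matrix(c(cN, nHap - cN, cS, nHap - cS), 2L,
                              byrow = TRUE))$p.value
  }
  out$fisherPA <- mapply(fp, out$fA_NFS, out$fA_SFS)
  out$fisherPB <- mapply(fp, out$fB_NFS, out$fB_SFS)
  rownames(out) <- NULL
  out
}
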