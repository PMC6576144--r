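#' Configuration of the two-slope synthetic cohort
#'
#' Defines the study design the generator emulates: two slopes (NFS/SFS) of
#' pooled isofemale lines, a neutral site-frequency-spectrum background with
#' partially shared ancestry between slopes, planted selective sweep
#' intervals, family-structured TE insertions, and a companion species sharing
#' a small fraction of polymorphic sites.
#'
#' @slot nLinesPerSlope Pooled lines per slope (default 9).
#' @slot haploidsPerPool Haploid genomes per pool (default 40).
#' @slot meanDepth Mean read depth per line (default 73).
#' @slot genomeLength Named numeric vector of chromosome lengths in bp.
#' @slot thetaPerSite Population-scaled mutation rate per bp (default 0.008,
#'   the SNP-density regime of a dense Drosophila cohort).
#' @slot migrationMix Interslope mixing weight in \[0,1\]. Each slope's
#'   population frequency drifts from the shared ancestral frequency (drawn
#'   from the neutral spectrum) under a Balding-Nichols beta model with drift
#'   strength \eqn{F = 1 - migrationMix}: \code{migrationMix = 1} makes the
#'   slopes identical up to sampling noise (FST near 0), smaller values give
#'   progressively stronger differentiation, up to fixation at 0. The value
#'   matching a desired mean FST is found by [calibrateDivergence()].
#' @slot sweeps data.frame \code{chrom,start,end,reduction,slope}: planted
#'   sweep intervals. \code{reduction} in (0,1\] is the retained-diversity
#'   factor (1 = no effect); inside a sweep a fraction \code{1 - reduction} of
#'   sites is fixed in the affected slope and the rest have frequencies tilted
#'   toward 0 or 1 by \eqn{q \to q^\gamma} or \eqn{1-(1-q)^\gamma} with
#'   \eqn{\gamma = 1/reduction}. \code{slope} is \code{NFS}, \code{SFS} or
#'   \code{both}.
#' @slot teFamilies data.frame \code{name,nSites,sharingProb}.
#' @slot sharedSpeciesFraction Fraction of species-A sites also polymorphic in
#'   the companion species (default 0.01).
#' @slot cooccurProb Probability that a transspecies site's major allele
#'   coincides between species (default 0.85).
#' @slot convergenceProb Fraction of transspecies sites whose interslope
#'   frequency split is copied between species (default 0.3).
#' @slot nGenes Number of genes to place (0 = one per ~15 kb).
#' @slot seed RNG seed; identical config + seed gives identical output.
#' @export
setClass("SimConfig", representation(
  nLinesPerSlope = "integer", haploidsPerPool = "integer",
  meanDepth = "numeric", genomeLength = "numeric", thetaPerSite = "numeric",
  migrationMix = "numeric", sweeps = "data.frame", teFamilies = "data.frame",
  sharedSpeciesFraction = "numeric", cooccurProb = "numeric",
  convergenceProb = "numeric", nGenes = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- NULL
  frac <- c(migrationMix = object@migrationMix,
            sharedSpeciesFraction = object@sharedSpeciesFraction,
            cooccurProb = object@cooccurProb,
            convergenceProb = object@convergenceProb)
  bad <- frac < 0 | frac > 1
  if (any(bad)) msg <- c(msg, paste("fractions outside [0,1]:",
                                    paste(names(frac)[bad], collapse = ", ")))
  if (object@nLinesPerSlope < 1L || object@haploidsPerPool < 4L)
    msg <- c(msg, "line and pool counts must be positive (pool >= 4)")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
  if (any(object@genomeLength <= 0) || is.null(names(object@genomeLength)))
    msg <- c(msg, "genomeLength must be a named vector of positive lengths")
  if (object@thetaPerSite <= 0) msg <- c(msg, "thetaPerSite must be positive")
  sw <- object@sweeps
  if (nrow(sw)) {
    if (!all(sw$chrom %in% names(object@genomeLength)) ||
        any(sw$start < 1) ||
        any(sw$end > object@genomeLength[sw$chrom]))
      msg <- c(msg, "sweep intervals must lie within the simulated genome")
    if (any(sw$end < sw$start)) msg <- c(msg, "sweep end < start")
    if (any(sw$reduction <= 0 | sw$reduction > 1))
      msg <- c(msg, "sweep reduction must be in (0, 1]")
    if (!all(sw$slope %in% c("NFS", "SFS", "both")))
      msg <- c(msg, "sweep slope must be NFS, SFS or both")
    for (ch in unique(sw$chrom)) {
      s <- sw[sw$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
        msg <- c(msg, "sweep intervals must not overlap")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname SimConfig-class
#' @param nLinesPerSlope,haploidsPerPool,meanDepth,genomeLength,thetaPerSite
#'   See slots.
#' @param migrationMix,sweeps,teFamilies,sharedSpeciesFraction See slots.
#' @param cooccurProb,convergenceProb,nGenes,seed See slots.
#' @return A validated \code{SimConfig}.
#' @examples
#' cfg <- simConfig(genomeLength = c(`2R` = 2e5), seed = 7)
#' @export
simConfig <- function(nLinesPerSlope = 9L, haploidsPerPool = 40L,
                      meanDepth = 73, genomeLength = c(`2R` = 1e6),
                      thetaPerSite = 0.008, migrationMix = 0.56,
                      sweeps = data.frame(chrom = character(),
                                          start = integer(), end = integer(),
                                          reduction = numeric(),
                                          slope = character()),
                      teFamilies = defaultTeFamilies(),
                      sharedSpeciesFraction = 0.01, cooccurProb = 0.85,
                      convergenceProb = 0.3, nGenes = 0L, seed = 1L) {
  new("SimConfig", nLinesPerSlope = as.integer(nLinesPerSlope),
      haploidsPerPool = as.integer(haploidsPerPool),
      meanDepth = meanDepth, genomeLength = genomeLength,
      thetaPerSite = thetaPerSite, migrationMix = migrationMix,
      sweeps = sweeps, teFamilies = teFamilies,
      sharedSpeciesFraction = sharedSpeciesFraction,
      cooccurProb = cooccurProb, convergenceProb = convergenceProb,
      nGenes = as.integer(nGenes), seed = as.integer(seed))
}

#' Default TE family design
#'
#' Family sizes and slope-sharing rates spanning the observed range in
#' Drosophila repeatomes: one old, ubiquitous, highly shared family (INE-1
#' like), one abundant intermediate family, and recently mobile families with
#' very low interslope sharing (P-element / 412 like).
#' @return data.frame \code{name,nSites,sharingProb}.
#' @export
defaultTeFamilies <- function() {
  data.frame(name = c("INE1like", "ROOlike", "Plike", "F412like", "MARlike"),
             nSites = c(1030L, 700L, 584L, 309L, 160L),
             sharingProb = c(0.88, 0.50, 0.06, 0.06, 0.07))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nLinesPerSlope, "+", object@nLinesPerSlope,
      "lines,", object@haploidsPerPool, "haploids/pool, depth",
      object@meanDepth, "\n")
  cat("  genome:", paste(names(object@genomeLength),
                         object@genomeLength, sep = "=", collapse = ", "),
      " theta:", object@thetaPerSite,
      " migrationMix:", object@migrationMix, "\n")
  cat("  sweeps:", nrow(object@sweeps), " TE families:",
      nrow(object@teFamilies), " seed:", object@seed, "\n")
})

# Draw derived-allele counts from the neutral spectrum xi_i ~ 1/i, i=1..n-1.
.rNeutralFreq <- function(nSites, nHaploids) {
  i <- seq_len(nHaploids - 1L)
  w <- (1 / i) / sum(1 / i)
  sample(i, nSites, replace = TRUE, prob = w) / nHaploids
}

# Slope frequency: Balding-Nichols drift around the shared ancestral
# frequency with drift strength F = 1 - migrationMix. F = 0 reproduces the
# ancestral frequency exactly (fully mixed slopes); F -> 1 drifts every site
# to fixation on one side.
.driftFreq <- function(pAnc, migrationMix) {
  F <- 1 - migrationMix
  if (F <= 0) return(pAnc)
  if (F >= 1) return(as.numeric(stats::rbinom(length(pAnc), 1L, pAnc)))
  stats::rbeta(length(pAnc), pAnc * (1 - F) / F, (1 - pAnc) * (1 - F) / F)
}

# Sweep distortion of slope frequencies inside one interval.
.distortSweep <- function(p, reduction) {
  nFix <- stats::rbinom(1L, length(p), 1 - reduction)
  fixIdx <- sample(length(p), nFix)
  p[fixIdx] <- ifelse(p[fixIdx] < 0.5, 0, 1)
  rest <- setdiff(seq_along(p), fixIdx)
  if (length(rest)) {
    gam <- 1 / reduction
    # tilt each surviving site toward its nearer boundary: the hitchhiking
    # footprint of excess rare plus near-fixed variants (ties split randomly)
    toZero <- p[rest] < 0.5 |
      (p[rest] == 0.5 & stats::runif(length(rest)) < 0.5)
    p[rest] <- ifelse(toZero, p[rest]^gam, 1 - (1 - p[rest])^gam)
  }
  p
}

# Pool + read sampling for one slope's frequency vector across that slope's
# lines: pool count ~ Binom(nPool, p), depth ~ Poisson(meanDepth),
# alt ~ Binom(depth, pool/nPool).
.sampleReads <- function(p, nLines, nPool, meanDepth) {
  nS <- length(p)
  rd <- ad <- matrix(0L, nS, nLines)
  for (l in seq_len(nLines)) {
    k <- stats::rbinom(nS, nPool, p)
    d <- stats::rpois(nS, meanDepth)
    a <- stats::rbinom(nS, d, k / nPool)
    ad[, l] <- a
    rd[, l] <- d - a
  }
  list(ref = rd, alt = ad)
}

# Random gene models: single-CDS genes, strand random, CDS length a multiple
# of 3, padded by short UTR flanks; placed without overlap.
.simGenes <- function(genomeLength, nGenes) {
  res <- list(genes = GRanges(), cds = GRanges())
  tot <- sum(genomeLength)
  counter <- 0L
  for (ch in names(genomeLength)) {
    L <- genomeLength[[ch]]
    nG <- max(1L, round(nGenes * L / tot))
    slotW <- floor(L / nG)
    gs <- ge <- cs <- ce <- integer(nG)
    str <- character(nG)
    for (g in seq_len(nG)) {
      # Drosophila-like gene sizes: CDS 0.9-2.7 kb plus short UTR flanks
      cdsLen <- 3L * sample(300:900, 1L)
      maxStart <- slotW - cdsLen - 900L
      if (maxStart < 1L) { cdsLen <- 300L; maxStart <- max(1L, slotW - 1200L) }
      off <- (g - 1L) * slotW
      cs[g] <- off + 450L + sample.int(max(1L, maxStart - 450L), 1L)
      ce[g] <- cs[g] + cdsLen - 1L
      gs[g] <- cs[g] - sample(100:400, 1L)
      ge[g] <- ce[g] + sample(100:400, 1L)
      str[g] <- sample(c("+", "-"), 1L)
    }
    ids <- sprintf("gene_%s_%04d", ch, seq_len(nG) + counter)
    counter <- counter + nG
    res$genes <- c(res$genes, GRanges(ch, IRanges(gs, ge), strand = str,
                                      gene_id = ids))
    res$cds <- c(res$cds, GRanges(ch, IRanges(cs, ce), strand = str,
                                  gene_id = ids, phase = 0L))
  }
  res
}

# TE insertion records for one species.
.simTe <- function(cfg, lineId, slope) {
  fam <- cfg@teFamilies
  nfsLines <- lineId[slope == "NFS"]; sfsLines <- lineId[slope == "SFS"]
  chroms <- names(cfg@genomeLength)
  chrProb <- cfg@genomeLength / sum(cfg@genomeLength)
  recs <- list()
  for (f in seq_len(nrow(fam))) {
    nS <- fam$nSites[f]
    ch <- sample(chroms, nS, replace = TRUE, prob = chrProb)
    pos <- vapply(ch, function(cc) sample.int(cfg@genomeLength[[cc]], 1L),
                  integer(1))
    shared <- stats::runif(nS) < fam$sharingProb[f]
    pick <- function(lns) {
      k <- 1L + stats::rbinom(1L, length(lns) - 1L, 0.4)
      sample(lns, k)
    }
    carrierList <- lapply(seq_len(nS), function(s) {
      if (shared[s]) c(pick(nfsLines), pick(sfsLines))
      else if (stats::runif(1) < 0.5) pick(nfsLines) else pick(sfsLines)
    })
    nCar <- lengths(carrierList)
    carriers <- unlist(carrierList, use.names = FALSE)
    recs[[f]] <- data.frame(
      family = fam$name[f],
      chrom = rep(unname(ch), nCar), pos = rep(unname(pos), nCar),
      line = carriers,
      slope = ifelse(carriers %in% nfsLines, "NFS", "SFS"),
      row.names = NULL)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate a two-slope pooled-sequencing cohort with known ground truth
#'
#' Generates, deterministically for a given config (seed included), a random
#' reference genome, gene models, a cohort of pooled SNP site tables for two
#' slopes, TE insertion calls, a companion-species site table sharing a small
#' fraction of polymorphic sites, and the ground truth of everything planted.
#'
#' Site frequencies are drawn by two-stage sampling: a population allele
#' frequency per slope from the neutral spectrum \eqn{\xi_i \propto 1/i}
#' (mixed between slopes with weight \code{migrationMix}), then per line a
#' binomial pool sample of \code{haploidsPerPool} genomes and binomial read
#' sampling at Poisson(\code{meanDepth}) coverage. Inside planted sweep
#' intervals the affected slope's frequencies are fixed or tilted toward the
#' extremes (see [SimConfig-class]). Sites monomorphic across all lines after
#' sweep distortion are dropped, so sweeps reduce apparent site density.
#'
#' @param config A [simConfig()] object.
#' @return List with elements \code{sites} ([PoolSiteTable-class]),
#'   \code{genes} (list of \code{genes}/\code{cds} \code{GRanges}),
#'   \code{te} (insertion records), \code{speciesB} ([PoolSiteTable-class]),
#'   \code{genome} (\code{DNAStringSet}), and \code{truth} (list: per-line
#'   sweep intervals, per-slope site frequencies, TE records, transspecies
#'   site map).
#' @examples
#' cohort <- simulateCohort(simConfig(genomeLength = c(`2R` = 5e4),
#'                                    nLinesPerSlope = 3, seed = 42))
#' cohort$sites
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  set.seed(config@seed)
  nPool <- config@haploidsPerPool
  nL <- config@nLinesPerSlope
  lineId <- c(sprintf("NFS_%02d", seq_len(nL)), sprintf("SFS_%02d", seq_len(nL)))
  slope <- rep(c("NFS", "SFS"), each = nL)

  # reference genome
  genome <- DNAStringSet(vapply(names(config@genomeLength), function(ch)
    paste(sample(c("A", "C", "G", "T"), config@genomeLength[[ch]],
                 replace = TRUE), collapse = ""), character(1)))
  names(genome) <- names(config@genomeLength)

  # genes
  nGenes <- if (config@nGenes > 0L) config@nGenes
            else max(1L, round(sum(config@genomeLength) / 15000))
  genes <- .simGenes(config@genomeLength, nGenes)

  # sites per chromosome
  aN <- harmonicNumber(nPool)
  siteList <- list()
  for (ch in names(config@genomeLength)) {
    L <- config@genomeLength[[ch]]
    nSites <- stats::rpois(1L, config@thetaPerSite * aN * L)
    pos <- sort(sample.int(L, min(nSites, L)))
    nSites <- length(pos)
    pShared <- .rNeutralFreq(nSites, nPool)
    pN <- .driftFreq(pShared, config@migrationMix)
    pS <- .driftFreq(pShared, config@migrationMix)
    sw <- config@sweeps[config@sweeps$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(sw))) {
      inSw <- pos >= sw$start[k] & pos <= sw$end[k]
      if (!any(inSw)) next
      if (sw$slope[k] %in% c("NFS", "both"))
        pN[inSw] <- .distortSweep(pN[inSw], sw$reduction[k])
      if (sw$slope[k] %in% c("SFS", "both"))
        pS[inSw] <- .distortSweep(pS[inSw], sw$reduction[k])
    }
    chStr <- as.character(genome[[ch]])
    ref <- substring(chStr, pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1), USE.NAMES = FALSE)
    siteList[[ch]] <- list(chrom = rep(ch, nSites), pos = pos, ref = ref,
                           alt = alt, pN = pN, pS = pS)
  }
  chrom <- unlist(lapply(siteList, `[[`, "chrom"), use.names = FALSE)
  pos <- unlist(lapply(siteList, `[[`, "pos"), use.names = FALSE)
  ref <- unlist(lapply(siteList, `[[`, "ref"), use.names = FALSE)
  alt <- unlist(lapply(siteList, `[[`, "alt"), use.names = FALSE)
  pN <- unlist(lapply(siteList, `[[`, "pN"), use.names = FALSE)
  pS <- unlist(lapply(siteList, `[[`, "pS"), use.names = FALSE)

  rn <- .sampleReads(pN, nL, nPool, config@meanDepth)
  rs <- .sampleReads(pS, nL, nPool, config@meanDepth)
  rd <- cbind(rn$ref, rs$ref); ad <- cbind(rn$alt, rs$alt)
  poly <- rowSums(ad) > 0L & rowSums(ad) < rowSums(rd + ad)
  sites <- PoolSiteTable(chrom = chrom[poly], pos = pos[poly],
                         ref = ref[poly], alt = alt[poly],
                         refDepth = rd[poly, , drop = FALSE],
                         altDepth = ad[poly, , drop = FALSE],
                         lineId = lineId, slope = slope)
  GenomeInfoDb::seqlengths(SummarizedExperiment::rowRanges(sites)) <-
    config@genomeLength[GenomeInfoDb::seqlevels(SummarizedExperiment::rowRanges(sites))]

  # TE insertions
  te <- .simTe(config, lineId, slope)

  # companion species: shared fraction of A's polymorphic sites + own sites
  spB <- .simSpeciesB(config, chrom[poly], pos[poly], ref[poly], alt[poly],
                      pN[poly], pS[poly], genome, lineId, slope)

  truth <- list(
    sweeps = .truthSweeps(config, lineId, slope),
    siteFreqs = data.frame(chrom = chrom[poly], pos = pos[poly],
                           pNFS = pN[poly], pSFS = pS[poly]),
    te = te,
    sharedSiteMap = spB$sharedMap)

  list(sites = sites, genes = genes, te = te, speciesB = spB$sites,
       genome = genome, truth = truth)
}

# Truth intervals expanded per line.
.truthSweeps <- function(config, lineId, slope) {
  sw <- config@sweeps
  if (!nrow(sw)) return(data.frame(line = character(), chrom = character(),
                                   start = integer(), end = integer()))
  out <- list()
  for (k in seq_len(nrow(sw))) {
    lns <- if (sw$slope[k] == "both") lineId
           else lineId[slope == sw$slope[k]]
    out[[k]] <- data.frame(line = lns, chrom = sw$chrom[k],
                           start = sw$start[k], end = sw$end[k])
  }
  do.call(rbind, out)
}

# Companion species site table.
.simSpeciesB <- function(config, chromA, posA, refA, altA, pNA, pSA,
                         genome, lineId, slope) {
  nA <- length(posA)
  nShared <- round(config@sharedSpeciesFraction * nA)
  sharedIdx <- sort(sample.int(nA, nShared))
  nPool <- config@haploidsPerPool
  # shared sites: major-allele co-occurrence + optional interslope convergence
  qA <- (pNA[sharedIdx] + pSA[sharedIdx]) / 2
  altMajorA <- qA > 0.5
  wantAltMajor <- ifelse(stats::runif(nShared) < config@cooccurProb,
                         altMajorA, !altMajorA)
  qB <- .rNeutralFreq(nShared, nPool)
  flip <- (qB > 0.5) != wantAltMajor
  qB[flip] <- 1 - qB[flip]
  qB <- pmin(pmax(qB, 1 / nPool), 1 - 1 / nPool)
  dA <- pNA[sharedIdx] - pSA[sharedIdx]
  conv <- stats::runif(nShared) < config@convergenceProb
  eps <- stats::rnorm(nShared, 0, 0.05)
  dB <- ifelse(conv, dA, eps)
  pNB <- pmin(pmax(qB + dB / 2, 0), 1)
  pSB <- pmin(pmax(qB - dB / 2, 0), 1)
  # non-shared species-B sites at fresh positions
  nOwn <- nA - nShared
  ownChrom <- sample(names(config@genomeLength), nOwn, replace = TRUE,
                     prob = config@genomeLength / sum(config@genomeLength))
  ownPos <- vapply(ownChrom, function(cc)
    sample.int(config@genomeLength[[cc]], 1L), integer(1))
  taken <- paste(chromA, posA)
  dup <- paste(ownChrom, ownPos) %in% taken | duplicated(paste(ownChrom, ownPos))
  ownChrom <- ownChrom[!dup]; ownPos <- ownPos[!dup]
  nOwn <- length(ownPos)
  gStr <- vapply(names(genome), function(ch) as.character(genome[[ch]]),
                 character(1))
  ownRef <- substring(gStr[ownChrom], ownPos, ownPos)
  ownAlt <- vapply(ownRef, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
    USE.NAMES = FALSE)
  pSharedOwn <- .rNeutralFreq(nOwn, nPool)
  pNOwn <- .driftFreq(pSharedOwn, config@migrationMix)
  pSOwn <- .driftFreq(pSharedOwn, config@migrationMix)

  chromB <- c(chromA[sharedIdx], ownChrom)
  posB <- c(posA[sharedIdx], ownPos)
  refB <- c(refA[sharedIdx], ownRef)
  altB <- c(altA[sharedIdx], ownAlt)
  pNB <- c(pNB, pNOwn); pSB <- c(pSB, pSOwn)
  ord <- order(chromB, posB)
  nL <- config@nLinesPerSlope
  rn <- .sampleReads(pNB[ord], nL, nPool, config@meanDepth)
  rs <- .sampleReads(pSB[ord], nL, nPool, config@meanDepth)
  rd <- cbind(rn$ref, rs$ref); ad <- cbind(rn$alt, rs$alt)
  poly <- rowSums(ad) > 0L & rowSums(ad) < rowSums(rd + ad)
  sites <- PoolSiteTable(chrom = chromB[ord][poly], pos = posB[ord][poly],
                         ref = refB[ord][poly], alt = altB[ord][poly],
                         refDepth = rd[poly, , drop = FALSE],
                         altDepth = ad[poly, , drop = FALSE],
                         lineId = sub("FS_", "FSb_", lineId), slope = slope)
  list(sites = sites,
       sharedMap = data.frame(chrom = chromA[sharedIdx],
                              posA = posA[sharedIdx],
                              posB = posA[sharedIdx]))
}

#' Calibrate the interslope mixing to a target mean FST
#'
#' Bisects \code{migrationMix} so that the simulated genome-wide mean windowed
#' FST matches \code{targetFst} within \code{tol}, averaged over
#' \code{nSeeds} seeds. Mean FST decreases monotonically in the mixing
#' weight, so bisection converges; a target outside the attainable range
#' (checked at mix 0 and 1) is an error.
#'
#' @param targetFst Target mean FST, in (0, 0.5).
#' @param config Template [simConfig()]; its \code{migrationMix} is replaced.
#' @param nSeeds Seeds averaged per evaluation (>= 3).
#' @param tol Convergence tolerance on mean FST (default 0.02).
#' @param windowSize Window used for the FST average.
#' @param maxIter Bisection iteration cap.
#' @return The config with calibrated \code{migrationMix}; the achieved mean
#'   FST is attached as attribute \code{"achievedFst"}.
#' @export
calibrateDivergence <- function(targetFst, config, nSeeds = 3L, tol = 0.02,
                                windowSize = 5000L, maxIter = 25L) {
  stopifnot(targetFst > 0, targetFst < 0.5)
  measure <- function(mix) {
    vals <- vapply(seq_len(nSeeds), function(k) {
      cfg <- config
      cfg@migrationMix <- mix
      cfg@seed <- config@seed + (k - 1L) * 1000L
      sim <- simulateCohort(cfg)
      ws <- windowStats(sim$sites, windowSize = windowSize,
                        nHaploids = config@haploidsPerPool)
      mean(ws$fst, na.rm = TRUE)
    }, numeric(1))
    mean(vals)
  }
  lo <- 0; hi <- 1
  fLo <- measure(lo)   # max differentiation
  fHi <- measure(hi)   # sampling noise only
  if (targetFst > fLo || targetFst < fHi)
    stop(sprintf("target FST %.3f unachievable: attainable range [%.3f, %.3f]",
                 targetFst, fHi, fLo))
  mid <- 0.5; fMid <- NA_real_
  for (it in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    fMid <- measure(mid)
    if (abs(fMid - targetFst) <= tol) break
    if (fMid > targetFst) lo <- mid else hi <- mid
  }
  out <- config
  out@migrationMix <- mid
  attr(out, "achievedFst") <- fMid
  out
}
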