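#' Parameters of the three-state sweep HMM
#'
#' Bundles the tuning parameters of the allele-frequency-spectrum HMM used to
#' segment a pooled line into Neutral / Intermediate / Selection states.
#'
#' @param nHaploids Haploid genomes per pool (default 40).
#' @param minCov,maxCov Per-site read-depth bounds (defaults 5, 250); sites
#'   outside are ignored by the decoder.
#' @param kTransition Per-site probability of switching state (default 1e-10,
#'   a strongly sticky chain: long homogeneous segments).
#' @param theta Per-line Watterson estimate (per site); carried for reporting.
#' @param tiltGamma Positive tilt controlling how strongly the Selection-state
#'   spectrum is pushed toward extreme frequencies (default 8).
#' @return A list with class \code{"HmmParams"}.
#' @export
hmmParams <- function(nHaploids = 40L, minCov = 5L, maxCov = 250L,
                      kTransition = 1e-10, theta = 0.005, tiltGamma = 8) {
  stopifnot(nHaploids >= 4L, minCov <= maxCov,
            kTransition > 0, kTransition < 1, theta > 0, tiltGamma >= 0)
  structure(list(nHaploids = as.integer(nHaploids), minCov = as.integer(minCov),
                 maxCov = as.integer(maxCov), kTransition = kTransition,
                 theta = theta, tiltGamma = tiltGamma),
            class = "HmmParams")
}

#' Hidden-state allele-frequency spectra
#'
#' Normalized spectra over derived-allele counts \eqn{i = 1..n-1}:
#' Neutral \eqn{\xi_i \propto 1/i}; Selection
#' \eqn{\xi_i \propto (1/i)\exp(-\gamma\,\min(i, n-i)/n)} (mass pushed to the
#' extremes, the post-hitchhiking signature); Intermediate the renormalized
#' elementwise geometric mean of the two.
#'
#' @param params An [hmmParams()] object.
#' @return A (n-1) x 3 matrix with columns \code{Neutral}, \code{Intermediate},
#'   \code{Selection}, each column summing to 1.
#' @export
stateSpectra <- function(params) {
  n <- params$nHaploids
  if (n < 4L) stop("nHaploids must be >= 4")
  i <- seq_len(n - 1L)
  neutral <- (1 / i) / sum(1 / i)
  sel <- (1 / i) * exp(-params$tiltGamma * pmin(i, n - i) / n)
  sel <- sel / sum(sel)
  inter <- sqrt(neutral * sel)
  inter <- inter / sum(inter)
  cbind(Neutral = neutral, Intermediate = inter, Selection = sel)
}

#' Emission log-probability of pooled read counts under a spectrum
#'
#' \eqn{\log \sum_{i=1}^{n-1} \xi_i \,\mathrm{Binom}(a \mid r+a, i/n)},
#' evaluated stably in log space.
#'
#' @param refCount,altCount Read counts (vectors of equal length).
#' @param spectrum Normalized spectrum over derived-allele counts 1..n-1.
#' @param nHaploids Haploid sample size n.
#' @return Vector of log-probabilities.
#' @export
emissionLogProb <- function(refCount, altCount, spectrum, nHaploids) {
  n <- nHaploids
  depth <- refCount + altCount
  i <- seq_len(n - 1L)
  # sites x (n-1) matrix of log xi_i + log Binom(a | d, i/n)
  lg <- outer(seq_along(depth), i, function(s, ii)
    stats::dbinom(altCount[s], depth[s], ii / n, log = TRUE))
  lg <- sweep(lg, 2L, log(spectrum), "+")
  logSumExp(lg)
}

# Emission log-probability matrix (sites x 3 states), caching duplicate
# (depth, alt) pairs -- read counts repeat heavily at realistic depths.
.emissionMatrix <- function(refCount, altCount, spectra, nHaploids) {
  key <- paste(refCount + altCount, altCount)
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  em <- vapply(colnames(spectra), function(s)
    emissionLogProb(refCount[uk], altCount[uk], spectra[, s], nHaploids),
    numeric(sum(uk)))
  em[idx, , drop = FALSE]
}

#' Decode the sweep HMM for one line on one chromosome
#'
#' Runs forward-backward (posterior state probabilities) and Viterbi decoding
#' over the three states \code{Neutral}, \code{Intermediate}, \code{Selection}.
#' The transition matrix has stay-probability \eqn{1-2k} and probability
#' \eqn{k} of switching to each other state; the initial distribution is
#' uniform. Sites outside the coverage bounds are dropped before decoding.
#'
#' @param x A [PoolSiteTable-class] (or any object accepted by
#'   [siteFrequency()]); only the column \code{line} is used.
#' @param line Line identifier (a column of \code{x}).
#' @param params An [hmmParams()] object.
#' @param chrom Optional chromosome to restrict to; default all, decoded
#'   independently per chromosome.
#' @return A data.frame with one row per retained site: \code{chrom}, \code{pos},
#'   \code{state} (Viterbi), and posterior columns \code{pNeutral},
#'   \code{pIntermediate}, \code{pSelection}.
#' @export
decodeSweepHmm <- function(x, line, params, chrom = NULL) {
  stopifnot(inherits(params, "HmmParams"))
  j <- match(line, lineIds(x))
  if (is.na(j)) stop("unknown line: ", line)
  rr <- rowRanges(x)
  ch <- as.character(seqnames(rr))
  keep <- if (is.null(chrom)) rep(TRUE, length(ch)) else ch %in% chrom
  r <- refDepth(x)[, j]; a <- altDepth(x)[, j]
  d <- r + a
  keep <- keep & d >= params$minCov & d <= params$maxCov
  if (!any(keep)) {
    return(data.frame(chrom = character(), pos = integer(), state = character(),
                      pNeutral = numeric(), pIntermediate = numeric(),
                      pSelection = numeric()))
  }
  spectra <- stateSpectra(params)
  out <- lapply(unique(ch[keep]), function(cc) {
    idx <- which(keep & ch == cc)
    em <- .emissionMatrix(r[idx], a[idx], spectra, params$nHaploids)
    dec <- .decodeCore(em, params$kTransition)
    data.frame(chrom = cc, pos = start(rr)[idx],
               state = colnames(spectra)[dec$path],
               pNeutral = dec$post[, 1L], pIntermediate = dec$post[, 2L],
               pSelection = dec$post[, 3L])
  })
  do.call(rbind, out)
}

# Forward-backward + Viterbi over a sites x K matrix of emission logprobs.
# Transition: stay 1-(K-1)k, switch k; uniform initial distribution.
.decodeCore <- function(em, k) {
  nT <- nrow(em); K <- ncol(em)
  logA <- matrix(log(k), K, K)
  diag(logA) <- log(1 - (K - 1) * k)
  logPi <- rep(-log(K), K)
  # forward
  fwd <- matrix(NA_real_, nT, K)
  fwd[1L, ] <- logPi + em[1L, ]
  # viterbi
  vit <- matrix(NA_real_, nT, K)
  ptr <- matrix(NA_integer_, nT, K)
  vit[1L, ] <- logPi + em[1L, ]
  for (t in seq_len(nT)[-1L]) {
    prevF <- fwd[t - 1L, ]
    prevV <- vit[t - 1L, ]
    for (s in seq_len(K)) {
      fwd[t, s] <- logSumExp(prevF + logA[, s]) + em[t, s]
      cand <- prevV + logA[, s]
      ptr[t, s] <- which.max(cand)
      vit[t, s] <- cand[ptr[t, s]] + em[t, s]
    }
  }
  # backward
  bwd <- matrix(0, nT, K)
  for (t in rev(seq_len(nT - 1L))) {
    nxt <- bwd[t + 1L, ] + em[t + 1L, ]
    for (s in seq_len(K)) bwd[t, s] <- logSumExp(nxt + logA[s, ])
  }
  lpost <- fwd + bwd
  post <- exp(lpost - apply(lpost, 1L, logSumExp))
  # viterbi backtrace
  path <- integer(nT)
  path[nT] <- which.max(vit[nT, ])
  if (nT > 1L) for (t in rev(seq_len(nT - 1L))) path[t] <- ptr[t + 1L, path[t + 1L]]
  list(path = path, post = post)
}

#' Call sweep regions from a decoded state path
#'
#' Maximal runs of consecutive sites whose Viterbi state is \code{Selection}
#' become regions spanning the first to last site position. Runs shorter than
#' \code{minSites} are dropped (single-site artifacts).
#'
#' @param decoded Output of [decodeSweepHmm()].
#' @param minSites Minimum run length in sites (default 3).
#' @param lineId Optional line identifier stored on the result.
#' @return \code{GRanges} of sweep regions with \code{nSites} and
#'   \code{meanPosterior} (mean Selection-state posterior) columns.
#' @export
callSweepRegions <- function(decoded, minSites = 3L, lineId = NA_character_) {
  if (!nrow(decoded)) {
    gr <- GRanges()
    gr$nSites <- integer(); gr$meanPosterior <- numeric(); gr$lineId <- character()
    return(gr)
  }
  res <- lapply(split(seq_len(nrow(decoded)), decoded$chrom), function(idx) {
    d <- decoded[idx, ]
    sel <- d$state == "Selection"
    r <- rle(sel)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minSites
    if (!any(keep)) return(NULL)
    data.frame(chrom = d$chrom[1L],
               start = d$pos[starts[keep]],
               end = d$pos[ends[keep]],
               nSites = r$lengths[keep],
               meanPosterior = mapply(function(s, e) mean(d$pSelection[s:e]),
                                      starts[keep], ends[keep]))
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    gr <- GRanges()
    gr$nSites <- integer(); gr$meanPosterior <- numeric(); gr$lineId <- character()
    return(gr)
  }
  gr <- GRanges(res$chrom, IRanges(res$start, res$end),
                nSites = res$nSites, meanPosterior = res$meanPosterior,
                lineId = lineId)
  sort(gr)
}

#' Sweep regions for every line of a cohort
#'
#' Convenience wrapper: decodes each line (with a per-line theta if supplied)
#' and calls its regions.
#'
#' @param x A [PoolSiteTable-class].
#' @param params An [hmmParams()] template; \code{theta} is overridden per line
#'   when \code{thetaPerLine} is given.
#' @param minSites Minimum sites per region.
#' @param thetaPerLine Optional named numeric vector of per-line Watterson
#'   estimates.
#' @return Named list of \code{GRanges}, one per line.
#' @export
sweepRegionsByLine <- function(x, params, minSites = 3L, thetaPerLine = NULL) {
  out <- lapply(lineIds(x), function(ln) {
    p <- params
    if (!is.null(thetaPerLine) && ln %in% names(thetaPerLine))
      p$theta <- thetaPerLine[[ln]]
    callSweepRegions(decodeSweepHmm(x, ln, p), minSites = minSites, lineId = ln)
  })
  names(out) <- lineIds(x)
  out
}

#' Classify genomic intervals by sweep sharing across slopes
#'
#' Partitions the genome into intervals swept in every line (\code{all}),
#' in every NFS line but not every SFS line (\code{NFS}), in every SFS line
#' but not every NFS line (\code{SFS}); everything else is unclassified
#' (\code{none}, not emitted). Sharing is strict: a region present in 8 of 9
#' lines of a slope does not count for that slope.
#'
#' @param regionsByLine Named list of per-line sweep \code{GRanges}.
#' @param slope Named character vector mapping line ids to \code{NFS}/\code{SFS}.
#' @return \code{GRanges} with a \code{class} column in
#'   \code{c("all","NFS","SFS")}.
#' @export
classifyRegions <- function(regionsByLine, slope) {
  if (is.null(names(regionsByLine)) ||
      !all(names(regionsByLine) %in% names(slope)))
    stop("every element of regionsByLine must have a slope label")
  slope <- .checkSlopes(slope[names(regionsByLine)])
  names(slope) <- names(regionsByLine)
  interAll <- function(lns) {
    if (!length(lns)) return(GRanges())
    acc <- reduce(regionsByLine[[lns[1L]]], ignore.strand = TRUE)
    for (ln in lns[-1L])
      acc <- GenomicRanges::intersect(acc, regionsByLine[[ln]],
                                      ignore.strand = TRUE)
    acc
  }
  nfsAll <- interAll(names(slope)[slope == "NFS"])
  sfsAll <- interAll(names(slope)[slope == "SFS"])
  allCls <- GenomicRanges::intersect(nfsAll, sfsAll, ignore.strand = TRUE)
  nfsOnly <- GenomicRanges::setdiff(nfsAll, sfsAll, ignore.strand = TRUE)
  sfsOnly <- GenomicRanges::setdiff(sfsAll, nfsAll, ignore.strand = TRUE)
  pieces <- list()
  if (length(allCls)) { allCls$class <- "all"; pieces <- c(pieces, list(allCls)) }
  if (length(nfsOnly)) { nfsOnly$class <- "NFS"; pieces <- c(pieces, list(nfsOnly)) }
  if (length(sfsOnly)) { sfsOnly$class <- "SFS"; pieces <- c(pieces, list(sfsOnly)) }
  if (!length(pieces)) {
    out <- GRanges()
    out$class <- character(0)
    return(out)
  }
  sort(do.call(c, pieces))
}
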