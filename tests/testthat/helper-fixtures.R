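# Shared fixtures and independent oracles for the suite.

# Small hand-specified site table: counts are (ref, alt) per line.
makeTinyTable <- function(pos = c(100L, 200L, 300L),
                          refCounts, altCounts,
                          lineId = c("n1", "n2", "s1", "s2"),
                          slope = c("NFS", "NFS", "SFS", "SFS"),
                          chrom = "2R",
                          ref = NULL, alt = NULL) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep(c("A", "C", "G", "T"), length.out = n)
  if (is.null(alt)) alt <- rep(c("G", "T", "A", "C"), length.out = n)
  PoolSiteTable(chrom = chrom, pos = pos, ref = ref, alt = alt,
                refDepth = refCounts, altDepth = altCounts,
                lineId = lineId, slope = slope)
}

# Textbook Tajima's D, coded independently of the package (scalar loops).
oracleTajimaD <- function(freqs, n) {
  seg <- freqs[freqs > 0 & freqs < 1]
  S <- length(seg)
  if (S < 3) return(NA_real_)
  ppi <- 0
  for (p in seg) ppi <- ppi + 2 * p * (1 - p) * n / (n - 1)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (ppi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables with
# the observed margins, summing probabilities <= observed (log-choose based;
# independent of stats::fisher.test / dhyper).
oracleFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  logp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(xs, logp, numeric(1))
  pObs <- logp(a)
  sum(exp(lp[lp <= pObs + 1e-7]))
}

# Exhaustive Viterbi over all K^T state paths for a T x K emission matrix.
oracleViterbi <- function(em, k) {
  nT <- nrow(em); K <- ncol(em)
  logA <- matrix(log(k), K, K); diag(logA) <- log(1 - (K - 1) * k)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), nT)))
  sc <- -log(K) + em[cbind(1L, paths[, 1L])]
  if (nT > 1L) for (t in 2:nT) {
    sc <- sc + logA[cbind(paths[, t - 1L], paths[, t])] +
      em[cbind(t, paths[, t])]
  }
  paths[which.max(sc), ]
}

# A small calibrated cohort with planted SFS sweeps, cached across test files
# (helpers are sourced once per run).
.cohortCache <- new.env()
demoCohort <- function() {
  if (!is.null(.cohortCache$sim)) return(.cohortCache$sim)
  sw <- data.frame(chrom = "2R",
                   start = c(50e3, 150e3, 250e3),
                   end = c(90e3, 190e3, 290e3),
                   reduction = 0.2, slope = "SFS")
  cfg <- simConfig(genomeLength = c(`2R` = 3e5), sweeps = sw, seed = 7)
  .cohortCache$cfg <- cfg
  .cohortCache$sim <- simulateCohort(cfg)
  .cohortCache$sim
}
demoConfig <- function() { demoCohort(); .cohortCache$cfg }
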