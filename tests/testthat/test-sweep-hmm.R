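test_that("state spectra are normalized and ordered by heterozygosity", {
  p <- hmmParams(nHaploids = 40L, tiltGamma = 8)
  sp <- stateSpectra(p)
  expect_equal(colSums(sp), c(Neutral = 1, Intermediate = 1, Selection = 1),
               tolerance = 1e-12)
  i <- 1:39
  het <- function(xi) sum(xi * 2 * (i / 40) * (1 - i / 40))
  expect_lt(het(sp[, "Selection"]), het(sp[, "Neutral"]))
  expect_lt(het(sp[, "Intermediate"]), het(sp[, "Neutral"]))
  # zero tilt: Selection collapses onto Neutral
  sp0 <- stateSpectra(hmmParams(tiltGamma = 0))
  expect_equal(sp0[, "Selection"], sp0[, "Neutral"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(stateSpectra(hmmParams(nHaploids = 3L)))
})

test_that("emission log-probabilities equal brute-force summation", {
  p <- hmmParams()
  sp <- stateSpectra(p)
  # fixture (r=30, a=5): sum over all 39 terms by hand
  brute <- 0
  for (i in 1:39)
    brute <- brute + sp[i, "Neutral"] * dbinom(5, 35, i / 40)
  expect_equal(emissionLogProb(30L, 5L, sp[, "Neutral"], 40L), log(brute),
               tolerance = 1e-12, ignore_attr = TRUE)
  # uniform spectrum: mean of binomial pmfs by linearity
  unif <- rep(1 / 39, 39)
  expect_equal(exp(emissionLogProb(10L, 10L, unif, 40L)),
               mean(dbinom(10, 20, (1:39) / 40)), tolerance = 1e-12)
  # depth 10, a=0, Neutral: the i=1 term dominates
  terms <- sp[, "Neutral"] * dbinom(0, 10, (1:39) / 40)
  expect_equal(which.max(terms), 1L)
  expect_gt(terms[1] / sum(terms), 0.5)
})

test_that("Viterbi equals exhaustive path enumeration on small inputs", {
  set.seed(11)
  k <- 1e-3  # loose chain so enumeration cases actually switch states
  for (trial in 1:50) {
    nT <- sample(2:8, 1)
    em <- matrix(log(runif(nT * 3)), nT, 3)
    dec <- poolSweeps:::.decodeCore(em, k)
    expect_identical(dec$path, unname(oracleViterbi(em, k)))
    expect_equal(rowSums(dec$post), rep(1, nT), tolerance = 1e-9)
  }
})

test_that("a 3-site toy decodes to the enumerated best path", {
  em <- matrix(log(c(0.9, 0.05, 0.05,
                     0.1, 0.1, 0.8,
                     0.8, 0.1, 0.1)), 3, 3, byrow = TRUE)
  dec <- poolSweeps:::.decodeCore(em, 1e-2)
  expect_identical(dec$path, unname(oracleViterbi(em, 1e-2)))
})

test_that("strongly neutral sites decode to an all-Neutral path", {
  set.seed(3)
  n <- 200L
  pop <- sample(1:39, n, replace = TRUE, prob = 1 / (1:39))
  d <- rpois(n, 73)
  a <- rbinom(n, d, pop / 40)
  st <- PoolSiteTable(chrom = "2R", pos = seq_len(n) * 50L,
                      ref = rep("A", n), alt = rep("G", n),
                      refDepth = cbind(d - a, d - a),
                      altDepth = cbind(a, a),
                      lineId = c("n1", "s1"), slope = c("NFS", "SFS"))
  dec <- decodeSweepHmm(st, "n1", hmmParams(kTransition = 1e-10))
  expect_true(all(dec$state == "Neutral"))
  expect_equal(rowSums(dec[, c("pNeutral", "pIntermediate", "pSelection")]),
               rep(1, nrow(dec)), tolerance = 1e-9)
})

test_that("region calling reports maximal Selection runs by position", {
  dec <- data.frame(chrom = "2R", pos = seq(10L, 60L, 10L),
                    state = c("Neutral", "Neutral", "Selection", "Selection",
                              "Selection", "Neutral"),
                    pNeutral = 0, pIntermediate = 0, pSelection = 1)
  reg <- callSweepRegions(dec, minSites = 3L, lineId = "L1")
  expect_length(reg, 1L)
  expect_equal(GenomicRanges::start(reg), 30L)
  expect_equal(GenomicRanges::end(reg), 50L)
  expect_equal(reg$nSites, 3L)
  # all-Neutral path: nothing
  dec$state <- "Neutral"
  expect_length(callSweepRegions(dec, minSites = 3L), 0L)
  # two runs split by one Neutral site stay two regions (no merging)
  dec2 <- data.frame(chrom = "2R", pos = seq(10L, 70L, 10L),
                     state = c("Selection", "Selection", "Selection",
                               "Neutral", "Selection", "Selection",
                               "Selection"),
                     pNeutral = 0, pIntermediate = 0, pSelection = 1)
  expect_length(callSweepRegions(dec2, minSites = 3L), 2L)
  # runs below minSites are dropped
  expect_length(callSweepRegions(dec2[1:4, ], minSites = 4L), 0L)
})

test_that("decreasing the transition probability never fragments more", {
  sim <- demoCohort()
  nRegions <- vapply(c(1e-4, 1e-6, 1e-8, 1e-10), function(k) {
    dec <- decodeSweepHmm(sim$sites, "SFS_01", hmmParams(kTransition = k))
    length(callSweepRegions(dec, minSites = 1L))
  }, numeric(1))
  expect_true(all(diff(nRegions) <= 0))
})

test_that("region classification follows strict all-lines sharing", {
  gr <- function(s, e) GenomicRanges::GRanges("2R", IRanges::IRanges(s, e))
  lines <- c(sprintf("N%d", 1:3), sprintf("S%d", 1:3))
  slope <- setNames(rep(c("NFS", "SFS"), each = 3), lines)
  # identical region everywhere -> "all"
  regs <- setNames(rep(list(gr(100, 200)), 6), lines)
  cls <- classifyRegions(regs, slope)
  expect_equal(as.character(cls$class), "all")
  # region in all SFS lines only -> "SFS"
  regs <- c(setNames(rep(list(GenomicRanges::GRanges()), 3), lines[1:3]),
            setNames(rep(list(gr(100, 200)), 3), lines[4:6]))
  cls <- classifyRegions(regs, slope)
  expect_equal(as.character(cls$class), "SFS")
  # region missing from one SFS line -> unclassified
  regs[["S3"]] <- GenomicRanges::GRanges()
  expect_length(classifyRegions(regs, slope), 0L)
  # partial overlaps are intersected before classification
  regs <- c(setNames(rep(list(gr(100, 300)), 3), lines[1:3]),
            setNames(rep(list(gr(200, 400)), 3), lines[4:6]))
  cls <- classifyRegions(regs, slope)
  df <- as.data.frame(cls)
  expect_setequal(df$class, c("all", "NFS", "SFS"))
  expect_equal(df$start[df$class == "all"], 200)
  expect_equal(df$end[df$class == "all"], 300)
  expect_error(classifyRegions(unname(regs), slope))
})

test_that("planted sweeps are recovered in the right lines", {
  sim <- demoCohort()
  cfg <- demoConfig()
  regs <- sweepRegionsByLine(sim$sites, hmmParams(theta = cfg@thetaPerSite))
  truth <- GenomicRanges::GRanges(cfg@sweeps$chrom,
                                  IRanges::IRanges(cfg@sweeps$start,
                                                   cfg@sweeps$end))
  sl <- setNames(slopes(sim$sites), lineIds(sim$sites))
  for (ln in names(regs)) {
    if (sl[[ln]] == "SFS") {
      # every planted interval recovered with >= 50% reciprocal overlap
      hits <- GenomicRanges::findOverlaps(truth, regs[[ln]])
      expect_equal(length(unique(S4Vectors::queryHits(hits))), length(truth))
    } else {
      expect_length(regs[[ln]], 0L)
    }
  }
})
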