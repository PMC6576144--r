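# two-line (one per slope) tables with exact frequencies via depth-100 counts
freqTable <- function(pos, ref, alt, fN, fS, chrom = "2R",
                      lineId = c("n1", "s1")) {
  d <- 100L
  altC <- cbind(as.integer(round(fN * d)), as.integer(round(fS * d)))
  PoolSiteTable(chrom = chrom, pos = pos, ref = ref, alt = alt,
                refDepth = d - altC, altDepth = altC,
                lineId = lineId, slope = c("NFS", "SFS"))
}

test_that("shared sites require matching coordinates and allele pairs", {
  A <- freqTable(c(100L, 200L, 300L), c("A", "C", "G"), c("G", "T", "A"),
                 c(0.3, 0.4, 0.5), c(0.2, 0.4, 0.6))
  # B: same pair at 100; swapped labels at 200; different pair at 300
  B <- freqTable(c(100L, 200L, 300L), c("A", "T", "G"), c("G", "C", "C"),
                 c(0.7, 0.9, 0.5), c(0.6, 0.8, 0.5), lineId = c("bn", "bs"))
  sh <- mapSharedSites(A, B)
  expect_setequal(sh$posA, c(100L, 200L))
  # swapped ref/alt re-expressed on A's alt allele
  expect_equal(sh$fB_NFS[sh$posA == 200L], 1 - 0.9)
  # symmetry: swapping species gives the same site set
  shBA <- mapSharedSites(B, A)
  expect_setequal(shBA$posA, sh$posB)
  # explicit coordinate map
  cm <- data.frame(chromA = "2R", posA = 100L, chromB = "2R", posB = 1100L)
  B2 <- freqTable(1100L, "A", "G", 0.7, 0.6, lineId = c("bn", "bs"))
  sh2 <- mapSharedSites(A, B2, coordMap = cm)
  expect_equal(sh2$posA, 100L)
  expect_equal(sh2$posB, 1100L)
  cmBad <- rbind(cm, data.frame(chromA = "2R", posA = 100L, chromB = "2R",
                                posB = 1200L))
  expect_error(mapSharedSites(A, B2, coordMap = cmBad), "one-to-one")
})

test_that("major-allele co-occurrence is high for copied, ~1 for independent", {
  set.seed(31)
  n <- 2000L
  pos <- seq_len(n) * 10L
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  f <- runif(n, 0.05, 0.95)
  A <- freqTable(pos, ref, alt, f, f)
  # B copies A at half the sites (shared) and has private sites elsewhere
  sharedIdx <- 1:1000
  privPos <- max(pos) + seq_len(500L) * 10L
  privRef <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  privAlt <- vapply(privRef, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1),
    USE.NAMES = FALSE)
  Bcopy <- freqTable(c(pos[sharedIdx], privPos),
                     c(ref[sharedIdx], privRef),
                     c(alt[sharedIdx], privAlt),
                     c(f[sharedIdx], runif(500, 0.05, 0.95)),
                     c(f[sharedIdx], runif(500, 0.05, 0.95)),
                     lineId = c("bn", "bs"))
  shared <- mapSharedSites(A, Bcopy)
  res <- majorAlleleCooccurrence(shared, A, Bcopy)
  expect_equal(res$observed[res$stratum == "all"], 1)
  expect_gt(res$fold[res$stratum == "all"], 2)
  # independent frequencies at shared sites: the same allele pair constrains
  # coincidence to ~1/2, well below the copied case and well above chance
  # base identity
  Bind <- freqTable(c(pos[sharedIdx], privPos),
                    c(ref[sharedIdx], privRef),
                    c(alt[sharedIdx], privAlt),
                    runif(1500, 0.05, 0.95), runif(1500, 0.05, 0.95),
                    lineId = c("bn", "bs"))
  resI <- majorAlleleCooccurrence(mapSharedSites(A, Bind), A, Bind)
  expect_equal(resI$observed[resI$stratum == "all"], 0.5, tolerance = 0.1)
  expect_lt(resI$fold[resI$stratum == "all"],
            res$fold[res$stratum == "all"] / 1.5)
})

test_that("the generator's planted co-occurrence is recovered", {
  cfg <- simConfig(genomeLength = c(`2R` = 4e5), sharedSpeciesFraction = 0.1,
                   cooccurProb = 0.85, seed = 19)
  sim <- simulateCohort(cfg)
  shared <- mapSharedSites(sim$sites, sim$speciesB)
  # shared count near the planted fraction of polymorphic sites
  expect_gt(nrow(shared), 0.07 * nrow(sim$sites))
  expect_lt(nrow(shared), 0.13 * nrow(sim$sites))
  res <- majorAlleleCooccurrence(shared, sim$sites, sim$speciesB)
  expect_equal(res$observed[1], 0.85, tolerance = 0.05)
  # independent background major bases coincide ~ sum of squared base
  # frequencies (~0.3), so the planted regime is > 2-fold enriched
  expect_gt(res$fold[1], 2)
})

test_that("interslope difference correlation sees planted convergence", {
  set.seed(41)
  n <- 1000L
  pos <- seq_len(n) * 10L
  ref <- rep("A", n); alt <- rep("G", n)
  dA <- runif(n, -0.4, 0.4)
  fN <- 0.5 + dA / 2; fS <- 0.5 - dA / 2
  A <- freqTable(pos, ref, alt, fN, fS)
  # identical interslope differences -> rho = 1
  B <- freqTable(pos, ref, alt, fN, fS, lineId = c("bn", "bs"))
  shared <- mapSharedSites(A, B)
  expect_equal(interslopeDiffCorrelation(shared)$rho, 1, tolerance = 1e-10)
  # independent differences -> |rho| < 0.1 at n = 1000
  dB <- runif(n, -0.4, 0.4)
  B2 <- freqTable(pos, ref, alt, 0.5 + dB / 2, 0.5 - dB / 2,
                  lineId = c("bn", "bs"))
  r0 <- interslopeDiffCorrelation(mapSharedSites(A, B2))$rho
  expect_lt(abs(r0), 0.1)
})

test_that("coding effects follow codon substitution, strand-aware", {
  genome <- Biostrings::DNAStringSet(c(`2R` = paste0(
    "AAAA", "TTTGCAAGT", "TTTT")))  # CDS at 5..13 on + strand
  cds <- GenomicRanges::GRanges("2R", IRanges::IRanges(5, 13), strand = "+",
                                gene_id = "g1")
  # third-position TTT -> TTC: synonymous (Phe)
  st <- freqTable(c(7L, 8L, 15L), c("T", "G", "T"), c("C", "T", "A"),
                  c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  eff <- annotateEffect(st, cds, genome)
  expect_equal(eff, c("synonymous", "nonsynonymous", "noncoding"))
  # serine -> phenylalanine: TCT -> TTT at codon position 2
  genome2 <- Biostrings::DNAStringSet(c(`2R` = paste0("AA", "TCTAAA", "GG")))
  cds2 <- GenomicRanges::GRanges("2R", IRanges::IRanges(3, 8), strand = "+",
                                 gene_id = "g1")
  st2 <- freqTable(4L, "C", "T", 0.5, 0.5)
  expect_equal(annotateEffect(st2, cds2, genome2), "nonsynonymous")
  # minus strand: genomic CDS CTCATA reads TAT GAG on the reverse strand
  genome3 <- Biostrings::DNAStringSet(c(`2R` = "AACTCATAA"))
  cds3 <- GenomicRanges::GRanges("2R", IRanges::IRanges(3, 8), strand = "-",
                                 gene_id = "g1")
  # site at genomic pos 3 (C) is the wobble base of GAG (Glu); C->T gives
  # GAA, still Glu: synonymous, and only resolvable strand-aware
  st3 <- freqTable(3L, "C", "T", 0.5, 0.5)
  expect_equal(annotateEffect(st3, cds3, genome3), "synonymous")
  # reference mismatch is an error
  stBad <- freqTable(4L, "G", "T", 0.5, 0.5)
  expect_error(annotateEffect(stBad, cds2, genome2), "mismatch")
})

test_that("slope-divergent filter applies all three conditions plus Fisher", {
  pos <- c(100L, 200L, 300L, 400L)
  ref <- rep("A", 4); alt <- rep("G", 4)
  # site 1: the published-style case (1.00/0.35 vs 0.59/0.30) -> passes
  # site 2: major on NFS in A but on SFS in B -> fails (iii)
  # site 3: synonymous with perfect divergence -> fails (i)
  # site 4: not divergent in A -> fails (ii)
  A <- freqTable(pos, ref, alt, c(1.00, 0.9, 1.0, 0.6), c(0.35, 0.2, 0.0, 0.6))
  B <- freqTable(pos, ref, alt, c(0.59, 0.2, 1.0, 0.9), c(0.30, 0.9, 0.0, 0.2),
                 lineId = c("bn", "bs"))
  shared <- mapSharedSites(A, B)
  shared <- shared[order(shared$posA), ]
  eff <- c("nonsynonymous", "nonsynonymous", "synonymous", "nonsynonymous")
  out <- slopeDivergentFilter(shared, eff, nLinesPerSlope = 9L)
  expect_equal(out$posA, 100L)
  expect_true(all(c("fisherPA", "fisherPB") %in% colnames(out)))
  # haploid-equivalent Fisher: counts round(f * 18)
  expect_equal(out$fisherPA,
               fisher.test(matrix(c(18, 0, 6, 12), 2, byrow = TRUE))$p.value)
  expect_lt(out$fisherPA, 0.0001)
})

test_that("divergent-filter survivors are nonsynonymous shared sites", {
  cfg <- simConfig(genomeLength = c(`2R` = 2e5), sharedSpeciesFraction = 0.05,
                   seed = 23)
  sim <- simulateCohort(cfg)
  shared <- mapSharedSites(sim$sites, sim$speciesB)
  eff <- annotateEffect(sim$sites, sim$genes$cds, sim$genome)[shared$idxA]
  out <- slopeDivergentFilter(shared, eff)
  if (nrow(out)) expect_true(all(out$effect == "nonsynonymous"))
  expect_true(all(out$posA %in% shared$posA))
})
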