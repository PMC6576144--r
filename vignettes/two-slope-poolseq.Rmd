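---
title: "Two-slope pooled-sequencing analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-slope pooled-sequencing analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolSweeps)
```

## The problem

poolSweeps analyses pooled sequencing (pool-seq) of isofemale *Drosophila*
lines collected from two contrasting habitats — a mesic, "European"
north-facing slope (NFS) and a xeric, "African" south-facing slope (SFS) of
the same canyon. Each line is a pool of roughly 40 haploid genomes sequenced
to ~73x, so allele frequencies are estimated from read counts rather than
genotypes. The package asks, at genome scale: how differentiated are the two
slopes, where has recent positive selection swept diversity away in one slope
but not the other, which genes sit in those slope-prevalent sweeps, do two
co-occurring species share polymorphisms in a way that suggests convergent
local adaptation, and how do transposable-element (TE) insertions differ
between the slopes?

Because the original raw reads are not needed to exercise any of this
machinery, the package ships a synthetic cohort generator that reproduces the
study design with known ground truth. Every statistic, the sweep HMM and all
downstream scores are tested against that truth.

## Pooled diversity statistics

All estimators act on the `PoolSiteTable`, a `RangedSummarizedExperiment` of
biallelic SNP sites by pooled lines with `refDepth`/`altDepth` read-count
assays. The per-line frequency is $\hat p = a/(r+a)$; the slope-level
frequency is the depth-weighted mean over that slope's lines (an unweighted
mean is available via `weighted = FALSE`).

Per 5-kb window (100 bp for fine-scale views) and per slope we report:

* expected heterozygosity $2\hat p(1-\hat p)\cdot n/(n-1)$, averaged over the
  window's SNPs, with $n = 40$ haploids per pool;
* Watterson's $\theta_W = S/(a_n L)$, $a_n = \sum_{i=1}^{n-1} 1/i$;
* Tajima's D with the classical constants for $n$ haploids, treating the
  window's frequency-based $\pi = \sum 2\hat p(1-\hat p)\,n/(n-1)$ as the
  pairwise diversity. D needs at least three segregating sites, otherwise it
  is reported as missing (missing values are always explicit `NA`s, never
  zeros);
* the per-SNP fixation index
  $F_{ST} = (H_T - \bar H_S)/H_T$ with $H_T$ from the mean of the two slope
  frequencies, averaged per window. Sites monomorphic in both slopes are
  missing, and negative estimates are reported as computed.

These are the classical estimators applied to pooled frequency estimates.
The pool-seq literature offers additional corrections for the two-stage
(pool, then read) sampling; those corrections are deliberately out of scope
here, so absolute values on real data should be read as comparative summaries
rather than unbiased point estimates. Per-gene statistics always use the
sites inside the gene span, never window averages.

## The sweep HMM

Sweep detection follows the spectrum-based hidden Markov model approach for
pool-seq: each line is segmented independently into three hidden states over
its ordered SNP sites.

* **Neutral** emits read counts from the standard neutral spectrum
  $\xi_i \propto 1/i$ over derived-allele counts $i = 1..n-1$.
* **Selection** emits from an exponentially tilted spectrum
  $\xi_i \propto (1/i)\exp(-\gamma\,\min(i, n-i)/n)$, which moves mass to
  extreme frequencies — the post-hitchhiking signature of swept or
  nearly-swept positions. The tilt $\gamma$ (default 8) is the one free
  shape parameter; the published derivation of the Selection-state spectrum
  is not reproducible from the available description, and the exponential
  tilt preserves the method's structure while remaining fully specified.
* **Intermediate** is the renormalized elementwise geometric mean of the two.

A site with $r$ reference and $a$ alternate reads contributes the emission
$\log \sum_i \xi_i\,\mathrm{Binom}(a \mid r+a, i/n)$, computed in log space.
Sites outside the coverage bounds (defaults 5–250 reads) are ignored. The
transition matrix keeps state with probability $1-2k$ and switches with $k$
to each alternative; the default $k = 10^{-10}$ per site makes segments very
sticky, so isolated odd sites cannot open a segment. Viterbi decoding is
authoritative for region calls (forward–backward posteriors are attached for
diagnostics); maximal runs of Selection sites become regions spanning the
first to last member site, and runs below `minSites = 3` are dropped as
single-site artifacts (the source method publishes no minimum; three sites
is the smallest run that cannot be produced by one noisy site plus an
adjacent fluctuation).

Alleles are treated as polarized (alternate = derived). The synthetic truth
is generated accordingly; application to real data would need outgroup
polarization first.

## Differential sweep scores

For each gene, $N$ counts the NFS lines whose sweep regions overlap the gene
span by at least one base pair and $S$ the SFS lines; the differential sweep
score is $N - S$, ranging over $[-9, 9]$ for the 9+9 design. Overlap (rather
than full containment) matches how multi-gene sweep regions are reported in
this literature; containment is available as an option. Slope-prevalent gene
sets use the conventional threshold $|score| \ge 6$. The per-gene interslope
difference in Tajima's D is defined as $D_{NFS} - D_{SFS}$, so SFS-prevalent
sweeps (negative scores) go with positive differences, and the Spearman
correlation between score and difference is negative when sweeps are real —
a sign check the synthetic cohorts enforce in every replicate.

## Transspecies polymorphism

Two species' site tables are matched through a one-to-one coordinate map
(identity for synthetic data); a transspecies site must be biallelic in both
species with the same allele pair (swapped ref/alt labels are renormalized).
Three statistics follow:

* **Major-allele co-occurrence.** Observed: the fraction of shared sites at
  which the same nucleotide is the major allele in both species. Expected:
  the chance that two independently drawn non-shared sites (one per species)
  have the same major nucleotide, $\sum_b f_A(b) f_B(b)$ over the four bases.
  The published analysis does not define its expectation precisely, so this
  background is the package's own construction; note that sharing the allele
  pair already forces coincidence of about one half under independent
  frequencies, so the informative comparison is against the copied-frequency
  extreme, not against fold = 1.
* **Interslope-difference correlation.** Spearman correlation of
  $p_{NFS} - p_{SFS}$ between species across shared sites; near zero absent
  convergent slope adaptation.
* **Slope-divergent nonsynonymous filter.** Retains shared SNPs that are
  nonsynonymous (codon substitution, strand-aware, standard nuclear code),
  have opposite major alleles on the two slopes in each species (frequencies
  of exactly 0.5 are ties and excluded), and agree between species on which
  allele is major on which slope. Fisher's exact test on the interslope
  contrast uses haploid-equivalent counts, `round(freq * 2 * lines)`:
  pooled read counts overstate the effective sample, so counts are scaled
  to the number of sampled genomes (2 per line since each isofemale line
  descends from one inseminated female). The counting unit is configurable
  because the source analysis does not state its own.

## TE insertion analysis

Insertion records (family, chromosome, position, line, slope) are collapsed
to insertion sites; exact position identity is the default (`mergeWindow = 0`)
because synthetic calls are exact, with a merge radius available for real
callers' positional jitter. A site is *shared* when it has carriers on both
slopes. Per family we report sharing percentages, per-slope abundances, a
two-sided Fisher exact test of abundance against the slope totals, and a
Fisher test of the family's sharing rate against all other families pooled.
Two-sidedness follows the usual "sum of probabilities not exceeding the
observed table" convention. Densities are insertion sites per 100-kb window
and slope; CDS disruptions are insertions falling inside an annotated CDS
interval (1-based, boundary inclusive). Per-site interslope divergence
scores are NFS carriers minus SFS carriers, the TE analogue of the gene
sweep score.

## The synthetic cohort generator

`simConfig()` fixes the study conditions: 9 lines per slope, 40 haploids per
pool, Poisson mean depth 73, $\theta = 0.008$ per site (the SNP density of a
dense *Drosophila* cohort: roughly one SNP per 30 bp), and a migration/drift
parameter calibrated so that genome-wide mean windowed $F_{ST}$ is 0.17, the
interslope differentiation regime of the system this design emulates
(`migrationMix = 0.56`; `calibrateDivergence()` re-derives it by bisection).

For each site, an ancestral frequency is drawn from the neutral spectrum
$\xi_i \propto 1/i$ with $i/40$ support. Each slope's population frequency
then drifts from the ancestral value under a Balding–Nichols beta model with
drift strength $F = 1 - migrationMix$. A two-draw mixture of shared and
private spectrum draws was considered first but cannot exceed mean per-SNP
$F_{ST} \approx 0.15$ — below the calibration target — because two
independent neutral draws are both usually rare; Balding–Nichols drift spans
the whole $F_{ST}$ range monotonically and is the standard model for exactly
this purpose. Lines then sample a 40-haploid pool binomially and reads
binomially at Poisson depth. Identical config and seed give bit-identical
cohorts.

Planted sweeps are intervals with a retained-diversity factor
`reduction` $\in (0,1]$ (1 = no effect): a fraction $1 - reduction$ of the
interval's sites is fixed in the affected slope, and survivors are tilted
toward their *nearer* allele-frequency boundary by $q \to q^\gamma$ /
$1 \to 1-(1-q)^\gamma$ with $\gamma = 1/reduction$. Tilting toward a random
side was tried and rejected: with a rare-variant-dominated spectrum it
manufactures intermediate frequencies and *raises* Tajima's D in swept
regions, inverting the diagnostic signature; the nearer-boundary tilt
produces the canonical excess of rare plus near-fixed variants, and with it
the swept slope's D is strictly lower in every simulated replicate.

Gene models are single-CDS genes of Drosophila-like size (CDS 0.9–2.7 kb,
one gene per ~15 kb, random strand) placed without overlap; sizes matter
because per-gene Tajima's D needs enough segregating sites inside swept
spans to remain defined. TE families are assigned sites uniformly and
carriers per slope after a shared/slope-specific coin flip with the family's
sharing probability; defaults span the observed range from an old ubiquitous
family (88% shared) to recently mobile families (6–7%). The companion
species shares `sharedSpeciesFraction` (1%) of polymorphic sites with
jittered frequencies, matching major alleles with probability
`cooccurProb = 0.85` and copying the interslope split for
`convergenceProb = 0.3` of shared sites.

What the generator does *not* emulate: linkage and recombination (sites are
exchangeable given their frequencies), indels and the indel-proximity
filter's real-data behaviour, depth heterogeneity beyond Poisson, reference
bias, TE positional jitter, and real demography (the qualitative
asymmetry of migration between slopes is representable by calibrating each
slope separately but is not claimed). Passing tests therefore demonstrate
correctness of the estimators, decoder and scores under the stated sampling
model — not robustness to alignment artifacts or linkage disequilibrium.

## Numerical choices

* Emission sums, forward–backward and Viterbi run entirely in log space;
  duplicate (depth, alt) pairs are computed once per line.
* Windows tile each chromosome from position 1 without overlap; a site
  belongs to exactly one window.
* Coordinates are 1-based inclusive everywhere inside the package (VCF/GFF
  convention); BED's 0-based half-open convention exists only at the I/O
  boundary, and the conversion is involutive.
* The SNP-near-indel filter removes SNPs with $|pos_{SNP} - pos_{indel}|
  \le 10$ using the indel's leftmost reference position, boundary inclusive
  (a SNP exactly 10 bp away is removed, 11 bp is kept).
* Fisher tests with a degenerate margin return p = 1; correlations of
  constant vectors are flagged as undefined rather than returned as 0.
* Problem sizes used by the shipped checks: 1-Mb cohorts for sweep
  recovery (five seeds), 100-kb cohorts for calibration (three seeds per
  bisection step) — sizes at which every acceptance quantity is stable
  across seeds while a full run stays comfortable on one CPU.

## A worked example

```{r example, eval = FALSE}
sw <- data.frame(chrom = "2R", start = 150e3, end = 190e3,
                 reduction = 0.2, slope = "SFS")
cfg <- simConfig(genomeLength = c(`2R` = 3e5), sweeps = sw, seed = 7)
sim <- simulateCohort(cfg)

ws <- windowStats(sim$sites)               # 5-kb diversity + FST table
regs <- sweepRegionsByLine(sim$sites, hmmParams(theta = cfg@thetaPerSite))
cls <- classifyRegions(regs, setNames(slopes(sim$sites), lineIds(sim$sites)))
sc <- differentialScore(sim$genes$genes, regs,
                        setNames(slopes(sim$sites), lineIds(sim$sites)),
                        geneStats = geneStats(sim$sites, sim$genes$genes))
prevalentGenes(sc, threshold = 6)
```

## Known limitations

* Estimators omit pool-seq-specific unbiasedness corrections; real-data
  values are comparative, not absolute.
* The Selection-state spectrum is a calibrated stand-in shape, not a
  hitchhiking model fit; $\gamma$ trades sensitivity against false calls.
* Allele polarization is assumed; folded-spectrum operation is not
  implemented.
* The sharing-rate Fisher test contrasts one family against all others
  pooled; with few families the background includes substantial structure.
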