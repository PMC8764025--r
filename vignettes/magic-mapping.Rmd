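---
title: "Founder mosaics and QTL mapping in a MAGIC cotton population"
author: "magicmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder mosaics and QTL mapping in a MAGIC cotton population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A MAGIC (multi-parent advanced-generation inter-cross) population crosses a
panel of inbred founders — here eleven Upland cotton lines — in a
half-diallel, random-mates the 55 F1 families for five generations with
bulked pollen, and then selfs for six generations by single seed descent.
Each of the resulting 550 recombinant inbred lines (RILs) is a mosaic of
founder genomes broken by hundreds of accumulated recombination events.
That structure supports two complementary association strategies: a
SNP-level mixed-model GWAS (sGWAS) and a haplotype-level GWAS (hGWAS) that
tests, for each recombination-delimited bin, the identity of the founder a
RIL inherited there.  The package implements the full chain: a forward
simulator of the breeding scheme, founder-mosaic reconstruction by HMM, bin
construction, both GWAS layers with their significance rules, a two-stage
pairwise epistasis scan with variance partitioning, and post-GWAS inference
of functional alleles from parental IBD groups.

Because the original data require terabytes of resequencing, every analysis
layer here is exercised against the simulator, whose truth records (exact
founder mosaics, planted QTL effects, planted interactions) make recovery
quantifiable.

# The breeding-scheme simulator

`simulateFounders()` draws inbred founder haplotypes over a site list with a
Beta-distributed allele-frequency spectrum (monomorphic patterns redrawn);
`breedPopulation()` advances the scheme.  Haplotypes are tracked as
founder-origin segment lists at crossover resolution, so the true mosaic of
every RIL is known exactly and genotypes are realized by lookup.

Key modeling choices:

* **Crossovers** are Poisson per chromosome (mean 1.5 per meiosis, matching
  the genome-wide average recombination rate reported for this population)
  with uniform placement and no interference.  No genetic map is assumed.
* **Bulked-pollen random mating** defaults to pollen drawn uniformly from
  the whole population (`matingScope = "across"`).  A within-family variant
  is available, but under it every RIL would descend from exactly two
  founders, which contradicts the observed many-founder mosaics and the
  absence of population structure in the real RILs (first two principal
  components ~5% of variance); across-population pollen reproduces both.
* **Selfing** is single seed descent: one selfed offspring per line per
  generation.  The simulator records each RIL's pre-selfing (S0)
  heterozygosity mask.  At S0-heterozygous sites the expected heterozygous
  fraction after $g$ selfing generations is exactly $(1/2)^g$ — the
  classical halving law — which the tests verify as a log-linear decay with
  slope $-1$ and, at $g = 6$, as the ~1.56% residual heterozygosity the
  population is known for.
* **Genotype degradation** emulates ~3x-coverage calling: calls are dropped
  at a missingness rate (default 10%) and surviving calls flipped at an
  error rate (default 1%).
* **Phenotypes** are composed from planted additive QTLs, planted pure
  interactions, a polygenic background and noise.  Components are
  sequentially orthogonalized and rescaled so each realized variance
  fraction equals its target exactly; interactions are additionally
  orthogonalized against both marginal dosages, so a "pure interaction" has
  exactly zero marginal effect over the realized genotype frequencies.
  Broad-sense heritability equals the summed genetic fractions; the line
  residual is scaled to make it exact in-sample.  Multi-environment records
  add line-independent location/year/replicate effects.

The polygenic background defaults to 200 random sites with i.i.d. effects.
One caveat matters at desk scale: on a two-chromosome toy genome the
linkage-disequilibrium window is a sizable share of the genome, so even a
"background" site is locally taggable by a bin.  Calibration experiments
(type-I error of the permutation threshold) therefore use a 26-chromosome
layout — 13 A-subgenome and 13 D-subgenome chromosomes, as in
allotetraploid cotton — and spread the background over all sites, which
reproduces the paper-scale regime where no single bin tags a detectable
polygenic share.  Signal-recovery experiments use the default two-chromosome
fixture, where this distortion is irrelevant.

**Fixture sizes.** The default desk fixture is 11 founders, two 60-Mb
chromosomes (one A, one D), 5,000 SNPs and 330 RILs (55 families x 6
lines).  The selfing-heterozygosity and threshold-calibration runs use the
26 x 25-Mb layout with ~2,600 SNPs and 550 or 200 RILs.  These sizes were
chosen so every property of interest is measured with adequate replication
on a single CPU.

# Founder-mosaic reconstruction

`inferMosaic()` runs a hidden Markov model per RIL and chromosome with the
K founders as states.

* **Emission.**  With error rate $\varepsilon$ (default 0.01), a homozygous
  RIL call matching a homozygous founder call emits $1-\varepsilon$, a
  mismatch emits $\varepsilon$; a heterozygous call on either side emits the
  half-match average $\tfrac12(1-\varepsilon)+\tfrac12\varepsilon$
  (heterozygous founder calls average their two alleles); missing calls
  emit 1.  Residual heterozygosity (~1.6%) is thus near-uninformative
  rather than penalized.
* **Transition.**  Between adjacent SNPs at distance $d$,
  $r = 1 - e^{-G c d}$ with $c$ the per-bp crossover rate (1.5 divided by
  the chromosome length) and $G$ the effective number of meioses.  The
  default $G = 11$ reflects the eleven generations of population
  development (5 random-mating + 6 selfing); the true effective count per
  lineage is larger but unknown, and recovery is insensitive to factor-2
  changes in $G$.  A stay keeps the founder, a switch is uniform over the
  other $K-1$.
* **Single-path approximation.**  The chain runs on the diploid call
  against homozygous-founder expectations rather than as a $K^2$ diplotype
  model; after six selfing generations the heterozygous fraction is small
  enough that the extra states buy little and cost a factor $K$ squared.
* Forward–backward is computed with per-site scaling; posteriors are exact
  (they match exhaustive path enumeration on small toys to 1e-9).

`callSegments()` labels each site with the argmax founder only when its
posterior exceeds $m/K$ (default $m = 2$: twice the uniform prior), else
"unknown"; ties break to the lowest founder index.  Runs of one label
become IBD segments with boundaries at midpoints between adjacent sites.
On the default fixture (10% missingness, 1% error) ~98% of the assigned
genome carries the true founder label.

`breakpointsHotspots()` pools the internal boundaries between
differently-labelled segments per RIL.  Boundaries flanking "unknown"
segments are excluded by default — they reflect assignment failure, not
recombination — with a switch to keep them.  Events are counted in sliding
windows (default 2 Mb window, 1 Mb step; both reported usages are exposed)
and a window with more than 50 events (strictly greater) is a hotspot.

# Bin-level haplotype GWAS

`buildBins()` takes the union of all RILs' segment boundaries per
chromosome; within a bin each RIL has exactly one founder state, and
adjacent bins with identical state vectors are merged.  Unknown states
become all-zero rows of the founder-indicator (dummy) design — they
contribute to the null but not to founder contrasts.

`binScan()` fits, per bin,
$y = X\beta + u_{bin} + u_{poly} + e$ with
$u_{bin} \sim N(0, \sigma_b^2 ZZ')$, $u_{poly} \sim N(0, \sigma_g^2 K)$,
and reports the REML likelihood ratio against the model without $u_{bin}$,
floored at zero.  $X$ is an intercept plus (optionally) the top 10
principal components; $K$ is the VanRaden kinship from MAF-filtered SNPs.
Numerically, $K$ is eigendecomposed once per trait, the polygenic ratio
$\lambda_g$ is fixed at its null-model REML estimate, the data are whitened
by $I + \lambda_g D$, and each bin's profiled 1-D likelihood in the bin
ratio follows from the Woodbury identity through the $K$ eigenvalues of the
projected indicator cross-product.  A coarse grid bounds each bin's
optimum and a Brent refinement sharpens it ("all" bins for observed scans,
the genome-wide maximum for permutation scans).  The grid/refine scheme and
the λ-profiling were validated against dense two-parameter grid searches of
the full restricted likelihood.

`permutationThresholds()` shuffles the phenotype across RILs, re-runs the
scan, and records the genome-wide maximum LRT per permutation.  Thresholds
are the nearest-rank 95th (significant) and 37th (suggestive) percentiles
of the permuted maxima; the 37th-percentile choice corresponds to roughly
one expected false positive per genome scan.  Percentiles are taken over
per-permutation maxima rather than pooled scores — the standard
genome-wide-error reading.  The polygenic ratio is held at the
observed-data estimate during permutations (refitting per permutation is
available and changes thresholds negligibly).

`callHqtl()` seeds loci with bins above the suggestive threshold and merges
bins separated by at most 1 Mb or at most 5 intervening bins; the peak bin
carries the locus statistic and a locus is flagged significant when its
peak clears the 95% threshold.  Single-locus PVE is the covariate-adjusted
R² of the phenotype on the peak bin's founder indicators; a joint
multi-locus PVE uses all peak bins at once.

# SNP-level mixed-model GWAS

`lmmAssoc()` standardizes the phenotype to unit variance (so effects are in
trait-SD units) and fits $y = \mu + x\beta + u + e$,
$u \sim N(0, \sigma_g^2 K)$.  Variance components are estimated once on the
SNP-free null model and reused for every SNP — the
population-parameters-previously-determined (EMMAX-style) approximation —
with an exact per-SNP REML mode retained for validation.  With $K = I$ the
model collapses to per-SNP ordinary least squares, which the tests assert
exactly.  Genomic-control lambda on simulated MAGIC populations stays
within [0.9, 1.1]: the polygenic term absorbs the family relatedness.  No
principal-component covariates are included by default (they are reserved
for the bin-level scan); a covariate argument exists.

The genome-wide threshold is $1/n$ with $n$ the total SNP count.
`callSqtl()` groups significant SNPs by single linkage at gaps strictly
below 700 kb, then repeatedly merges adjacent clusters whenever any
cross-cluster pair of significant SNPs has $r^2 \ge 0.4$; the peak SNP is
the minimum-P member and the interval the span of member SNPs.

# Epistasis

`pruneForEpistasis()` removes MAF < 5% sites and LD-prunes with a 50-kb
window, 5-SNP step and $r^2 < 0.5$ bound, dropping the lower-MAF member of
each offending pair (ties: the downstream one); a final single-step sweep
guarantees no surviving within-window pair violates the bound, which the
tests audit independently.

`pairwiseScan()` (stage 1) t-tests the interaction coefficient of
$y \sim x_1 + x_2 + x_1 x_2$ for every pruned pair by exact least squares,
organized as cross-products of the dosage matrix with a handful of
n-vectors per anchor SNP so that ~10⁶ pairs run in seconds; pairs with
interaction $P \le 10^{-4}$ survive.  A perfectly fitting interaction
(zero residual) is kept with $P = 0$ rather than skipped; genuinely
collinear pairs are counted and dropped.  Stage 2 (`confirmPairs()`)
refits candidates with population-structure covariates, multiplies the
interaction P by the number of candidates (Bonferroni over the
candidate set, not over all possible pairs) and keeps adjusted $P < 0.01$.

`interactionPve()` residualizes both the phenotype and the product term on
the covariates and marginal dosages and reports the explained share of the
total phenotypic sum of squares.  `classifyPair()` maps a pair to AA/AD/DD
by the subgenomes of its chromosomes; `linkToSqtl()` flags pairs whose
bin-delimited locus intervals overlap same-trait sQTLs; and
`recombinantFractionComparison()` contrasts, per pair, the fraction of RILs
with a breakpoint inside either interval against random interval pairs
matched for width and (within chromosomes) separation, with a two-sided
rank-sum test.

# Multi-environment phenotypes

`fitBlup()` reproduces the study's mixed model term for term:
`value ~ (1|line) + (1|location) + (1|year) + (1|replicate:location:year) +
(1|line:location) + (1|line:year)`, fitted by REML with lme4.  Terms whose
grouping factor collapses to one level are dropped with a warning; with no
replication at all the BLUP degenerates to the centered raw value with a
flag.  Broad-sense heritability uses the line-mean form
$H^2 = \sigma^2_{line} / (\sigma^2_{line} + \sigma^2_{l \times loc}/L +
\sigma^2_{l \times yr}/Y + \sigma^2_e/(LYR))$ with harmonic-mean design
numbers — the source study reports heritabilities without defining the
estimator, so the estimator here is declared, not inferred.  In balanced
one-way designs the BLUPs match the closed-form shrinkage
$\frac{r\sigma^2_g}{r\sigma^2_g + \sigma^2_e}(\bar y_i - \bar y)$, which
anchors the tests.

# SNP annotation, PCA, LD

`annotateSnps()` classifies sites with the precedence exonic > splicing >
intronic > upstream/downstream (1 kb) > intergenic, where splicing means
within 2 bp of a splice junction; because reported splicing variants occur
on both sides of junctions, a separate flag marks junction-proximal exonic
variants while the primary class follows the precedence.  Coding
consequences come from translating the reference and alternate codons on
the annotated strand (synonymous / non-synonymous / stop-gain / stop-loss,
amino-acid change 1-based in protein coordinates); CDS lengths not
divisible by 3 skip the transcript with a warning.

`genoPca()` uses standardized, mean-imputed dosages and the SVD;
`ldDecay()` averages squared Pearson correlations of dosages (the
PLINK-compatible allele-count r²) in 5-kb distance bins to 2 Mb and reports
the halving distance — the smallest distance where the smoothed curve first
drops below half its maximum (the curve maximum, not a theoretical
zero-distance value) — together with the r² there.

# Functional-allele inference

`groupByIbd()` groups RILs by their founder state at the peak bin(s) of a
QTL (with several peak bins, only RILs whose states agree are grouped);
groups of at most 3 RILs are dropped.  Group means are compared by one-way
ANOVA, and each group against the whole population by a two-sided Welch
t-test (the unequal-variance form of the Student test).
`diagnosticSnps()` tests genotype-count tables of two contrasting groups
with a two-sided Fisher exact test — the frequency-shift claim in the
source study names no test, so the operationalization is declared here —
and reports modal genotypes with frequencies.  `defineAlleles()` builds
haplotype strings from a defining SNP set (e.g. the non-synonymous SNPs of
a candidate gene), excluding heterozygous or missing carriers, keeps
alleles with more than 3 carriers and contrasts them with t-tests.

# Numerical and degenerate-input conventions

Interval objects are GRanges (1-based, closed) throughout; BED output is
converted to 0-based half-open at the writer and the conversion is
unit-tested in both directions.  Posterior rows are normalized to sum to 1
(checked to 1e-9); REML optimizations use Brent's method at tolerance 1e-8
with an explicit boundary check at $\lambda = 0$; LRTs are floored at 0;
argmax ties break deterministically to the lowest index; monomorphic SNPs
and single-state bins are skipped with logged counts; all-missing RILs get
a flagged uniform posterior.  Every stochastic function takes a `seed`
argument feeding the global RNG, and `magicConfig()` /
`writeConfig()` round-trip the full parameter set through YAML.

# What the tests do and do not show

All truth-recovery claims are made against the simulator.  It emulates the
breeding design, recombination counts, residual heterozygosity,
low-coverage degradation and planted architectures, but not allele-sharing
between founders from shared ancestry (founder haplotypes are exchangeable
draws), reference bias, segregation distortion, or selection during
population development — the ~24% of the real genome untraceable to a
single parent is therefore underrepresented, and real-data unknown
fractions will be higher than the simulator's.  Passing tests show the
algorithms implement their models correctly and recover what they planted;
they do not certify performance on data whose violations of these
assumptions are material.

# Known limitations

* The HMM is single-path; strongly heterozygous material (early
  generations, outcrossers) needs the diplotype extension that is out of
  scope here.
* Permutation thresholds assume exchangeability of line values; under
  strong polygenic dependence on small toy genomes they are mildly
  anti-conservative (see the calibration discussion above).
* Founder residual heterozygosity affects founder genotype calls but
  transmission draws from the first haplotype; at the default (fully
  inbred) setting this is immaterial.
* `lmmAssoc()`'s default path fixes variance components at the null
  estimate; strongly associated SNPs slightly inflate the residual and the
  exact mode should be used for final effect estimates at top hits.
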