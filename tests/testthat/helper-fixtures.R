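## Shared fixtures, built once per test run and cached.

.fxCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (is.null(.fxCache[[name]])) assign(name, force(expr), envir = .fxCache)
  .fxCache[[name]]
}

## mid-size population reused across GWAS-level tests: 11 founders,
## 2 x 60 Mb chromosomes, 1500 SNPs, 220 RILs
deskFixture <- function() cachedFixture("desk", {
  fx <- magicFixture(seed = 101, nSites = 1500, linesPerFamily = 4)
  fx$truth <- trueSegments(fx$pop)
  fx$K <- kinshipMatrix(fx$gm)
  fx$Keig <- kinshipEigen(fx$K)
  fx
})

## small population for quick structural tests: 4 founders, 40 RILs
smallFixture <- function() cachedFixture("small", {
  set.seed(7)
  layout <- GenomeLayout(c("A01", "D01"), c(2e7, 2e7))
  panel <- simulateFounders(layout, nFounders = 4, nSites = 400)
  pop <- breedPopulation(panel, nRandomMating = 2, nSelfing = 4,
                         linesPerFamily = 8, popPerFamily = 10)
  list(layout = layout, panel = panel, pop = pop,
       gm = realizeGenotypes(pop), truth = trueSegments(pop))
})

## build a GenotypeMatrix by hand
tinyGm <- function(calls, pos = NULL, chrom = "A01", layout = NULL,
                   ref = NULL, alt = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("S", seq_len(ncol(calls)))
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                                  ref = ref, alt = alt)
  GenotypeMatrix(calls, sites, layout)
}

## build an IBD segment GRanges by hand from (chrom, start, end, ril,
## founder) rows
segGr <- function(df, layout = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start, df$end), ril = df$ril, founder = df$founder)
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- layout@chrom
    GenomeInfoDb::seqinfo(gr) <- asSeqinfo(layout)
  }
  gr
}

## length-weighted agreement between called and true segments, plus the
## fraction of the genome confidently assigned
mosaicAccuracy <- function(called, truth, layout) {
  md <- S4Vectors::mcols(called)
  tmd <- S4Vectors::mcols(truth)
  correct <- 0; assigned <- 0
  for (r in unique(md$ril)) {
    s <- called[md$ril == r & md$founder != "unknown"]
    t <- truth[tmd$ril == r]
    ov <- GenomicRanges::findOverlaps(s, t)
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      s[S4Vectors::queryHits(ov)], t[S4Vectors::subjectHits(ov)]))
    ok <- S4Vectors::mcols(s)$founder[S4Vectors::queryHits(ov)] ==
      S4Vectors::mcols(t)$founder[S4Vectors::subjectHits(ov)]
    correct <- correct + sum(w[ok])
    assigned <- assigned + sum(w)
  }
  nRil <- length(unique(md$ril))
  list(accuracy = correct / assigned,
       assignedFraction = assigned / (sum(chromLengths(layout)) * nRil))
}

## per-RIL founder contribution matrix (percent) from a segment set
contributionMatrix <- function(segments, founders) {
  md <- S4Vectors::mcols(segments)
  w <- GenomicRanges::width(segments)
  rils <- unique(md$ril)
  out <- matrix(0, length(rils), length(founders),
                dimnames = list(rils, founders))
  for (i in seq_along(rils)) {
    sel <- md$ril == rils[i]
    tot <- sum(w[sel])
    for (f in founders)
      out[i, f] <- 100 * sum(w[sel & md$founder == f]) / tot
  }
  out
}
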