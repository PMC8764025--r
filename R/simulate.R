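## Forward simulator of the MAGIC breeding scheme: inbred founders crossed in
## a half-diallel, bulked-pollen random mating, then single-seed-descent
## selfing.  Haplotypes are tracked as founder-origin segment lists at
## crossover resolution, which makes the true mosaic of every RIL available
## exactly.

#' Founder panel: inbred founder haplotypes over a shared site list
#'
#' @slot hapA,hapB integer matrices (founders x sites) of haploid alt-allele
#'   dosages (0/1).  For fully inbred founders the two are identical; a
#'   residual-heterozygosity parameter > 0 makes them differ at a random
#'   subset of sites (founder genotype calls are then heterozygous there).
#' @slot sites GRanges of SNP positions with ref/alt alleles.
#' @slot ids founder labels.
#' @slot layout the \linkS4class{GenomeLayout}.
#' @export
setClass("FounderPanel",
  representation(hapA = "matrix", hapB = "matrix", sites = "GRanges",
                 ids = "character", layout = "GenomeLayout"))

setValidity("FounderPanel", function(object) {
  msg <- character()
  if (ncol(object@hapA) != length(object@sites))
    msg <- c(msg, "haplotype length must equal site count")
  if (!identical(dim(object@hapA), dim(object@hapB)))
    msg <- c(msg, "hapA and hapB must have identical dimensions")
  if (nrow(object@hapA) != length(object@ids))
    msg <- c(msg, "one haplotype pair per founder ID")
  if (!all(object@hapA %in% 0:1) || !all(object@hapB %in% 0:1))
    msg <- c(msg, "haploid alleles must be 0 (ref) or 1 (alt)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FounderPanel", function(object) {
  cat("FounderPanel:", length(object@ids), "founders x",
      length(object@sites), "sites\n")
})

#' Simulate an inbred founder panel
#'
#' Site positions are drawn uniformly along each chromosome (proportional to
#' length); founder alleles at each site are Bernoulli draws from a
#' Beta-distributed allele frequency, with monomorphic site patterns
#' redrawn so every site segregates among the founders.
#'
#' @param layout a \linkS4class{GenomeLayout}
#' @param nFounders number of founders (default 11)
#' @param nSites number of SNPs (default 5000)
#' @param residualHet per-founder fraction of sites left heterozygous
#'   (default 0: fully inbred)
#' @param betaShape shape of the symmetric Beta allele-frequency spectrum
#' @param seed optional seed (sets the global RNG)
#' @return a \linkS4class{FounderPanel}
#' @export
simulateFounders <- function(layout, nFounders = 11L, nSites = 5000L,
                             residualHet = 0, betaShape = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- chromLengths(layout)
  nPer <- pmax(2L, round(nSites * lens / sum(lens)))
  pos <- lapply(seq_along(lens), function(i)
    sort(sample.int(lens[i] - 2L, nPer[i]) + 1L))
  sites <- GenomicRanges::GRanges(
    rep(names(lens), lengths(pos)),
    IRanges::IRanges(unlist(pos), width = 1L))
  n <- length(sites)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  S4Vectors::mcols(sites)$ref <- ref
  S4Vectors::mcols(sites)$alt <- unname(alt)
  hap <- matrix(0L, nFounders, n)
  todo <- seq_len(n)
  while (length(todo)) {
    p <- stats::rbeta(length(todo), betaShape, betaShape)
    hap[, todo] <- rbinom(nFounders * length(todo), 1L, rep(p, each = nFounders))
    cs <- colSums(hap[, todo, drop = FALSE])
    todo <- todo[cs == 0L | cs == nFounders]
  }
  hapB <- hap
  if (residualHet > 0) {
    flip <- matrix(rbinom(length(hap), 1L, residualHet) == 1L,
                   nrow = nFounders)
    hapB[flip] <- 1L - hapB[flip]
  }
  ids <- paste0("P", seq_len(nFounders))
  rownames(hap) <- rownames(hapB) <- ids
  new("FounderPanel", hapA = hap, hapB = hapB, sites = sites, ids = ids,
      layout = layout)
}

#' All unordered founder pairs of a half-diallel
#'
#' @param n number of founders (>= 2)
#' @return two-column matrix of founder indices, one row per cross; no selfs,
#'   no reciprocals, n(n-1)/2 rows
#' @examples
#' nrow(halfDiallelPairs(11))  # 55
#' @export
halfDiallelPairs <- function(n) {
  if (n < 2L) stop("a half-diallel needs at least 2 founders")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(p1 = idx[, "row"], p2 = idx[, "col"])[order(idx[, "row"], idx[, "col"]), ,
                                              drop = FALSE]
}

## -- haplotype segment machinery ------------------------------------------
## A haplotype is, per chromosome, list(end = segment end positions (bp,
## 1-based closed, last = chromosome length), origin = founder index).

pureHap <- function(founder, layout) {
  lens <- chromLengths(layout)
  lapply(lens, function(L) list(end = as.numeric(L), origin = as.integer(founder)))
}

originAt <- function(chromHap, pos) {
  chromHap$origin[findInterval(pos - 0.5, chromHap$end) + 1L]
}

mergeRuns <- function(end, origin) {
  if (length(origin) > 1L) {
    keep <- c(origin[-1L] != origin[-length(origin)], TRUE)
    end <- end[keep]; origin <- origin[keep]
  }
  list(end = end, origin = origin)
}

hapSlice <- function(chromHap, from, to) {
  i1 <- findInterval(from - 0.5, chromHap$end) + 1L
  i2 <- findInterval(to - 0.5, chromHap$end) + 1L
  end <- chromHap$end[i1:i2]
  end[length(end)] <- to
  list(end = end, origin = chromHap$origin[i1:i2])
}

recombineChrom <- function(hA, hB, xo, startFirst, chromLen) {
  if (!length(xo)) return(if (startFirst) hA else hB)
  bounds <- c(xo, chromLen)
  cur <- startFirst
  ends <- numeric(0); orig <- integer(0)
  from <- 1
  for (b in bounds) {
    src <- if (cur) hA else hB
    sl <- hapSlice(src, from, b)
    ends <- c(ends, sl$end); orig <- c(orig, sl$origin)
    from <- b + 1
    cur <- !cur
  }
  mergeRuns(ends, orig)
}

#' Simulate one meiosis of a diploid parent
#'
#' Crossover counts per chromosome are Poisson with the given mean, crossover
#' positions are uniform along the chromosome (no interference), and the
#' gamete alternates between the two parental haplotypes at crossovers,
#' starting from a random one.
#'
#' @param individual list with elements \code{h1}, \code{h2} (haplotype
#'   segment lists as produced by the breeding functions)
#' @param layout a \linkS4class{GenomeLayout}
#' @param xoverPerChrom mean crossovers per chromosome per meiosis
#'   (default 1.5)
#' @return list with \code{hap} (gamete haplotype) and \code{crossovers}
#'   (numeric positions per chromosome)
#' @export
simulateMeiosis <- function(individual, layout, xoverPerChrom = 1.5) {
  lens <- chromLengths(layout)
  xos <- vector("list", length(lens)); names(xos) <- names(lens)
  hap <- vector("list", length(lens)); names(hap) <- names(lens)
  for (i in seq_along(lens)) {
    L <- lens[i]
    nx <- rpois(1L, xoverPerChrom)
    xo <- if (nx > 0L) sort(unique(ceiling(runif(nx, 1, L - 1)))) else numeric(0)
    xos[[i]] <- xo
    hap[[i]] <- recombineChrom(individual$h1[[i]], individual$h2[[i]], xo,
                               runif(1L) < 0.5, L)
  }
  list(hap = hap, crossovers = xos)
}

#' MAGIC population with true founder mosaics
#'
#' Result of \code{\link{breedPopulation}}: the final RILs' haplotype pairs as
#' founder-origin segment lists (the exact truth every reconstruction method
#' is benchmarked against), the founder panel, the family of origin of each
#' RIL, the heterozygosity mask of each RIL's pre-selfing (S0) ancestor, and
#' optionally the per-generation heterozygosity trajectory during selfing.
#'
#' @slot panel the \linkS4class{FounderPanel}
#' @slot haplotypes list (one per RIL) of \code{list(h1, h2)} segment lists
#' @slot rilIds RIL labels
#' @slot families two-column matrix of founder indices per RIL (the cross the
#'   RIL's seed-parent lineage descends from)
#' @slot s0Het logical matrix (sites x RILs): TRUE where the RIL's S0
#'   ancestor was heterozygous
#' @slot hetHistory numeric matrix (selfing generation 0..S x RILs) of
#'   heterozygous fractions at S0-heterozygous sites, or a 0-row matrix when
#'   not tracked
#' @export
setClass("MagicPopulation",
  representation(panel = "FounderPanel", haplotypes = "list",
                 rilIds = "character", families = "matrix",
                 s0Het = "matrix", hetHistory = "matrix"))

setMethod("show", "MagicPopulation", function(object) {
  cat("MagicPopulation:", length(object@rilIds), "RILs from",
      nrow(unique(object@families)), "families,",
      length(object@panel@ids), "founders\n")
})

hapAlleles <- function(hap, panel) {
  ## haploid alt dosages of one haplotype over the panel's site list
  rr <- panel@sites
  chr <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  out <- integer(length(rr))
  for (cc in names(hap)) {
    i <- which(chr == cc)
    o <- originAt(hap[[cc]], pos[i])
    out[i] <- panel@hapA[cbind(o, i)]
  }
  out
}

rilCalls <- function(ind, panel) {
  hapAlleles(ind$h1, panel) + hapAlleles(ind$h2, panel)
}

hetMask <- function(ind, panel) {
  hapAlleles(ind$h1, panel) != hapAlleles(ind$h2, panel)
}

#' Breed a MAGIC population
#'
#' Implements the breeding scheme: all half-diallel F1 crosses found the
#' population; bulked-pollen random mating runs for \code{nRandomMating}
#' generations (each seed parent is pollinated by a gamete from a random
#' individual of the pollen pool); then \code{linesPerFamily} lines per
#' family are advanced by \code{nSelfing} generations of single-seed-descent
#' selfing.
#'
#' @param panel a \linkS4class{FounderPanel}
#' @param nRandomMating random-mating generations (default 5)
#' @param nSelfing selfing generations (default 6)
#' @param linesPerFamily lines sampled per founding family (default 10)
#' @param popPerFamily individuals maintained per family during random
#'   mating (default 20)
#' @param xoverPerChrom mean crossovers per chromosome per meiosis
#'   (default 1.5)
#' @param matingScope \code{"across"} (default): pollen is bulked over the
#'   whole population; \code{"within"}: pollen comes from the seed parent's
#'   own founding family.
#' @param trackHet record the heterozygous fraction at S0-heterozygous sites
#'   for every selfing generation (used by the selfing-decay diagnostics)
#' @param seed optional seed (sets the global RNG)
#' @return a \linkS4class{MagicPopulation}
#' @export
breedPopulation <- function(panel, nRandomMating = 5L, nSelfing = 6L,
                            linesPerFamily = 10L, popPerFamily = 20L,
                            xoverPerChrom = 1.5,
                            matingScope = c("across", "within"),
                            trackHet = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matingScope <- match.arg(matingScope)
  layout <- panel@layout
  fam <- halfDiallelPairs(length(panel@ids))
  nFam <- nrow(fam)

  gam <- function(ind) simulateMeiosis(ind, layout, xoverPerChrom)$hap
  ## founding F1 populations: every individual of family f is the identical
  ## F1 of founders fam[f, ]
  pops <- lapply(seq_len(nFam), function(f)
    replicate(popPerFamily,
              list(h1 = pureHap(fam[f, 1L], layout),
                   h2 = pureHap(fam[f, 2L], layout)),
              simplify = FALSE))

  for (g in seq_len(nRandomMating)) {
    flat <- unlist(pops, recursive = FALSE)
    pops <- lapply(seq_len(nFam), function(f) {
      lapply(seq_len(popPerFamily), function(k) {
        mother <- pops[[f]][[sample.int(popPerFamily, 1L)]]
        father <- if (matingScope == "across")
          flat[[sample.int(length(flat), 1L)]]
        else pops[[f]][[sample.int(popPerFamily, 1L)]]
        list(h1 = gam(mother), h2 = gam(father))
      })
    })
  }

  ## select lines per family and self by single seed descent
  lines <- list(); famOf <- integer(0)
  for (f in seq_len(nFam)) {
    pick <- sample.int(popPerFamily, min(linesPerFamily, popPerFamily))
    if (linesPerFamily > popPerFamily)
      pick <- c(pick, sample.int(popPerFamily, linesPerFamily - popPerFamily,
                                 replace = TRUE))
    lines <- c(lines, pops[[f]][pick])
    famOf <- c(famOf, rep(f, linesPerFamily))
  }
  nRil <- length(lines)
  s0Het <- vapply(lines, hetMask, logical(length(panel@sites)), panel = panel)

  hetHist <- NULL
  if (trackHet) {
    hetHist <- matrix(NA_real_, nSelfing + 1L, nRil)
    hetHist[1L, ] <- 1
  }
  for (s in seq_len(nSelfing)) {
    lines <- lapply(lines, function(ind) list(h1 = gam(ind), h2 = gam(ind)))
    if (trackHet)
      hetHist[s + 1L, ] <- vapply(seq_len(nRil), function(i) {
        m <- hetMask(lines[[i]], panel)
        if (any(s0Het[, i])) mean(m[s0Het[, i]]) else NA_real_
      }, numeric(1))
  }

  ids <- sprintf("RIL%03d", seq_len(nRil))
  colnames(s0Het) <- ids
  famMat <- fam[famOf, , drop = FALSE]
  rownames(famMat) <- ids
  new("MagicPopulation", panel = panel, haplotypes = lines, rilIds = ids,
      families = famMat, s0Het = s0Het,
      hetHistory = if (trackHet) hetHist else matrix(numeric(0), 0, 0))
}

#' Realize true genotype calls of a MAGIC population
#'
#' @param pop a \linkS4class{MagicPopulation}
#' @return a \linkS4class{GenotypeMatrix} of error-free calls
#' @export
realizeGenotypes <- function(pop) {
  calls <- vapply(pop@haplotypes, rilCalls, integer(length(pop@panel@sites)),
                  panel = pop@panel)
  colnames(calls) <- pop@rilIds
  GenotypeMatrix(calls, pop@panel@sites, pop@panel@layout)
}

#' Founder genotype calls of the panel
#'
#' @param panel a \linkS4class{FounderPanel}
#' @return a \linkS4class{GenotypeMatrix} (founders as samples); residual
#'   founder heterozygosity shows up as het calls
#' @export
founderGenotypes <- function(panel) {
  calls <- t(panel@hapA + panel@hapB)
  colnames(calls) <- panel@ids
  GenotypeMatrix(calls, panel@sites, panel@layout)
}

#' True founder-mosaic segments of every RIL
#'
#' The two haplotypes of a RIL are overlaid; where they carry the same
#' founder the consensus label is that founder, where they differ (residual
#' heterozygous stretches) the label is \code{"unknown"}.  This is the truth
#' object the HMM reconstruction and the bin map are benchmarked against.
#'
#' @param pop a \linkS4class{MagicPopulation}
#' @return GRanges with mcols \code{ril}, \code{founder}
#' @export
trueSegments <- function(pop) {
  layout <- pop@panel@layout
  lens <- chromLengths(layout)
  ids <- pop@panel@ids
  out <- vector("list", length(pop@rilIds) * length(lens)); k <- 0L
  for (i in seq_along(pop@rilIds)) {
    ind <- pop@haplotypes[[i]]
    for (cc in names(lens)) {
      h1 <- ind$h1[[cc]]; h2 <- ind$h2[[cc]]
      ends <- sort(unique(c(h1$end, h2$end)))
      o1 <- originAt(h1, ends); o2 <- originAt(h2, ends)
      lab <- ifelse(o1 == o2, ids[o1], "unknown")
      m <- mergeRuns(ends, factor(lab, levels = c(ids, "unknown")))
      st <- c(1, head(m$end, -1) + 1)
      k <- k + 1L
      out[[k]] <- GenomicRanges::GRanges(cc, IRanges::IRanges(st, m$end),
        ril = pop@rilIds[i], founder = as.character(m$origin))
    }
  }
  gr <- suppressWarnings(do.call(c, out[seq_len(k)]))
  GenomeInfoDb::seqlevels(gr) <- layout@chrom
  GenomeInfoDb::seqinfo(gr) <- asSeqinfo(layout)
  gr
}

#' Degrade genotype calls with missingness and error
#'
#' Each call is independently set missing with \code{missingRate}; each
#' surviving call is flipped to one of the two other states with
#' \code{errorRate}, emulating low-coverage genotyping.
#'
#' @param gm a \linkS4class{GenotypeMatrix} of true calls
#' @param missingRate probability a call is dropped
#' @param errorRate probability a surviving call is mis-called
#' @param seed optional seed (sets the global RNG)
#' @return a degraded \linkS4class{GenotypeMatrix}
#' @export
degradeGenotypes <- function(gm, missingRate = 0.1, errorRate = 0.01,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(missingRate >= 0, missingRate <= 1, errorRate >= 0, errorRate <= 1)
  cl <- genotypeCalls(gm)
  n <- length(cl)
  if (missingRate > 0) cl[runif(n) < missingRate] <- NA_integer_
  if (errorRate > 0) {
    hit <- which(!is.na(cl) & runif(n) < errorRate)
    if (length(hit)) {
      shift <- sample.int(2L, length(hit), replace = TRUE)
      cl[hit] <- (cl[hit] + shift) %% 3L
    }
  }
  GenotypeMatrix(cl, siteRanges(gm))
}

#' Simulate phenotypes with a planted genetic architecture
#'
#' The genetic value of each line is a sum of planted additive QTL terms,
#' planted pairwise-interaction terms and a polygenic background.  Components
#' are sequentially orthogonalized (interactions additionally against both
#' marginal dosages, making them pure interactions over the realized
#' genotype frequencies) and rescaled so each component's realized variance
#' fraction equals its target exactly; the non-genetic line residual is
#' likewise orthogonalized and scaled so broad-sense heritability is exact
#' in-sample.  Plot-level records add line-independent location/year/
#' replicate effects and plot noise.
#'
#' @param gm \linkS4class{GenotypeMatrix} of true line genotypes
#' @param qtl data.frame with columns \code{site} (row index into \code{gm})
#'   and \code{pve}, or NULL
#' @param epi data.frame with columns \code{site1}, \code{site2}, \code{pve},
#'   or NULL
#' @param h2 broad-sense heritability of the line value (total genetic PVE)
#' @param polygenicPve variance fraction of the polygenic background; default
#'   fills the gap between the planted terms and \code{h2}
#' @param polygenicSites number of background sites (default 200)
#' @param env list with \code{L}, \code{Y}, \code{R} (locations, years,
#'   replicates) and variance components \code{varLocation}, \code{varYear},
#'   \code{varRep} in line-variance units
#' @param seed optional seed (sets the global RNG)
#' @return list with \code{pheno} (long-format plot records), \code{lineValues}
#'   (named per-line genetic value + line residual), and \code{truth}
#'   (planted sites, realized effects and variance fractions)
#' @export
simulatePhenotypes <- function(gm, qtl = NULL, epi = NULL, h2 = 0.6,
                               polygenicPve = NULL, polygenicSites = 200L,
                               env = list(L = 1L, Y = 1L, R = 1L,
                                          varLocation = 0, varYear = 0,
                                          varRep = 0),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- t(genotypeCalls(gm))          # lines x sites
  n <- nrow(X)
  planted <- sum(qtl$pve %||% 0) + sum(epi$pve %||% 0)
  if (is.null(polygenicPve)) polygenicPve <- max(0, h2 - planted)
  if (planted + polygenicPve > min(1, h2 + 1e-12))
    stop("requested total PVE exceeds the heritability budget")
  basis <- matrix(1, n, 1L)          # orthogonalization basis so far
  comps <- NULL
  addComp <- function(v, extra = NULL, pve) {
    B <- cbind(basis, extra)
    r <- stats::lsfit(B, v, intercept = FALSE)$residuals
    if (var(r) < 1e-12) stop("planted component is collinear with the rest")
    scl <- sqrt(pve / var(r))
    list(comp = r * scl, scale = scl)
  }
  truthQtl <- truthEpi <- NULL
  if (!is.null(qtl) && nrow(qtl)) {
    truthQtl <- qtl
    truthQtl$effect <- NA_real_
    for (k in seq_len(nrow(qtl))) {
      x <- X[, qtl$site[k]]
      a <- addComp(x, pve = qtl$pve[k])
      comps <- cbind(comps, a$comp); basis <- cbind(basis, a$comp)
      truthQtl$effect[k] <- a$scale
    }
  }
  if (!is.null(epi) && nrow(epi)) {
    truthEpi <- epi
    truthEpi$effect <- NA_real_
    for (k in seq_len(nrow(epi))) {
      x1 <- X[, epi$site1[k]]; x2 <- X[, epi$site2[k]]
      a <- addComp(x1 * x2, extra = cbind(x1, x2), pve = epi$pve[k])
      comps <- cbind(comps, a$comp); basis <- cbind(basis, a$comp)
      truthEpi$effect[k] <- a$scale
    }
  }
  polySites <- integer(0)
  if (polygenicPve > 0) {
    polySites <- sample.int(ncol(X), min(polygenicSites, ncol(X)))
    z <- X[, polySites, drop = FALSE] %*% rnorm(length(polySites))
    a <- addComp(drop(z), pve = polygenicPve)
    comps <- cbind(comps, a$comp); basis <- cbind(basis, a$comp)
  }
  g <- if (is.null(comps)) numeric(n) else rowSums(comps)
  residVar <- 1 - (planted + polygenicPve)
  eLine <- if (residVar > 0) {
    r <- stats::lsfit(basis, rnorm(n), intercept = FALSE)$residuals
    r * sqrt(residVar / var(r))
  } else numeric(n)
  lineValues <- setNames(g + eLine, colnames(genotypeCalls(gm)))

  L <- env$L %||% 1L; Y <- env$Y %||% 1L; R <- env$R %||% 1L
  locEff <- rnorm(L, 0, sqrt(env$varLocation %||% 0))
  yearEff <- rnorm(Y, 0, sqrt(env$varYear %||% 0))
  repEff <- rnorm(L * Y * R, 0, sqrt(env$varRep %||% 0))
  des <- expand.grid(line = seq_len(n), location = seq_len(L),
                     year = seq_len(Y), replicate = seq_len(R))
  repIdx <- as.integer(interaction(des$location, des$year, des$replicate,
                                   drop = TRUE))
  nPlots <- L * Y * R
  plotNoise <- if (nPlots > 1L && residVar > 0)
    rnorm(nrow(des), 0, sqrt(residVar * (nPlots - 1L))) else 0
  ## line value already carries the line-mean residual; extra plot noise has
  ## variance residVar*(LYR-1) so the plot residual totals residVar*LYR and
  ## the line mean keeps variance residVar
  pheno <- data.frame(
    line = names(lineValues)[des$line],
    location = paste0("loc", des$location),
    year = 2000L + des$year,
    replicate = des$replicate,
    value = lineValues[des$line] + locEff[des$location] + yearEff[des$year] +
      repEff[repIdx] + plotNoise,
    row.names = NULL)
  truth <- list(qtl = truthQtl, epi = truthEpi, polygenicPve = polygenicPve,
                polygenicSites = polySites, h2 = h2,
                geneticValues = setNames(g, names(lineValues)),
                components = comps,
                envVar = list(location = env$varLocation %||% 0,
                              year = env$varYear %||% 0,
                              rep = env$varRep %||% 0))
  list(pheno = pheno, lineValues = lineValues, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Desk-scale MAGIC fixture
#'
#' The package's default study-condition fixture: 11 inbred founders, two
#' 60-Mb chromosomes (one per subgenome), 5,000 SNPs, a half-diallel of 55
#' families bred through 5 random-mating and 6 selfing generations, 6 lines
#' per family (330 RILs), and 3x-coverage-like degradation (10% missingness,
#' 1% call error).
#'
#' @param seed seed for all stages
#' @param nSites number of SNPs
#' @param linesPerFamily lines per family
#' @param nFounders number of founders
#' @param missingRate,errorRate degradation rates for the observed calls
#' @param chromLen chromosome length (bp)
#' @param ... further arguments passed to \code{\link{breedPopulation}}
#' @return list with \code{layout}, \code{panel}, \code{pop}, \code{gm}
#'   (true calls) and \code{obs} (degraded calls)
#' @export
magicFixture <- function(seed = 1L, nSites = 5000L, linesPerFamily = 6L,
                         nFounders = 11L, missingRate = 0.1,
                         errorRate = 0.01, chromLen = 6e7, ...) {
  set.seed(seed)
  layout <- GenomeLayout(c("A01", "D01"), c(chromLen, chromLen))
  panel <- simulateFounders(layout, nFounders = nFounders, nSites = nSites)
  pop <- breedPopulation(panel, linesPerFamily = linesPerFamily, ...)
  gm <- realizeGenotypes(pop)
  obs <- degradeGenotypes(gm, missingRate, errorRate)
  list(layout = layout, panel = panel, pop = pop, gm = gm, obs = obs)
}
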