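## Two-stage genome-wide pairwise interaction scan.  Stage 1 fits
## y ~ x1 + x2 + x1:x2 by ordinary least squares for every pruned SNP pair
## (blockwise matrix algebra) and keeps interaction P <= 1e-4; stage 2 adds
## population-structure covariates, Bonferroni-adjusts over the candidate
## pairs and keeps adjusted P < 0.01.

#' MAF and windowed LD pruning for the epistasis scan
#'
#' Sites below the MAF filter are removed; then, within sliding windows,
#' one SNP of every pair with r-squared >= \code{r2Max} is removed (the one
#' with lower MAF; tie: the larger position), with the window advancing by
#' \code{step} SNPs.  A final single-step sweep guarantees that no
#' surviving pair within \code{windowBp} of each other exceeds the r-squared
#' bound.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param mafMin MAF filter (default 0.05)
#' @param r2Max LD bound (default 0.5)
#' @param windowBp window size (default 50 kb)
#' @param step SNPs advanced per window (default 5)
#' @return integer vector of retained site indices (rows of \code{gm})
#' @export
pruneForEpistasis <- function(gm, mafMin = 0.05, r2Max = 0.5,
                              windowBp = 5e4, step = 5L) {
  keep <- which(maf(gm) >= mafMin)
  X <- codeGenotypes(gm)[, keep, drop = FALSE]
  rr <- siteRanges(gm)
  chr <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  mafs <- maf(gm)[keep]
  alive <- rep(TRUE, length(keep))
  pruneWindow <- function(idx) {
    ## idx: positions into keep[] currently alive within one window
    while (length(idx) > 1L) {
      r2 <- suppressWarnings(cor(X[, idx]))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      hit <- which(r2 >= r2Max, arr.ind = TRUE)
      if (!nrow(hit)) break
      pair <- hit[1L, ]
      drop <- if (mafs[idx[pair[1L]]] < mafs[idx[pair[2L]]]) pair[1L]
              else if (mafs[idx[pair[1L]]] > mafs[idx[pair[2L]]]) pair[2L]
              else pair[which.max(pos[idx[pair]])]
      alive[idx[drop]] <<- FALSE
      idx <- idx[-drop]
    }
    idx
  }
  for (cc in unique(chr)) {
    ci <- which(chr == cc)
    for (stepSize in c(step, 1L)) {
      i <- 1L
      while (i <= length(ci)) {
        if (alive[ci[i]]) {
          win <- ci[ci >= ci[i] & pos[ci] >= pos[ci[i]] &
                    pos[ci] <= pos[ci[i]] + windowBp]
          win <- win[alive[win]]
          if (length(win) > 1L) pruneWindow(win)
        }
        i <- i + stepSize
      }
    }
  }
  out <- keep[alive]
  mmLog("prune", kept = length(out), removed = length(keep) - length(out))
  out
}

#' Stage-1 genome-wide pairwise interaction scan
#'
#' For every pair of pruned SNPs the interaction coefficient of
#' \code{y ~ x1 + x2 + x1:x2} is t-tested by exact least squares, computed
#' blockwise: for each anchor SNP the phenotype, the partner dosages and the
#' product terms are residualized on (1, x1) and the remaining 2-predictor
#' solve is vectorized over partners.
#'
#' @param y phenotype vector
#' @param G coded dosage matrix (samples x pruned sites), e.g.
#'   \code{codeGenotypes(gm)[, pruned]}
#' @param cutoff stage-1 interaction P cutoff (default 1e-4)
#' @return data.frame of candidate pairs: \code{i}, \code{j} (column indices
#'   into \code{G}), \code{beta}, \code{p}; attribute \code{"skipped"}
#'   counts collinear pairs
#' @export
pairwiseScan <- function(y, G, cutoff = 1e-4) {
  n <- length(y)
  m <- ncol(G)
  df <- n - 4L
  out <- list(); skipped <- 0L
  yc <- y - mean(y)
  G2 <- G * G
  c1 <- colSums(G)                 # xj' 1
  c2 <- colSums(G2)                # xj' xj
  for (i in seq_len(max(0L, m - 1L))) {
    x1 <- G[, i]
    jj <- (i + 1L):m
    m1 <- mean(x1)
    x1c <- x1 - m1
    s11 <- sum(x1c^2)
    if (s11 < 1e-12) { skipped <- skipped + length(jj); next }
    ry <- yc - x1c * (sum(x1c * yc) / s11)
    sy <- sum(ry^2)
    ## everything below is a cross-product of G (or G^2) with an n-vector;
    ## after residualizing on (1, x1) the 2-predictor solve is closed-form
    T1 <- crossprod(G[, jj, drop = FALSE],
                    cbind(x1, x1 * x1c, x1 * ry, ry))
    T2 <- crossprod(G2[, jj, drop = FALSE], cbind(x1 * x1, x1))
    gx1 <- T1[, 1L]                # xj' x1  (= 1' w)
    x1cx <- gx1 - m1 * c1[jj]      # x1c' xj
    a11 <- c2[jj] - c1[jj]^2 / n - x1cx^2 / s11
    a22 <- T2[, 1L] - gx1^2 / n - T1[, 2L]^2 / s11
    a12 <- T2[, 2L] - c1[jj] * gx1 / n - x1cx * T1[, 2L] / s11
    b1r <- T1[, 4L]
    b2r <- T1[, 3L]
    det <- a11 * a22 - a12^2
    ok <- det > 1e-10 * pmax(a11 * a22, 1e-300)
    skipped <- skipped + sum(!ok)
    beta1 <- (a22 * b1r - a12 * b2r) / det
    beta2 <- (a11 * b2r - a12 * b1r) / det
    rss <- sy - beta1 * b1r - beta2 * b2r
    se2 <- pmax(rss, 0) / df * a11 / det
    good <- ok & se2 > 0
    tstat <- numeric(length(jj))
    tstat[good] <- beta2[good] / sqrt(se2[good])
    p <- 2 * pt(-abs(tstat), df)
    ## a perfect fit (zero residual) is maximal evidence, not a skip
    perfect <- ok & se2 <= 0 & abs(beta2) > 1e-12
    p[perfect] <- 0
    hit <- which((good | perfect) & p <= cutoff)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(i = i, j = jj[hit],
                                            beta = beta2[hit], p = p[hit])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(), j = integer(), beta = numeric(), p = numeric())
  attr(res, "skipped") <- skipped
  res
}

#' Stage-2 covariate-controlled confirmation of candidate pairs
#'
#' Refits each candidate with population-structure covariates
#' (\code{y ~ PCs + x1 + x2 + x1:x2}), Bonferroni-multiplies the interaction
#' P by the number of candidates and keeps adjusted P below \code{alpha}.
#'
#' @param y phenotype vector
#' @param G coded dosage matrix (as in \code{\link{pairwiseScan}})
#' @param candidates stage-1 table with columns \code{i}, \code{j}
#' @param pcs matrix of principal-component covariates (may be NULL)
#' @param alpha adjusted-P threshold (default 0.01)
#' @return candidates with added \code{beta2}, \code{p2}, \code{padj},
#'   filtered to \code{padj < alpha}
#' @export
confirmPairs <- function(y, G, candidates, pcs = NULL, alpha = 0.01) {
  m <- nrow(candidates)
  if (!m) return(cbind(candidates, beta2 = numeric(0), p2 = numeric(0),
                       padj = numeric(0)))
  res <- t(vapply(seq_len(m), function(k) {
    x1 <- G[, candidates$i[k]]; x2 <- G[, candidates$j[k]]
    X <- cbind(1, pcs, x1, x2, x1 * x2)
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
    ncf <- length(cf)
    rss <- sum(fit$residuals^2)
    df <- length(y) - fit$rank
    XtXinv <- chol2inv(chol(crossprod(X[, !is.na(cf), drop = FALSE])))
    se <- sqrt(rss / df * XtXinv[sum(!is.na(cf)), sum(!is.na(cf))])
    b <- cf[ncf]
    c(b, 2 * pt(-abs(b / se), df))
  }, numeric(2)))
  out <- candidates
  out$beta2 <- res[, 1L]
  out$p2 <- res[, 2L]
  out$padj <- pmin(1, out$p2 * m)
  out[out$padj < alpha, , drop = FALSE]
}

#' Variance explained by one epistatic interaction
#'
#' The phenotype and the product term are both residualized on the
#' covariates and the two marginal dosages; the PVE is the explained sum of
#' squares of the residual-on-residual regression relative to the total
#' phenotypic sum of squares.
#'
#' @param y phenotype vector
#' @param x1,x2 dosage vectors of the interacting SNPs
#' @param pcs covariates (may be NULL)
#' @return PVE fraction in [0, 1]
#' @export
interactionPve <- function(y, x1, x2, pcs = NULL) {
  B <- cbind(1, pcs, x1, x2)
  qrB <- qr(B)
  ry <- qr.resid(qrB, y)
  rw <- qr.resid(qrB, x1 * x2)
  if (sum(rw^2) < 1e-12) return(structure(0, degenerate = TRUE))
  drop(crossprod(rw, ry))^2 / (sum(rw^2) * sum((y - mean(y))^2))
}

#' Subgenome class of an interacting chromosome pair
#'
#' @param chrom1,chrom2 chromosome names
#' @param layout \linkS4class{GenomeLayout}
#' @return \code{"AA"}, \code{"AD"} or \code{"DD"} (unordered)
#' @export
classifyPair <- function(chrom1, chrom2, layout) {
  sub <- subgenomes(layout)
  s <- sort(c(sub[[chrom1]], sub[[chrom2]]))
  paste(s, collapse = "")
}

#' Bin-delimited interval of an epistatic locus
#'
#' @param site row index into the genotype matrix
#' @param gm the \linkS4class{GenotypeMatrix}
#' @param binmap a \linkS4class{BinMap}
#' @return GRanges of the bin containing the SNP
#' @export
epiInterval <- function(site, gm, binmap) {
  hit <- GenomicRanges::findOverlaps(siteRanges(gm)[site], binRanges(binmap),
                                     select = "first")
  binRanges(binmap)[hit]
}

#' Fraction of epistatic pairs linked to sQTL loci
#'
#' A pair is linked when either of its (bin-delimited) locus intervals
#' overlaps any same-trait sQTL interval.
#'
#' @param intervals1,intervals2 GRanges of the two locus intervals, parallel
#'   to the pairs
#' @param sqtl sQTL table from \code{\link{callSqtl}}
#' @return list with \code{linked} (logical per pair) and \code{fraction}
#' @export
linkToSqtl <- function(intervals1, intervals2, sqtl) {
  if (!nrow(sqtl)) return(list(linked = rep(FALSE, length(intervals1)),
                               fraction = 0))
  sq <- GenomicRanges::GRanges(sqtl$chrom,
                               IRanges::IRanges(sqtl$start, sqtl$end))
  l1 <- GenomicRanges::countOverlaps(intervals1, sq) > 0
  l2 <- GenomicRanges::countOverlaps(intervals2, sq) > 0
  linked <- l1 | l2
  list(linked = linked, fraction = mean(linked))
}

#' Recombinant fractions at epistatic pairs versus matched random pairs
#'
#' For each pair of locus intervals, the fraction of RILs carrying at least
#' one recombination breakpoint inside either interval; the same statistic
#' over random interval pairs matched for widths and (for intra-chromosomal
#' pairs) separation; and a two-sided rank-sum comparison.
#'
#' @param intervals1,intervals2 GRanges pairs of epistatic locus intervals
#' @param segments IBD segments of all RILs (truth or HMM output)
#' @param layout \linkS4class{GenomeLayout}
#' @param nRandom number of matched random pairs (default 100)
#' @param seed RNG seed
#' @return list with \code{observed}, \code{random} (fractions) and
#'   \code{p} (Wilcoxon rank-sum)
#' @export
recombinantFractionComparison <- function(intervals1, intervals2, segments,
                                          layout, nRandom = 100L, seed = 1L) {
  set.seed(seed)
  md <- S4Vectors::mcols(segments)
  rils <- unique(md$ril)
  chr <- as.character(GenomicRanges::seqnames(segments))
  en <- GenomicRanges::end(segments)
  o <- order(md$ril, chr, GenomicRanges::start(segments))
  rl <- md$ril[o]; ch <- chr[o]; e2 <- en[o]
  internal <- rl[-1L] == rl[-length(rl)] & ch[-1L] == ch[-length(ch)]
  bpChr <- ch[which(internal)]
  bpPos <- e2[which(internal)]
  bpRil <- rl[which(internal)]
  fracFor <- function(c1, s1, e1, c2, s2, e2b) {
    inIt <- (bpChr == c1 & bpPos >= s1 & bpPos <= e1) |
      (bpChr == c2 & bpPos >= s2 & bpPos <= e2b)
    length(unique(bpRil[inIt])) / length(rils)
  }
  obs <- vapply(seq_along(intervals1), function(k) {
    fracFor(as.character(GenomicRanges::seqnames(intervals1[k])),
            GenomicRanges::start(intervals1[k]),
            GenomicRanges::end(intervals1[k]),
            as.character(GenomicRanges::seqnames(intervals2[k])),
            GenomicRanges::start(intervals2[k]),
            GenomicRanges::end(intervals2[k]))
  }, numeric(1))
  lens <- chromLengths(layout)
  rnd <- numeric(nRandom)
  for (r in seq_len(nRandom)) {
    k <- sample.int(length(intervals1), 1L)
    w1 <- GenomicRanges::width(intervals1[k])
    w2 <- GenomicRanges::width(intervals2[k])
    c1 <- as.character(GenomicRanges::seqnames(intervals1[k]))
    c2 <- as.character(GenomicRanges::seqnames(intervals2[k]))
    if (c1 == c2) {
      sep <- GenomicRanges::start(intervals2[k]) -
        GenomicRanges::start(intervals1[k])
      s1 <- sample.int(max(1, lens[[c1]] - abs(sep) - w2), 1L)
      s2 <- s1 + abs(sep)
      rnd[r] <- fracFor(c1, s1, s1 + w1 - 1, c1, s2, s2 + w2 - 1)
    } else {
      cc1 <- sample(names(lens), 1L)
      cc2 <- sample(setdiff(names(lens), cc1), 1L)
      s1 <- sample.int(max(1, lens[[cc1]] - w1), 1L)
      s2 <- sample.int(max(1, lens[[cc2]] - w2), 1L)
      rnd[r] <- fracFor(cc1, s1, s1 + w1 - 1, cc2, s2, s2 + w2 - 1)
    }
  }
  p <- suppressWarnings(wilcox.test(obs, rnd)$p.value)
  list(observed = obs, random = rnd, p = p)
}
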