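## Bin-level haplotype GWAS.  Model per bin:
##   y = X beta + u_bin + u_poly + e,
## u_bin ~ N(0, sb^2 Z Z') with Z the founder-indicator design of the bin,
## u_poly ~ N(0, sg^2 K), e ~ N(0, se^2 I); X is an intercept plus the top
## principal components.  The bin effect is tested with a REML likelihood
## ratio against the model without u_bin.
##
## Fitting: K is eigendecomposed once per trait; the polygenic ratio
## lambda_g = sg^2/se^2 is estimated on the null model and held fixed while
## the bin ratio lambda_b is profiled per bin.  After whitening by
## W = I + lambda_g D the per-bin restricted likelihood reduces, via the
## Woodbury identity, to a 1-D criterion driven by the K eigenvalues of the
## projected indicator cross-product, which makes genome scans and
## permutation re-scans cheap.

#' Eigendecomposition of a kinship matrix
#' @param K symmetric positive semi-definite relatedness matrix
#' @return list with \code{U} (eigenvectors) and \code{d} (eigenvalues,
#'   floored at 0)
#' @export
kinshipEigen <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  list(U = e$vectors, d = pmax(e$values, 0))
}

## -2 * restricted log-likelihood (up to an additive constant) of
## y = X b + u_poly + e at polygenic ratio lambda, in kinship eigen coords.
remlNullCrit <- function(lambda, ys, Xs, d) {
  w <- 1 + lambda * d
  yw <- ys / sqrt(w); Xw <- Xs / sqrt(w)
  qrX <- qr(Xw)
  rss <- sum(qr.resid(qrX, yw)^2)
  n <- length(ys); p <- ncol(Xs)
  R <- qr.R(qrX)
  (n - p) * log(rss) + sum(log(w)) + 2 * sum(log(abs(diag(R))))
}

#' Null-model REML fit of the polygenic variance ratio
#'
#' @param y phenotype vector
#' @param X fixed-effect design (intercept + covariates)
#' @param Keig kinship eigendecomposition from \code{\link{kinshipEigen}}
#' @param interval search interval for lambda_g = sigma_g^2 / sigma_e^2
#' @return list with \code{lambda}, \code{sigma2e}, \code{sigma2g}
#' @export
remlNullKinship <- function(y, X, Keig, interval = c(1e-6, 1e6)) {
  ys <- drop(crossprod(Keig$U, y))
  Xs <- crossprod(Keig$U, X)
  opt <- optimize(function(l) remlNullCrit(exp(l), ys, Xs, Keig$d),
                  log(interval), tol = 1e-8)
  lambda <- exp(opt$minimum)
  ## boundary check against lambda ~ 0
  if (remlNullCrit(1e-10, ys, Xs, Keig$d) <= opt$objective) lambda <- 0
  w <- 1 + lambda * Keig$d
  yw <- ys / sqrt(w); Xw <- Xs / sqrt(w)
  rss <- sum(qr.resid(qr(Xw), yw)^2)
  s2e <- rss / (length(y) - ncol(X))
  list(lambda = lambda, sigma2e = s2e, sigma2g = lambda * s2e)
}

## Per-bin sufficient statistics after whitening: eigenvalues mu of the
## projected indicator cross-product and the rotated score c = E' Z~' P y~.
binScanPrep <- function(binmap, Ut, Q1, subset = NULL) {
  states <- binStates(binmap)
  if (!is.null(subset)) states <- states[subset, , drop = FALSE]
  nF <- length(binmap@founders)
  B <- nrow(states)
  n <- ncol(states)
  mus <- matrix(0, B, nF)
  Es <- vector("list", B)
  PZl <- vector("list", B)
  for (b in seq_len(B)) {
    Z <- binDesign(states[b, ], nF)
    Zt <- Ut %*% Z
    PZ <- Zt - Q1 %*% crossprod(Q1, Zt)
    M <- crossprod(PZ)
    e <- eigen(M, symmetric = TRUE)
    mus[b, ] <- pmax(e$values, 0)
    Es[[b]] <- e$vectors
    PZl[[b]] <- PZ
  }
  list(mus = mus, Es = Es, PZ = do.call(cbind, PZl), B = B, nF = nF, n = n)
}

## Profiled REML criterion in the bin ratio for one bin.
binCrit <- function(lambda, r0, c2, mu, nmp) {
  q <- r0 - lambda * sum(c2 / (1 + lambda * mu))
  nmp * log(q) + sum(log1p(lambda * mu))
}

#' REML likelihood-ratio scan over all bins
#'
#' @param y phenotype (one value per RIL, e.g. a BLUP)
#' @param binmap a \linkS4class{BinMap}
#' @param Keig kinship eigendecomposition
#' @param X fixed-effect design; default intercept only.  Pass the top 10
#'   principal components as additional columns for the full model.
#' @param lambda polygenic ratio; estimated from the null model when NULL
#' @param grid candidate values of the bin variance ratio scanned before
#'   refinement
#' @param refine \code{"all"} refines every bin's optimum with a 1-D
#'   optimizer, \code{"top"} only the grid-best bin (enough for permutation
#'   maxima), \code{"none"} reports grid optima
#' @param prep precomputed per-bin statistics (internal reuse across
#'   permutations)
#' @param subset optional bin indices restricting the scan
#' @return numeric vector of LRT scores (one per bin, floored at 0) with
#'   attribute \code{"lambda"}
#' @export
binScan <- function(y, binmap, Keig, X = NULL, lambda = NULL,
                    grid = c(0, 10^seq(-3, 3, length.out = 25)),
                    refine = c("all", "top", "none"), prep = NULL,
                    subset = NULL) {
  refine <- match.arg(refine)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  if (is.null(lambda))
    lambda <- remlNullKinship(y, X, Keig)$lambda
  w <- 1 + lambda * Keig$d
  Ut <- t(Keig$U) / sqrt(w)
  Xt <- Ut %*% X
  qrX <- qr(Xt)
  Q1 <- qr.Q(qrX)
  if (is.null(prep)) prep <- binScanPrep(binmap, Ut, Q1, subset)
  yt <- drop(Ut %*% y)
  Py <- yt - Q1 %*% crossprod(Q1, yt)
  r0 <- sum(Py^2)
  nmp <- n - ncol(X)
  g <- drop(crossprod(prep$PZ, Py))        # length B * nF
  C2 <- matrix(0, prep$B, prep$nF)
  for (b in seq_len(prep$B)) {
    gb <- g[((b - 1L) * prep$nF + 1L):(b * prep$nF)]
    C2[b, ] <- drop(crossprod(prep$Es[[b]], gb))^2
  }
  crit0 <- nmp * log(r0)
  best <- rep(crit0, prep$B)
  for (l in grid[grid > 0]) {
    qv <- r0 - l * rowSums(C2 / (1 + l * prep$mus))
    cr <- nmp * log(qv) + rowSums(log1p(l * prep$mus))
    best <- pmin(best, cr)
  }
  lrt <- crit0 - best
  doRefine <- switch(refine, all = seq_len(prep$B),
                     top = which.max(lrt), none = integer(0))
  for (b in doRefine) {
    opt <- optimize(binCrit, c(1e-6, 1e4), r0 = r0, c2 = C2[b, ],
                    mu = prep$mus[b, ], nmp = nmp, tol = 1e-8)
    lrt[b] <- max(lrt[b], crit0 - opt$objective)
  }
  lrt <- pmax(lrt, 0)
  attr(lrt, "lambda") <- lambda
  attr(lrt, "prep") <- prep
  lrt
}

#' Exact REML LRT for a single bin
#'
#' Joint 1-D profiled fit of the bin ratio at a given (or null-estimated)
#' polygenic ratio; used for oracle-level checks and spot re-fits.
#'
#' @inheritParams binScan
#' @param states integer founder-state vector of the bin (NA = unknown)
#' @param nFounders number of founders
#' @return LRT score (>= 0)
#' @export
fitBinLrt <- function(y, states, nFounders, Keig = NULL, X = NULL,
                      lambda = NULL) {
  n <- length(y)
  if (is.null(Keig)) Keig <- list(U = diag(n), d = rep(0, n))
  if (is.null(X)) X <- matrix(1, n, 1L)
  if (is.null(lambda)) lambda <- remlNullKinship(y, X, Keig)$lambda
  w <- 1 + lambda * Keig$d
  Ut <- t(Keig$U) / sqrt(w)
  Xt <- Ut %*% X
  Q1 <- qr.Q(qr(Xt))
  Z <- binDesign(states, nFounders)
  Zt <- Ut %*% Z
  PZ <- Zt - Q1 %*% crossprod(Q1, Zt)
  M <- crossprod(PZ)
  e <- eigen(M, symmetric = TRUE)
  mu <- pmax(e$values, 0)
  yt <- drop(Ut %*% y)
  Py <- yt - Q1 %*% crossprod(Q1, yt)
  r0 <- sum(Py^2)
  c2 <- drop(crossprod(e$vectors, drop(crossprod(PZ, Py))))^2
  nmp <- n - ncol(X)
  opt <- optimize(binCrit, c(1e-8, 1e6), r0 = r0, c2 = c2, mu = mu,
                  nmp = nmp, tol = 1e-10)
  max(0, nmp * log(r0) - opt$objective)
}

nearestRank <- function(x, q) {
  s <- sort(x)
  s[pmax(1L, ceiling(q * length(s)))]
}

#' Permutation thresholds for the bin scan
#'
#' Phenotype values are shuffled across RILs; each permutation re-runs the
#' genome scan and records the genome-wide maximum LRT.  The significant and
#' suggestive thresholds are the nearest-rank 95th and 37th percentiles of
#' the permuted maxima.  The polygenic ratio is held at the observed-data
#' null estimate during permutation re-scans (set \code{refitNull = TRUE} to
#' re-estimate it per permutation).
#'
#' @inheritParams binScan
#' @param nPerm number of permutations (>= 20; default 100)
#' @param seed seed for the permutation sequence
#' @param refitNull re-estimate lambda_g for each permuted phenotype
#' @return list with \code{significant}, \code{suggestive}, \code{maxima},
#'   \code{scan} (observed LRT per bin) and \code{lambda}
#' @export
permutationThresholds <- function(y, binmap, Keig, X = NULL, nPerm = 100L,
                                  seed = 1L, refitNull = FALSE,
                                  subset = NULL) {
  if (nPerm < 20L) stop("use at least 20 permutations")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  scan <- binScan(y, binmap, Keig, X, refine = "all", subset = subset)
  lambda <- attr(scan, "lambda")
  prep <- attr(scan, "prep")
  set.seed(seed)
  maxima <- numeric(nPerm)
  for (i in seq_len(nPerm)) {
    yp <- y[sample.int(n)]
    sc <- binScan(yp, binmap, Keig, X,
                  lambda = if (refitNull) NULL else lambda,
                  refine = "top",
                  prep = if (refitNull) NULL else prep, subset = subset)
    maxima[i] <- max(sc)
  }
  list(significant = nearestRank(maxima, 0.95),
       suggestive = nearestRank(maxima, 0.37),
       maxima = maxima, scan = as.numeric(scan), lambda = lambda)
}

#' Call haplotype QTLs from a bin scan
#'
#' Bins above the suggestive threshold seed loci; bins merge into one locus
#' when their gap is <= 1 Mb or they are separated by <= 5 intervening bins.
#' The peak bin is the maximum-LRT member; a locus is flagged significant
#' when its peak exceeds the significant threshold.  Single-locus PVE is the
#' R-squared of the phenotype on the peak bin's founder indicators after
#' projecting out the fixed covariates; a joint multi-locus PVE over all
#' peak bins is returned as an attribute.
#'
#' @param scan LRT vector from \code{\link{binScan}}
#' @param thresholds list with \code{significant} and \code{suggestive}
#' @param binmap the \linkS4class{BinMap} scanned
#' @param y phenotype used for PVE and founder-effect estimates
#' @param X fixed covariates projected out before PVE
#' @param mergeGapBp bp merging rule (default 1 Mb)
#' @param mergeBins intervening-bin merging rule (default 5)
#' @return data.frame of loci (chrom, start, end, peakBin, peakLrt,
#'   significant, pve, nBins) with attributes \code{"jointPve"} and
#'   \code{"founderEffects"}
#' @export
callHqtl <- function(scan, thresholds, binmap, y, X = NULL,
                     mergeGapBp = 1e6, mergeBins = 5L) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  sig <- which(scan > thresholds$suggestive)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peakBin = integer(),
                      peakLrt = numeric(), significant = logical(),
                      pve = numeric(), nBins = integer())
  if (!length(sig)) return(empty)
  bins <- binRanges(binmap)
  chr <- as.character(GenomicRanges::seqnames(bins))
  st <- GenomicRanges::start(bins); en <- GenomicRanges::end(bins)
  grp <- cumsum(c(1L, vapply(seq_along(sig)[-1L], function(i) {
    a <- sig[i - 1L]; b <- sig[i]
    gap <- st[b] - en[a]
    sameChr <- chr[a] == chr[b]
    as.integer(!(sameChr && (gap <= mergeGapBp || b - a - 1L <= mergeBins)))
  }, integer(1))))
  Q1 <- qr.Q(qr(X))
  py <- y - Q1 %*% crossprod(Q1, y)
  ssT <- sum(py^2)
  states <- binStates(binmap)
  nF <- length(binmap@founders)
  pvePeak <- function(b) {
    Z <- binDesign(states[b, ], nF)
    PZ <- Z - Q1 %*% crossprod(Q1, Z)
    f <- qr.fitted(qr(PZ), py)
    sum(f^2) / ssT
  }
  loci <- lapply(split(sig, grp), function(mem) {
    peak <- mem[which.max(scan[mem])]
    data.frame(chrom = chr[peak], start = min(st[mem]), end = max(en[mem]),
               peakBin = peak, peakLrt = scan[peak],
               significant = scan[peak] > thresholds$significant,
               pve = pvePeak(peak), nBins = length(mem))
  })
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  ## joint PVE over all peak bins and per-founder effects at each peak
  Zall <- do.call(cbind, lapply(out$peakBin, function(b)
    binDesign(states[b, ], nF)))
  PZ <- Zall - Q1 %*% crossprod(Q1, Zall)
  attr(out, "jointPve") <- sum(qr.fitted(qr(PZ), py)^2) / ssT
  attr(out, "founderEffects") <- lapply(out$peakBin, function(b) {
    s <- states[b, ]
    eff <- tapply(y, factor(binmap@founders[s], levels = binmap@founders),
                  mean) - mean(y)
    eff
  })
  out
}
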