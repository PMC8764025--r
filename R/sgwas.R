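## SNP-level mixed-model GWAS: y = mu + x beta + u + e with u ~ N(0, sg^2 K).
## Variance components are estimated once on the null model and reused for
## every SNP (the population-parameters-previously-determined approximation);
## an exact per-SNP REML mode is available for validation.

#' Numeric dosage coding of a GenotypeMatrix
#'
#' Transposes calls to samples x sites and (by default) mean-imputes
#' missing dosages, the coding used by the kinship, PCA, LD and scan layers.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param impute mean-impute missing calls (default TRUE)
#' @return numeric matrix (samples x sites)
#' @export
codeGenotypes <- function(gm, impute = TRUE) {
  X <- t(genotypeCalls(gm)) * 1.0       # samples x sites
  if (impute && anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  X
}

#' VanRaden kinship matrix
#'
#' Centered 0/1/2 dosage cross-product scaled by the summed expected locus
#' variance 2 p (1 - p); missing calls are mean-imputed; sites below the MAF
#' filter are dropped.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param mafMin minimum minor-allele frequency (default 0.05)
#' @return symmetric relatedness matrix (samples x samples)
#' @export
kinshipMatrix <- function(gm, mafMin = 0.05) {
  if (ncol(gm) < 2L) stop("kinship needs at least 2 samples")
  keep <- which(maf(gm) >= mafMin)
  X <- codeGenotypes(gm)[, keep, drop = FALSE]
  p <- colMeans(X) / 2
  Xc <- sweep(X, 2L, 2 * p)
  denom <- sum(2 * p * (1 - p))
  tcrossprod(Xc) / denom
}

#' Mixed-model single-SNP association scan
#'
#' The phenotype is standardized to unit variance so allele effects are in
#' trait-SD units.  By default the polygenic variance ratio is fit once on
#' the SNP-free null model and per-SNP effects are generalized least squares
#' under that covariance (EMMAX-style); \code{exact = TRUE} re-estimates the
#' ratio per SNP.
#'
#' @param y phenotype vector (per-line BLUPs)
#' @param gm \linkS4class{GenotypeMatrix}
#' @param K kinship matrix (identity collapses the model to per-SNP OLS)
#' @param mafMin minimum MAF; lower-frequency and monomorphic SNPs are
#'   skipped
#' @param X optional covariate design (intercept added automatically)
#' @param exact per-SNP REML refit (slow; validation only)
#' @param standardize divide y by its SD (default TRUE)
#' @return data.frame with one row per tested SNP: \code{site} (row index in
#'   \code{gm}), \code{chrom}, \code{pos}, \code{beta}, \code{se}, \code{p}
#' @export
lmmAssoc <- function(y, gm, K, mafMin = 0.05, X = NULL, exact = FALSE,
                     standardize = TRUE) {
  n <- length(y)
  stopifnot(n == ncol(gm))
  if (standardize) y <- y / sd(y)
  X0 <- cbind(rep(1, n), X)
  keep <- which(maf(gm) >= mafMin & maf(gm) > 0)
  G <- codeGenotypes(gm)[, keep, drop = FALSE]
  Keig <- kinshipEigen(K)
  rr <- siteRanges(gm)
  if (exact) {
    res <- t(vapply(seq_along(keep), function(j) {
      fit <- remlNullKinship(y, cbind(X0, G[, j]), Keig)
      glsSnp(y, X0, G[, j, drop = FALSE], Keig, fit$lambda)
    }, numeric(3)))
  } else {
    fit <- remlNullKinship(y, X0, Keig)
    res <- glsSnp(y, X0, G, Keig, fit$lambda)
  }
  out <- data.frame(site = keep,
                    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
                    pos = GenomicRanges::start(rr)[keep],
                    beta = res[, 1L], se = res[, 2L], p = res[, 3L])
  mmLog("sgwas", tested = nrow(out), skipped = nrow(gm) - nrow(out))
  out
}

## GLS effect, SE and Wald P for each SNP column at fixed lambda.
glsSnp <- function(y, X0, G, Keig, lambda) {
  n <- length(y)
  w <- 1 + lambda * Keig$d
  Ut <- t(Keig$U) / sqrt(w)
  yt <- drop(Ut %*% y)
  Xt <- Ut %*% X0
  Gt <- Ut %*% G
  Q1 <- qr.Q(qr(Xt))
  ry <- yt - Q1 %*% crossprod(Q1, yt)
  RG <- Gt - Q1 %*% crossprod(Q1, Gt)
  sxx <- colSums(RG^2)
  sxy <- drop(crossprod(RG, ry))
  beta <- sxy / sxx
  df <- n - ncol(X0) - 1L
  rss <- pmax(sum(ry^2) - beta * sxy, 0)
  s2 <- rss / df
  se <- sqrt(s2 / sxx)
  p <- 2 * pt(-abs(beta / se), df)
  cbind(beta, se, p)
}

#' Genome-wide significance threshold 1/n
#'
#' @param n total number of genomic SNPs
#' @return list with \code{p} (= 1/n) and \code{log10} (= -log10(1/n))
#' @examples
#' signif(sgwasThreshold(1548294)$p, 2)   # 6.5e-07
#' @export
sgwasThreshold <- function(n) {
  if (n <= 0) stop("n must be positive")
  list(p = 1 / n, log10 = log10(n))
}

#' Group significant SNPs into sQTL loci
#'
#' Significant SNPs are first clustered by single linkage at an inter-SNP
#' gap below \code{gapBp}; adjacent clusters on one chromosome are then
#' merged (transitively) whenever any cross-cluster pair of significant
#' SNPs is in LD at r-squared >= \code{mergeR2}.  The peak SNP is the
#' minimum-P member; the interval is the span of member SNPs; PVE is the
#' covariate-adjusted R-squared of the phenotype on the peak SNP when a
#' phenotype is supplied.
#'
#' @param assoc scan table from \code{\link{lmmAssoc}}
#' @param threshold P-value threshold (e.g. \code{sgwasThreshold(n)$p})
#' @param gm the \linkS4class{GenotypeMatrix} scanned (for LD)
#' @param y optional phenotype for PVE
#' @param X optional covariates projected out before PVE
#' @param gapBp clustering gap (strictly less than; default 700 kb)
#' @param mergeR2 LD merging threshold (default 0.4)
#' @return data.frame of loci: chrom, start, end, peakSite, peakPos, peakP,
#'   peakBeta, pve, nSnps
#' @export
callSqtl <- function(assoc, threshold, gm, y = NULL, X = NULL,
                     gapBp = 7e5, mergeR2 = 0.4) {
  sig <- assoc[assoc$p < threshold, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      peakSite = integer(), peakPos = numeric(),
                      peakP = numeric(), peakBeta = numeric(),
                      pve = numeric(), nSnps = integer())
  if (!nrow(sig)) return(empty)
  sig <- sig[order(sig$chrom, sig$pos), ]
  Gall <- codeGenotypes(gm)
  loci <- list()
  for (cc in unique(sig$chrom)) {
    s <- sig[sig$chrom == cc, ]
    grp <- cumsum(c(1L, as.integer(diff(s$pos) >= gapBp)))
    cl <- split(seq_len(nrow(s)), grp)
    ## transitive LD merging of adjacent clusters
    repeat {
      merged <- FALSE
      i <- 1L
      while (i < length(cl)) {
        g1 <- Gall[, s$site[cl[[i]]], drop = FALSE]
        g2 <- Gall[, s$site[cl[[i + 1L]]], drop = FALSE]
        r2 <- suppressWarnings(cor(g1, g2))^2
        if (any(r2 >= mergeR2, na.rm = TRUE)) {
          cl[[i]] <- c(cl[[i]], cl[[i + 1L]])
          cl[[i + 1L]] <- NULL
          merged <- TRUE
        } else i <- i + 1L
      }
      if (!merged) break
    }
    for (mem in cl) {
      peak <- mem[which.min(s$p[mem])]
      pve <- NA_real_
      if (!is.null(y)) {
        n <- length(y)
        X0 <- if (is.null(X)) matrix(1, n, 1L) else cbind(1, X)
        Q1 <- qr.Q(qr(X0))
        py <- y - Q1 %*% crossprod(Q1, y)
        px <- Gall[, s$site[peak]] -
          Q1 %*% crossprod(Q1, Gall[, s$site[peak]])
        pve <- drop(crossprod(px, py))^2 / (sum(px^2) * sum(py^2))
      }
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = cc, start = min(s$pos[mem]), end = max(s$pos[mem]),
        peakSite = s$site[peak], peakPos = s$pos[peak], peakP = s$p[peak],
        peakBeta = s$beta[peak], pve = pve, nSnps = length(mem))
    }
  }
  out <- do.call(rbind, loci)
  out[order(out$chrom, out$start), ]
}
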