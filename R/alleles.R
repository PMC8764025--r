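## Post-GWAS functional-allele inference: RILs are grouped by their founder
## IBD state at the peak bin(s) of a QTL, groups are contrasted against the
## whole population, diagnostic SNPs separate contrasting parental groups,
## and non-synonymous-SNP haplotype strings define functional alleles.

#' Group RILs into parental IBD groups at peak bins
#'
#' With several peak bins a RIL is included only if its state agrees across
#' all of them.  Groups smaller than \code{minN} are excluded.  Group means
#' are compared by one-way ANOVA, and each group is compared against all
#' RILs with a two-sided Welch t-test.
#'
#' @param binmap a \linkS4class{BinMap}
#' @param peakBins integer indices of the peak bin(s)
#' @param y named phenotype vector over the RILs of the bin map
#' @param minN minimum group size kept (default 4, i.e. n > 3)
#' @return list with \code{groups} (data.frame: founder, n, mean, tP,
#'   ordered by mean) and \code{anovaP}
#' @export
groupByIbd <- function(binmap, peakBins, y, minN = 4L) {
  st <- binStates(binmap)[peakBins, , drop = FALSE]
  agree <- apply(st, 2L, function(s) !anyNA(s) && length(unique(s)) == 1L)
  state <- st[1L, ]
  state[!agree] <- NA_integer_
  lab <- binmap@founders[state]
  keep <- !is.na(lab)
  tab <- table(lab[keep])
  good <- names(tab)[tab >= minN]
  use <- keep & lab %in% good
  groups <- do.call(rbind, lapply(good, function(f) {
    yi <- y[use & lab == f]
    data.frame(founder = f, n = length(yi), mean = mean(yi),
               tP = t.test(yi, y)$p.value)
  }))
  groups <- groups[order(groups$mean), ]
  rownames(groups) <- NULL
  anovaP <- NA_real_
  if (length(good) >= 2L) {
    fit <- lm(y[use] ~ factor(lab[use]))
    anovaP <- anova(fit)[["Pr(>F)"]][1L]
  } else warning("fewer than 2 parental groups; ANOVA skipped")
  list(groups = groups, anovaP = anovaP)
}

#' Diagnostic SNPs between two parental IBD groups
#'
#' For each SNP in the region, the genotype-count table of the two groups
#' (missing calls excluded) is tested with a two-sided Fisher exact test;
#' SNPs are ranked by P.  Modal genotypes and their within-group frequencies
#' are reported.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param groupA,groupB character vectors of RIL IDs
#' @param region GRanges restricting the SNPs tested
#' @return data.frame: site, chrom, pos, p, modalA, freqA, modalB, freqB,
#'   ordered by p
#' @export
diagnosticSnps <- function(gm, groupA, groupB, region) {
  stopifnot(length(groupA) > 0, length(groupB) > 0)
  rr <- siteRanges(gm)
  inRegion <- which(GenomicRanges::countOverlaps(rr, region) > 0)
  cl <- genotypeCalls(gm)
  rows <- list()
  for (i in inRegion) {
    a <- cl[i, groupA]; b <- cl[i, groupB]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) next
    counts <- rbind(tabulate(a + 1L, 3L), tabulate(b + 1L, 3L))
    nz <- colSums(counts) > 0
    p <- if (sum(nz) < 2L) 1 else fisher.test(counts[, nz, drop = FALSE])$p.value
    gl <- c("homRef", "het", "homAlt")
    rows[[length(rows) + 1L]] <- data.frame(
      site = i, chrom = as.character(GenomicRanges::seqnames(rr))[i],
      pos = GenomicRanges::start(rr)[i], p = p,
      modalA = gl[which.max(counts[1L, ])],
      freqA = max(counts[1L, ]) / length(a),
      modalB = gl[which.max(counts[2L, ])],
      freqB = max(counts[2L, ]) / length(b))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out[order(out$p), ]
}

#' Define functional alleles from a SNP set
#'
#' RILs heterozygous or missing at any defining SNP are excluded from allele
#' assignment (their count is reported); the allele of a carrier is the
#' concatenated homozygous base per SNP.  Alleles carried by more than
#' \code{minN - 1} RILs are kept and contrasted with pairwise two-sided
#' Welch t-tests on the phenotype.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param snpSet integer row indices of the defining SNPs (in order)
#' @param y named phenotype vector
#' @param minN minimum carriers (default 4, i.e. n > 3)
#' @return list with \code{alleles} (data.frame: allele, n, mean),
#'   \code{tests} (pairwise data.frame: allele1, allele2, p, effect),
#'   \code{excluded} (count of het/missing carriers)
#' @export
defineAlleles <- function(gm, snpSet, y, minN = 4L) {
  cl <- genotypeCalls(gm)[snpSet, , drop = FALSE]
  rr <- siteRanges(gm)[snpSet]
  homOk <- apply(cl, 2L, function(g) !anyNA(g) && all(g %in% c(0L, 2L)))
  excluded <- sum(!homOk)
  base <- function(g, i) if (g == 0L) S4Vectors::mcols(rr)$ref[i] else
    S4Vectors::mcols(rr)$alt[i]
  strings <- vapply(which(homOk), function(s)
    paste(vapply(seq_along(snpSet), function(i) base(cl[i, s], i),
                 character(1)), collapse = "_"), character(1))
  names(strings) <- colnames(cl)[homOk]
  tab <- table(strings)
  good <- names(tab)[tab >= minN]
  if (!length(good)) {
    mmLog("define_alleles", alleles = 0, excluded = excluded)
    return(list(alleles = data.frame(), tests = data.frame(),
                excluded = excluded))
  }
  alleles <- do.call(rbind, lapply(good, function(al) {
    yi <- y[names(strings)[strings == al]]
    data.frame(allele = al, n = length(yi), mean = mean(yi))
  }))
  tests <- data.frame()
  if (length(good) > 1L) {
    cmb <- utils::combn(good, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      y1 <- y[names(strings)[strings == cmb[1L, k]]]
      y2 <- y[names(strings)[strings == cmb[2L, k]]]
      data.frame(allele1 = cmb[1L, k], allele2 = cmb[2L, k],
                 p = t.test(y1, y2)$p.value, effect = mean(y1) - mean(y2))
    }))
  }
  list(alleles = alleles, tests = tests, excluded = excluded)
}
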