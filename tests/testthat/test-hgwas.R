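test_that("bin boundaries are the union of segment boundaries", {
  layout <- GenomeLayout("A01", 100)
  segs <- segGr(rbind(
    data.frame(chrom = "A01", start = c(1, 31), end = c(30, 100),
               ril = "R1", founder = c("P1", "P2")),
    data.frame(chrom = "A01", start = c(1, 51), end = c(50, 100),
               ril = "R2", founder = c("P2", "P1"))), layout)
  bm <- buildBins(segs, layout, founders = c("P1", "P2"))
  expect_equal(GenomicRanges::start(binRanges(bm)), c(1, 31, 51))
  expect_equal(GenomicRanges::end(binRanges(bm)), c(30, 50, 100))
  st <- binStates(bm, labels = TRUE)
  expect_equal(unname(st[, "R1"]), c("P1", "P2", "P2"))
  expect_equal(unname(st[, "R2"]), c("P2", "P2", "P1"))
  ## a single RIL without breakpoints: one bin per chromosome
  one <- segGr(data.frame(chrom = "A01", start = 1, end = 100,
                          ril = "R1", founder = "P1"), layout)
  expect_equal(length(binRanges(buildBins(one, layout))), 1L)
  ## non-partitioning input is fatal
  bad <- segGr(data.frame(chrom = "A01", start = c(1, 40), end = c(30, 100),
                          ril = "R1", founder = c("P1", "P2")), layout)
  expect_error(buildBins(bad, layout), "partition")
})

test_that("bin states equal segment lookup at bin midpoints (oracle)", {
  fx <- smallFixture()
  bm <- buildBins(fx$truth, fx$layout, founders = fx$panel@ids)
  bins <- binRanges(bm)
  mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(bins),
    IRanges::IRanges(floor((GenomicRanges::start(bins) +
                            GenomicRanges::end(bins)) / 2), width = 1L))
  st <- binStates(bm, labels = TRUE)
  md <- S4Vectors::mcols(fx$truth)
  for (r in sample(colnames(st), 5L)) {
    segs <- fx$truth[md$ril == r]
    hit <- GenomicRanges::findOverlaps(mids, segs, select = "first")
    oracle <- S4Vectors::mcols(segs)$founder[hit]
    called <- st[, r]
    called[is.na(called)] <- "unknown"
    expect_equal(unname(called), oracle)
  }
  ## tiling: bin lengths sum to chromosome lengths exactly
  bySum <- tapply(GenomicRanges::width(bins),
                  as.character(GenomicRanges::seqnames(bins)), sum)
  expect_equal(as.numeric(bySum[names(chromLengths(fx$layout))]),
               as.numeric(chromLengths(fx$layout)))
})

test_that("founder-indicator designs code states and unknowns", {
  Z <- binDesign(c(1L, 2L, 1L), 2)
  expect_equal(unname(Z), rbind(c(1, 0), c(0, 1), c(1, 0)))
  Zu <- binDesign(c(1L, NA, 2L), 3)
  expect_equal(unname(Zu[2L, ]), c(0, 0, 0))
  expect_true(all(rowSums(Zu) %in% c(0, 1)))
  Z11 <- binDesign(sample(1:11, 30, TRUE), 11)
  expect_equal(ncol(Z11), 11L)
  expect_true(all(rowSums(Z11) == 1))
  Zd <- binDesign(c(1L, 2L, 1L), 2, dropRedundant = TRUE)
  expect_equal(ncol(Zd), 1L)
})

test_that("a state-constant bin has LRT 0 and scale shifts do not matter", {
  set.seed(60)
  y <- rnorm(40)
  expect_equal(fitBinLrt(y, rep(1L, 40), 3), 0, tolerance = 1e-6)
  st <- sample(1:4, 40, TRUE)
  l1 <- fitBinLrt(y, st, 4)
  l2 <- fitBinLrt(5 + 3 * y, st, 4)
  expect_equal(l1, l2, tolerance = 1e-5)
})

test_that("profiled REML LRT matches a brute-force grid search", {
  set.seed(61)
  n <- 30
  st <- sample(1:4, n, TRUE)
  Z <- binDesign(st, 4)
  y <- drop(Z %*% c(-1, 0, 1, 2)) + rnorm(n)
  X <- matrix(1, n, 1)
  ## independent oracle: dense REML likelihood over a (sigma_b, sigma_e) grid
  m2ll <- function(sb2, se2) {
    V <- sb2 * tcrossprod(Z) + se2 * diag(n)
    Vi <- solve(V)
    XVX <- crossprod(X, Vi %*% X)
    beta <- solve(XVX, crossprod(X, Vi %*% y))
    r <- y - X %*% beta
    drop(determinant(V)$modulus + determinant(XVX)$modulus +
         crossprod(r, Vi %*% r))
  }
  se2grid <- seq(0.3, 3, length.out = 120)
  sb2grid <- c(0, exp(seq(log(0.01), log(20), length.out = 160)))
  vals <- outer(sb2grid, se2grid, Vectorize(m2ll))
  lrtOracle <- min(vals[1L, ]) - min(vals)
  lrt <- fitBinLrt(y, st, 4, Keig = list(U = diag(n), d = rep(0, n)),
                   lambda = 0)
  expect_equal(lrt, lrtOracle, tolerance = 0.02)
})

test_that("permutation thresholds use nearest-rank quantiles and a seed", {
  expect_equal(magicmap:::nearestRank(1:100, 0.95), 95L)
  expect_equal(magicmap:::nearestRank(1:100, 0.37), 37L)
  expect_equal(magicmap:::nearestRank(rep(3.5, 10), 0.95), 3.5)
  fx <- smallFixture()
  bm <- buildBins(fx$truth, fx$layout, founders = fx$panel@ids)
  K <- kinshipMatrix(fx$gm, mafMin = 0.05)
  Keig <- kinshipEigen(K)
  set.seed(62)
  y <- rnorm(length(fx$pop@rilIds))
  sub <- round(seq(1, length(binRanges(bm)), length.out = 30))
  t1 <- permutationThresholds(y, bm, Keig, nPerm = 20, seed = 9,
                              subset = sub)
  t2 <- permutationThresholds(y, bm, Keig, nPerm = 20, seed = 9,
                              subset = sub)
  expect_identical(t1$maxima, t2$maxima)
  expect_identical(t1$significant, t2$significant)
  expect_gte(t1$significant, t1$suggestive)
  expect_error(permutationThresholds(y, bm, Keig, nPerm = 5), "20")
})

test_that("hQTL merging follows the 1-Mb / 5-bin rules", {
  ## 30 contiguous 200-kb bins on one chromosome, 40 RILs
  layout <- GenomeLayout("A01", 6e6)
  n <- 40
  set.seed(63)
  states <- matrix(sample(1:4, 30 * n, TRUE), 30, n,
                   dimnames = list(NULL, paste0("R", 1:n)))
  bins <- GenomicRanges::GRanges("A01",
    IRanges::IRanges(seq(1, by = 2e5, length.out = 30),
                     width = 2e5))
  bm <- new("BinMap", bins = bins, states = states,
            founders = paste0("P", 1:4))
  y <- rnorm(n)
  thr <- list(significant = 10, suggestive = 5)
  ## two significant bins 0.8 Mb apart (gap rule): bins 1 and 6
  scan <- rep(0, 30); scan[c(1, 6)] <- c(8, 12)
  hq <- callHqtl(scan, thr, bm, y)
  expect_equal(nrow(hq), 1L)
  expect_equal(hq$peakBin, 6L)
  expect_true(hq$significant)
  expect_equal(hq$nBins, 2L)
  ## 2 Mb and 7 intervening bins apart: two loci
  scan2 <- rep(0, 30); scan2[c(1, 12)] <- c(8, 12)
  hq2 <- callHqtl(scan2, thr, bm, y)
  expect_equal(nrow(hq2), 2L)
  ## <= 5 intervening bins merges even across a > 1 Mb gap
  scan3 <- rep(0, 30); scan3[c(1, 7)] <- c(8, 12)
  expect_equal(nrow(callHqtl(scan3, thr, bm, y)), 1L)
  ## joint PVE bounds
  scan4 <- rep(0, 30); scan4[c(1, 12, 25)] <- c(8, 12, 9)
  hq4 <- callHqtl(scan4, thr, bm, y)
  expect_gte(attr(hq4, "jointPve"), max(hq4$pve) - 1e-10)
  expect_lte(attr(hq4, "jointPve"), 1)
})
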