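test_that("LD pruning removes duplicates and passes its own audit", {
  set.seed(80)
  n <- 60
  base <- matrix(rbinom(n * 30, 2, 0.5), 30, n)
  base[2L, ] <- base[1L, ]                  # duplicate 1 kb apart
  pos <- sort(sample.int(2e5, 30))
  pos[2L] <- pos[1L] + 1000L
  gm <- tinyGm(base, pos = sort(pos))
  kept <- pruneForEpistasis(gm, mafMin = 0)
  expect_false(all(c(1L, 2L) %in% kept))
  ## post-hoc audit: no surviving within-window pair at r2 >= 0.5
  X <- t(base)
  pos <- GenomicRanges::start(siteRanges(gm))
  for (a in seq_along(kept)) for (b in seq_along(kept)) {
    if (b <= a) next
    i <- kept[a]; j <- kept[b]
    if (abs(pos[j] - pos[i]) > 5e4) next
    r2 <- suppressWarnings(cor(X[, i], X[, j]))^2
    if (is.finite(r2)) expect_lt(r2, 0.5)
  }
  ## independent SNPs are all retained
  set.seed(81)
  ind <- matrix(rbinom(200 * 20, 2, 0.5), 20, 200)
  gmi <- tinyGm(ind, pos = seq(1e3, by = 6e4, length.out = 20))
  expect_equal(length(pruneForEpistasis(gmi, mafMin = 0)), 20L)
})

test_that("a pure product phenotype is caught only by the interaction", {
  set.seed(82)
  n <- 120
  x1 <- rbinom(n, 2, 0.5); x2 <- rbinom(n, 2, 0.5)
  y <- x1 * x2
  G <- cbind(x1, x2, matrix(rbinom(n * 8, 2, 0.5), n, 8))
  cand <- pairwiseScan(y, G, cutoff = 1e-4)
  expect_true(any(cand$i == 1L & cand$j == 2L))
  top <- cand[cand$i == 1L & cand$j == 2L, ]
  expect_lt(top$p, 1e-20)
  f <- suppressWarnings(summary(lm(y ~ x1 * x2)))$coefficients
  expect_equal(top$beta, f["x1:x2", 1L], tolerance = 1e-10)
})

test_that("stage-1 false-positive rate matches its cutoff under the null", {
  set.seed(83)
  n <- 100; m <- 450
  G <- matrix(rbinom(n * m, 2, 0.5), n, m)
  y <- rnorm(n)
  cutoff <- 1e-4
  cand <- pairwiseScan(y, G, cutoff = cutoff)
  nPairs <- m * (m - 1) / 2 - attr(cand, "skipped")
  expected <- nPairs * cutoff
  expect_lt(abs(nrow(cand) - expected), 3 * sqrt(expected) + 1)
})

test_that("Bonferroni confirmation multiplies by the candidate count", {
  set.seed(84)
  n <- 150
  x1 <- rbinom(n, 2, 0.5); x2 <- rbinom(n, 2, 0.5)
  G <- cbind(x1, x2, matrix(rbinom(n * 20, 2, 0.5), n, 20))
  w <- x1 * x2
  y <- scale(resid(lm(w ~ x1 + x2)))[, 1L] + rnorm(n, 0, 1.2)
  cand <- data.frame(i = c(1L, rep(3L, 9)), j = c(2L, 4:12))
  conf <- confirmPairs(y, G, cand, alpha = 1)
  expect_equal(conf$padj, pmin(1, conf$p2 * nrow(cand)))
  ## with m = 1 a raw P of 0.005 survives alpha = 0.01
  c1 <- confirmPairs(y, G, data.frame(i = 1L, j = 2L), alpha = 0.01)
  expect_true(nrow(c1) %in% c(0L, 1L))
  if (nrow(c1)) expect_equal(c1$padj, c1$p2)
})

test_that("a covariate explaining the interaction kills the pair", {
  set.seed(85)
  n <- 200
  x1 <- rbinom(n, 2, 0.5); x2 <- rbinom(n, 2, 0.5)
  w <- resid(lm(I(x1 * x2) ~ x1 + x2))
  pc <- scale(w + rnorm(n, 0, 0.05))      # covariate carrying the signal
  y <- drop(scale(w)) * 0.6 + rnorm(n, 0, 0.8)
  G <- cbind(x1, x2)
  cand <- data.frame(i = 1L, j = 2L)
  without <- confirmPairs(y, G, cand, pcs = NULL, alpha = 0.01)
  with <- confirmPairs(y, G, cand, pcs = pc, alpha = 0.01)
  expect_equal(nrow(without), 1L)
  expect_equal(nrow(with), 0L)
})

test_that("interaction PVE matches the closed form and recovers truth", {
  set.seed(86)
  n <- 300
  x1 <- rbinom(n, 2, 0.5); x2 <- rbinom(n, 2, 0.5)
  w <- resid(lm(I(x1 * x2) ~ x1 + x2))
  y <- w + rnorm(n)
  pve <- interactionPve(y, x1, x2)
  rw <- resid(lm(w ~ x1 + x2))
  oracle <- sum(rw * y)^2 / (sum(rw^2) * sum((y - mean(y))^2))
  expect_equal(pve, oracle, tolerance = 1e-12)
  ## no interaction in truth
  y0 <- rnorm(n) + 0.3 * x1
  expect_lt(interactionPve(y0, x1, x2), 0.05)
})

test_that("subgenome classification is symmetric", {
  layout <- GenomeLayout(c("A07", "A08", "D04", "D05", "D09", "A10"),
                         rep(1e8, 6))
  expect_equal(classifyPair("A07", "A08", layout), "AA")
  expect_equal(classifyPair("D09", "A10", layout), "AD")
  expect_equal(classifyPair("A10", "D09", layout), "AD")
  expect_equal(classifyPair("D04", "D05", layout), "DD")
  for (a in layout@chrom) for (b in layout@chrom)
    expect_equal(classifyPair(a, b, layout), classifyPair(b, a, layout))
})

test_that("sQTL linkage fractions equal brute-force interval overlap", {
  sqtl <- data.frame(chrom = c("A01", "D01"), start = c(1e6, 5e6),
                     end = c(2e6, 6e6))
  i1 <- GenomicRanges::GRanges(c("A01", "A01", "D01"),
    IRanges::IRanges(c(1.5e6, 3e6, 4e6), width = 2e5))
  i2 <- GenomicRanges::GRanges(c("D01", "A01", "D01"),
    IRanges::IRanges(c(8e6, 4e6, 5.5e6), width = 2e5))
  lk <- linkToSqtl(i1, i2, sqtl)
  expect_equal(lk$linked, c(TRUE, FALSE, TRUE))
  expect_equal(lk$fraction, 2 / 3)
  expect_equal(linkToSqtl(i1, i2, sqtl[0, ])$fraction, 0)
})

test_that("epistatic locus intervals are the bins containing the SNPs", {
  gm <- tinyGm(matrix(0:1, 4, 10), pos = c(100, 5e5, 1.2e6, 1.8e6))
  bins <- GenomicRanges::GRanges("A01",
    IRanges::IRanges(c(1, 1e6 + 1), c(1e6, 2e6)))
  bm <- new("BinMap", bins = bins,
            states = matrix(1L, 2, 10, dimnames = list(NULL, paste0("R", 1:10))),
            founders = "P1")
  expect_equal(GenomicRanges::start(epiInterval(2L, gm, bm)), 1)
  expect_equal(GenomicRanges::start(epiInterval(3L, gm, bm)), 1e6 + 1)
})

test_that("recombinant fractions separate hotspot from empty intervals", {
  set.seed(87)
  layout <- GenomeLayout(c("A01", "D01"), c(1e7, 1e7))
  ## 60 RILs, each with one breakpoint near 5 Mb on A01 (a hotspot)
  rows <- do.call(rbind, lapply(1:60, function(i) {
    bp <- 5e6 + sample(-2e4:2e4, 1L)
    rbind(data.frame(chrom = "A01", start = c(1, bp + 1), end = c(bp, 1e7),
                     ril = paste0("R", i), founder = c("P1", "P2")),
          data.frame(chrom = "D01", start = 1, end = 1e7,
                     ril = paste0("R", i), founder = "P1"))
  }))
  segs <- segGr(rows, layout)
  hot <- GenomicRanges::GRanges("A01", IRanges::IRanges(4.9e6, 5.1e6))
  cold <- GenomicRanges::GRanges("D01", IRanges::IRanges(1e6, 1.2e6))
  res <- recombinantFractionComparison(hot, cold, segs, layout,
                                       nRandom = 50, seed = 88)
  expect_equal(length(res$observed), 1L)
  expect_gt(res$observed, median(res$random))
  ## intervals with no breakpoints anywhere give fraction 0
  quiet <- GenomicRanges::GRanges("D01", IRanges::IRanges(2e6, 2.2e6))
  res0 <- recombinantFractionComparison(cold, quiet, segs, layout,
                                        nRandom = 10, seed = 89)
  expect_equal(res0$observed, 0)
})
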