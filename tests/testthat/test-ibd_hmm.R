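test_that("forward-backward equals exhaustive path enumeration", {
  layout <- GenomeLayout("A01", 1e7)
  params <- HmmParams(eps = 0.01, G = 11)
  set.seed(50)
  for (rep in 1:4) {
    S <- 6; K <- 3
    fc <- matrix(sample(c(0L, 0L, 2L, 2L, 1L), S * K, TRUE), S, K)
    truePath <- c(rep(1L, 3), rep(2L, 3))
    obs <- fc[cbind(seq_len(S), truePath)]
    obs[sample.int(S, 1L)] <- NA          # one missing call
    pos <- sort(sample.int(9e6, S))
    sites <- GenomicRanges::GRanges("A01", IRanges::IRanges(pos, width = 1L))
    post <- inferMosaic(obs, fc, sites, layout, params)
    oracle <- bruteForcePosterior(obs, fc, pos, 1e7, 0.01, 11, 1.5)
    expect_equal(unname(post), oracle, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(unname(rowSums(post)), rep(1, S), tolerance = 1e-9)
  }
})

test_that("dominant and uninformative likelihood limits behave", {
  layout <- GenomeLayout("A01", 1e7)
  set.seed(51)
  K <- 5; S <- 50
  ## founder 3 informative against every other founder at every site
  fc <- matrix(2L, S, K)
  fc[, 3L] <- 0L
  sites <- GenomicRanges::GRanges("A01",
    IRanges::IRanges(sort(sample.int(5e5, S)), width = 1L))
  post <- inferMosaic(fc[, 3L], fc, sites, layout, HmmParams())
  expect_true(all(post[, 3L] > 0.999))
  ## all founders identical: uniform posterior
  fcSame <- matrix(rep(fc[, 1L], K), S, K)
  postU <- inferMosaic(fc[, 1L], fcSame, sites, layout, HmmParams())
  expect_equal(unname(postU), matrix(1 / K, S, K), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## all-missing RIL: uniform and flagged
  postM <- inferMosaic(rep(NA_integer_, S), fc, sites, layout, HmmParams())
  expect_true(attr(postM, "allMissing"))
  expect_equal(unname(postM), matrix(1 / K, S, K), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("segment calling applies the 2/K rule and midpoint boundaries", {
  layout <- GenomeLayout("A01", 100)
  sites <- GenomicRanges::GRanges("A01",
    IRanges::IRanges(c(10, 20, 30, 40), width = 1L))
  post <- matrix(0.02, 4, 11, dimnames = list(NULL, paste0("P", 1:11)))
  post[1:2, 1L] <- 0.8; post[3:4, 2L] <- 0.8
  post <- post / rowSums(post)
  segs <- callSegments(post, sites, layout, HmmParams(), ril = "R1")
  expect_equal(length(segs), 2L)
  expect_equal(GenomicRanges::end(segs)[1L], 25)
  expect_equal(GenomicRanges::start(segs)[2L], 26)
  expect_equal(GenomicRanges::start(segs)[1L], 1)
  expect_equal(GenomicRanges::end(segs)[2L], 100)
  expect_equal(S4Vectors::mcols(segs)$founder, c("P1", "P2"))
  ## max posterior 0.17 < 2/11: unknown
  postU <- matrix((1 - 0.17) / 10, 4, 11)
  postU[, 4L] <- 0.17
  segsU <- callSegments(postU, sites, layout, HmmParams(), ril = "R1")
  expect_equal(unique(S4Vectors::mcols(segsU)$founder), "unknown")
  ## constant label: exactly one segment spanning the chromosome
  post1 <- matrix(rep(post[1L, ], each = 4), 4)
  segs1 <- callSegments(post1, sites, layout, HmmParams())
  expect_equal(length(segs1), 1L)
  expect_equal(GenomicRanges::width(segs1), 100)
})

test_that("mosaic summaries add to 100% and flag partition violations", {
  layout <- GenomeLayout("A01", 1000)
  one <- segGr(data.frame(chrom = "A01", start = 1, end = 1000,
                          ril = "R1", founder = "P5"), layout)
  sm <- summarizeMosaics(one, layout)
  expect_equal(unname(sm$contributions["P5"]), 100)
  two <- segGr(data.frame(chrom = "A01", start = c(1, 501),
                          end = c(500, 1000), ril = "R1",
                          founder = c("P1", "P2")), layout)
  sm2 <- summarizeMosaics(two, layout)
  expect_equal(unname(sm2$contributions[c("P1", "P2")]), c(50, 50))
  bad <- segGr(data.frame(chrom = "A01", start = 1, end = 700,
                          ril = "R1", founder = "P1"), layout)
  expect_error(summarizeMosaics(bad, layout), "partition")
})

test_that("breakpoint windows count hand-placed events, hotspot rule is >", {
  layout <- GenomeLayout("A01", 1e7)
  ## one RIL, one switch: a single breakpoint
  segs <- segGr(data.frame(chrom = "A01", start = c(1, 5e6 + 1),
                           end = c(5e6, 1e7), ril = "R1",
                           founder = c("P1", "P2")), layout)
  bh <- breakpointsHotspots(segs, layout)
  expect_equal(length(bh$breakpoints), 1L)
  expect_equal(GenomicRanges::start(bh$breakpoints), 5e6)
  ## unknown-flanked boundaries are excluded by default, kept on request
  segsU <- segGr(data.frame(chrom = "A01", start = c(1, 4e6 + 1, 6e6 + 1),
                            end = c(4e6, 6e6, 1e7), ril = "R1",
                            founder = c("P1", "unknown", "P2")), layout)
  expect_equal(length(breakpointsHotspots(segsU, layout)$breakpoints), 0L)
  expect_equal(length(breakpointsHotspots(segsU, layout,
    excludeUnknown = FALSE)$breakpoints), 2L)
  ## 10 hand-placed breakpoints across many RILs vs direct window counts
  set.seed(52)
  bpPos <- sort(sample.int(9e6, 10))
  rows <- do.call(rbind, lapply(seq_along(bpPos), function(i)
    data.frame(chrom = "A01", start = c(1, bpPos[i] + 1),
               end = c(bpPos[i], 1e7), ril = paste0("R", i),
               founder = c("P1", "P2"))))
  bh10 <- breakpointsHotspots(segGr(rows, layout), layout,
                              windowBp = 2e6, stepBp = 1e6)
  ws <- GenomicRanges::start(bh10$windows)
  we <- GenomicRanges::end(bh10$windows)
  oracle <- vapply(seq_along(ws), function(i)
    sum(bpPos >= ws[i] & bpPos <= we[i]), integer(1))
  expect_equal(S4Vectors::mcols(bh10$windows)$count, oracle)
  ## hotspot boundary: 51 events is a hotspot, 50 is not
  rows51 <- do.call(rbind, lapply(1:51, function(i)
    data.frame(chrom = "A01", start = c(1, 1e6 + i),
               end = c(1e6 + i - 1, 1e7), ril = paste0("R", i),
               founder = c("P1", "P2"))))
  bh51 <- breakpointsHotspots(segGr(rows51, layout), layout)
  expect_true(any(S4Vectors::mcols(bh51$windows)$hotspot))
  bh50 <- breakpointsHotspots(segGr(rows51[-(1:2), ], layout), layout)
  expect_false(any(S4Vectors::mcols(bh50$windows)$hotspot))
})

test_that("more missingness never increases the confidently assigned share", {
  set.seed(53)
  layout <- GenomeLayout(c("A01", "D01"), c(3e7, 3e7))
  panel <- simulateFounders(layout, nFounders = 11, nSites = 800)
  pop <- breedPopulation(panel, linesPerFamily = 1, popPerFamily = 6)
  gm <- realizeGenotypes(pop)
  fg <- founderGenotypes(panel)
  assignedFrac <- vapply(c(0, 0.2, 0.5), function(mr) {
    obs <- degradeGenotypes(gm, missingRate = mr, errorRate = 0.01,
                            seed = 54)
    segs <- inferMosaics(obs, fg, layout)
    md <- S4Vectors::mcols(segs)
    sum(GenomicRanges::width(segs)[md$founder != "unknown"]) /
      sum(GenomicRanges::width(segs))
  }, numeric(1))
  expect_true(all(diff(assignedFrac) <= 0.02))
})
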