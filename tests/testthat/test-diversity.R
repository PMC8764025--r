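## hand-built annotation fixture: one plus-strand two-exon gene, one
## minus-strand single-exon gene, one broken-CDS gene on a 5-kb chromosome
annotFixture <- function() {
  base <- rep("G", 5000)
  base[2056] <- "A"                     # codon 2 of gene1: GGA (Gly)
  base[2060:2062] <- c("T", "G", "G")   # codon 4 of gene1: TGG (Trp)
  seqs <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(seqs) <- "A01"
  tx <- GenomicRanges::GRanges("A01",
    IRanges::IRanges(c(2001, 4001, 3001), c(2600, 4300, 3100)),
    strand = c("+", "-", "+"),
    txId = c("t1", "t2", "t3"), geneId = c("g1", "g2", "g3"))
  exons <- GenomicRanges::GRanges("A01",
    IRanges::IRanges(c(2001, 2201, 4001, 3001), c(2100, 2600, 4300, 3050)),
    strand = c("+", "+", "-", "+"),
    txId = c("t1", "t1", "t2", "t3"))
  cds <- GenomicRanges::GRanges("A01",
    IRanges::IRanges(c(2051, 2201, 4001, 3001), c(2100, 2351, 4300, 3050)),
    strand = c("+", "+", "-", "+"),
    txId = c("t1", "t1", "t2", "t3"))
  list(models = list(tx = tx, exons = exons, cds = cds), refSeq = seqs)
}

snpAt <- function(pos, alt, ref = "G") {
  GenomicRanges::GRanges("A01", IRanges::IRanges(pos, width = 1L),
                         ref = ref, alt = alt)
}

test_that("SNP annotation classifies regions with the stated precedence", {
  fx <- annotFixture()
  sites <- c(snpAt(2056, "G", ref = "A"),  # GGA -> GGG, synonymous
             snpAt(2058, "A"),             # GGG -> GAG, non-synonymous
             snpAt(2062, "A"),             # TGG -> TGA, stop-gain
             snpAt(2102, "A"),             # intron, 2 bp from junction
             snpAt(2150, "A"),             # plain intronic
             snpAt(2099, "A"),             # exonic but near junction
             snpAt(1002, "A"),             # 999 bp upstream
             snpAt(1000, "A"),             # 1001 bp upstream -> intergenic
             snpAt(4299, "A"))             # minus strand: CCC -> CTC
  ann <- suppressWarnings(annotateSnps(sites, fx$models, fx$refSeq))
  expect_equal(ann$region,
               c("exonic", "exonic", "exonic", "splicing", "intronic",
                 "exonic", "upstream_downstream", "intergenic", "exonic"))
  expect_equal(ann$coding[1:3],
               c("synonymous", "non_synonymous", "stop_gain"))
  expect_equal(ann$aaFrom[2L], "G"); expect_equal(ann$aaTo[2L], "E")
  expect_equal(ann$aaPos[2L], 3L)
  expect_true(ann$splicingFlag[6L])
  ## minus-strand codon translated on the annotated strand
  expect_equal(ann$coding[9L], "non_synonymous")
  expect_equal(ann$aaFrom[9L], "P"); expect_equal(ann$aaTo[9L], "L")
  expect_equal(ann$aaPos[9L], 1L)
  ## broken CDS is skipped with a warning, region still exonic
  expect_warning(a3 <- annotateSnps(snpAt(3010, "A"), fx$models, fx$refSeq),
                 "divisible")
  expect_equal(a3$region, "exonic")
  expect_true(is.na(a3$coding))
  ## classes are exclusive and exhaustive
  expect_true(all(ann$region %in% c("exonic", "splicing", "intronic",
                                    "upstream_downstream", "intergenic")))
  expect_error(annotateSnps(snpAt(9999, "A"), fx$models, fx$refSeq),
               "outside")
})

test_that("heterozygosity counts het calls among non-missing", {
  expect_equal(heterozygosity(tinyGm(matrix(c(0L, 2L, 0L, 2L), 2)))$overall, 0)
  expect_equal(heterozygosity(tinyGm(matrix(1L, 3, 2)))$overall, 1)
  gm <- tinyGm(rbind(c(0L, 1L), c(NA, 1L)))
  expect_equal(heterozygosity(gm)$overall, 2 / 3)
  expect_error(heterozygosity(tinyGm(matrix(NA_integer_, 2, 2))), "missing")
})

test_that("PCA separates structured samples and matches a direct SVD", {
  set.seed(40)
  grpA <- matrix(rbinom(30 * 25, 2, 0.1), 30, 25)
  grpB <- matrix(rbinom(30 * 25, 2, 0.9), 30, 25)
  gm <- tinyGm(cbind(t(grpA), t(grpB)))
  p <- genoPca(gm, k = 5, mafMin = 0)
  expect_gt(abs(mean(p$scores[1:25, 1L]) - mean(p$scores[26:50, 1L])), 1)
  expect_gt(p$varExplained[1L], max(p$varExplained[-1L]))
  ## duplicated samples get identical scores
  X <- matrix(rbinom(200, 2, 0.4), 20, 10)
  gmd <- tinyGm(cbind(X, X))
  pd <- genoPca(gmd, k = 3, mafMin = 0)
  expect_equal(unname(pd$scores[1:10, ]), unname(pd$scores[11:20, ]),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## variance fractions equal an independent eigendecomposition
  set.seed(41)
  R <- matrix(rbinom(50 * 200, 2, 0.3), 50, 200)
  gmr <- tinyGm(t(R))
  pr <- genoPca(gmr, k = 10, mafMin = 0)
  Z <- scale(R[, apply(R, 2, sd) > 0])
  ev <- eigen(cov(Z), symmetric = TRUE)$values
  expect_equal(pr$varExplained, (ev / sum(ev))[1:10], tolerance = 1e-8)
  expect_lte(sum(pr$varExplained), 1)
  expect_error(genoPca(gmr, k = 100), "sample")
})

test_that("random mating leaves no dominant structure axis", {
  fx <- deskFixture()
  p <- genoPca(fx$gm, k = 5)
  expect_lt(sum(p$varExplained[1:2]), 0.10)
})

test_that("LD r2 equals squared Pearson correlation of dosages", {
  x1 <- c(0, 0, 1, 1, 2, 2, 0, 2)
  x2 <- c(0, 1, 1, 2, 2, 2, 0, 0)
  layout <- GenomeLayout("A01", 2e6)
  gm <- tinyGm(rbind(x1, x2, x1), pos = c(1000, 9000, 30000),
               layout = layout)
  ld <- ldDecay(gm, layout, smoothWin = 1)
  bin <- ceiling(8000 / 5000)
  expect_equal(ld$r2[bin], cor(x1, x2)^2)
  binDup <- ceiling(29000 / 5000)
  expect_equal(ld$r2[binDup], 1)       # duplicated site pair
  ## independent sites: mean r2 ~ 1/n
  set.seed(42)
  n <- 200
  Xi <- matrix(rbinom(n * 120, 2, 0.5), 120, n)
  gmi <- tinyGm(Xi, pos = sort(sample.int(1.9e6, 120)), layout = layout)
  ldi <- ldDecay(gmi, layout, smoothWin = 1)
  expect_lt(abs(weighted.mean(ldi$r2, ldi$n, na.rm = TRUE) - 1 / n), 0.003)
})

test_that("LD on the MAGIC fixture decays with distance", {
  fx <- deskFixture()
  ld <- ldDecay(fx$gm, fx$layout, subgenome = "A")
  near <- weighted.mean(ld$r2[ld$dist < 1e5], ld$n[ld$dist < 1e5],
                        na.rm = TRUE)
  far <- weighted.mean(ld$r2[ld$dist > 1.5e6], ld$n[ld$dist > 1.5e6],
                       na.rm = TRUE)
  expect_gt(near, far)
  expect_true(is.finite(ld$halvingDistance))
  expect_true(all(ld$r2 >= 0 & ld$r2 <= 1, na.rm = TRUE))
})
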