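## Population-descriptive layer: SNP functional annotation against gene
## models, heterozygosity, PCA, and LD decay with halving distance.

#' Read gene models from a GFF3 file
#'
#' Extracts mRNA/exon/CDS features into the light structure used by
#' \code{\link{annotateSnps}}.  Requires the rtracklayer package.
#'
#' @param path GFF3 path
#' @return list with \code{tx}, \code{exons}, \code{cds} GRanges (exons and
#'   CDS carry a \code{txId} metadata column; tx carries \code{txId} and
#'   \code{geneId})
#' @export
readGeneModels <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3")
  g <- rtracklayer::import(path, format = "gff3")
  ty <- tolower(as.character(g$type))
  tx <- g[ty %in% c("mrna", "transcript")]
  parent1 <- function(x) vapply(as.list(x$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  txOut <- GenomicRanges::granges(tx)
  S4Vectors::mcols(txOut)$txId <- tx$ID
  S4Vectors::mcols(txOut)$geneId <- parent1(tx)
  ex <- g[ty == "exon"]; cds <- g[ty == "cds"]
  exOut <- GenomicRanges::granges(ex)
  S4Vectors::mcols(exOut)$txId <- parent1(ex)
  cdsOut <- GenomicRanges::granges(cds)
  S4Vectors::mcols(cdsOut)$txId <- parent1(cds)
  list(tx = txOut, exons = exOut, cds = cdsOut)
}

aaName <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon)))
}

revcompBase <- function(b) chartr("ACGT", "TGCA", b)

#' Functional annotation of SNPs against gene models
#'
#' Region classes follow the precedence exonic > splicing > intronic >
#' upstream/downstream > intergenic, with splicing defined as an intronic
#' variant within 2 bp of a splice junction and upstream/downstream as
#' within 1 kb of a transcript start or end.  Exonic SNPs inside a CDS get a
#' coding class (synonymous, non-synonymous, stop-gain, stop-loss) from
#' translating the reference and alternate codons on the annotated strand;
#' amino-acid changes are reported 1-based in protein coordinates.  A
#' splicing flag marks any variant (exonic or intronic) within 2 bp of a
#' junction.  Transcripts whose CDS length is not divisible by 3 are skipped
#' with a warning.
#'
#' @param sites GRanges of SNPs with \code{ref}/\code{alt} metadata
#' @param models gene models as from \code{\link{readGeneModels}} (or built
#'   in code with the same shape)
#' @param refSeq named \link[Biostrings]{DNAStringSet} covering the sites
#' @param flankBp upstream/downstream window (default 1000)
#' @param spliceBp splice-junction window (default 2)
#' @return data.frame per SNP: \code{region}, \code{coding}, \code{gene},
#'   \code{aaFrom}, \code{aaPos}, \code{aaTo}, \code{splicingFlag}
#' @export
annotateSnps <- function(sites, models, refSeq, flankBp = 1000L,
                         spliceBp = 2L) {
  n <- length(sites)
  chrAll <- as.character(GenomicRanges::seqnames(sites))
  if (!all(chrAll %in% names(refSeq)))
    stop("site outside reference sequence")
  if (any(GenomicRanges::start(sites) >
          Biostrings::width(refSeq)[match(chrAll, names(refSeq))]))
    stop("site outside reference sequence")
  out <- data.frame(region = rep("intergenic", n),
                    coding = NA_character_, gene = NA_character_,
                    aaFrom = NA_character_, aaPos = NA_integer_,
                    aaTo = NA_character_, splicingFlag = FALSE)
  ovTx <- GenomicRanges::findOverlaps(sites, models$tx, ignore.strand = TRUE)
  ovEx <- GenomicRanges::findOverlaps(sites, models$exons,
                                      ignore.strand = TRUE)
  exonic <- unique(S4Vectors::queryHits(ovEx))
  genic <- unique(S4Vectors::queryHits(ovTx))
  intronic <- setdiff(genic, exonic)
  flank <- GenomicRanges::resize(models$tx,
    GenomicRanges::width(models$tx) + 2L * flankBp, fix = "center")
  nearGene <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(sites, flank, ignore.strand = TRUE)))
  updown <- setdiff(nearGene, genic)
  out$region[updown] <- "upstream_downstream"
  out$region[intronic] <- "intronic"
  out$region[exonic] <- "exonic"

  ## splice-junction proximity: internal exon boundaries of multi-exon tx
  exByTx <- split(models$exons, models$exons$txId)
  jPos <- list(); jChr <- list()
  for (txid in names(exByTx)) {
    e <- GenomicRanges::sort(exByTx[[txid]], ignore.strand = TRUE)
    if (length(e) < 2L) next
    st <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
    jPos[[txid]] <- c(en[-length(en)], st[-1L])   # internal boundaries
    jChr[[txid]] <- rep(as.character(GenomicRanges::seqnames(e))[1L],
                        2L * (length(e) - 1L))
  }
  if (length(jPos)) {
    jp <- unlist(jPos, use.names = FALSE)
    jgr <- GenomicRanges::GRanges(unlist(jChr, use.names = FALSE),
      IRanges::IRanges(jp - spliceBp, jp + spliceBp))
    nearJ <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(sites, jgr, ignore.strand = TRUE)))
    out$splicingFlag[nearJ] <- TRUE
    out$region[intersect(nearJ, intronic)] <- "splicing"
  }

  ## gene assignment: first overlapping transcript's gene
  if (length(ovTx)) {
    first <- !duplicated(S4Vectors::queryHits(ovTx))
    out$gene[S4Vectors::queryHits(ovTx)[first]] <-
      models$tx$geneId[S4Vectors::subjectHits(ovTx)[first]]
  }

  ## coding consequences within CDS
  cdsByTx <- split(models$cds, models$cds$txId)
  ovCds <- GenomicRanges::findOverlaps(sites, models$cds,
                                       ignore.strand = TRUE)
  badTx <- character(0)
  for (h in seq_along(ovCds)) {
    i <- S4Vectors::queryHits(ovCds)[h]
    if (!is.na(out$coding[i])) next
    txid <- models$cds$txId[S4Vectors::subjectHits(ovCds)[h]]
    cds <- GenomicRanges::sort(cdsByTx[[txid]], ignore.strand = TRUE)
    strand <- as.character(GenomicRanges::strand(cds))[1L]
    chrom <- as.character(GenomicRanges::seqnames(cds))[1L]
    lens <- GenomicRanges::width(cds)
    if (sum(lens) %% 3L != 0L) { badTx <- c(badTx, txid); next }
    seqs <- vapply(seq_along(cds), function(k) as.character(
      Biostrings::subseq(refSeq[[chrom]], GenomicRanges::start(cds)[k],
                         GenomicRanges::end(cds)[k])), character(1))
    cdsSeq <- paste(seqs, collapse = "")
    pos <- GenomicRanges::start(sites)[i]
    off <- cumsum(c(0L, lens))
    k <- which(GenomicRanges::start(cds) <= pos &
               GenomicRanges::end(cds) >= pos)[1L]
    cdsPosPlus <- off[k] + pos - GenomicRanges::start(cds)[k] + 1L
    refB <- substr(cdsSeq, cdsPosPlus, cdsPosPlus)
    altB <- S4Vectors::mcols(sites)$alt[i]
    if (strand == "-") {
      cdsSeq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cdsSeq)))
      cdsPos <- sum(lens) - cdsPosPlus + 1L
      refB <- revcompBase(refB)
      altB <- revcompBase(altB)
    } else cdsPos <- cdsPosPlus
    codIdx <- (cdsPos - 1L) %/% 3L
    within <- (cdsPos - 1L) %% 3L + 1L
    codon <- substr(cdsSeq, codIdx * 3L + 1L, codIdx * 3L + 3L)
    altCodon <- codon
    substr(altCodon, within, within) <- altB
    aa1 <- aaName(codon); aa2 <- aaName(altCodon)
    cls <- if (aa1 == aa2) "synonymous"
      else if (aa2 == "*") "stop_gain"
      else if (aa1 == "*") "stop_loss"
      else "non_synonymous"
    out$coding[i] <- cls
    out$aaFrom[i] <- aa1; out$aaPos[i] <- codIdx + 1L; out$aaTo[i] <- aa2
  }
  if (length(badTx))
    warning("CDS length not divisible by 3; skipped: ",
            paste(unique(badTx), collapse = ", "))
  out
}

#' Heterozygosity of a genotype matrix
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @return list with \code{overall} (fraction of non-missing calls that are
#'   heterozygous) and \code{perSample}
#' @export
heterozygosity <- function(gm) {
  cl <- genotypeCalls(gm)
  if (all(is.na(cl))) stop("all calls missing")
  list(overall = mean(cl == 1L, na.rm = TRUE),
       perSample = colMeans(cl == 1L, na.rm = TRUE))
}

#' Principal components of a genotype matrix
#'
#' Dosages are MAF-filtered, mean-imputed, centered and scaled to unit
#' variance; scores and per-component variance fractions come from the
#' singular value decomposition of the sample matrix.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param k number of components
#' @param mafMin MAF filter (default 0.05)
#' @return list with \code{scores} (samples x k) and \code{varExplained}
#'   (fractions of total variance, summing to <= 1)
#' @export
genoPca <- function(gm, k = 10L, mafMin = 0.05) {
  if (k > ncol(gm)) stop("k exceeds the sample count")
  keep <- which(maf(gm) >= mafMin)
  X <- codeGenotypes(gm)[, keep, drop = FALSE]
  sds <- apply(X, 2L, sd)
  X <- X[, sds > 0, drop = FALSE]
  X <- scale(X)
  sv <- svd(X, nu = k, nv = 0)
  scores <- sv$u * rep(sv$d[seq_len(k)], each = nrow(X))
  rownames(scores) <- rownames(X)
  list(scores = scores, varExplained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' LD decay curve and halving distance for one subgenome
#'
#' r-squared is the squared Pearson correlation of 0/1/2 dosage codings
#' between all intra-chromosomal SNP pairs up to \code{maxDist} apart,
#' averaged in \code{binBp} windows of distance.  The halving distance is
#' the smallest distance at which the (moving-average smoothed) curve first
#' drops below half of its maximum; the r-squared value there is reported
#' alongside.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param layout \linkS4class{GenomeLayout}
#' @param subgenome \code{"A"}, \code{"D"} or \code{"other"}; NULL uses all
#'   chromosomes
#' @param maxDist maximum pair distance (default 2 Mb)
#' @param binBp distance-bin width (default 5 kb)
#' @param smoothWin moving-average window (bins) for the halving rule
#' @return list with \code{dist} (bin midpoints), \code{r2} (mean per bin),
#'   \code{n} (pairs per bin), \code{halvingDistance}, \code{r2AtHalving}
#' @export
ldDecay <- function(gm, layout, subgenome = NULL, maxDist = 2e6,
                    binBp = 5e3, smoothWin = 5L) {
  rr <- siteRanges(gm)
  chrAll <- as.character(GenomicRanges::seqnames(rr))
  chroms <- layout@chrom
  if (!is.null(subgenome)) chroms <- chroms[subgenomes(layout) == subgenome]
  nBins <- ceiling(maxDist / binBp)
  sums <- numeric(nBins); cnts <- numeric(nBins)
  X <- codeGenotypes(gm)
  for (cc in chroms) {
    idx <- which(chrAll == cc)
    if (length(idx) < 2L) next
    pos <- GenomicRanges::start(rr)[idx]
    Xc <- X[, idx, drop = FALSE]
    ok <- apply(Xc, 2L, sd) > 0
    Xc <- Xc[, ok, drop = FALSE]; pos <- pos[ok]
    m <- ncol(Xc)
    if (m < 2L) next
    chunk <- 512L
    starts <- seq(1L, m, by = chunk)
    for (s in starts) {
      e <- min(s + chunk - 1L, m)
      hi <- findInterval(pos[e] + maxDist, pos)
      C <- suppressWarnings(cor(Xc[, s:e, drop = FALSE],
                                Xc[, s:hi, drop = FALSE]))
      for (a in seq_len(e - s + 1L)) {
        i <- s + a - 1L
        jj <- which(pos[s:hi] > pos[i] & pos[s:hi] - pos[i] <= maxDist)
        if (!length(jj)) next
        d <- pos[s:hi][jj] - pos[i]
        r2 <- C[a, jj]^2
        b <- pmin(nBins, ceiling(d / binBp))
        tb <- tapply(r2, b, sum); nb <- table(b)
        bi <- as.integer(names(tb))
        sums[bi] <- sums[bi] + tb
        cnts[bi] <- cnts[bi] + as.numeric(nb)
      }
    }
  }
  mean2 <- ifelse(cnts > 0, sums / cnts, NA_real_)
  mids <- (seq_len(nBins) - 0.5) * binBp
  sm <- mean2
  if (smoothWin > 1L) {
    f <- rep(1 / smoothWin, smoothWin)
    ok <- !is.na(mean2)
    sm[ok] <- stats::filter(mean2[ok], f, sides = 2)
    ## edges keep the raw means
    sm[is.na(sm) & ok] <- mean2[is.na(sm) & ok]
  }
  half <- max(sm, na.rm = TRUE) / 2
  below <- which(!is.na(sm) & sm < half)
  hd <- if (length(below)) mids[below[1L]] else NA_real_
  list(dist = mids, r2 = mean2, n = cnts, halvingDistance = hd,
       r2AtHalving = if (length(below)) sm[below[1L]] else NA_real_)
}
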