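## Founder-mosaic reconstruction.  States are the K founders; emissions
## compare the RIL's diploid call with each founder's call under an error
## rate eps; transitions between adjacent SNPs follow an exponential map of
## physical distance scaled by the effective meiosis count G.  Chromosomes
## are unlinked and run independently through forward-backward.

emissionMatrix <- function(obs, founderCalls, eps) {
  ## obs: length-S vector of RIL calls; founderCalls: S x K matrix
  S <- length(obs); K <- ncol(founderCalls)
  E <- matrix(1, S, K)
  fHom <- founderCalls %in% c(0L, 2L)
  dim(fHom) <- dim(founderCalls)
  obsM <- matrix(obs, S, K)
  known <- !is.na(obsM) & !is.na(founderCalls)
  ## heterozygous RIL call, or heterozygous founder call: half-match
  half <- known & (obsM == 1L | founderCalls == 1L)
  E[half] <- 0.5
  homo <- known & !half
  E[homo] <- ifelse(obsM[homo] == founderCalls[homo], 1 - eps, eps)
  E
}

#' Posterior founder probabilities for one RIL
#'
#' Runs forward-backward per chromosome.  The transition from SNP i to i+1 is
#' stay with probability 1 - r and switch to each other founder with
#' r / (K - 1), where r = 1 - exp(-G * c * d), d the physical gap and c the
#' per-bp crossover rate (crossovers per chromosome divided by chromosome
#' length).
#'
#' @param obs integer vector of the RIL's calls (0/1/2, NA missing) over the
#'   shared site list
#' @param founderCalls matrix (sites x founders) of founder calls
#' @param sites GRanges of the shared site list
#' @param layout \linkS4class{GenomeLayout} (chromosome lengths set the
#'   crossover rate)
#' @param params \linkS4class{HmmParams}
#' @return matrix (sites x founders) of posterior probabilities, each row
#'   summing to 1; attribute \code{"allMissing"} flags a RIL with no data
#' @export
inferMosaic <- function(obs, founderCalls, sites, layout,
                        params = HmmParams()) {
  if (length(obs) != nrow(founderCalls) || length(obs) != length(sites))
    stop("RIL, founders and site list must share the same sites")
  K <- ncol(founderCalls)
  if (K < 2L) stop("need at least 2 founders")
  E <- emissionMatrix(obs, founderCalls, params@eps)
  chr <- as.character(GenomicRanges::seqnames(sites))
  pos <- GenomicRanges::start(sites)
  lens <- chromLengths(layout)
  post <- matrix(NA_real_, length(obs), K,
                 dimnames = list(NULL, colnames(founderCalls)))
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    S <- length(idx)
    cRate <- params@xoverPerChrom / lens[[cc]]
    r <- 1 - exp(-params@G * cRate * diff(pos[idx]))
    Ec <- E[idx, , drop = FALSE]
    ## forward with per-site scaling
    alpha <- matrix(0, S, K)
    a <- Ec[1L, ] / K
    alpha[1L, ] <- a / sum(a)
    if (S > 1L) for (i in 2:S) {
      sw <- r[i - 1L] / (K - 1)
      a <- ((1 - r[i - 1L] - sw) * alpha[i - 1L, ] + sw) * Ec[i, ]
      alpha[i, ] <- a / sum(a)
    }
    beta <- matrix(1 / K, S, K)
    b <- rep(1, K)
    if (S > 1L) for (i in (S - 1L):1L) {
      sw <- r[i] / (K - 1)
      eb <- Ec[i + 1L, ] * b
      b <- (1 - r[i] - sw) * eb + sw * sum(eb)
      b <- b / sum(b)
      beta[i, ] <- b
    } else beta[1L, ] <- 1
    p <- alpha * beta
    post[idx, ] <- p / rowSums(p)
  }
  attr(post, "allMissing") <- all(is.na(obs))
  post
}

#' Segment a mosaic posterior into founder-labelled IBD blocks
#'
#' Each site is labelled with the argmax founder only if its posterior
#' exceeds m/K (m the unknown-assignment multiplier, K the founder count),
#' otherwise \code{"unknown"}; ties go to the lowest founder index.  Maximal
#' runs of one label become segments, with boundaries at the midpoint
#' between adjacent differently-labelled sites, and the first/last segment
#' extended to the chromosome ends.
#'
#' @param post posterior matrix from \code{\link{inferMosaic}}
#' @param sites GRanges of the site list
#' @param layout \linkS4class{GenomeLayout}
#' @param params \linkS4class{HmmParams}
#' @param ril RIL label stored in the output
#' @return GRanges with mcols \code{ril}, \code{founder}, \code{meanProb}
#' @export
callSegments <- function(post, sites, layout, params = HmmParams(),
                         ril = "RIL") {
  K <- ncol(post)
  founders <- colnames(post)
  if (is.null(founders)) founders <- paste0("P", seq_len(K))
  thr <- params@unknownMult / K
  top <- max.col(post, ties.method = "first")
  pmax <- post[cbind(seq_len(nrow(post)), top)]
  lab <- ifelse(pmax > thr, top, 0L)   # 0 = unknown
  chr <- as.character(GenomicRanges::seqnames(sites))
  pos <- GenomicRanges::start(sites)
  lens <- chromLengths(layout)
  out <- list()
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    l <- lab[idx]; p <- pos[idx]
    brk <- which(l[-1L] != l[-length(l)])
    ends <- c(floor((p[brk] + p[brk + 1L]) / 2), lens[[cc]])
    starts <- c(1, head(ends, -1) + 1)
    runIdx <- c(0L, brk)
    mp <- vapply(seq_along(starts), function(s) {
      lo <- runIdx[s] + 1L
      hi <- if (s < length(starts)) runIdx[s + 1L] else length(l)
      f <- l[lo]
      if (f == 0L) NA_real_ else mean(post[idx[lo:hi], f])
    }, numeric(1))
    fLab <- ifelse(l[runIdx + 1L] == 0L, "unknown", founders[l[runIdx + 1L]])
    out[[cc]] <- GenomicRanges::GRanges(cc, IRanges::IRanges(starts, ends),
      ril = ril, founder = fLab, meanProb = mp)
  }
  gr <- suppressWarnings(do.call(c, unname(out)))
  GenomeInfoDb::seqlevels(gr) <- layout@chrom
  GenomeInfoDb::seqinfo(gr) <- asSeqinfo(layout)
  gr
}

#' Reconstruct founder mosaics for all RILs
#'
#' @param gmRils \linkS4class{GenotypeMatrix} of RIL calls
#' @param gmFounders \linkS4class{GenotypeMatrix} of founder calls (same
#'   sites)
#' @param layout \linkS4class{GenomeLayout}
#' @param params \linkS4class{HmmParams}
#' @return GRanges of IBD segments over all RILs (mcols \code{ril},
#'   \code{founder}, \code{meanProb})
#' @export
inferMosaics <- function(gmRils, gmFounders, layout, params = HmmParams()) {
  if (nrow(gmRils) != nrow(gmFounders) ||
      !all(GenomicRanges::start(siteRanges(gmRils)) ==
           GenomicRanges::start(siteRanges(gmFounders))))
    stop("RIL and founder matrices must share the same site list")
  fc <- genotypeCalls(gmFounders)
  cl <- genotypeCalls(gmRils)
  sites <- siteRanges(gmRils)
  segs <- vector("list", ncol(cl))
  for (i in seq_len(ncol(cl))) {
    post <- inferMosaic(cl[, i], fc, sites, layout, params)
    segs[[i]] <- callSegments(post, sites, layout, params,
                              ril = colnames(cl)[i])
  }
  out <- suppressWarnings(do.call(c, segs))
  mmLog("infer_ibd", rils = ncol(cl), segments = length(out),
        unknownFrac = round(sum(GenomicRanges::width(
          out[S4Vectors::mcols(out)$founder == "unknown"])) /
          sum(GenomicRanges::width(out)), 4))
  out
}

#' Summaries of a mosaic segment set
#'
#' Founder contributions (percent of genome, with unknown listed alongside),
#' segment counts and mean lengths per subgenome, and per-RIL segment counts.
#' Contributions and the unknown share sum to 100 per RIL and in aggregate.
#'
#' @param segments GRanges of IBD segments (all RILs)
#' @param layout \linkS4class{GenomeLayout}
#' @return list with \code{contributions} (percent per founder label),
#'   \code{bySubgenome} (assigned-segment count and mean length), and
#'   \code{perRil} (segment counts)
#' @export
summarizeMosaics <- function(segments, layout) {
  md <- S4Vectors::mcols(segments)
  w <- GenomicRanges::width(segments)
  rils <- unique(md$ril)
  glen <- sum(chromLengths(layout))
  for (r in rils) {
    tot <- sum(w[md$ril == r])
    if (abs(tot - glen) > 0.5)
      stop("segments of ", r, " do not partition the genome")
  }
  contrib <- 100 * vapply(split(w, md$founder), sum, numeric(1)) /
    sum(w)
  sub <- subgenomes(layout)[as.character(GenomicRanges::seqnames(segments))]
  assigned <- md$founder != "unknown"
  bySub <- do.call(rbind, lapply(split(which(assigned), sub[assigned]),
    function(i) data.frame(n = length(i), meanLength = mean(w[i]))))
  perRil <- table(md$ril)
  list(contributions = contrib, bySubgenome = bySub,
       perRil = as.vector(perRil[rils]))
}

#' Pooled recombination breakpoints, window counts and hotspots
#'
#' A breakpoint is the internal boundary between two differently-labelled
#' adjacent segments of one RIL; boundaries adjacent to an unknown segment
#' are excluded by default (they reflect assignment failure rather than
#' recombination).  Events are counted in sliding windows and windows with
#' more than \code{hotspotCount} events are flagged as hotspots.
#'
#' @param segments GRanges of IBD segments (all RILs)
#' @param layout \linkS4class{GenomeLayout}
#' @param windowBp sliding-window size (default 2 Mb)
#' @param stepBp window step (default 1 Mb)
#' @param hotspotCount hotspot threshold: hotspot iff count > this
#'   (default 50)
#' @param excludeUnknown drop boundaries flanking unknown segments
#' @return list with \code{breakpoints} (GRanges of positions, mcol
#'   \code{ril}) and \code{windows} (GRanges with \code{count},
#'   \code{hotspot})
#' @export
breakpointsHotspots <- function(segments, layout, windowBp = 2e6,
                                stepBp = 1e6, hotspotCount = 50L,
                                excludeUnknown = TRUE) {
  stopifnot(windowBp >= stepBp, stepBp > 0)
  md <- S4Vectors::mcols(segments)
  chr <- as.character(GenomicRanges::seqnames(segments))
  o <- order(md$ril, chr, GenomicRanges::start(segments))
  bp <- list(); k <- 0L
  rl <- md$ril[o]; ch <- chr[o]
  en <- GenomicRanges::end(segments)[o]; fo <- md$founder[o]
  same <- rl[-1L] == rl[-length(rl)] & ch[-1L] == ch[-length(ch)]
  keep <- same
  if (excludeUnknown)
    keep <- keep & fo[-1L] != "unknown" & fo[-length(fo)] != "unknown"
  idx <- which(keep)
  bps <- GenomicRanges::GRanges(ch[idx], IRanges::IRanges(en[idx], width = 1L),
                                ril = rl[idx])
  GenomeInfoDb::seqlevels(bps) <- layout@chrom
  GenomeInfoDb::seqinfo(bps) <- asSeqinfo(layout)
  lens <- chromLengths(layout)
  wins <- list()
  for (cc in names(lens)) {
    starts <- seq(1, max(1, lens[[cc]] - 1), by = stepBp)
    wins[[cc]] <- GenomicRanges::GRanges(cc,
      IRanges::IRanges(starts, pmin(starts + windowBp - 1, lens[[cc]])))
  }
  windows <- suppressWarnings(do.call(c, unname(wins)))
  GenomeInfoDb::seqlevels(windows) <- layout@chrom
  GenomeInfoDb::seqinfo(windows) <- asSeqinfo(layout)
  cnt <- GenomicRanges::countOverlaps(windows, bps)
  S4Vectors::mcols(windows)$count <- cnt
  S4Vectors::mcols(windows)$hotspot <- cnt > hotspotCount
  list(breakpoints = bps, windows = windows)
}
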