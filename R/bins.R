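## Recombination-bin construction: bin boundaries are the union of all RILs'
## segment boundaries, so within a bin each RIL carries exactly one founder
## state.

#' Build a recombination-bin map from IBD segments
#'
#' Bin boundaries are the sorted union of every RIL's segment boundaries per
#' chromosome; each RIL's state in a bin is inherited from its covering
#' segment; adjacent bins whose full state vectors are identical across all
#' RILs are merged.
#'
#' @param segments GRanges of IBD segments for all RILs (mcols \code{ril},
#'   \code{founder})
#' @param layout \linkS4class{GenomeLayout}
#' @param founders founder labels fixing the state coding; defaults to the
#'   sorted founder labels present
#' @return a \linkS4class{BinMap}
#' @export
buildBins <- function(segments, layout, founders = NULL) {
  md <- S4Vectors::mcols(segments)
  rils <- unique(md$ril)
  if (is.null(founders))
    founders <- setdiff(sort(unique(md$founder)), "unknown")
  chr <- as.character(GenomicRanges::seqnames(segments))
  en <- GenomicRanges::end(segments)
  st <- GenomicRanges::start(segments)
  lens <- chromLengths(layout)
  binList <- list(); stateList <- list()
  for (cc in layout@chrom) {
    ci <- chr == cc
    ends <- sort(unique(c(en[ci], lens[[cc]])))
    if (max(en[ci]) > lens[[cc]])
      stop("segment beyond chromosome end on ", cc)
    starts <- c(1, head(ends, -1) + 1)
    mids <- (starts + ends) / 2
    states <- matrix(NA_integer_, length(ends), length(rils),
                     dimnames = list(NULL, rils))
    for (r in rils) {
      ri <- which(ci & md$ril == r)
      ri <- ri[order(st[ri])]
      if (!length(ri)) stop("RIL ", r, " has no segments on ", cc)
      if (st[ri][1L] != 1 || en[ri][length(ri)] != lens[[cc]] ||
          (length(ri) > 1L && any(st[ri][-1L] != en[ri][-length(ri)] + 1)))
        stop("segments of ", r, " do not partition chromosome ", cc)
      seg <- findInterval(mids - 0.5, en[ri]) + 1L
      states[, r] <- match(md$founder[ri][seg], founders)
    }
    ## merge adjacent bins with identical state vectors across all RILs
    if (nrow(states) > 1L) {
      same <- vapply(seq_len(nrow(states) - 1L), function(i)
        identical(states[i, ], states[i + 1L, ]), logical(1))
      keepEnd <- c(!same, TRUE)
      ends <- ends[keepEnd]
      starts <- c(1, head(ends, -1) + 1)
      states <- states[keepEnd, , drop = FALSE]
    }
    binList[[cc]] <- GenomicRanges::GRanges(cc, IRanges::IRanges(starts, ends))
    stateList[[cc]] <- states
  }
  bins <- suppressWarnings(do.call(c, unname(binList)))
  GenomeInfoDb::seqlevels(bins) <- layout@chrom
  GenomeInfoDb::seqinfo(bins) <- asSeqinfo(layout)
  bm <- new("BinMap", bins = bins, states = do.call(rbind, stateList),
            founders = founders)
  mmLog("build_bins", bins = length(bins), rils = length(rils))
  bm
}

#' Founder-indicator design matrix for one bin
#'
#' Dummy coding of the founder states at one bin: one column per founder,
#' rows are RILs; a RIL with unknown state gets an all-zero row (it
#' contributes to the null, not to founder contrasts).  For fixed-effect
#' identifiability checks one redundant column can be dropped.
#'
#' @param states integer state vector for one bin (NA = unknown), as one row
#'   of \code{\link{binStates}}
#' @param nFounders total number of founders (columns)
#' @param dropRedundant drop the last observed-founder column
#' @return indicator matrix (RILs x founders); row sums are 0 (unknown) or 1
#' @export
binDesign <- function(states, nFounders, dropRedundant = FALSE) {
  n <- length(states)
  Z <- matrix(0, n, nFounders)
  ok <- !is.na(states)
  Z[cbind(which(ok), states[ok])] <- 1
  rownames(Z) <- names(states)
  if (dropRedundant) {
    obs <- which(colSums(Z) > 0)
    if (length(obs) > 1L) Z <- Z[, -obs[length(obs)], drop = FALSE]
  }
  Z
}
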