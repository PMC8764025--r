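#' @import methods
#' @import stats
#' @importFrom utils read.delim write.table head tail
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Genome layout: chromosomes, lengths and subgenome labels
#'
#' Describes the reference genome the pipeline operates on: an ordered set of
#' chromosomes with their lengths (bp) and, for allotetraploid genomes such as
#' Upland cotton, the subgenome (\code{"A"}, \code{"D"} or \code{"other"})
#' each chromosome belongs to.  The subgenome partition drives the LD-decay,
#' mosaic-summary and epistasis-classification layers.
#'
#' @slot chrom ordered chromosome names (unique).
#' @slot lengths chromosome lengths in bp, parallel to \code{chrom}.
#' @slot subgenome one of \code{"A"}, \code{"D"}, \code{"other"} per
#'   chromosome.
#' @export
setClass("GenomeLayout",
  representation(chrom = "character", lengths = "numeric",
                 subgenome = "character"))

setValidity("GenomeLayout", function(object) {
  msg <- character()
  if (anyDuplicated(object@chrom)) msg <- c(msg, "chromosome names must be unique")
  if (length(object@lengths) != length(object@chrom) ||
      length(object@subgenome) != length(object@chrom))
    msg <- c(msg, "chrom, lengths and subgenome must have equal length")
  if (any(!is.finite(object@lengths)) || any(object@lengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (!all(object@subgenome %in% c("A", "D", "other")))
    msg <- c(msg, "subgenome labels must be 'A', 'D' or 'other'")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeLayout
#'
#' @param chrom chromosome names.
#' @param lengths chromosome lengths in bp.
#' @param subgenome subgenome label per chromosome (\code{"A"}, \code{"D"} or
#'   \code{"other"}).  Defaults to a guess from the leading letter of the
#'   chromosome name.
#' @return a \linkS4class{GenomeLayout}.
#' @examples
#' GenomeLayout(c("A01", "D01"), c(6e7, 6e7))
#' @export
GenomeLayout <- function(chrom, lengths, subgenome = NULL) {
  if (is.null(subgenome)) {
    first <- substr(chrom, 1L, 1L)
    subgenome <- ifelse(first %in% c("A", "D"), first, "other")
  }
  new("GenomeLayout", chrom = as.character(chrom),
      lengths = as.numeric(lengths), subgenome = as.character(subgenome))
}

#' @describeIn GenomeLayout chromosome names
#' @param x,object a \code{GenomeLayout}
#' @export
setMethod("names", "GenomeLayout", function(x) x@chrom)

#' Chromosome lengths of a GenomeLayout
#' @param x a \linkS4class{GenomeLayout}
#' @return named numeric vector of lengths (bp)
#' @export
chromLengths <- function(x) setNames(x@lengths, x@chrom)

#' Subgenome labels of a GenomeLayout
#' @param x a \linkS4class{GenomeLayout}
#' @return named character vector of subgenome labels
#' @export
subgenomes <- function(x) setNames(x@subgenome, x@chrom)

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout with", length(object@chrom), "chromosomes\n")
  cat(" ", paste0(object@chrom, " (", object@subgenome, ", ",
                  round(object@lengths / 1e6, 1), " Mb)", collapse = ", "),
      "\n")
})

#' Seqinfo view of a GenomeLayout
#' @param layout a \linkS4class{GenomeLayout}
#' @return a \link[GenomeInfoDb]{Seqinfo}
#' @export
asSeqinfo <- function(layout) {
  GenomeInfoDb::Seqinfo(seqnames = layout@chrom,
                        seqlengths = as.integer(layout@lengths))
}

#' Biallelic genotype matrix
#'
#' Sites-by-samples biallelic SNP calls stored as a
#' \link[SummarizedExperiment]{RangedSummarizedExperiment}: the \code{"calls"}
#' assay holds integer alt-allele dosages (0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, \code{NA} = missing) and the
#' row ranges carry chromosome, 1-based position and the \code{ref}/\code{alt}
#' alleles.
#'
#' @export
setClass("GenotypeMatrix",
         contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object) < 1L || ncol(object) < 1L)
    msg <- c(msg, "site and sample counts must be positive")
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    cl <- SummarizedExperiment::assay(object, "calls")
    if (!all(cl %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "calls must be 0, 1, 2 or NA")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  md <- S4Vectors::mcols(rr)
  if (!all(c("ref", "alt") %in% colnames(md)))
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt' alleles")
  else if (any(nchar(md$ref) != 1L) || any(nchar(md$alt) != 1L))
    msg <- c(msg, "alleles must be single bases")
  pos <- GenomicRanges::start(rr)
  chr <- as.character(GenomicRanges::seqnames(rr))
  ok <- all(vapply(split(pos, chr), function(p) !is.unsorted(p, strictly = TRUE),
                   logical(1)))
  if (!ok) msg <- c(msg, "positions must be strictly increasing within chromosome")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix (sites x samples) of alt dosages 0/1/2, NA for
#'   missing.  Row order must follow \code{sites}.
#' @param sites a \link[GenomicRanges]{GRanges} of SNP positions (width 1)
#'   with metadata columns \code{ref} and \code{alt} (single bases).
#' @param layout optional \linkS4class{GenomeLayout} used to attach seqinfo.
#' @return a \linkS4class{GenotypeMatrix}
#' @export
GenotypeMatrix <- function(calls, sites, layout = NULL) {
  storage.mode(calls) <- "integer"
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(sites) <- layout@chrom
    GenomeInfoDb::seqinfo(sites) <- asSeqinfo(layout)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowRanges = sites)
  new("GenotypeMatrix", se)
}

#' Genotype calls of a GenotypeMatrix
#' @param x a \linkS4class{GenotypeMatrix}
#' @return integer matrix of alt dosages (sites x samples)
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' Site ranges of a GenotypeMatrix
#' @param x a \linkS4class{GenotypeMatrix}
#' @return GRanges with ref/alt metadata
#' @export
siteRanges <- function(x) SummarizedExperiment::rowRanges(x)

#' Per-site minor-allele frequency
#'
#' Alt-allele frequency is computed over non-missing calls; the minor-allele
#' frequency is its fold into [0, 0.5].  Monomorphic sites have MAF 0; sites
#' with no non-missing call get NA.
#'
#' @param x a \linkS4class{GenotypeMatrix}
#' @return numeric vector of per-site MAF in [0, 0.5]
#' @export
maf <- function(x) {
  cl <- genotypeCalls(x)
  p <- rowMeans(cl, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

setMethod("show", "GenotypeMatrix", function(object) {
  cl <- genotypeCalls(object)
  cat("GenotypeMatrix:", nrow(object), "sites x", ncol(object), "samples\n")
  cat("  missing:", round(100 * mean(is.na(cl)), 2), "%  het:",
      round(100 * mean(cl == 1L, na.rm = TRUE), 2), "%\n")
})

#' Hidden-Markov-model parameters for founder-mosaic inference
#'
#' @slot eps genotyping-error rate used by the emission model (in (0, 0.5)).
#' @slot G effective number of meioses scaling the transition rate; the
#'   default 11 reflects the eleven generations of population development
#'   (5 random-mating + 6 selfing).
#' @slot unknownMult multiplier m of the uniform prior 1/K above which the
#'   argmax founder is accepted; below it the state is "unknown" (default 2).
#' @slot xoverPerChrom expected crossovers per chromosome per meiosis used to
#'   convert physical distance to switch probability (default 1.5).
#' @export
setClass("HmmParams",
  representation(eps = "numeric", G = "numeric", unknownMult = "numeric",
                 xoverPerChrom = "numeric"),
  prototype(eps = 0.01, G = 11, unknownMult = 2, xoverPerChrom = 1.5))

setValidity("HmmParams", function(object) {
  msg <- character()
  if (object@eps <= 0 || object@eps >= 0.5) msg <- c(msg, "eps must be in (0, 0.5)")
  if (object@G < 1) msg <- c(msg, "G must be >= 1")
  if (object@unknownMult < 1) msg <- c(msg, "unknownMult must be >= 1")
  if (object@xoverPerChrom <= 0) msg <- c(msg, "xoverPerChrom must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct HmmParams
#' @param eps emission error rate (default 0.01)
#' @param G effective meiosis count (default 11)
#' @param unknownMult unknown-assignment multiplier m (default 2)
#' @param xoverPerChrom crossovers per chromosome per meiosis (default 1.5)
#' @return an \linkS4class{HmmParams}
#' @export
HmmParams <- function(eps = 0.01, G = 11, unknownMult = 2,
                      xoverPerChrom = 1.5) {
  new("HmmParams", eps = eps, G = G, unknownMult = unknownMult,
      xoverPerChrom = xoverPerChrom)
}

#' Recombination-bin map
#'
#' A partition of the genome into bins delimited by the pooled recombination
#' breakpoints of all RILs.  Within a bin every RIL carries exactly one
#' founder state (or unknown, coded NA).
#'
#' @slot bins GRanges tiling each chromosome without gaps or overlaps.
#' @slot states integer matrix (bins x RILs) of founder indices; NA = unknown.
#' @slot founders founder labels indexed by the state codes.
#' @export
setClass("BinMap",
  representation(bins = "GRanges", states = "matrix", founders = "character"))

setValidity("BinMap", function(object) {
  msg <- character()
  if (length(object@bins) != nrow(object@states))
    msg <- c(msg, "states must have one row per bin")
  chr <- as.character(GenomicRanges::seqnames(object@bins))
  st <- GenomicRanges::start(object@bins); en <- GenomicRanges::end(object@bins)
  for (cc in unique(chr)) {
    i <- which(chr == cc)
    if (any(st[i][-1] != en[i][-length(i)] + 1L))
      msg <- c(msg, sprintf("bins do not tile chromosome %s", cc))
  }
  v <- object@states[!is.na(object@states)]
  if (length(v) && (min(v) < 1L || max(v) > length(object@founders)))
    msg <- c(msg, "state codes outside founder index range")
  if (length(msg)) msg else TRUE
})

#' Bin ranges of a BinMap
#' @param x a \linkS4class{BinMap}
#' @return GRanges of bins
#' @export
binRanges <- function(x) x@bins

#' Founder states of a BinMap
#' @param x a \linkS4class{BinMap}
#' @param labels return founder labels instead of integer codes
#' @return matrix (bins x RILs) of founder states; NA = unknown origin
#' @export
binStates <- function(x, labels = FALSE) {
  if (!labels) return(x@states)
  out <- matrix(x@founders[x@states], nrow = nrow(x@states),
                dimnames = dimnames(x@states))
  out
}

setMethod("show", "BinMap", function(object) {
  cat("BinMap:", length(object@bins), "bins x", ncol(object@states),
      "RILs;", length(object@founders), "founders\n")
  ns <- apply(object@states, 1L, function(s) length(unique(s[!is.na(s)])))
  cat("  founder states per bin:", min(ns), "-", max(ns),
      "; unknown fraction:", round(mean(is.na(object@states)), 3), "\n")
})
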