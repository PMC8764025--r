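## Readers/writers for the standard formats the pipeline touches, plus the
## run configuration.  Internally every interval object is a GRanges (1-based
## closed); BED output is converted to 0-based half-open at this boundary.

mmLog <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[magicmap] %s %s", stage,
                  paste(names(kv), unname(kv), sep = "=", collapse = " ")))
  invisible(NULL)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Multi-allelic records and records whose REF/ALT are not single bases are
#' skipped (their count is logged and attached as an attribute).  Genotypes
#' are mapped to alt dosages; half calls and \code{./.} become missing.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples optional character vector restricting (and ordering) the
#'   samples; an unknown ID is an error.
#' @param layout optional \linkS4class{GenomeLayout} attached to the result.
#' @return a \linkS4class{GenotypeMatrix}; attribute \code{"skipped"} carries
#'   the number of non-biallelic-SNP records dropped.
#' @export
readVcfGenotypes <- function(path, samples = NULL, layout = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  keep <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  nskip <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (!is.null(samples)) {
    bad <- setdiff(samples, colnames(gt))
    if (length(bad)) stop("unknown sample ID in subset: ", bad[1L])
    gt <- gt[, samples, drop = FALSE]
  }
  core <- gsub("|", "/", substr(gt, 1L, 3L), fixed = TRUE)
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  calls[core %in% c("0/0")] <- 0L
  calls[core %in% c("0/1", "1/0")] <- 1L
  calls[core %in% c("1/1")] <- 2L
  sites <- GenomicRanges::GRanges(fix[, "CHROM"],
    IRanges::IRanges(as.integer(fix[, "POS"]), width = 1L),
    ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]))
  gm <- GenotypeMatrix(calls, sites, layout)
  mmLog("read_vcf", sites = nrow(gm), samples = ncol(gm), skipped = nskip)
  attr(gm, "skipped") <- nskip
  gm
}

#' Write a GenotypeMatrix as a minimal VCF 4.2 file
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param path output path (plain text)
#' @return the path, invisibly
#' @export
writeVcfGenotypes <- function(gm, path) {
  rr <- siteRanges(gm)
  cl <- genotypeCalls(gm)
  gtmap <- c("0/0", "0/1", "1/1")
  gtxt <- matrix("./.", nrow(cl), ncol(cl))
  ok <- !is.na(cl)
  gtxt[ok] <- gtmap[cl[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  sl <- GenomeInfoDb::seqlengths(rr)
  if (!all(is.na(sl)))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>", names(sl), sl))
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", colnames(cl)),
                            collapse = "\t"))
  body <- paste(as.character(GenomicRanges::seqnames(rr)),
                GenomicRanges::start(rr), ".",
                S4Vectors::mcols(rr)$ref, S4Vectors::mcols(rr)$alt,
                ".", "PASS", ".", "GT",
                apply(gtxt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  mmLog("write_vcf", sites = nrow(cl), samples = ncol(cl))
  invisible(path)
}

#' Write IBD segments as BED (0-based half-open)
#'
#' Segments are GRanges (1-based closed) with metadata columns \code{ril} and
#' \code{founder}; the name column of the BED output is \code{"RIL:founder"}.
#' Overlapping segments for one RIL on one chromosome violate the mosaic
#' partition and are an error.
#'
#' @param segments GRanges with mcols \code{ril}, \code{founder}
#' @param path output BED path
#' @return the path, invisibly
#' @export
writeSegmentsBed <- function(segments, path) {
  md <- S4Vectors::mcols(segments)
  key <- paste(md$ril, as.character(GenomicRanges::seqnames(segments)))
  for (k in unique(key)) {
    s <- segments[key == k]
    s <- GenomicRanges::sort(s, ignore.strand = TRUE)
    if (length(s) > 1L &&
        any(GenomicRanges::start(s)[-1] <= GenomicRanges::end(s)[-length(s)]))
      stop("overlapping segments for ", k, ": mosaic partition violated")
  }
  o <- order(as.character(GenomicRanges::seqnames(segments)),
             GenomicRanges::start(segments))
  segments <- segments[o]
  md <- S4Vectors::mcols(segments)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(segments)),
                   start = GenomicRanges::start(segments) - 1L,
                   end = GenomicRanges::end(segments),
                   name = paste(md$ril, md$founder, sep = ":"))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  mmLog("write_bed", segments = nrow(df))
  invisible(path)
}

#' Read a multi-environment phenotype table
#'
#' Expects a TSV with header columns \code{line}, \code{location},
#' \code{year}, \code{replicate} followed by one numeric column per trait.
#' Empty trait cells are missing values.  Returns long-format records; a
#' duplicated (line, location, year, replicate, trait) design row is an
#' error, as is a non-numeric trait cell.
#'
#' @param path TSV path
#' @return data.frame with columns line, location, year, replicate, trait,
#'   value
#' @export
readPhenotypeTable <- function(path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  keyCols <- c("line", "location", "year", "replicate")
  if (!all(keyCols %in% names(raw)))
    stop("phenotype table must have columns ", paste(keyCols, collapse = ", "))
  traits <- setdiff(names(raw), keyCols)
  if (!length(traits)) stop("no trait columns found")
  recs <- lapply(traits, function(tr) {
    val <- raw[[tr]]
    val[val == ""] <- NA
    num <- suppressWarnings(as.numeric(val))
    bad <- which(!is.na(val) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' for trait %s at row %d",
                   val[bad[1L]], tr, bad[1L]))
    data.frame(raw[keyCols], trait = tr, value = num,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  key <- do.call(paste, c(out[c(keyCols, "trait")], sep = "\r"))
  if (anyDuplicated(key)) {
    d <- out[which(duplicated(key))[1L], ]
    stop(sprintf("duplicated design row: line=%s location=%s year=%s replicate=%s trait=%s",
                 d$line, d$location, d$year, d$replicate, d$trait))
  }
  mmLog("read_phenotypes", records = nrow(out), traits = length(traits))
  out
}

#' Default run configuration
#'
#' A nested list of every tunable parameter of the pipeline with its default,
#' plus the random seed.  Serializes losslessly through YAML via
#' \code{\link{writeConfig}} / \code{\link{readConfig}}.
#'
#' @param seed random seed recorded with the run
#' @return nested configuration list
#' @export
magicConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(nFounders = 11L, nRandomMating = 5L, nSelfing = 6L,
               linesPerFamily = 10L, popPerFamily = 20L,
               xoverPerChrom = 1.5, matingScope = "across",
               residualHet = 0, nSites = 5000L, missingRate = 0.1,
               errorRate = 0.01, polygenicSites = 200L),
    hmm = list(eps = 0.01, G = 11, unknownMult = 2, xoverPerChrom = 1.5),
    hgwas = list(nPerm = 100L, sigQuantile = 0.95, sugQuantile = 0.37,
                 mergeGapBp = 1e6, mergeBins = 5L, nPcs = 10L),
    sgwas = list(mafMin = 0.05, clusterGapBp = 7e5, mergeR2 = 0.4),
    epistasis = list(mafMin = 0.05, pruneR2 = 0.5, pruneWindowBp = 5e4,
                     pruneStep = 5L, stage1P = 1e-4, adjP = 0.01),
    diversity = list(mafMin = 0.05, ldMaxBp = 2e6, ldBinBp = 5e3,
                     flankBp = 1000L, spliceBp = 2L),
    breakpoints = list(windowBp = 2e6, stepBp = 1e6, hotspotCount = 50L),
    alleles = list(minGroup = 4L)
  )
}

#' Write a configuration list to YAML
#' @param config configuration list (see \code{\link{magicConfig}})
#' @param path output YAML path
#' @return the path, invisibly
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a configuration list from YAML
#' @param path YAML path
#' @return configuration list
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
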