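## Multi-environment phenotype reduction: per-line BLUPs and broad-sense
## heritability from the mixed model
##   value ~ (1|line) + (1|location) + (1|year) + (1|replicate:location:year)
##         + (1|line:location) + (1|line:year)
## fitted by REML with lme4.

#' Per-line BLUPs, variance components and heritability for one trait
#'
#' Random-effect terms whose grouping factor has a single level are dropped
#' with a warning.  With no repetition at all (one record per line) the BLUP
#' is the centered raw value and the residual variance is flagged as 0.
#'
#' @param pheno long-format records from \code{\link{readPhenotypeTable}} or
#'   \code{\link{simulatePhenotypes}} (columns line, location, year,
#'   replicate, value; or a \code{trait} column selected via \code{trait})
#' @param trait trait name when \code{pheno} holds several traits
#' @return list with \code{blup} (named, centered), \code{varcomp} (named
#'   vector: line, location, year, rep, lineLocation, lineYear, residual),
#'   \code{h2} (broad-sense heritability on a line-mean basis) and
#'   \code{means} (harmonic-mean numbers of locations, years, replicates)
#' @export
fitBlup <- function(pheno, trait = NULL) {
  if (!is.null(trait)) pheno <- pheno[pheno$trait == trait, , drop = FALSE]
  pheno <- pheno[!is.na(pheno$value), , drop = FALSE]
  if (length(unique(pheno$line)) < 2L) stop("need at least 2 lines")
  pheno$line <- factor(pheno$line)
  pheno$location <- factor(pheno$location)
  pheno$year <- factor(pheno$year)
  pheno$rly <- interaction(pheno$replicate, pheno$location, pheno$year,
                           drop = TRUE)
  pheno$ll <- interaction(pheno$line, pheno$location, drop = TRUE)
  pheno$ly <- interaction(pheno$line, pheno$year, drop = TRUE)

  hm <- function(x) length(x) / sum(1 / x)
  perLine <- split(pheno, pheno$line)
  L <- hm(vapply(perLine, function(d) length(unique(d$location)), numeric(1)))
  Y <- hm(vapply(perLine, function(d) length(unique(d$year)), numeric(1)))
  R <- hm(vapply(perLine, function(d)
    mean(table(interaction(d$location, d$year, drop = TRUE))), numeric(1)))
  means <- c(L = L, Y = Y, R = R)

  if (nrow(pheno) == length(unique(pheno$line))) {
    warning("no repetition: BLUPs are centered raw values, residual variance 0")
    blup <- tapply(pheno$value, pheno$line, mean) - mean(pheno$value)
    vc <- c(line = var(pheno$value), location = 0, year = 0, rep = 0,
            lineLocation = 0, lineYear = 0, residual = 0)
    return(list(blup = blup, varcomp = vc, h2 = 1, means = means,
                residualZero = TRUE))
  }

  terms <- c(line = "(1|line)", location = "(1|location)",
             year = "(1|year)", rep = "(1|rly)",
             lineLocation = "(1|ll)", lineYear = "(1|ly)")
  lev <- c(line = nlevels(pheno$line), location = nlevels(pheno$location),
           year = nlevels(pheno$year), rep = nlevels(pheno$rly),
           lineLocation = nlevels(pheno$ll), lineYear = nlevels(pheno$ly))
  ## a term needs >1 level; the line-by-environment interactions also need
  ## >1 level of the environment margin (else they alias the line term)
  usable <- lev > 1L
  usable["rep"] <- lev[["rep"]] > 1L && lev[["rep"]] < nrow(pheno)
  usable["lineLocation"] <- lev[["lineLocation"]] > 1L && lev[["location"]] > 1L
  usable["lineYear"] <- lev[["lineYear"]] > 1L && lev[["year"]] > 1L
  if (any(!usable))
    warning("dropping single-level terms: ",
            paste(names(terms)[!usable], collapse = ", "))
  form <- as.formula(paste("value ~", paste(terms[usable], collapse = " + ")))
  fit <- lme4::lmer(form, data = pheno, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8)))
  vcd <- as.data.frame(lme4::VarCorr(fit))
  vc <- setNames(rep(0, 7),
                 c("line", "location", "year", "rep", "lineLocation",
                   "lineYear", "residual"))
  map <- c(line = "line", location = "location", year = "year", rly = "rep",
           ll = "lineLocation", ly = "lineYear", Residual = "residual")
  for (i in seq_len(nrow(vcd)))
    vc[map[[vcd$grp[i]]]] <- vcd$vcov[i]
  blupLine <- lme4::ranef(fit)$line[, 1L]
  names(blupLine) <- rownames(lme4::ranef(fit)$line)
  h2 <- heritability(vc, L, Y, R)
  list(blup = blupLine, varcomp = vc, h2 = h2, means = means,
       residualZero = FALSE)
}

#' Broad-sense heritability on a line-mean basis
#'
#' H2 = s2_line / (s2_line + s2_lineLocation/L + s2_lineYear/Y +
#' s2_residual/(L*Y*R)) with L, Y, R the harmonic-mean numbers of locations,
#' years and replicates.
#'
#' @param varcomp named variance components (as from \code{\link{fitBlup}})
#' @param L,Y,R harmonic-mean design sizes
#' @return heritability fraction in [0, 1]
#' @export
heritability <- function(varcomp, L = 1, Y = 1, R = 1) {
  den <- varcomp[["line"]] + varcomp[["lineLocation"]] / L +
    varcomp[["lineYear"]] / Y + varcomp[["residual"]] / (L * Y * R)
  if (den <= 0) stop("zero denominator in heritability")
  unname(varcomp[["line"]] / den)
}

#' Pairwise Pearson correlations between trait BLUPs
#'
#' @param blupTable matrix or data.frame (lines x traits)
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   traits yield NA entries (flagged with a warning)
#' @export
traitCorrelations <- function(blupTable) {
  blupTable <- as.matrix(blupTable)
  if (nrow(blupTable) < 3L) stop("need at least 3 lines")
  sds <- apply(blupTable, 2L, sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("zero-variance trait(s): ",
            paste(colnames(blupTable)[which(sds == 0)], collapse = ", "))
  r <- suppressWarnings(cor(blupTable, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}
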