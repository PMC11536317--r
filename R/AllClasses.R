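#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges
#' @importFrom S4Vectors metadata
#' @importFrom stats cor var sd rnorm runif rpois rbinom optimize pf pchisq
#'   setNames complete.cases aggregate coef quantile
#' @importFrom utils read.table write.table head
NULL

#' GenotypeMatrix: SNP dosages with genomic positions
#'
#' An S4 container for a set of individuals genotyped at biallelic SNPs,
#' extending [SummarizedExperiment::RangedSummarizedExperiment-class]. The
#' single assay, `"dosage"`, holds counts of the alternate allele per
#' individual and locus. For inbred (RIL) panels dosages are 0/1/2; testcross
#' hybrids built with [makeTestcross()] carry half-integer dosages at residual
#' heterozygous RIL loci. Loci live in `rowRanges()` as a `GRanges`, strictly
#' sorted by (chromosome, position), with SNP identifiers of the form
#' `S{chrom}_{pos}` as names.
#'
#' @slot metadata list; carries `panelType` (`"inbred"` or `"hybrid"`) and a
#'   `hetFraction` record for RIL panels.
#'
#' @seealso [GenotypeMatrix()] for construction, [readGenotypes()] for file
#'   input, [dosages()], [snpIds()], [snpLoci()].
#' @export
setClass("GenotypeMatrix",
         contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    dd <- d[!is.na(d)]
    if (length(dd) && (min(dd) < 0 || max(dd) > 2))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  gr <- SummarizedExperiment::rowRanges(object)
  if (length(gr) > 1L) {
    chrom <- as.integer(as.character(GenomicRanges::seqnames(gr)))
    pos <- GenomicRanges::start(gr)
    o <- order(chrom, pos)
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "loci must be sorted by (chrom, pos)")
    if (anyDuplicated(paste(chrom, pos)))
      msg <- c(msg, "duplicated loci")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix, individuals in columns and SNPs in rows (the
#'   SummarizedExperiment orientation), values in `[0, 2]` with `NA` for
#'   missing calls.
#' @param chrom,pos integer vectors of chromosome number and 1-based physical
#'   position (bp), one per row of `dosage`. Omitted when `dosage` has
#'   rownames of the form `S{chrom}_{pos}`, which are then parsed.
#' @param panelType `"inbred"` for RIL panels or `"hybrid"` for testcrosses.
#' @param hetThreshold for inbred panels, the tolerated fraction of
#'   heterozygous (dosage 1) calls before a warning is issued; RILs are
#'   expected to be nearly homozygous.
#'
#' @details Unsorted loci are sorted (with a warning), so downstream window
#'   queries can assume (chrom, pos) order.
#'
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' m <- matrix(c(0, 2, 2, 0, 0, 2), nrow = 2,
#'             dimnames = list(c("S1_100", "S1_200"), paste0("RIL", 1:3)))
#' gm <- GenotypeMatrix(m)
#' dosages(gm)
#' @export
GenotypeMatrix <- function(dosage, chrom = NULL, pos = NULL,
                           panelType = c("inbred", "hybrid"),
                           hetThreshold = 0.05) {
  panelType <- match.arg(panelType)
  dosage <- as.matrix(dosage)
  if (is.null(chrom) || is.null(pos)) {
    if (is.null(rownames(dosage)))
      stop("either chrom/pos or SNP-id rownames are required")
    loc <- parseSnpId(rownames(dosage))
    chrom <- loc$chrom
    pos <- loc$pos
  }
  stopifnot(length(chrom) == nrow(dosage), length(pos) == nrow(dosage))
  o <- order(chrom, pos)
  if (!identical(o, seq_len(nrow(dosage)))) {
    warning("loci were not sorted by (chrom, pos); sorting")
    dosage <- dosage[o, , drop = FALSE]
    chrom <- chrom[o]
    pos <- pos[o]
  }
  ids <- formatSnpId(chrom, pos)
  rownames(dosage) <- ids
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("ind", seq_len(ncol(dosage)))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
    snpId = ids)
  names(gr) <- ids
  hetFrac <- NA_real_
  if (panelType == "inbred") {
    hetFrac <- mean(dosage == 1, na.rm = TRUE)
    if (is.finite(hetFrac) && hetFrac > hetThreshold)
      warning(sprintf(
        "heterozygous fraction %.3f exceeds RIL tolerance %.3f",
        hetFrac, hetThreshold))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = gr)
  new("GenotypeMatrix", se,
      metadata = list(panelType = panelType, hetFraction = hetFrac))
}

#' ValidationPolicy: thresholds of the two-criterion validation rule
#'
#' Bundles the three tunable thresholds of the validation rule: the p-value
#' cutoff for a significant association in the validation-set scan, the
#' half-width of the physical window searched around a published SNP, and the
#' minimum linkage-disequilibrium r-squared between the published SNP and a
#' window candidate. Defaults are the published rule: p < 0.02, +/- 2 Mbp,
#' r-squared > 0.2. Both p and r-squared cutoffs are strict inequalities;
#' window bounds are inclusive.
#'
#' @slot pThreshold numeric in (0, 1).
#' @slot windowBp positive number of base pairs (half-width).
#' @slot r2Threshold numeric in \[0, 1).
#' @export
setClass("ValidationPolicy",
         representation(pThreshold = "numeric",
                        windowBp = "numeric",
                        r2Threshold = "numeric"))

setValidity("ValidationPolicy", function(object) {
  msg <- character()
  if (length(object@pThreshold) != 1L || object@pThreshold <= 0 ||
      object@pThreshold >= 1)
    msg <- c(msg, "pThreshold must be a single value in (0, 1)")
  if (length(object@windowBp) != 1L || object@windowBp <= 0)
    msg <- c(msg, "windowBp must be a single positive number")
  if (length(object@r2Threshold) != 1L || object@r2Threshold < 0 ||
      object@r2Threshold >= 1)
    msg <- c(msg, "r2Threshold must be a single value in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param pThreshold,windowBp,r2Threshold see the class slots.
#' @rdname ValidationPolicy-class
#' @examples
#' ValidationPolicy()  # the published rule
#' @export
ValidationPolicy <- function(pThreshold = 0.02, windowBp = 2e6,
                             r2Threshold = 0.2) {
  new("ValidationPolicy", pThreshold = pThreshold, windowBp = windowBp,
      r2Threshold = r2Threshold)
}

setMethod("show", "ValidationPolicy", function(object) {
  cat("ValidationPolicy: p <", object@pThreshold,
      "| window +/-", format(object@windowBp, big.mark = ","),
      "bp | r2 >", object@r2Threshold, "\n")
})

#' VarianceComponents: REML decomposition of phenotypic variance
#'
#' Holds the genotypic (`Vg`), genotype-by-environment (`Vgxe`) and residual
#' (`Vres`) variance components of a multi-environment trial, their standard
#' errors, and the derived phenotypic variance `Vp = Vg + Vgxe + Vres`. A
#' component is flagged significant when it exceeds twice its standard error.
#'
#' @slot vg,vgxe,vres non-negative variance components (trait units squared).
#' @slot se named numeric of standard errors (`vg`, `vgxe`, `vres`); `NA` when
#'   a component sits on the zero boundary.
#' @slot trait character trait label.
#' @export
setClass("VarianceComponents",
         representation(vg = "numeric", vgxe = "numeric", vres = "numeric",
                        se = "numeric", trait = "character"))

setValidity("VarianceComponents", function(object) {
  if (any(c(object@vg, object@vgxe, object@vres) < 0))
    "variance components must be non-negative" else TRUE
})

#' @param vg,vgxe,vres,se,trait see the class slots.
#' @rdname VarianceComponents-class
#' @export
VarianceComponents <- function(vg, vgxe, vres,
                               se = c(vg = NA_real_, vgxe = NA_real_,
                                      vres = NA_real_),
                               trait = NA_character_) {
  new("VarianceComponents", vg = vg, vgxe = vgxe, vres = vres,
      se = se, trait = trait)
}

#' @describeIn VarianceComponents-class phenotypic variance Vg + Vgxe + Vres.
#' @param x,object a `VarianceComponents`.
#' @export
phenotypicVariance <- function(x) x@vg + x@vgxe + x@vres

#' @describeIn VarianceComponents-class logical flags, component > 2 SE.
#' @export
isSignificant <- function(x) {
  est <- c(vg = x@vg, vgxe = x@vgxe, vres = x@vres)
  est > 2 * x@se[names(est)]
}

setMethod("show", "VarianceComponents", function(object) {
  est <- c(Vg = object@vg, Vgxe = object@vgxe, Vres = object@vres)
  se <- object@se
  cat("VarianceComponents",
      if (!is.na(object@trait)) paste0("[", object@trait, "]"), "\n")
  for (i in seq_along(est))
    cat(sprintf("  %-5s %8.2f +/- %s\n", names(est)[i], est[i],
                ifelse(is.na(se[i]), "NA", sprintf("%.2f", se[i]))))
  cat(sprintf("  %-5s %8.2f\n", "Vp", phenotypicVariance(object)))
})

#' HeritabilityEstimate: family-mean-basis heritability
#'
#' @slot h2 heritability in \[0, 1\] (NA when all components are zero).
#' @slot se delta-method standard error.
#' @slot e number of environments entering the family means.
#' @slot r number of replicates per environment.
#' @seealso [heritabilityFamilyMean()]
#' @export
setClass("HeritabilityEstimate",
         representation(h2 = "numeric", se = "numeric",
                        e = "numeric", r = "numeric"))

setMethod("show", "HeritabilityEstimate", function(object) {
  cat(sprintf("Family-mean h2 = %s +/- %s  (e = %d, r = %d)\n",
              ifelse(is.na(object@h2), "NA", sprintf("%.3f", object@h2)),
              ifelse(is.na(object@se), "NA", sprintf("%.3f", object@se)),
              as.integer(object@e), as.integer(object@r)))
})

#' NullModelFit: variance components of the polygenic null model
#'
#' REML fit of the intercept-only mixed model `y = mu + g + e` with
#' `g ~ N(0, sigma2g * K)` and `e ~ N(0, sigma2e * I)`, obtained by spectral
#' decomposition of the kinship `K`. The fit carries the rotation needed to
#' test every SNP with these variance components held fixed (P3D).
#'
#' @slot sigma2g,sigma2e non-negative variance components.
#' @slot lambda the ratio sigma2g / sigma2e maximising the REML likelihood.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot beta fixed-effect (intercept) estimate.
#' @slot rotation list with eigenvectors `U` and eigenvalues `d` of `K`.
#' @slot ids individual identifiers, in model order.
#' @seealso [fitNull()], [scanSnps()]
#' @export
setClass("NullModelFit",
         representation(sigma2g = "numeric", sigma2e = "numeric",
                        lambda = "numeric", logLik = "numeric",
                        beta = "numeric", rotation = "list",
                        ids = "character"))

setMethod("show", "NullModelFit", function(object) {
  h2 <- object@sigma2g / (object@sigma2g + object@sigma2e)
  cat(sprintf(paste0("NullModelFit: sigma2g = %.4g, sigma2e = %.4g ",
                     "(lambda = %.4g, pseudo-h2 = %.2f), %d individuals\n"),
              object@sigma2g, object@sigma2e, object@lambda, h2,
              length(object@ids)))
})
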