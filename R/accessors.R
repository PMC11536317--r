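#' Accessors for GenotypeMatrix
#'
#' `dosages()` returns the individuals-by-SNP dosage matrix (note the
#' transpose relative to the internal SummarizedExperiment storage, which is
#' SNP-by-individual); `snpIds()` the `S{chrom}_{pos}` labels; `snpLoci()` the
#' loci as a `GRanges`; `individualIds()` the sample labels; `panelType()`
#' whether the panel is inbred or hybrid; `hetFraction()` the recorded
#' fraction of heterozygous calls (RIL panels).
#'
#' @param x a [GenotypeMatrix-class].
#' @return See each description.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
dosages <- function(x) t(SummarizedExperiment::assay(x, "dosage"))

#' @rdname genotype-accessors
#' @export
snpIds <- function(x) names(SummarizedExperiment::rowRanges(x))

#' @rdname genotype-accessors
#' @export
snpLoci <- function(x) SummarizedExperiment::rowRanges(x)

#' @rdname genotype-accessors
#' @export
individualIds <- function(x) colnames(x)

#' @rdname genotype-accessors
#' @export
panelType <- function(x) S4Vectors::metadata(x)$panelType

#' @rdname genotype-accessors
#' @export
hetFraction <- function(x) S4Vectors::metadata(x)$hetFraction

#' Chromosome and position vectors of a GenotypeMatrix
#'
#' @param x a [GenotypeMatrix-class].
#' @return integer vector.
#' @export
snpChrom <- function(x) {
  as.integer(as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(x))))
}

#' @rdname snpChrom
#' @export
snpPos <- function(x) {
  GenomicRanges::start(SummarizedExperiment::rowRanges(x))
}
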