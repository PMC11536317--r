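#' Linkage-disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors at two loci (composite
#' LD). For a fully homozygous RIL panel this equals the haplotype-frequency
#' r-squared; for hybrid panels, where phase is unknown, the dosage
#' correlation is the estimable quantity. Individuals missing either dosage
#' are excluded pairwise. A locus monomorphic among the scored individuals
#' has no defined LD: `NA` is returned (rendered "No" in reports).
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param a,b SNP identifiers present in `genotypes`.
#' @return single numeric r-squared in \[0, 1\], or `NA`.
#' @examples
#' m <- matrix(c(0, 0, 2, 2, 0, 0, 2, 2, 2, 2, 0, 0), nrow = 4,
#'             dimnames = list(paste0("i", 1:4), c("S1_1", "S1_2", "S1_3")))
#' gm <- GenotypeMatrix(t(m))
#' ldR2(gm, "S1_1", "S1_2")  # duplicated column: 1
#' ldR2(gm, "S1_1", "S1_3")  # complemented column: still 1
#' @export
ldR2 <- function(genotypes, a, b) {
  ids <- snpIds(genotypes)
  for (s in c(a, b))
    if (!s %in% ids) stop("locus absent from genotype matrix: ", s)
  D <- SummarizedExperiment::assay(genotypes, "dosage")
  dosageR2(D[a, ], D[b, ])
}

dosageR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD of all SNPs within a physical window of a focal SNP
#'
#' r-squared between the focal SNP and every other SNP on the same
#' chromosome within `halfWidth` bp (bounds inclusive: a neighbour exactly
#' `halfWidth` away is included).
#'
#' @inheritParams ldR2
#' @param focal focal SNP identifier (must be in `genotypes`).
#' @param halfWidth window half-width in bp (default 2 Mbp).
#' @return data.frame `snp_a` (focal), `snp_b`, `n` (individuals scored at
#'   both loci), `distance_bp`, `r2`; zero rows when the window is empty.
#' @export
ldWindow <- function(genotypes, focal, halfWidth = 2e6) {
  stopifnot(halfWidth > 0)
  ids <- snpIds(genotypes)
  if (!focal %in% ids) stop("locus absent from genotype matrix: ", focal)
  chrom <- snpChrom(genotypes)
  pos <- snpPos(genotypes)
  fi <- match(focal, ids)
  sel <- which(chrom == chrom[fi] & abs(pos - pos[fi]) <= halfWidth)
  sel <- setdiff(sel, fi)
  D <- SummarizedExperiment::assay(genotypes, "dosage")
  x <- D[fi, ]
  res <- lapply(sel, function(j) {
    ok <- !is.na(x) & !is.na(D[j, ])
    data.frame(snp_a = focal, snp_b = ids[j], n = sum(ok),
               distance_bp = abs(pos[j] - pos[fi]),
               r2 = dosageR2(x, D[j, ]), stringsAsFactors = FALSE)
  })
  if (!length(res))
    return(data.frame(snp_a = character(), snp_b = character(),
                      n = integer(), distance_bp = numeric(),
                      r2 = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Write an LD table
#'
#' Tab-separated `snp_a`, `snp_b`, `n`, `r2`, with `NA` for undefined pairs.
#' @param ld data.frame from [ldWindow()].
#' @param path output file.
#' @export
writeLd <- function(ld, path) {
  utils::write.table(ld, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
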