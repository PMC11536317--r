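#' Parse SNP identifiers of the form S{chrom}_{pos}
#'
#' SNP labels encode their own genomic coordinates: the number between the
#' leading `S` and the underscore is the chromosome, the number after the
#' underscore the 1-based physical position in bp. `parseSnpId()` is
#' vectorised and is the exact inverse of [formatSnpId()].
#'
#' @param id character vector of SNP identifiers.
#' @return A data.frame with columns `id`, `chrom`, `pos` (`chrom` integer,
#'   `pos` double to accommodate positions beyond .Machine$integer.max).
#' @examples
#' parseSnpId("S1_3708430")   # chrom 1, pos 3708430
#' parseSnpId(c("S10_1", "S9_5656122"))
#' @export
parseSnpId <- function(id) {
  id <- as.character(id)
  ok <- grepl("^S[0-9]+_[0-9]+$", id)
  if (!all(ok))
    stop("malformed SNP id(s): ",
         paste(utils::head(id[!ok], 5L), collapse = ", "))
  us <- regexpr("_", id, fixed = TRUE)
  chrom <- as.integer(substr(id, 2L, us - 1L))
  pos <- as.numeric(substring(id, us + 1L))
  if (any(chrom < 1L) || any(pos < 1))
    stop("SNP ids must have chrom >= 1 and pos >= 1")
  data.frame(id = id, chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' @param chrom,pos integer vectors of chromosome and 1-based position.
#' @rdname parseSnpId
#' @export
formatSnpId <- function(chrom, pos) {
  sprintf("S%d_%s", as.integer(chrom), format(pos, scientific = FALSE,
                                              trim = TRUE))
}

#' Physical distance between two SNPs
#'
#' Absolute base-pair distance between two loci named by their
#' `S{chrom}_{pos}` identifiers. Loci on different chromosomes have no
#' defined physical distance; `NA` is returned (a defined "undefined" result,
#' not an error). Vectorised over pairs.
#'
#' @param a,b SNP identifiers (character), recycled to common length.
#' @return numeric vector of distances in bp, `NA` for cross-chromosome pairs.
#' @examples
#' snpDistance("S1_19252698", "S1_18200092")  # 1052606
#' snpDistance("S9_5656122", "S9_5656939")    # 817
#' snpDistance("S1_100", "S2_100")            # NA: different chromosomes
#' @export
snpDistance <- function(a, b) {
  pa <- parseSnpId(a)
  pb <- parseSnpId(b)
  n <- max(nrow(pa), nrow(pb))
  ca <- rep_len(pa$chrom, n); cb <- rep_len(pb$chrom, n)
  qa <- rep_len(pa$pos, n); qb <- rep_len(pb$pos, n)
  ifelse(ca == cb, abs(qa - qb), NA_real_)
}
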