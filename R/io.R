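IUPAC_HET <- c(AG = "R", GA = "R", CT = "Y", TC = "Y", CG = "S", GC = "S",
               AT = "W", TA = "W", GT = "K", TG = "K", AC = "M", CA = "M")

#' Read a genotype matrix from HapMap or VCF
#'
#' Reads biallelic SNP genotypes into a [GenotypeMatrix-class], with dosages
#' oriented to the declared alternate allele (second allele of the HapMap
#' `alleles` column; `ALT` in VCF). Multi-allelic records are dropped with a
#' message reporting the count. Loci arriving unsorted are sorted with a
#' warning.
#'
#' HapMap calls may be two-letter diploid (`AA`, `AG`, `NN`) or single-letter
#' IUPAC (`A`, `R`, `N`); unknown codes raise a record-level error. VCF input
#' is parsed with \pkg{vcfR}.
#'
#' @param path file path.
#' @param format `"hapmap"` or `"vcf"`.
#' @param panelType,hetThreshold passed to [GenotypeMatrix()].
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("hapmap", "vcf"),
                          panelType = "inbred", hetThreshold = 0.05) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         hapmap = readHapMap(path, panelType, hetThreshold),
         vcf = readVcfGenotypes(path, panelType, hetThreshold))
}

readHapMap <- function(path, panelType = "inbred", hetThreshold = 0.05) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  if (!nrow(tab)) stop("empty genotype file: ", path)
  std <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#", "center",
           "protLSID", "assayLSID", "panelLSID", "QCcode")
  nmeta <- max(which(names(tab) %in% std))
  samples <- names(tab)[(nmeta + 1L):ncol(tab)]
  alle <- strsplit(tab$alleles, "/", fixed = TRUE)
  nall <- lengths(alle)
  if (any(nall != 2L)) {
    message(sum(nall != 2L), " non-biallelic record(s) dropped")
    keep <- nall == 2L
    tab <- tab[keep, , drop = FALSE]
    alle <- alle[keep]
    if (!nrow(tab)) stop("no biallelic records in ", path)
  }
  ref <- vapply(alle, `[`, "", 1L)
  alt <- vapply(alle, `[`, "", 2L)
  calls <- as.matrix(tab[, samples, drop = FALSE])
  dos <- matrix(NA_real_, nrow(tab), length(samples),
                dimnames = list(NULL, samples))
  for (i in seq_len(nrow(tab))) {
    het2 <- c(paste0(ref[i], alt[i]), paste0(alt[i], ref[i]))
    hom_ref <- c(paste0(ref[i], ref[i]), ref[i])
    hom_alt <- c(paste0(alt[i], alt[i]), alt[i])
    het <- c(het2, IUPAC_HET[paste0(ref[i], alt[i])])
    miss <- c("NN", "N", "--", "-")
    x <- calls[i, ]
    d <- rep(NA_real_, length(x))
    d[x %in% hom_ref] <- 0
    d[x %in% het] <- 1
    d[x %in% hom_alt] <- 2
    bad <- !(x %in% c(hom_ref, het, hom_alt, miss))
    if (any(bad))
      stop(sprintf("unknown allele code '%s' at %s (alleles %s/%s)",
                   x[bad][1L], tab[["rs#"]][i], ref[i], alt[i]))
    dos[i, ] <- d
  }
  GenotypeMatrix(dosage = dos, chrom = as.integer(tab$chrom),
                 pos = as.numeric(tab$pos), panelType = panelType,
                 hetThreshold = hetThreshold)
}

readVcfGenotypes <- function(path, panelType = "inbred",
                             hetThreshold = 0.05) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!nrow(vcf@fix)) stop("empty VCF: ", path)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT)
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) dropped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
    if (!nrow(fix)) stop("no biallelic records in ", path)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  cnt <- function(g) {
    g[g %in% c(".", "./.", ".|.")] <- NA
    a <- strsplit(g, "[/|]")
    vapply(a, function(z) {
      if (anyNA(z) || !length(z)) return(NA_real_)
      sum(z == "1")
    }, numeric(1))
  }
  dos <- t(apply(gt, 1L, cnt))
  colnames(dos) <- colnames(gt)
  GenotypeMatrix(dosage = dos,
                 chrom = as.integer(sub("^chr", "", fix$CHROM)),
                 pos = as.numeric(fix$POS), panelType = panelType,
                 hetThreshold = hetThreshold)
}

#' Write a GenotypeMatrix as a HapMap table
#'
#' @param x a [GenotypeMatrix-class]. Dosages 0/1/2 are written as `AA`/`AG`/
#'   `GG` with `A` the reference and `G` the alternate allele; missing as
#'   `NN`. Fractional hybrid dosages cannot be represented and raise an
#'   error.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHapMap <- function(x, path) {
  d <- SummarizedExperiment::assay(x, "dosage")
  if (any(d[!is.na(d)] %% 1 != 0))
    stop("fractional dosages cannot be written as HapMap calls")
  code <- c("AA", "AG", "GG")
  calls <- matrix("NN", nrow(d), ncol(d), dimnames = dimnames(d))
  ok <- !is.na(d)
  calls[ok] <- code[d[ok] + 1L]
  meta <- data.frame(`rs#` = snpIds(x), alleles = "A/G",
                     chrom = snpChrom(x), pos = snpPos(x), strand = "+",
                     `assembly#` = NA, center = NA, protLSID = NA,
                     assayLSID = NA, panelLSID = NA, QCcode = NA,
                     check.names = FALSE)
  utils::write.table(cbind(meta, calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Phenotype tables are tab-separated with a header and one row per plot:
#' columns `genotype`, `env`, `rep`, `block`, `trait`, `value`. The reader
#' checks that each (genotype, environment, replicate) combination appears at
#' most once per trait.
#'
#' @param path file path.
#' @return A data.frame of plot records.
#' @export
readPhenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("genotype", "env", "rep", "block", "trait", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  key <- with(tab, paste(genotype, env, rep, trait, sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicated (genotype, env, rep) records for a trait")
  tab$value <- as.numeric(tab$value)
  tab
}

#' @param phenotypes a data.frame as returned by [readPhenotypes()] or
#'   [simulatePhenotypes()].
#' @rdname readPhenotypes
#' @export
writePhenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a published-QTL table
#'
#' Ingests a delimited table whose first two columns name a SNP (`S{chrom}_
#' {pos}`) and the QTL it belongs to (`QTL_{chrom}_{k}`). SNPs sharing a QTL
#' code are grouped into one QTL; member order follows physical position. A
#' member whose chromosome disagrees with its QTL code is an error.
#'
#' @param path file path, or a data.frame already holding the columns.
#' @param snpCol,qtlCol column names (defaults `snp`, `qtl`).
#' @param trait optional trait label attached to every QTL.
#' @return A data.frame of class `publishedQtls` with one row per member SNP:
#'   columns `qtl`, `snp`, `chrom`, `pos`, `trait`.
#' @export
readPublishedQtls <- function(path, snpCol = "snp", qtlCol = "qtl",
                              trait = NA_character_) {
  tab <- if (is.data.frame(path)) path else
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  if (!all(c(snpCol, qtlCol) %in% names(tab)))
    stop("published-QTL table needs columns '", snpCol, "' and '", qtlCol, "'")
  loc <- parseSnpId(tab[[snpCol]])
  qtl <- tab[[qtlCol]]
  qchrom <- suppressWarnings(as.integer(sub("^QTL_([0-9]+)_.*$", "\\1", qtl)))
  bad <- !is.na(qchrom) & qchrom != loc$chrom
  if (any(bad))
    stop("member SNP on wrong chromosome for its QTL code: ",
         paste(tab[[snpCol]][bad], collapse = ", "))
  out <- data.frame(qtl = qtl, snp = loc$id, chrom = loc$chrom,
                    pos = loc$pos, trait = trait, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  out <- out[order(match(out$qtl, unique(qtl))), ]
  rownames(out) <- NULL
  class(out) <- c("publishedQtls", "data.frame")
  out
}

#' Number of QTLs in a published-QTL table
#' @param qtls result of [readPublishedQtls()].
#' @export
nQtls <- function(qtls) length(unique(qtls$qtl))

#' Read a printed validation table
#'
#' Parses tables laid out like published QTL-validation reports: columns for
#' the published SNP, its QTL code, its p-value in the validation-set scan,
#' the best window candidate SNP, the candidate's p-value, the physical
#' distance, and the LD r-squared. Thousands separators in the distance
#' column are stripped; `"No"` (LD not computable) and `"Same SNP"` markers
#' in the r-squared column become `NA` with `sameSnp = TRUE` for the latter;
#' blank continuation cells (member rows sharing the QTL's candidate) become
#' `NA`.
#'
#' @param path file path.
#' @return data.frame with columns `snp`, `qtl`, `p_published`,
#'   `candidate_snp`, `candidate_p`, `distance_bp`, `r2`, `sameSnp`.
#' @export
readValidationTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           colClasses = "character", fill = TRUE)
  need <- c("snp", "qtl", "p_published", "candidate_snp", "candidate_p",
            "distance_bp", "ld_r2")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("validation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  r2raw <- tab$ld_r2
  same <- !is.na(r2raw) & tolower(r2raw) == "same snp"
  noLd <- !is.na(r2raw) & tolower(r2raw) == "no"
  r2 <- suppressWarnings(as.numeric(r2raw))
  r2[same | noLd] <- NA_real_
  data.frame(
    snp = tab$snp, qtl = tab$qtl,
    p_published = as.numeric(tab$p_published),
    candidate_snp = tab$candidate_snp,
    candidate_p = as.numeric(tab$candidate_p),
    distance_bp = as.numeric(gsub(",", "", tab$distance_bp, fixed = TRUE)),
    r2 = r2, sameSnp = same, ldNo = noLd,
    stringsAsFactors = FALSE)
}

#' Read and write GWAS result tables
#'
#' Tab-separated with columns `snp`, `chrom`, `pos`, `maf`, `effect`, `se`,
#' `p`, `tested`.
#' @param path file path.
#' @export
readGwas <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("snp", "p")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("GWAS table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"tested" %in% names(tab)) tab$tested <- TRUE
  if (!all(c("chrom", "pos") %in% names(tab))) {
    loc <- parseSnpId(tab$snp)
    tab$chrom <- loc$chrom
    tab$pos <- loc$pos
  }
  tab
}

#' @param scan a GWAS result data.frame from [scanSnps()].
#' @rdname readGwas
#' @export
writeGwas <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
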