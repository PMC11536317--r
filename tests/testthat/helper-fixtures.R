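# shared builders for small in-code fixtures

fixturePath <- function(name) {
  system.file("extdata", name, package = "QTLValidate", mustWork = TRUE)
}

validationFixtures <- function() {
  list(
    yield_ivs = fixturePath("published_validation_grain_yield_ivs.tsv"),
    yield_hvs = fixturePath("published_validation_grain_yield_hvs.tsv"),
    tunnel_ivs = fixturePath("published_validation_tunnel_length_ivs.tsv"),
    tunnel_hvs = fixturePath("published_validation_tunnel_length_hvs.tsv"))
}

# dosage matrix (individuals x snps) -> GenotypeMatrix; these ad-hoc
# matrices are not RIL panels, so the heterozygosity guard is off
gmFromInd <- function(M, ...) GenotypeMatrix(t(M), hetThreshold = 1, ...)

# small RIL panel + map for pipeline tests
tinyMagic <- function(nRils = 80, nChrom = 2, lociPerChrom = 40, g = 6,
                      seed = 42) {
  set.seed(seed)
  map <- geneticMap(nChrom = nChrom, lociPerChrom = lociPerChrom)
  founders <- simulateFounders(map)
  rils <- simulateMagicRils(founders, map, nRils = nRils, g = g)
  list(map = map, founders = founders, rils = rils)
}

# hand-written HapMap text: 2 SNPs x 3 samples with known dosages
writeTinyHapMap <- function(path) {
  lines <- c(
    paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
            "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
            "ind1", "ind2", "ind3"), collapse = "\t"),
    paste(c("S1_100", "A/G", "1", "100", "+", rep("NA", 6),
            "AA", "AG", "GG"), collapse = "\t"),
    paste(c("S2_500", "C/T", "2", "500", "+", rep("NA", 6),
            "TT", "CC", "NN"), collapse = "\t"))
  writeLines(lines, path)
  path
}

writeTinyVcf <- function(path, multiallelic = TRUE) {
  body <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "ind1", "ind2", "ind3"), collapse = "\t"),
    paste(c("1", "100", "S1_100", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("2", "500", "S2_500", "C", "T", ".", "PASS", ".", "GT",
            "1/1", "0/0", "./."), collapse = "\t"))
  if (multiallelic)
    body <- c(body,
              paste(c("3", "900", "S3_900", "A", "G,T", ".", "PASS", ".",
                      "GT", "0/1", "1/2", "0/0"), collapse = "\t"))
  writeLines(body, path)
  path
}

# independent haplotype-frequency LD oracle for fully homozygous panels:
# r2 = D^2 / (pA qA pB qB) from two-locus haplotype counts
haplotypeR2 <- function(x, y) {
  stopifnot(all(x %in% c(0, 2)), all(y %in% c(0, 2)))
  a <- x / 2
  b <- y / 2
  pA <- mean(a)
  pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  pAB <- mean(a * b)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# independent dense-matrix REML log-likelihood for the one-ratio null model
denseReml <- function(lambda, y, K) {
  n <- length(y)
  V <- lambda * K + diag(n)
  Vi <- solve(V)
  one <- rep(1, n)
  xvx <- drop(t(one) %*% Vi %*% one)
  beta <- drop(t(one) %*% Vi %*% y) / xvx
  r <- y - beta
  s2 <- drop(t(r) %*% Vi %*% r) / (n - 1)
  -0.5 * ((n - 1) * log(2 * pi * s2) + determinant(V)$modulus[1] +
            log(xvx) + (n - 1))
}
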