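#' Build a genetic map for simulation
#'
#' Random physical SNP positions per chromosome with map (cM) positions
#' proportional to physical position, i.e. a uniform recombination rate.
#' Defaults approximate a maize-like genome: 10 chromosomes of 200 Mbp at
#' 0.7 cM/Mbp (about 1.4 Morgans per chromosome).
#'
#' @param nChrom number of chromosomes.
#' @param lociPerChrom SNPs per chromosome (recycled).
#' @param chromLengthBp physical chromosome length in bp (recycled).
#' @param cmPerMb recombination rate in cM per Mbp.
#' @return data.frame (`chrom`, `pos`, `cm`, `id`) sorted by (chrom, pos),
#'   class `geneticMap`.
#' @examples
#' map <- geneticMap(nChrom = 2, lociPerChrom = 50)
#' @export
geneticMap <- function(nChrom = 10, lociPerChrom = 100,
                       chromLengthBp = 2e8, cmPerMb = 0.7) {
  lociPerChrom <- rep_len(lociPerChrom, nChrom)
  chromLengthBp <- rep_len(chromLengthBp, nChrom)
  out <- do.call(rbind, lapply(seq_len(nChrom), function(ch) {
    pos <- sort(sample.int(chromLengthBp[ch], lociPerChrom[ch]))
    data.frame(chrom = ch, pos = as.numeric(pos),
               cm = pos / 1e6 * cmPerMb)
  }))
  out$id <- formatSnpId(out$chrom, out$pos)
  class(out) <- c("geneticMap", "data.frame")
  out
}

#' Simulate founder haplotypes
#'
#' Draws `nFounders` fully homozygous founder inbreds, each a single 0/1
#' haplotype over the map's loci. Every locus is guaranteed polymorphic
#' across the founder set (loci drawn monomorphic have one founder's allele
#' flipped), so the derived MAGIC population can segregate everywhere.
#'
#' @param map a [geneticMap()].
#' @param nFounders number of founders; must be a power of two so the
#'   crossing funnel is balanced.
#' @return matrix `nFounders` x nLoci of 0/1 alleles, rows `F1..Fk`, columns
#'   the SNP ids.
#' @export
simulateFounders <- function(map, nFounders = 8) {
  if (nFounders < 2 || bitwAnd(nFounders, nFounders - 1L) != 0)
    stop("nFounders must be a power of two (balanced funnel)")
  nl <- nrow(map)
  H <- matrix(rbinom(nFounders * nl, 1L, 0.5), nrow = nFounders,
              dimnames = list(paste0("F", seq_len(nFounders)), map$id))
  mono <- which(colSums(H) %in% c(0L, nFounders))
  for (j in mono) {
    i <- sample.int(nFounders, 1L)
    H[i, j] <- 1L - H[i, j]
  }
  H
}

# One meiosis: recombine two founder-origin haplotypes along the map.
# Crossovers per chromosome ~ Poisson(map length in Morgans), positions
# uniform on the cM scale (Haldane: no interference).
meiosis <- function(h1, h2, mapSplit) {
  out <- integer(length(h1))
  for (k in seq_along(mapSplit)) {
    idx <- mapSplit[[k]]$idx
    cm <- mapSplit[[k]]$cm
    lenM <- (cm[length(cm)] - cm[1L]) / 100
    nx <- rpois(1L, lenM)
    phase <- sample.int(2L, 1L)
    if (nx == 0L) {
      out[idx] <- if (phase == 1L) h1[idx] else h2[idx]
    } else {
      xo <- sort(runif(nx, min = cm[1L], max = cm[length(cm)]))
      seg <- findInterval(cm, xo)  # 0..nx, increments at each crossover
      useFirst <- (seg + phase) %% 2L == 0L
      out[idx] <- ifelse(useFirst, h1[idx], h2[idx])
    }
  }
  out
}

splitMap <- function(map) {
  lapply(split(seq_len(nrow(map)), map$chrom),
         function(i) list(idx = i, cm = map$cm[i]))
}

#' Simulate a MAGIC RIL population
#'
#' Each RIL descends from its own balanced funnel over a random permutation
#' of the founders (pairwise two-way crosses, then four-way, then the
#' eight-way cross) followed by `g` generations of single-seed-descent
#' selfing. Meioses place crossovers by a Poisson count with mean equal to
#' the chromosome map length in Morgans and uniform positions (Haldane, no
#' interference).
#'
#' @param founders founder haplotypes from [simulateFounders()].
#' @param map the [geneticMap()] used for `founders`.
#' @param nRils number of RILs.
#' @param g selfing generations after the funnel (default 6; residual
#'   heterozygosity halves each generation).
#' @return A [GenotypeMatrix-class] of `nRils` individuals; its metadata
#'   carries `founderShare`, the nRils x nFounders matrix of realised founder
#'   genome proportions.
#' @export
simulateMagicRils <- function(founders, map, nRils = 600, g = 6) {
  if (!nrow(map)) stop("empty genetic map")
  if (g < 1) stop("g must be >= 1")
  stopifnot(ncol(founders) == nrow(map))
  nF <- nrow(founders)
  ms <- splitMap(map)
  nl <- nrow(map)
  dos <- matrix(NA_real_, nl, nRils,
                dimnames = list(map$id, sprintf("RIL%03d", seq_len(nRils))))
  share <- matrix(0, nRils, nF, dimnames = list(colnames(dos),
                                                rownames(founders)))
  for (r in seq_len(nRils)) {
    ord <- sample.int(nF)
    # funnel: each level halves the number of lineages
    gen <- lapply(ord, function(f) list(h1 = rep(f, nl), h2 = rep(f, nl)))
    while (length(gen) > 1L) {
      gen <- lapply(seq_len(length(gen) / 2L), function(i) {
        p1 <- gen[[2L * i - 1L]]
        p2 <- gen[[2L * i]]
        list(h1 = meiosis(p1$h1, p1$h2, ms), h2 = meiosis(p2$h1, p2$h2, ms))
      })
    }
    ind <- gen[[1L]]
    for (s in seq_len(g))
      ind <- list(h1 = meiosis(ind$h1, ind$h2, ms),
                  h2 = meiosis(ind$h1, ind$h2, ms))
    a1 <- founders[cbind(ind$h1, seq_len(nl))]
    a2 <- founders[cbind(ind$h2, seq_len(nl))]
    dos[, r] <- a1 + a2
    tab <- tabulate(c(ind$h1, ind$h2), nbins = nF)
    share[r, ] <- tab / (2 * nl)
  }
  gm <- GenotypeMatrix(dosage = dos, chrom = map$chrom, pos = map$pos,
                       panelType = "inbred")
  S4Vectors::metadata(gm)$founderShare <- share
  gm
}

#' Simulate an unrelated homozygous tester haplotype
#'
#' @param map a [geneticMap()].
#' @param altFreq per-locus probability of carrying the alternate allele.
#' @return named 0/1 vector over the map's loci.
#' @export
simulateTester <- function(map, altFreq = 0.5) {
  setNames(rbinom(nrow(map), 1L, altFreq), map$id)
}

#' Cross RILs to a common homozygous tester
#'
#' Hybrid dosage at each locus is (RIL dosage)/2 + tester allele count, i.e.
#' one gamete from the (near-homozygous) RIL plus the tester gamete. Fully
#' homozygous RIL loci give dosages 0, 1 or 2; residual heterozygous RIL loci
#' give half-integer expected dosages.
#'
#' @param rils a [GenotypeMatrix-class] of inbred lines.
#' @param tester named 0/1 vector (alternate-allele indicator of the
#'   homozygous tester) covering the RIL loci; values outside `{0, 1}` are
#'   rejected as a heterozygous/invalid tester.
#' @return A [GenotypeMatrix-class] with `panelType = "hybrid"`; individuals
#'   renamed `<ril>xT`.
#' @export
makeTestcross <- function(rils, tester) {
  ids <- snpIds(rils)
  if (is.null(names(tester))) {
    if (length(tester) != length(ids))
      stop("unnamed tester must cover all RIL loci")
    names(tester) <- ids
  }
  miss <- setdiff(ids, names(tester))
  if (length(miss)) stop("tester lacks loci: ", paste(utils::head(miss, 3),
                                                      collapse = ", "))
  tv <- tester[ids]
  if (any(!tv %in% c(0, 1)))
    stop("heterozygous or invalid tester locus (alleles must be 0/1)")
  d <- SummarizedExperiment::assay(rils, "dosage")
  hyb <- d / 2 + tv  # recycled down columns: tv is per-locus (rows)
  colnames(hyb) <- paste0(colnames(d), "xT")
  GenotypeMatrix(dosage = hyb, chrom = snpChrom(rils), pos = snpPos(rils),
                 panelType = "hybrid")
}

#' Variance-component presets of the three evaluation sets
#'
#' Calibration presets carrying the variance structure, trait means/ranges,
#' and trial dimensions of the three evaluation sets the pipeline targets:
#' the whole 608-line MAGIC population (augmented design, unreplicated),
#' the 56/64-entry inbred validation set (IVS; 8 x 8 lattice, 2 years under
#' infestation, 2 replicates) and the 52/56-entry hybrid validation set
#' (HVS; 8 x 7 lattice; tunnel length scored in 4 infested/naturally
#' infested environments, grain yield in 6).
#'
#' @param set one of `"whole_magic"`, `"ivs"`, `"hvs"`.
#' @return list with `n`, `blockSize`, and per trait (`tunnel_cm`,
#'   `yield`) the components `vg`, `vgxe`, `vres`, `mean`, `range`, `e`
#'   (environments), `r` (replicates).
#' @examples
#' magicPreset("ivs")$tunnel_cm
#' @export
magicPreset <- function(set = c("whole_magic", "ivs", "hvs")) {
  set <- match.arg(set)
  switch(set,
    whole_magic = list(
      set = set, n = 608, blockSize = 8, replicates = 1,
      tunnel_cm = list(vg = 21, vgxe = 7, vres = 91, mean = 35,
                       range = c(0, 59), e = 2, r = 1),
      yield = list(vg = 78, vgxe = 3, vres = 186, mean = 42.4,
                   range = c(0, 114), e = 2, r = 1, units = "g/plant")),
    ivs = list(
      set = set, n = 64, blockSize = 8, replicates = 2,
      tunnel_cm = list(vg = 107, vgxe = 38, vres = 75, mean = 25,
                       range = c(6, 63), e = 2, r = 2),
      yield = list(vg = 229, vgxe = 174, vres = 582, mean = 73.3,
                   range = c(20, 117), e = 4, r = 2, units = "g/plant")),
    hvs = list(
      set = set, n = 56, blockSize = 8, replicates = 2,
      tunnel_cm = list(vg = 21, vgxe = 17, vres = 119, mean = 29,
                       range = c(16, 40), e = 4, r = 2),
      yield = list(vg = 118, vgxe = 40, vres = 396, mean = 7.6,
                   range = c(4.6, 9.4), e = 6, r = 2, units = "Mg/ha")))
}

#' Simulate lattice-design field phenotypes
#'
#' Generates plot-level phenotypes for each genotype under a resolvable
#' incomplete-block (lattice-like) design: `e` environments x `r` complete
#' replicates, genotypes randomised into incomplete blocks of `blockSize`
#' within each replicate. The observation model is
#'
#' `value = mean + QTL effects + polygenic effect + environment effect +
#'  GxE deviation + block effect + residual`
#'
#' QTL contributions are `additive * (dosage - 1)` plus `dominance` for
#' heterozygous (dosage 1) genotypes. The polygenic effect is drawn so the
#' total genotypic variance matches `vg` (its variance is `vg` minus the
#' realised QTL variance, floored at 0); across the two traits polygenic
#' effects have genetic correlation `rho`. GxE deviations are independent
#' `N(0, vgxe)` per genotype x environment; residuals `N(0, vres)` per plot.
#' Environment, replicate and block effects are nuisance draws with standard
#' deviations `envSd`, `repSd`, `blockSd`.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param traits named list; each element a list with `vg`, `vgxe`, `vres`,
#'   `mean`, and optionally `qtl` (data.frame with `snp`, `additive` and
#'   optionally `dominance`). Defaults to the IVS tunnel-length preset.
#' @param rho genetic correlation between the polygenic parts of the first
#'   two traits (ignored for a single trait).
#' @param e,r,blockSize environments, replicates per environment, incomplete-
#'   block size.
#' @param envSd,repSd,blockSd nuisance effect standard deviations.
#' @param truncateAtZero clamp negative plot values at 0 (rate reported via
#'   a message); off by default because truncation biases variance
#'   components.
#' @return data.frame (`genotype`, `env`, `rep`, `block`, `trait`, `value`)
#'   with attribute `geneticValues` (genotype x trait matrix of simulated
#'   true genotypic values).
#' @export
simulatePhenotypes <- function(genotypes,
                               traits = list(tunnel_cm =
                                               magicPreset("ivs")$tunnel_cm),
                               rho = 0.5, e = 2, r = 2, blockSize = 8,
                               envSd = 2, repSd = 0.5, blockSd = 1,
                               truncateAtZero = FALSE) {
  D <- dosages(genotypes)  # individuals x loci
  n <- nrow(D)
  if (e < 1 || r < 1) stop("need at least one environment and replicate")
  ids <- rownames(D)
  nt <- length(traits)
  if (is.null(names(traits))) names(traits) <- paste0("trait", seq_len(nt))

  # polygenic draws, correlated across the first two traits
  z <- matrix(rnorm(n * max(nt, 2L)), n)
  if (nt >= 2L)
    z[, 2L] <- rho * z[, 1L] + sqrt(max(0, 1 - rho^2)) * z[, 2L]

  gv <- matrix(0, n, nt, dimnames = list(ids, names(traits)))
  for (t in seq_len(nt)) {
    tr <- traits[[t]]
    qv <- numeric(n)
    if (!is.null(tr$qtl) && nrow(tr$qtl)) {
      qs <- tr$qtl
      missing <- setdiff(qs$snp, colnames(D))
      if (length(missing))
        stop("QTL snp(s) absent from genotypes: ",
             paste(missing, collapse = ", "))
      for (k in seq_len(nrow(qs))) {
        dk <- D[, qs$snp[k]]
        qv <- qv + qs$additive[k] * (dk - 1)
        if (!is.null(qs$dominance) && !is.na(qs$dominance[k]))
          qv <- qv + qs$dominance[k] * (dk == 1)
      }
    }
    polyVar <- max(0, tr$vg - var(qv))
    gv[, t] <- qv + sqrt(polyVar) * z[, t]
  }

  nBlocks <- ceiling(n / blockSize)
  rows <- vector("list", e * r)
  ii <- 0L
  envNames <- sprintf("env%d", seq_len(e))
  envEff <- setNames(rnorm(e, 0, envSd), envNames)
  gxe <- array(rnorm(n * e * nt, 0,
                     rep(vapply(traits, function(tr) sqrt(tr$vgxe),
                                numeric(1)), each = n * e)),
               dim = c(n, e, nt), dimnames = list(ids, envNames,
                                                  names(traits)))
  for (ev in seq_len(e)) {
    for (rp in seq_len(r)) {
      ii <- ii + 1L
      perm <- sample(ids)
      blk <- rep(seq_len(nBlocks), each = blockSize, length.out = n)
      blkEff <- rnorm(nBlocks, 0, blockSd)
      repEff <- rnorm(1L, 0, repSd)
      base <- lapply(seq_len(nt), function(t) {
        tr <- traits[[t]]
        val <- tr$mean + gv[perm, t] + envEff[ev] + gxe[perm, ev, t] +
          repEff + blkEff[blk] + rnorm(n, 0, sqrt(tr$vres))
        data.frame(genotype = perm, env = envNames[ev], rep = rp,
                   block = blk, trait = names(traits)[t], value = val,
                   stringsAsFactors = FALSE)
      })
      rows[[ii]] <- do.call(rbind, base)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (truncateAtZero) {
    neg <- out$value < 0
    if (any(neg))
      message(sprintf("truncated %d/%d plot values at zero (%.1f%%)",
                      sum(neg), length(neg), 100 * mean(neg)))
    out$value[neg] <- 0
  }
  attr(out, "geneticValues") <- gv
  out
}
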