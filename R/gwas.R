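imputeColMeans <- function(M) {
  nas <- which(is.na(M))
  if (length(nas)) {
    cm <- colMeans(M, na.rm = TRUE)
    M[nas] <- cm[(nas - 1L) %/% nrow(M) + 1L]
  }
  M
}

#' Genomic kinship matrix
#'
#' Centered (VanRaden-type) marker-based relationship matrix:
#' `K = W W' / (2 * sum(p * (1 - p)))` with `W` the dosage matrix centered
#' at twice the allele frequency. Missing dosages are mean-imputed per
#' locus; monomorphic loci carry no information and are dropped. The
#' construction is positive semi-definite; a small ridge is added to the
#' diagonal only in the numerically degenerate case of a smallest eigenvalue
#' below zero.
#'
#' @param genotypes a [GenotypeMatrix-class] (or an individuals x SNP dosage
#'   matrix).
#' @return n x n symmetric matrix with individual ids as dimnames.
#' @export
computeKinship <- function(genotypes) {
  M <- if (is(genotypes, "GenotypeMatrix")) dosages(genotypes) else
    as.matrix(genotypes)
  if (nrow(M) < 2L) stop("kinship needs >= 2 individuals")
  M <- imputeColMeans(M)
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci; kinship undefined")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(M, 2L, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    K <- K + diag(-min(ev) + 1e-8, nrow(K))
  K
}

remlProfile <- function(loglam, yr, xr, d, n) {
  lam <- exp(loglam)
  dl <- lam * d + 1
  xtx <- sum(xr^2 / dl)
  beta <- sum(xr * yr / dl) / xtx
  r <- yr - xr * beta
  rss <- sum(r^2 / dl)
  s2 <- rss / (n - 1)
  -0.5 * ((n - 1) * log(2 * pi * s2) + sum(log(dl)) + log(xtx) + (n - 1))
}

#' Fit the polygenic null model by REML
#'
#' Intercept-only mixed model `y = mu + g + e`, `g ~ N(0, sigma2g K)`,
#' `e ~ N(0, sigma2e I)`, maximised by restricted maximum likelihood.
#' The kinship is spectrally decomposed once and the restricted likelihood
#' profiled over the single variance ratio `lambda = sigma2g / sigma2e`
#' (one-dimensional optimisation on the log scale, with the boundary
#' `lambda = 0` also considered). The resulting fit is reused by
#' [scanSnps()] for every SNP test (P3D).
#'
#' @param phenotype an `adjustedMeans` data.frame (from [estimateBlues()])
#'   or a named numeric vector of phenotype values.
#' @param kinship matrix from [computeKinship()]; individuals are aligned to
#'   the phenotype by name.
#' @param lambdaFixed optionally hold the variance ratio fixed (e.g. 0 for
#'   an ordinary least-squares scan) instead of estimating it.
#' @return A [NullModelFit-class].
#' @export
fitNull <- function(phenotype, kinship, lambdaFixed = NULL) {
  if (is.data.frame(phenotype))
    y <- setNames(phenotype$blue, phenotype$genotype)
  else y <- phenotype
  y <- y[!is.na(y)]
  ids <- intersect(rownames(kinship), names(y))
  if (length(ids) < 3L) stop("fewer than 3 aligned individuals")
  y <- y[ids]
  if (stats::var(y) == 0) stop("phenotype has zero variance; degenerate fit")
  K <- kinship[ids, ids]
  eg <- eigen(K, symmetric = TRUE)
  n <- length(y)
  yr <- drop(crossprod(eg$vectors, y))
  xr <- drop(crossprod(eg$vectors, rep(1, n)))
  d <- pmax(eg$values, 0)
  if (is.null(lambdaFixed)) {
    opt <- optimize(remlProfile, interval = c(-14, 14), yr = yr, xr = xr,
                    d = d, n = n, maximum = TRUE, tol = 1e-8)
    ll0 <- remlProfile(-Inf, yr, xr, d, n)  # boundary: lambda = 0
    if (ll0 >= opt$objective) {
      lam <- 0; ll <- ll0
    } else {
      lam <- exp(opt$maximum); ll <- opt$objective
    }
  } else {
    lam <- lambdaFixed
    ll <- remlProfile(if (lam > 0) log(lam) else -Inf, yr, xr, d, n)
  }
  dl <- lam * d + 1
  xtx <- sum(xr^2 / dl)
  beta <- sum(xr * yr / dl) / xtx
  s2e <- sum((yr - xr * beta)^2 / dl) / (n - 1)
  new("NullModelFit", sigma2g = lam * s2e, sigma2e = s2e, lambda = lam,
      logLik = ll, beta = beta,
      rotation = list(U = eg$vectors, d = d), ids = ids)
}

#' Mixed-model association scan with P3D
#'
#' Tests the additive dosage term of every SNP in a generalized-least-squares
#' regression with the null model's variance components held fixed
#' ("previously determined population parameters": the variance ratio is
#' estimated once by [fitNull()] and reused for each SNP). The phenotype,
#' intercept and dosage columns are rotated into the kinship eigenbasis and
#' whitened, after which each test is an ordinary F test of the SNP
#' coefficient with `n - 2` denominator degrees of freedom (n minus the
#' intercept rank minus the SNP term).
#'
#' SNPs failing the minor-allele-frequency filter (or monomorphic after
#' imputation) are reported with `tested = FALSE` and `NA` statistics rather
#' than dropped.
#'
#' @param phenotype as in [fitNull()].
#' @param genotypes a [GenotypeMatrix-class].
#' @param null a [NullModelFit-class] fitted on the same individuals.
#' @param maf minor-allele-frequency threshold (default 0.05).
#' @return data.frame of class `gwasScan`: `snp`, `chrom`, `pos`, `maf`,
#'   `effect`, `se`, `p`, `tested`.
#' @export
scanSnps <- function(phenotype, genotypes, null, maf = 0.05) {
  if (is.data.frame(phenotype))
    y <- setNames(phenotype$blue, phenotype$genotype)
  else y <- phenotype
  ids <- null@ids
  if (!all(ids %in% names(y)) || !all(ids %in% individualIds(genotypes)))
    stop("null model, phenotype and genotypes must share individuals")
  y <- y[ids]
  M <- imputeColMeans(dosages(genotypes)[ids, , drop = FALSE])
  n <- length(y)
  p <- colMeans(M) / 2
  mafv <- pmin(p, 1 - p)
  tested <- mafv >= maf & apply(M, 2L, stats::sd) > 0
  if (!any(tested))
    warning("all SNPs removed by the MAF filter; empty scan")

  w <- 1 / sqrt(null@lambda * null@rotation$d + 1)
  Ut <- t(null@rotation$U)
  yt <- w * drop(Ut %*% y)
  ot <- w * drop(Ut %*% rep(1, n))
  St <- (w * (Ut %*% M))
  # residualize on the (whitened) intercept
  oo <- sum(ot^2)
  yt <- yt - ot * (sum(ot * yt) / oo)
  St <- St - outer(ot, drop(crossprod(St, ot)) / oo)
  sss <- colSums(St^2)
  sy <- drop(crossprod(St, yt))
  yy <- sum(yt^2)
  beta <- sy / sss
  df2 <- n - 2
  rss <- pmax(yy - beta * sy, 0)
  Fst <- (beta * sy) / (rss / df2)
  pv <- pf(Fst, 1, df2, lower.tail = FALSE)
  se <- sqrt((rss / df2) / sss)
  bad <- !tested | sss < 1e-12
  beta[bad] <- se[bad] <- pv[bad] <- NA_real_
  out <- data.frame(snp = snpIds(genotypes), chrom = snpChrom(genotypes),
                    pos = snpPos(genotypes), maf = unname(mafv),
                    effect = unname(beta), se = unname(se), p = unname(pv),
                    tested = unname(tested & !bad), stringsAsFactors = FALSE)
  class(out) <- c("gwasScan", "data.frame")
  out
}
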