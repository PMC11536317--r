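subsetTrait <- function(phenotypes, trait) {
  if (!is.null(phenotypes$trait)) {
    if (is.null(trait)) {
      tr <- unique(phenotypes$trait)
      if (length(tr) > 1L) stop("several traits present; specify `trait`")
      trait <- tr
    }
    phenotypes <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  }
  if (!nrow(phenotypes)) stop("no records for trait ", trait)
  phenotypes$genotype <- factor(phenotypes$genotype)
  phenotypes$env <- factor(phenotypes$env)
  phenotypes$envRep <- factor(paste(phenotypes$env, phenotypes$rep,
                                    sep = ":"))
  phenotypes$envRepBlock <- factor(paste(phenotypes$envRep,
                                         phenotypes$block, sep = ":"))
  attr(phenotypes, "trait") <- trait
  phenotypes
}

# random terms supported by the data: a factor with a single level, or one
# that is confounded 1:1 with a finer term, contributes nothing estimable
randomTerms <- function(dat) {
  terms <- character()
  if (nlevels(dat$env) > 1L) terms <- c(terms, "(1 | env)")
  if (nlevels(dat$envRep) > nlevels(dat$env))
    terms <- c(terms, "(1 | envRep)")
  if (nlevels(dat$envRepBlock) > nlevels(dat$envRep) &&
      nlevels(dat$envRepBlock) < nrow(dat))
    terms <- c(terms, "(1 | envRepBlock)")
  terms
}

#' Best linear unbiased estimators of genotype means
#'
#' One-stage mixed-model analysis of a multi-environment lattice trial:
#' genotype enters as a fixed factor; environment, replicate within
#' environment, and incomplete block within replicate as random factors.
#' The fixed genotype estimates are the BLUEs across environments. With a
#' single complete environment/replicate the model degenerates to ordinary
#' least squares and BLUEs equal raw genotype means.
#'
#' @param phenotypes plot-level data.frame (`genotype`, `env`, `rep`,
#'   `block`, `trait`, `value`), e.g. from [readPhenotypes()] or
#'   [simulatePhenotypes()].
#' @param trait trait to analyse (may be omitted for single-trait tables).
#' @return data.frame of class `adjustedMeans` with columns `genotype`,
#'   `blue`, `se`; genotypes with no phenotypic record get `NA` rows rather
#'   than being dropped silently. Attribute `trait` carries the label.
#' @export
estimateBlues <- function(phenotypes, trait = NULL) {
  dat <- subsetTrait(phenotypes, trait)
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  terms <- randomTerms(dat)
  if (length(terms)) {
    fml <- stats::as.formula(paste("value ~ 0 + genotype +",
                                   paste(terms, collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.conv.grad = "ignore"))))
    b <- lme4::fixef(fit)
    se <- sqrt(Matrix::diag(stats::vcov(fit)))
  } else {
    fit <- stats::lm(value ~ 0 + genotype, data = dat)
    b <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  }
  names(b) <- sub("^genotype", "", names(b))
  names(se) <- names(b)
  gts <- levels(dat$genotype)
  out <- data.frame(genotype = gts,
                    blue = unname(b[gts]),
                    se = unname(se[gts]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$blue))
    warning(sum(is.na(out$blue)), " genotype(s) without estimable BLUE ",
            "(no phenotypic records); reported as NA")
  attr(out, "trait") <- attr(dat, "trait")
  class(out) <- c("adjustedMeans", "data.frame")
  out
}

#' REML variance components of a multi-environment trial
#'
#' Fits the all-random model `value ~ (1|genotype) + (1|env) +
#' (1|genotype:env) + (1|env:rep) + (1|env:rep:block)` by REML and extracts
#' the genotypic, genotype-by-environment and residual components. Negative
#' solutions are constrained to zero by the fitter. Standard errors come
#' from the inverse Fisher information of the variance parameters at the
#' REML solution, evaluated directly on the mixed-model covariance matrix
#' (components estimated at the zero boundary get `NA`).
#'
#' @inheritParams estimateBlues
#' @param computeSe skip the (order n^3) information-matrix step when FALSE.
#' @return A [VarianceComponents-class].
#' @export
estimateVarianceComponents <- function(phenotypes, trait = NULL,
                                       computeSe = TRUE) {
  dat <- subsetTrait(phenotypes, trait)
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  if (nlevels(droplevels(dat$env)) < 2L)
    stop("variance-component estimation needs >= 2 environments")
  if (nlevels(droplevels(dat$genotype)) < 2L)
    stop("variance-component estimation needs >= 2 genotypes")
  dat$gxe <- factor(paste(dat$genotype, dat$env, sep = ":"))
  terms <- c("(1 | genotype)", "(1 | env)", "(1 | gxe)", randomTerms(dat))
  terms <- unique(terms)
  fml <- stats::as.formula(paste("value ~ 1 +",
                                 paste(terms, collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           check.conv.grad = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    i <- vc$grp == g
    if (any(i)) vc$vcov[i] else 0
  }
  vg <- getv("genotype")
  vgxe <- getv("gxe")
  vres <- getv("Residual")
  se <- c(vg = NA_real_, vgxe = NA_real_, vres = NA_real_)
  if (computeSe) {
    se <- tryCatch(vcInformationSe(fit, c(genotype = vg, gxe = vgxe)),
                   error = function(e) se)
  }
  VarianceComponents(vg = vg, vgxe = vgxe, vres = vres, se = se,
                     trait = as.character(attr(dat, "trait")))
}

# Asymptotic REML standard errors for (Vg, Vgxe, Vres): Fisher information
# I_ij = tr(P Vi P Vj) / 2 with P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1 and
# Vi = Zi Zi' (identity for the residual). Components on the zero boundary
# are excluded (their SE is reported NA).
vcInformationSe <- function(fit, focal) {
  n <- stats::nobs(fit)
  X <- lme4::getME(fit, "X")
  Ztl <- lme4::getME(fit, "Ztlist")
  cnms <- names(lme4::getME(fit, "cnms"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comps <- setNames(vc$vcov[match(cnms, vc$grp)], cnms)
  vres <- vc$vcov[vc$grp == "Residual"]
  Zs <- lapply(Ztl, Matrix::t)
  names(Zs) <- cnms
  V <- Matrix::Diagonal(n, vres)
  for (k in seq_along(Zs))
    V <- V + comps[k] * Matrix::tcrossprod(Zs[[k]])
  Vi <- solve(as(V, "generalMatrix"))
  XtVi <- Matrix::crossprod(X, Vi)
  P <- Vi - Matrix::t(XtVi) %*% solve(XtVi %*% X, XtVi)
  P <- as.matrix(P)
  design <- c(Zs[intersect(c("genotype", "gxe"), names(Zs))],
              list(resid = Matrix::Diagonal(n)))
  m <- length(design)
  info <- matrix(0, m, m)
  PZ <- lapply(design, function(Z) P %*% as.matrix(Z))
  for (i in seq_len(m)) for (j in i:m) {
    tij <- sum(Matrix::crossprod(as.matrix(design[[i]]), PZ[[j]])^2)
    info[i, j] <- info[j, i] <- tij / 2
  }
  covm <- tryCatch(solve(info), error = function(e) NULL)
  out <- c(vg = NA_real_, vgxe = NA_real_, vres = NA_real_)
  if (!is.null(covm)) {
    sds <- sqrt(pmax(diag(covm), 0))
    names(sds) <- c(intersect(c("genotype", "gxe"), names(Zs)), "resid")
    if ("genotype" %in% names(sds) && comps["genotype"] > 1e-10)
      out["vg"] <- sds[["genotype"]]
    if ("gxe" %in% names(sds) && comps["gxe"] > 1e-10)
      out["vgxe"] <- sds[["gxe"]]
    out["vres"] <- sds[["resid"]]
  }
  out
}

#' Family-mean heritability
#'
#' Heritability on a family (line) mean basis over `e` environments and `r`
#' replicates per environment:
#'
#' `h2 = Vg / (Vg + Vgxe / e + Vres / (e * r))`
#'
#' The standard error is by the delta method, treating the component
#' estimates as independent with the standard errors carried by `vc` (or a
#' covariance matrix passed via `vcov`).
#'
#' @param vc a [VarianceComponents-class], or a named list/vector with
#'   `vg`, `vgxe`, `vres` (and optionally `se`).
#' @param e number of environments contributing to the family means.
#' @param r number of replicates per environment.
#' @param vcov optional 3 x 3 covariance matrix of (Vg, Vgxe, Vres).
#' @return A [HeritabilityEstimate-class]; `h2` is `NA` when all components
#'   are zero (heritability undefined).
#' @examples
#' h <- heritabilityFamilyMean(list(vg = 107, vgxe = 38, vres = 75),
#'                             e = 2, r = 2)
#' round(h@h2, 2)  # 0.74
#' @export
heritabilityFamilyMean <- function(vc, e, r, vcov = NULL) {
  stopifnot(e >= 1, r >= 1)
  if (is(vc, "VarianceComponents")) {
    vg <- vc@vg; vgxe <- vc@vgxe; vres <- vc@vres
    sevec <- vc@se
  } else {
    vg <- vc$vg; vgxe <- vc$vgxe; vres <- vc$vres
    sevec <- if (!is.null(vc$se)) vc$se else
      c(vg = NA_real_, vgxe = NA_real_, vres = NA_real_)
  }
  if (any(c(vg, vgxe, vres) < 0)) stop("variance components must be >= 0")
  denom <- vg + vgxe / e + vres / (e * r)
  if (denom == 0) {
    message("all variance components are zero; heritability undefined")
    return(new("HeritabilityEstimate", h2 = NA_real_, se = NA_real_,
               e = e, r = r))
  }
  h2 <- vg / denom
  grad <- c((denom - vg) / denom^2,
            -vg / (e * denom^2),
            -vg / (e * r * denom^2))
  if (is.null(vcov)) {
    s <- sevec[c("vg", "vgxe", "vres")]
    vcov <- diag(ifelse(is.na(s), 0, s)^2, 3L)
    seUndef <- all(is.na(s))
  } else seUndef <- FALSE
  se <- sqrt(drop(t(grad) %*% vcov %*% grad))
  if (seUndef) se <- NA_real_
  new("HeritabilityEstimate", h2 = h2, se = se, e = e, r = r)
}
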