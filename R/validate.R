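#' Select the tails of two trait distributions
#'
#' Builds an extreme-line subset from the BLUE distributions of two traits:
#' for a growing per-trait count `k`, the union of the `k` highest and `k`
#' lowest genotypes of each trait is taken until it reaches `nTarget`
#' genotypes. The procedure keeps genetic variability for both traits while
#' limiting the number of entries to what a replicated lattice can hold.
#' Ties at a cut rank, and any trimming when the final step overshoots, are
#' resolved by lexicographic genotype id (logged via a message), so the
#' selection is deterministic.
#'
#' @param bluesA,bluesB `adjustedMeans` data.frames (one per trait) covering
#'   a common candidate pool.
#' @param nTarget size of the subset to select.
#' @return character vector of `nTarget` genotype ids, sorted.
#' @export
selectTails <- function(bluesA, bluesB, nTarget) {
  pool <- intersect(bluesA$genotype[!is.na(bluesA$blue)],
                    bluesB$genotype[!is.na(bluesB$blue)])
  if (nTarget > length(pool))
    stop("nTarget exceeds the candidate pool (", length(pool), ")")
  rank_ids <- function(blues) {
    b <- blues[blues$genotype %in% pool, ]
    if (stats::var(b$blue) == 0) {
      message("constant trait contributes no tails; selection driven by ",
              "the other trait")
      return(character())
    }
    b <- b[order(b$blue, b$genotype), ]  # ties by id, deterministic
    b$genotype
  }
  loA <- rank_ids(bluesA); hiA <- rev(loA)
  loB <- rank_ids(bluesB); hiB <- rev(loB)
  if (!length(loA) && !length(loB))
    stop("both traits constant; no tails to select")
  prev <- character()
  for (k in seq_len(length(pool))) {
    sel <- unique(c(utils::head(loA, k), utils::head(hiA, k),
                    utils::head(loB, k), utils::head(hiB, k)))
    if (length(sel) >= nTarget) {
      if (length(sel) > nTarget) {
        added <- sort(setdiff(sel, prev))
        drop <- added[seq_len(length(sel) - nTarget)]
        message("tail selection overshot by ", length(drop),
                "; trimmed by lexicographic id")
        sel <- setdiff(sel, drop)
      }
      return(sort(sel))
    }
    prev <- sel
  }
  sort(prev)
}

#' Decision of the two-criterion validation rule
#'
#' Pure rule evaluation on the evidence for one published-SNP / candidate
#' pair: criterion 1 (`same_snp`) holds when the candidate is the published
#' SNP itself (distance 0) with p below the threshold; criterion 2
#' (`ld_window`) when the candidate lies within the window (inclusive), has
#' p below the threshold, and is in LD with the published SNP above the
#' r-squared threshold (strict; an undefined r-squared fails). Exposed so
#' printed validation tables can be re-scored directly from their p,
#' distance and r-squared columns.
#'
#' @param candidateP candidate SNP p-value in the validation-set scan.
#' @param distanceBp distance between published and candidate SNP (bp); `NA`
#'   means no candidate / different chromosome.
#' @param r2 LD r-squared between published SNP and candidate (`NA` =
#'   not computable).
#' @param policy a [ValidationPolicy-class].
#' @return character, one of `"same_snp"`, `"ld_window"`, `"none"`
#'   (vectorised).
#' @export
policyDecision <- function(candidateP, distanceBp, r2,
                           policy = ValidationPolicy()) {
  n <- max(length(candidateP), length(distanceBp), length(r2))
  candidateP <- rep_len(candidateP, n)
  distanceBp <- rep_len(distanceBp, n)
  r2 <- rep_len(r2, n)
  sig <- !is.na(candidateP) & candidateP < policy@pThreshold
  same <- sig & !is.na(distanceBp) & distanceBp == 0
  win <- sig & !is.na(distanceBp) & distanceBp <= policy@windowBp &
    !is.na(r2) & r2 > policy@r2Threshold
  ifelse(same, "same_snp", ifelse(win, "ld_window", "none"))
}

emptyRecord <- function(snp, qtl = NA_character_, set = NA_character_,
                        pPub = NA_real_) {
  data.frame(qtl = qtl, snp = snp, set = set, p_published = pPub,
             candidate_snp = NA_character_, candidate_p = NA_real_,
             distance_bp = NA_real_, r2 = NA_real_, criterion = "none",
             validated = FALSE, flag = NA_character_,
             stringsAsFactors = FALSE)
}

#' Validate one published SNP against a new association scan
#'
#' Applies the two-criterion rule to a single published SNP. Criterion 1 is
#' checked first: the published SNP itself significant in the scan. Failing
#' that, all scanned SNPs within the physical window that pass the p
#' threshold and whose LD r-squared with the published SNP exceeds the
#' r-squared threshold are candidates; the best is chosen by smallest p,
#' ties by smallest distance, then by position order. The record always
#' carries the published SNP's own p-value in the subset scan, whatever the
#' outcome.
#'
#' If the published SNP is absent from the genotype matrix its LD with any
#' candidate is not computable, so only criterion 1 evidence (which needs
#' the SNP in the scan) can apply; the record is flagged.
#'
#' @param published published SNP identifier (`S{chrom}_{pos}`).
#' @param scan `gwasScan` data.frame from [scanSnps()] (or [readGwas()]).
#' @param genotypes [GenotypeMatrix-class] of the validation set, used for
#'   LD; may be `NULL`, disabling criterion 2.
#' @param policy a [ValidationPolicy-class].
#' @param set optional label (`"ivs"`, `"hvs"`, ...) stored in the record.
#' @return one-row data.frame: `qtl`, `snp`, `set`, `p_published`,
#'   `candidate_snp`, `candidate_p`, `distance_bp`, `r2`, `criterion`,
#'   `validated`, `flag`.
#' @export
validateSnp <- function(published, scan, genotypes = NULL,
                        policy = ValidationPolicy(), set = NA_character_) {
  loc <- parseSnpId(published)
  hit <- scan[scan$snp == published, , drop = FALSE]
  pPub <- if (nrow(hit)) hit$p[1L] else NA_real_
  rec <- emptyRecord(published, set = set, pPub = pPub)

  # criterion 1: same SNP significant
  if (nrow(hit) && isTRUE(hit$tested[1L]) && !is.na(hit$p[1L]) &&
      hit$p[1L] < policy@pThreshold) {
    rec$candidate_snp <- published
    rec$candidate_p <- hit$p[1L]
    rec$distance_bp <- 0
    rec$criterion <- "same_snp"
    rec$validated <- TRUE
    return(rec)
  }

  # criterion 2: significant SNP in the window, in LD with the published SNP
  cand <- scan[scan$tested & !is.na(scan$p) &
                 scan$p < policy@pThreshold &
                 scan$chrom == loc$chrom &
                 abs(scan$pos - loc$pos) <= policy@windowBp &
                 scan$snp != published, , drop = FALSE]
  if (!nrow(cand)) return(rec)
  pubInGeno <- !is.null(genotypes) && published %in% snpIds(genotypes)
  if (!pubInGeno) {
    rec$flag <- if (is.null(genotypes)) "no genotypes; LD criterion disabled"
      else "published SNP absent from genotypes; LD not computable"
    return(rec)
  }
  cand$r2 <- vapply(cand$snp, function(s) {
    if (s %in% snpIds(genotypes)) ldR2(genotypes, published, s) else NA_real_
  }, numeric(1))
  cand$distance <- abs(cand$pos - loc$pos)
  ok <- !is.na(cand$r2) & cand$r2 > policy@r2Threshold
  if (!any(ok)) {
    # report the nearest-p candidate as evidence even though it fails
    best <- cand[order(cand$p, cand$distance, cand$pos), ][1L, ]
    rec$candidate_snp <- best$snp
    rec$candidate_p <- best$p
    rec$distance_bp <- best$distance
    rec$r2 <- best$r2
    return(rec)
  }
  best <- cand[ok, ][order(cand$p[ok], cand$distance[ok], cand$pos[ok]),
                     ][1L, ]
  rec$candidate_snp <- best$snp
  rec$candidate_p <- best$p
  rec$distance_bp <- best$distance
  rec$r2 <- best$r2
  rec$criterion <- "ld_window"
  rec$validated <- TRUE
  rec
}

#' Validate a multi-SNP QTL
#'
#' A published QTL (one or more member SNPs sharing a QTL code) is validated
#' when any member SNP validates. The reported row is the member record with
#' the strongest evidence: validated records first, then smallest candidate
#' p, then smallest distance.
#'
#' @param members character vector of member SNP ids (or a one-QTL subset of
#'   a [readPublishedQtls()] table).
#' @param qtl QTL code stored in the record.
#' @inheritParams validateSnp
#' @return one-row data.frame as in [validateSnp()], plus `n_members`.
#' @export
validateQtl <- function(members, scan, genotypes = NULL,
                        policy = ValidationPolicy(), qtl = NA_character_,
                        set = NA_character_) {
  if (is.data.frame(members)) {
    if (is.na(qtl)) qtl <- members$qtl[1L]
    members <- members$snp
  }
  if (!length(members)) stop("QTL must have at least one member SNP")
  recs <- do.call(rbind, lapply(members, validateSnp, scan = scan,
                                genotypes = genotypes, policy = policy,
                                set = set))
  o <- order(!recs$validated,
             ifelse(is.na(recs$candidate_p), Inf, recs$candidate_p),
             ifelse(is.na(recs$distance_bp), Inf, recs$distance_bp))
  best <- recs[o[1L], , drop = FALSE]
  best$qtl <- qtl
  best$n_members <- length(members)
  rownames(best) <- NULL
  best
}

#' Validate every QTL in a published-QTL table
#'
#' @param qtls a [readPublishedQtls()] table.
#' @inheritParams validateSnp
#' @return data.frame of class `validationRecords`, one row per QTL.
#' @export
validateQtls <- function(qtls, scan, genotypes = NULL,
                         policy = ValidationPolicy(), set = NA_character_) {
  out <- do.call(rbind, lapply(unique(qtls$qtl), function(q) {
    validateQtl(qtls[qtls$qtl == q, , drop = FALSE], scan = scan,
                genotypes = genotypes, policy = policy, qtl = q, set = set)
  }))
  class(out) <- c("validationRecords", "data.frame")
  out
}

#' Concordance of validation decisions across two sets
#'
#' Classifies every published QTL by where it validated: in both the inbred
#' and hybrid validation sets, in one only, or in neither. A QTL present in
#' only one record list is classified with the missing set treated as
#' not-validated and flagged.
#'
#' @param ivs,hvs `validationRecords` for the inbred and hybrid sets.
#' @return list of class `crossSetSummary`: `perQtl` (data.frame `qtl`,
#'   `ivs`, `hvs`, `category`, `flag`) and `counts` (named integer vector
#'   over `both`, `ivs_only`, `hvs_only`, `neither`).
#' @export
crossSetSummary <- function(ivs, hvs) {
  qtls <- union(ivs$qtl, hvs$qtl)
  vi <- setNames(ivs$validated, ivs$qtl)[qtls]
  vh <- setNames(hvs$validated, hvs$qtl)[qtls]
  flag <- ifelse(is.na(vi), "absent from IVS records",
                 ifelse(is.na(vh), "absent from HVS records", NA_character_))
  vi[is.na(vi)] <- FALSE
  vh[is.na(vh)] <- FALSE
  category <- ifelse(vi & vh, "both",
                     ifelse(vi, "ivs_only",
                            ifelse(vh, "hvs_only", "neither")))
  counts <- vapply(c("both", "ivs_only", "hvs_only", "neither"),
                   function(k) sum(category == k), integer(1))
  out <- list(perQtl = data.frame(qtl = qtls, ivs = unname(vi),
                                  hvs = unname(vh), category = category,
                                  flag = flag, stringsAsFactors = FALSE,
                                  row.names = NULL),
              counts = counts)
  class(out) <- "crossSetSummary"
  out
}

#' @export
print.crossSetSummary <- function(x, ...) {
  cat("Cross-set QTL validation summary (", sum(x$counts), " QTLs)\n",
      sep = "")
  for (k in names(x$counts))
    cat(sprintf("  %-9s %d\n", k, x$counts[[k]]))
  invisible(x)
}
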