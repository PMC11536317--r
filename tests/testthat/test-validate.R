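# A constructed scenario with known LD structure: published SNP S1_1000000,
# a tightly linked significant neighbour, an unlinked significant SNP, and a
# distant significant SNP outside any 2-Mbp window.
validationScenario <- function() {
  set.seed(61)
  n <- 60
  a <- rbinom(n, 1, 0.5)
  linked <- ifelse(rbinom(n, 1, 0.1) == 1, 1 - a, a)  # r2 ~ 0.64
  unlinked <- rbinom(n, 1, 0.5)
  far <- rbinom(n, 1, 0.5)
  M <- cbind(S1_1000000 = 2 * a,
             S1_1500000 = 2 * linked,
             S1_2200000 = 2 * unlinked,
             S1_9000000 = 2 * far)
  rownames(M) <- sprintf("r%02d", seq_len(n))
  gm <- gmFromInd(M)
  scan <- data.frame(snp = colnames(M),
                     chrom = 1L, pos = c(1e6, 1.5e6, 2.2e6, 9e6),
                     maf = 0.5,
                     effect = 1, se = 0.3,
                     p = c(0.5, 0.001, 0.003, 0.0005),
                     tested = TRUE, stringsAsFactors = FALSE)
  list(gm = gm, scan = scan)
}

test_that("the two-criterion rule reproduces the worked published rows", {
  pol <- ValidationPolicy()
  # same SNP significant -> criterion 1
  expect_equal(policyDecision(0.009, 0, NA), "same_snp")
  # in-window significant SNP but r2 below threshold -> not validated
  expect_equal(policyDecision(0.004, 628496, 0.01), "none")
  # in-window, significant, in LD -> criterion 2
  expect_equal(policyDecision(0.002, 1052606, 0.22), "ld_window")
  # nearest qualifying SNP beyond the 2-Mbp window -> not validated
  expect_equal(policyDecision(0.013, 2874606, 0.07), "none")
  # thresholds are strict inequalities; window bound inclusive
  expect_equal(policyDecision(0.02, 0, NA), "none")
  expect_equal(policyDecision(0.01, 2e6, 0.2), "none")
  expect_equal(policyDecision(0.01, 2e6, 0.21), "ld_window")
  expect_equal(policyDecision(0.01, 2e6 + 1, 0.9), "none")
})

test_that("validateSnp picks the best in-LD window candidate", {
  sc <- validationScenario()
  rec <- validateSnp("S1_1000000", sc$scan, sc$gm)
  # the unlinked SNP has smaller p but fails r2; the linked one validates
  expect_true(rec$validated)
  expect_equal(rec$criterion, "ld_window")
  expect_equal(rec$candidate_snp, "S1_1500000")
  expect_equal(rec$distance_bp, 5e5)
  expect_gt(rec$r2, 0.2)
  expect_equal(rec$p_published, 0.5)  # own subset p always carried

  # criterion 1 takes precedence when the published SNP itself is significant
  scan2 <- sc$scan
  scan2$p[1] <- 0.011
  rec2 <- validateSnp("S1_1000000", scan2, sc$gm)
  expect_equal(rec2$criterion, "same_snp")
  expect_equal(rec2$distance_bp, 0)

  # a published SNP absent from the genotype matrix is flagged, LD disabled
  rec3 <- validateSnp("S1_1100000", sc$scan, sc$gm)
  expect_false(rec3$validated)
  expect_match(rec3$flag, "absent")

  # raising the r2 threshold above the pair's LD de-validates
  rec4 <- validateSnp("S1_1000000", sc$scan, sc$gm,
                      ValidationPolicy(r2Threshold = 0.95))
  expect_false(rec4$validated)
})

test_that("a QTL validates when any member SNP validates", {
  sc <- validationScenario()
  members <- c("S1_3000000", "S1_1000000")  # first member has no evidence
  rec <- validateQtl(members, sc$scan, sc$gm, qtl = "QTL_1_1")
  expect_true(rec$validated)
  expect_equal(rec$snp, "S1_1000000")
  expect_equal(rec$n_members, 2L)
  recNone <- validateQtl("S2_1000000", sc$scan, sc$gm, qtl = "QTL_2_1")
  expect_false(recNone$validated)
  expect_error(validateQtl(character(), sc$scan, sc$gm), "at least one")
})

test_that("cross-set summary classifies QTLs and flags missing ones", {
  mk <- function(qtl, val) {
    r <- QTLValidate:::emptyRecord(paste0("S1_", seq_along(qtl)), qtl = qtl)
    r$validated <- val
    r
  }
  ivs <- mk(c("QTL_1_1", "QTL_1_2", "QTL_1_3"), c(TRUE, TRUE, FALSE))
  hvs <- mk(c("QTL_1_1", "QTL_1_2", "QTL_1_4"), c(TRUE, FALSE, TRUE))
  s <- crossSetSummary(ivs, hvs)
  pq <- s$perQtl
  expect_equal(pq$category[pq$qtl == "QTL_1_1"], "both")
  expect_equal(pq$category[pq$qtl == "QTL_1_2"], "ivs_only")
  expect_equal(pq$category[pq$qtl == "QTL_1_4"], "hvs_only")
  expect_equal(pq$category[pq$qtl == "QTL_1_3"], "neither")
  expect_match(pq$flag[pq$qtl == "QTL_1_4"], "absent from IVS")
  expect_equal(sum(s$counts), 4L)
})

test_that("tail selection keeps both distributions' extremes", {
  set.seed(62)
  n <- 200
  ids <- sprintf("g%03d", 1:n)
  blA <- data.frame(genotype = ids, blue = rnorm(n, 30, 8), se = 1)
  blB <- data.frame(genotype = ids, blue = rnorm(n, 50, 12), se = 1)
  sel <- selectTails(blA, blB, 56)
  expect_length(sel, 56)
  expect_identical(sel, sort(sel))
  # the selected set is enriched for variance in both traits
  expect_gt(var(blA$blue[blA$genotype %in% sel]), var(blA$blue))
  expect_gt(var(blB$blue[blB$genotype %in% sel]), var(blB$blue))
  # deterministic
  expect_identical(sel, selectTails(blA, blB, 56))
  # whole pool when nTarget equals the pool size
  expect_identical(selectTails(blA, blB, n), sort(ids))
  # a constant trait leaves selection to the other trait
  blC <- data.frame(genotype = ids, blue = 1, se = 1)
  sel2 <- suppressMessages(selectTails(blA, blC, 20))
  ranks <- rank(blA$blue)[blA$genotype %in% sel2]
  expect_true(all(ranks <= 10 | ranks > n - 10))
  expect_error(selectTails(blA, blB, n + 1), "exceeds")
})

test_that("reports mirror the published layout and stay self-consistent", {
  sc <- validationScenario()
  qtls <- readPublishedQtls(data.frame(
    snp = c("S1_1000000", "S1_9500000"),
    qtl = c("QTL_1_1", "QTL_1_2")))
  recs <- validateQtls(qtls, sc$scan, sc$gm, set = "ivs")
  fmt <- renderReport(recs)
  expect_equal(nrow(fmt), 2L)
  expect_equal(sum(fmt$validated), sum(recs$validated))
  expect_equal(fmt$distance_bp[fmt$qtl == "QTL_1_1"], "500,000")
  # undefined r2 prints "No"
  expect_true(all(fmt$ld_r2[is.na(recs$r2) & recs$criterion != "same_snp"]
                  %in% "No"))
  # empty record list -> header-only table
  fmt0 <- renderReport(recs[0, ])
  expect_equal(nrow(fmt0), 0L)
  # files written: machine-readable TSV plus formatted text
  f <- withr::local_tempfile(fileext = ".tsv")
  renderReport(recs, summary = NULL, path = f)
  expect_true(file.exists(f))
  expect_true(file.exists(paste0(f, ".txt")))
  back <- utils::read.table(f, header = TRUE, sep = "\t", na.strings = "NA")
  expect_equal(nrow(back), 2L)
})
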