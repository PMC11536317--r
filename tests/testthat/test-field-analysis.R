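simpleTrial <- function(gEff, e = 2, r = 2, vres = 1, seed = 1,
                        blockSize = 4) {
  set.seed(seed)
  n <- length(gEff)
  ids <- sprintf("g%02d", seq_len(n))
  out <- do.call(rbind, lapply(seq_len(e), function(ev) {
    do.call(rbind, lapply(seq_len(r), function(rp) {
      perm <- sample(ids)
      data.frame(genotype = perm, env = paste0("e", ev), rep = rp,
                 block = rep(seq_len(ceiling(n / blockSize)),
                             each = blockSize, length.out = n),
                 trait = "t", value = gEff[match(perm, ids)] +
                   rnorm(n, 0, sqrt(vres)))
    }))
  }))
  rownames(out) <- NULL
  out
}

test_that("BLUEs equal raw means on a single-environment complete design", {
  gEff <- c(g1 = 10, g2 = 14, g3 = 20, g4 = 7)
  ph <- data.frame(genotype = names(gEff), env = "e1", rep = 1, block = 1,
                   trait = "t", value = unname(gEff))
  bl <- estimateBlues(ph)
  expect_equal(setNames(bl$blue, bl$genotype), gEff, tolerance = 1e-8)

  # balanced two-env data with zero residual: BLUE is the plain mean
  ph2 <- rbind(
    data.frame(genotype = names(gEff), env = "e1", rep = 1, block = 1,
               trait = "t", value = unname(gEff) + 2),
    data.frame(genotype = names(gEff), env = "e2", rep = 1, block = 1,
               trait = "t", value = unname(gEff) - 2))
  bl2 <- estimateBlues(ph2)
  # genotype contrasts are exact; the absolute level carries the usual
  # mixed-model shrinkage of the two random environment effects
  expect_equal(diff(setNames(bl2$blue, bl2$genotype)[names(gEff)]),
               diff(gEff), tolerance = 1e-6)
  expect_equal(setNames(bl2$blue, bl2$genotype), gEff, tolerance = 0.05)
})

test_that("BLUEs recover true genotype ranking under the IVS noise level", {
  set.seed(21)
  gEff <- rnorm(64, 25, sqrt(107))
  names(gEff) <- sprintf("g%02d", 1:64)
  ph <- simpleTrial(gEff, e = 2, r = 2, vres = 75, seed = 22, blockSize = 8)
  bl <- estimateBlues(ph)
  expect_gt(cor(bl$blue, gEff[bl$genotype], method = "spearman"), 0.9)
})

test_that("a genotype missing one environment keeps a BLUE with larger SE", {
  gEff <- setNames(rnorm(12, 20, 3), sprintf("g%02d", 1:12))
  ph <- simpleTrial(gEff, e = 2, r = 2, vres = 2, seed = 3)
  drop <- ph$genotype == "g01" & ph$env == "e2"
  bl <- estimateBlues(ph[!drop, ])
  expect_false(is.na(bl$blue[bl$genotype == "g01"]))
  expect_gt(bl$se[bl$genotype == "g01"], median(bl$se[bl$genotype != "g01"]))
})

test_that("variance components floor at zero and flag significance", {
  # no genotypic signal at all
  ph <- simpleTrial(setNames(rep(0, 20), sprintf("g%02d", 1:20)),
                    e = 2, r = 2, vres = 4, seed = 8)
  vc <- estimateVarianceComponents(ph, computeSe = FALSE)
  expect_gte(vc@vg, 0)
  expect_lt(vc@vg, 1)
  expect_equal(phenotypicVariance(vc), vc@vg + vc@vgxe + vc@vres)

  # strong genotypic signal is flagged significant via the information SE
  gEff <- setNames(rnorm(40, 0, 10), sprintf("g%02d", 1:40))
  ph2 <- simpleTrial(gEff, e = 2, r = 2, vres = 4, seed = 9)
  vc2 <- estimateVarianceComponents(ph2)
  expect_true(isSignificant(vc2)[["vg"]])
  expect_false(is.na(vc2@se[["vg"]]))
  expect_error(estimateVarianceComponents(ph2[ph2$env == "e1", ]),
               ">= 2 environments")
})

test_that("family-mean heritability follows the closed form", {
  h_ivs <- heritabilityFamilyMean(list(vg = 107, vgxe = 38, vres = 75),
                                  e = 2, r = 2)
  expect_equal(round(h_ivs@h2, 2), 0.74)
  h_hvs <- heritabilityFamilyMean(list(vg = 21, vgxe = 17, vres = 119),
                                  e = 4, r = 2)
  expect_equal(round(h_hvs@h2, 2), 0.52)
  # no noise -> 1; no components -> undefined
  expect_equal(heritabilityFamilyMean(list(vg = 5, vgxe = 0, vres = 0),
                                      e = 1, r = 1)@h2, 1)
  expect_message(
    h0 <- heritabilityFamilyMean(list(vg = 0, vgxe = 0, vres = 0), 2, 2),
    "undefined")
  expect_true(is.na(h0@h2))
})

test_that("heritability is monotone in environments and replicates", {
  vc <- list(vg = 21, vgxe = 17, vres = 119)
  h <- function(e, r) heritabilityFamilyMean(vc, e, r)@h2
  es <- vapply(1:6, h, numeric(1), r = 2)
  rs <- vapply(1:6, function(r) h(2, r), numeric(1))
  expect_true(all(diff(es) > 0))
  expect_true(all(diff(rs) > 0))
  expect_true(all(c(es, rs) >= 0 & c(es, rs) <= 1))
})

test_that("delta-method SE responds to component uncertainty", {
  h <- heritabilityFamilyMean(list(vg = 107, vgxe = 38, vres = 75,
                                   se = c(vg = 30, vgxe = 17, vres = 12)),
                              e = 2, r = 2)
  expect_gt(h@se, 0)
  expect_lt(h@se, 0.5)
})
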