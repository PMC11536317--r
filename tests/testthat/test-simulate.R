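test_that("founder sets are homozygous, polymorphic, and need a balanced funnel", {
  set.seed(1)
  map <- geneticMap(nChrom = 2, lociPerChrom = 500)
  H <- simulateFounders(map, nFounders = 8)
  expect_equal(dim(H), c(8L, 1000L))
  expect_true(all(H %in% c(0L, 1L)))
  cs <- colSums(H)
  expect_true(all(cs >= 1 & cs <= 7))  # every locus polymorphic
  H2 <- simulateFounders(map, nFounders = 2)  # biparental special case
  expect_equal(nrow(H2), 2L)
  expect_true(all(colSums(H2) == 1))
  expect_error(simulateFounders(map, nFounders = 6), "power of two")
})

test_that("selfing drives RILs towards homozygosity", {
  x <- tinyMagic(nRils = 60, nChrom = 2, lociPerChrom = 50, g = 6)
  het <- hetFraction(x$rils)
  # selfing halves heterozygosity each generation from at most 1/2 at the
  # 8-way cross; allow 3 binomial SEs above the (1/2)^6 ceiling
  n <- 60 * 100
  expect_lt(het, 0.5^6 + 3 * sqrt(0.5^6 * (1 - 0.5^6) / n))
  # increasing g decreases heterozygosity (in expectation over seeds)
  set.seed(5)
  map <- geneticMap(nChrom = 2, lociPerChrom = 50)
  fnd <- simulateFounders(map)
  h2g <- hetFraction(suppressWarnings(
    simulateMagicRils(fnd, map, nRils = 60, g = 2)))
  h8g <- hetFraction(simulateMagicRils(fnd, map, nRils = 60, g = 8))
  expect_gt(h2g, h8g)
  expect_error(simulateMagicRils(fnd, map[0, ], nRils = 5), "empty")
  expect_error(simulateMagicRils(fnd, map, nRils = 5, g = 0), "g must be")
})

test_that("founder genome shares average 1/8 across RILs", {
  x <- tinyMagic(nRils = 300, nChrom = 3, lociPerChrom = 40, g = 4,
                 seed = 99)
  share <- S4Vectors::metadata(x$rils)$founderShare
  expect_equal(rowSums(share), rep(1, 300), ignore_attr = TRUE)
  avg <- colMeans(share)
  # Monte-Carlo error of a mean founder share over 300 RILs
  se <- apply(share, 2, sd) / sqrt(300)
  expect_true(all(abs(avg - 1 / 8) < 4 * se))
})

test_that("crossover counts follow the map length in Morgans", {
  set.seed(3)
  # one chromosome of exactly 1 Morgan (100 cM)
  map <- data.frame(chrom = 1, pos = seq(1, 1e6, length.out = 201))
  map$cm <- seq(0, 100, length.out = 201)
  map$id <- formatSnpId(map$chrom, round(map$pos))
  ms <- QTLValidate:::splitMap(map)
  h1 <- rep(1L, 201); h2 <- rep(2L, 201)
  xo <- replicate(2000, {
    g <- QTLValidate:::meiosis(h1, h2, ms)
    sum(diff(g) != 0)
  })
  # observable switches undercount crossovers only via double hits between
  # adjacent markers; with 201 markers on 1 M that loss is ~0.25%
  expect_equal(mean(xo), 1, tolerance = 0.08)
})

test_that("testcross dosages follow gamete arithmetic and reject bad testers", {
  m <- rbind(S1_100 = c(2, 0, 2), S1_200 = c(0, 2, 2))
  colnames(m) <- paste0("R", 1:3)
  rils <- GenotypeMatrix(m)
  tester <- c(S1_100 = 1, S1_200 = 0)
  hyb <- makeTestcross(rils, tester)
  D <- dosages(hyb)
  expect_equal(unname(D[, "S1_100"]), c(2, 1, 2))  # RIL 2 + alt tester -> 2
  expect_equal(unname(D[, "S1_200"]), c(0, 1, 1))  # RIL 2 + ref tester -> 1
  expect_equal(panelType(hyb), "hybrid")
  expect_error(makeTestcross(rils, c(S1_100 = 1, S1_200 = 2)),
               "heterozygous or invalid")
  expect_error(makeTestcross(rils, c(S1_100 = 1)), "lacks loci")
})

test_that("noise-free phenotypes are constant within environment", {
  x <- tinyMagic(nRils = 12, nChrom = 1, lociPerChrom = 10)
  set.seed(2)
  ph <- simulatePhenotypes(
    x$rils, traits = list(t1 = list(vg = 0, vgxe = 0, vres = 0, mean = 10)),
    e = 2, r = 2, envSd = 2, repSd = 0, blockSd = 0)
  spread <- tapply(ph$value, ph$env, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
})

test_that("simulated genetic correlation tracks rho and seeds reproduce", {
  x <- tinyMagic(nRils = 400, nChrom = 1, lociPerChrom = 10)
  set.seed(10)
  ph <- simulatePhenotypes(
    x$rils,
    traits = list(t1 = list(vg = 50, vgxe = 0, vres = 1, mean = 0),
                  t2 = list(vg = 20, vgxe = 0, vres = 1, mean = 0)),
    rho = 0.6, e = 1, r = 1)
  gv <- attr(ph, "geneticValues")
  r <- cor(gv[, 1], gv[, 2])
  expect_equal(r, 0.6, tolerance = 3 / sqrt(400))
  # bit-reproducible under a fixed seed
  set.seed(10)
  ph2 <- simulatePhenotypes(
    x$rils,
    traits = list(t1 = list(vg = 50, vgxe = 0, vres = 1, mean = 0),
                  t2 = list(vg = 20, vgxe = 0, vres = 1, mean = 0)),
    rho = 0.6, e = 1, r = 1)
  expect_identical(ph$value, ph2$value)
})

test_that("presets carry the published variance structure", {
  iv <- magicPreset("ivs")
  expect_equal(iv$tunnel_cm[c("vg", "vgxe", "vres")],
               list(vg = 107, vgxe = 38, vres = 75))
  expect_equal(iv$tunnel_cm$e, 2)
  expect_equal(iv$tunnel_cm$r, 2)
  hv <- magicPreset("hvs")
  expect_equal(hv$tunnel_cm[c("vg", "vgxe", "vres")],
               list(vg = 21, vgxe = 17, vres = 119))
  expect_equal(hv$tunnel_cm$e, 4)
  wm <- magicPreset("whole_magic")
  expect_equal(wm$tunnel_cm$range, c(0, 59))
  expect_equal(wm$yield$range, c(0, 114))
})
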