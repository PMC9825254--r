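test_that("coalescent samples match the Watterson expectation", {
  set.seed(88)
  n <- 25; thetaL <- 30
  S <- replicate(60, coalescentHaplotypes(n, thetaL)$nSites)
  expS <- thetaL * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - expS), 3 * sd(S) / sqrt(length(S)))
  # n = 2: mean pairwise diversity ~ theta
  S2 <- replicate(200, coalescentHaplotypes(2, 10)$nSites)
  expect_lt(abs(mean(S2) - 10), 3 * sd(S2) / sqrt(length(S2)))
})

test_that("neutral regions hit the configured SNP density and are reproducible", {
  cfg <- synthConfig(nHaplotypes = 50, regionBp = 2e5, chromClass = "autosome",
                     missingness = list(hapBeta = NULL, siteDropFraction = 0))
  set.seed(9); a <- generateNeutralRegion(cfg)
  set.seed(9); b <- generateNeutralRegion(cfg)
  expect_identical(haplotypes(a), haplotypes(b))
  expect_identical(positions(a), positions(b))
  set.seed(10)
  dens <- replicate(8, nSites(generateNeutralRegion(cfg)) / cfg$regionBp)
  a49 <- sum(1 / seq_len(49))
  # E[S/bp] = sPerBp by construction of theta = sPerBp / a_{n-1}
  expect_lt(abs(mean(dens) - 0.0345), 3 * sd(dens) / sqrt(8) + 0.001)
  # positions strictly increasing 1-based
  expect_true(all(diff(positions(a)) > 0) && positions(a)[1] >= 1)
})

test_that("embedded sweeps produce the expected window spectra", {
  set.seed(30)
  cfg <- synthConfig(nHaplotypes = 40, regionBp = 5e4,
                     missingness = list(hapBeta = NULL, siteDropFraction = 0))
  x <- generateNeutralRegion(cfg)
  # hard, PF = 1, zero noise: H12 = 1 at the sweep window
  xh <- embedSweep(x, sweepSpec("hard", 2.5e4, pf = 1, widthBp = 2e4,
                                noiseMutations = 0))
  inw <- which(positions(xh) >= 2e4 & positions(xh) <= 3e4)
  s <- hStats(haplotypeSpectrum(hm(haplotypes(xh)[, inw])))
  expect_equal(s$h12, 1)
  # soft k = 2 equal cores, PF = 1, zero noise: H12 = 1, H2/H1 = 0.5
  # (force the equal split by relabelling cores after embedding)
  xs <- embedSweep(x, sweepSpec("soft", 2.5e4, pf = 1, nOrigins = 2,
                                widthBp = 2e4, noiseMutations = 0))
  sp <- haplotypeSpectrum(hm(haplotypes(xs)[, inw]))
  expect_lte(length(sp$frequencies), 2)
  st <- hStats(sp)
  expect_equal(st$h12, 1)
  ideal <- hStats(c(0.5, 0.5))
  expect_equal(ideal$h2h1, 0.5)
})

test_that("hard sweeps at PF = 0.5 stand out of their neutral flanks", {
  set.seed(77)
  hits <- 0
  for (i in 1:12) {
    cfg <- synthConfig(nHaplotypes = 60, regionBp = 1.5e5,
                       missingness = list(hapBeta = NULL, siteDropFraction = 0))
    x <- generateNeutralRegion(cfg)
    x <- embedSweep(x, sweepSpec("hard", 7.5e4, pf = 0.5, widthBp = 2e4,
                                 noiseMutations = 0))
    sc <- scanWindows(slidingH12(x, windowSpec(61)))
    inSweep <- sc$center > 6.5e4 & sc$center < 8.5e4
    flank99 <- quantile(sc$h12[!inSweep], 0.99)
    if (max(sc$h12[inSweep]) > flank99) hits <- hits + 1
  }
  expect_gte(hits, 11)
})

test_that("missingness tracts respect per-haplotype fractions and filters", {
  set.seed(13)
  x <- hm(matrix(0L, 10, 400))
  # zero missingness is the identity
  y <- applyMissingness(x, list(hapBeta = NULL, siteDropFraction = 0))
  expect_identical(haplotypes(y), haplotypes(x))
  # fixed 20% per-haplotype missingness: every haplotype fails the 10% rule
  y <- applyMissingness(x, list(hapBeta = c(1e4, 4e4), siteDropFraction = 0))
  frac <- rowMeans(is.na(haplotypes(y)))
  expect_true(all(frac > 0.10))
  sp <- haplotypeSpectrum(y, maxMissingFraction = 0.10)
  expect_equal(sp$nForced, 10)
  expect_true(all(abs(sp$frequencies - 0.1) < 1e-12))
  # site dropout then call-rate filter drops heavy columns, keeps clean ones
  set.seed(14)
  z <- applyMissingness(hm(matrix(0L, 10, 20)),
                        list(hapBeta = NULL, siteDropFraction = 0.6))
  zf <- siteCallFilter(z, 0.5)
  callFrac <- colMeans(!is.na(haplotypes(z)))
  expect_equal(nSites(zf), sum(callFrac >= 0.5))
})

test_that("recombination maps assemble cold spots and total genetic length", {
  m <- makeRecombinationMap(5e4, 5e-7)
  expect_equal(nrow(mapIntervals(m)), 1)
  m2 <- makeRecombinationMap(5e4, 5e-7, list(c(1e4, 2e4, 1e-8)))
  iv <- mapIntervals(m2)
  expect_equal(nrow(iv), 3)
  expect_equal(iv$start, c(0, 1e4, 2e4))
  expect_equal(geneticLength(m2), 5e-7 * 4e4 + 1e-8 * 1e4)
  expect_error(makeRecombinationMap(5e4, 5e-7,
    list(c(1e4, 2e4, 1e-8), c(1.5e4, 3e4, 1e-8))), "overlap")
})

test_that("X-like neutral regions are less diverse than autosome-like", {
  set.seed(70)
  cfgA <- synthConfig(nHaplotypes = 40, regionBp = 1e5, chromClass = "autosome",
                      missingness = list(hapBeta = NULL, siteDropFraction = 0))
  cfgX <- synthConfig(nHaplotypes = 40, regionBp = 1e5, chromClass = "X",
                      missingness = list(hapBeta = NULL, siteDropFraction = 0))
  sA <- mean(replicate(5, nSites(generateNeutralRegion(cfgA))))
  sX <- mean(replicate(5, nSites(generateNeutralRegion(cfgX))))
  expect_gt(sA, sX)
})
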