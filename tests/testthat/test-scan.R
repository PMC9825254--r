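test_that("window calibration reproduces the published arithmetic", {
  expect_equal(expectedWindowLength(401, 0.0345), 11623)
  expect_equal(expectedWindowLength(401, 0.0227), 17665)
  expect_equal(expectedWindowLength(100, 0.01), 10000)
  expect_error(expectedWindowLength(100, 0), "> 0")
  expect_equal(calibrateXWindow(401, 0.0345, 0.0227), 264)
  expect_equal(calibrateXWindow(401, 0.02, 0.02), 401)
  expect_equal(calibrateXWindow(401, 0.02, 0.01), 201) # round half-up
})

test_that("sliding H12 matches the spectrum path and handles down-sampling", {
  # identical haplotypes: H12 = 1 everywhere
  x <- hm(matrix(1L, 100, 30))
  sc <- slidingH12(x, windowSpec(10))
  expect_true(all(scanWindows(sc)$h12 == 1))
  expect_equal(nrow(scanWindows(sc)), 21)
  # all singletons, n = 100: H12 = 0.02^2 + 98e-4 = 0.0102
  m <- diag(100L) # row i carries a private allele at site i: all unique
  x <- hm(m)
  sc <- slidingH12(x, windowSpec(100))
  expect_equal(scanWindows(sc)$h12, 0.02^2 + 98 * 1e-4)
  # downsample_to = n_snps is a no-op for any seed
  set.seed(10)
  m2 <- matrix(sample(0:1, 50 * 25, replace = TRUE), 50, 25)
  a <- slidingH12(hm(m2), windowSpec(12, 12), seed = 1)
  b <- slidingH12(hm(m2), windowSpec(12), seed = 2)
  expect_equal(scanWindows(a)$h12, scanWindows(b)$h12)
  # window coordinates come from SNP positions
  sc <- slidingH12(hm(m2, pos = seq(10, by = 7, length.out = 25)), windowSpec(12))
  w <- scanWindows(sc)
  expect_equal(w$start[1], 10)
  expect_equal(w$end[1], 10 + 11 * 7)
  expect_equal(w$center, (w$start + w$end) / 2)
})

test_that("scan windows agree with the R spectrum on matrices with missingness", {
  set.seed(91)
  m <- matrix(sample(c(0L, 1L, NA), 40 * 15, replace = TRUE,
                     prob = c(.45, .45, .1)), 40, 15)
  m[, colSums(!is.na(m)) == 0] <- 0L
  x <- hm(m)
  sc <- scanWindows(slidingH12(x, windowSpec(15)))
  sp <- haplotypeSpectrum(x, maxMissingFraction = 0.10)
  hs <- hStats(sp)
  expect_equal(sc$h12, hs$h12, tolerance = 1e-12)
  expect_equal(sc$h2h1, hs$h2h1, tolerance = 1e-12)
  expect_equal(sc$nForced, sp$nForced)
})

test_that("FDR threshold is the 10th order statistic with tie handling", {
  expect_equal(fdrThreshold(1:100, 10), 91)
  expect_equal(fdrThreshold(rep(0.3, 10)), 0.3)
  v <- c(rep(0.5, 5), rep(0.4, 6), 0.1)
  expect_equal(fdrThreshold(v), 0.4)
  expect_equal(fdrThreshold(sample(1:100)), fdrThreshold(1:100))
  expect_error(fdrThreshold(1:9), "at least 10")
  expect_warning(fdrThreshold(1:50, 10), "fewer than 10x")
  # monotone: adding a larger value weakly increases the threshold
  expect_gte(fdrThreshold(c(1:100, 200)), fdrThreshold(1:100))
})

test_that("peak calling groups runs, excludes within 500 kb, masks low rho", {
  mkScan <- function(centers, h12) {
    w <- data.frame(
      start = centers - 500, end = centers + 500, center = centers,
      h1 = h12, h2 = 0, h12 = h12, h2h1 = 0.1, nForced = 0L
    )
    new("ScanResult", windows = w, spec = list(nSnps = 10L, downsampleTo = 0L,
        maxMissingFraction = 0.1), chromLabel = "c", chromClass = "autosome")
  }
  # nothing above threshold
  expect_equal(nrow(callPeaks(mkScan(1:5 * 1000, rep(0.1, 5)), 0.2)), 0)
  # two runs 300 kb apart (separated by a sub-threshold window): only the
  # higher apex survives the exclusion rule
  centers <- c(seq(1e5, 1.02e5, 1e3), 2.5e5, seq(4e5, 4.02e5, 1e3))
  h12 <- c(0.35, 0.40, 0.35, 0.05, 0.28, 0.30, 0.29)
  pk <- callPeaks(mkScan(centers, h12), 0.2, exclusionBp = 5e5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$apexH12, 0.40)
  # 600 kb apart: both survive, ranked by apex H12
  centers2 <- c(seq(1e5, 1.02e5, 1e3), 2.5e5, seq(7e5, 7.02e5, 1e3))
  pk2 <- callPeaks(mkScan(centers2, h12), 0.2)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$rank, 1:2)
  expect_gt(abs(pk2$apexCenter[1] - pk2$apexCenter[2]), 5e5)
  # masking inside a cold spot removes the peak from the reported set
  map <- makeRecombinationMap(1e6, 5e-7, list(c(0.9e4, 1.2e5, 1e-8)))
  pk3 <- callPeaks(mkScan(centers2, h12), 0.2, map = map)
  expect_true(pk3$masked[pk3$apexCenter < 2e5])
  expect_false(pk3$masked[pk3$apexCenter > 2e5])
})

test_that("scan maxima localise embedded hard sweeps", {
  set.seed(17)
  hits <- 0
  reps <- 20
  for (i in seq_len(reps)) {
    cfg <- synthConfig(nHaplotypes = 60, regionBp = 1.2e5, chromClass = "autosome",
                       missingness = list(hapBeta = NULL, siteDropFraction = 0))
    x <- generateNeutralRegion(cfg)
    x <- embedSweep(x, sweepSpec("hard", positionBp = 6e4, widthBp = 2e4))
    sc <- scanWindows(slidingH12(x, windowSpec(61, 40)))
    apex <- sc$center[which.max(sc$h12)]
    if (abs(apex - 6e4) <= 1e4 + expectedWindowLength(61, 0.0345)) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.95 * reps) - 1)
})

test_that("401 -> 265 down-sampling does not alter neutral scan results", {
  # regression guard: the density-equalising down-sampling must change
  # window H12 by no more than the neutral between-window spread, and by a
  # negligible absolute amount
  set.seed(55)
  cfg <- synthConfig(nHaplotypes = 100, regionBp = 3e4,
                     missingness = list(hapBeta = NULL, siteDropFraction = 0))
  x <- generateNeutralRegion(cfg)
  full <- scanWindows(slidingH12(x, windowSpec(401)))
  down <- scanWindows(slidingH12(x, windowSpec(401, 265), seed = 9))
  meanDiff <- mean(abs(full$h12 - down$h12))
  expect_lte(meanDiff, sd(full$h12) + 1e-12)
  expect_lt(meanDiff, 0.005)
})

test_that("footprint length follows the plug-in formula", {
  expect_equal(footprintLength(0.0005, 1e6, 5e-7),
               0.0005 / (log(500) * 5e-9))
  expect_equal(footprintLength(0.001, 1e6, 1e-6),
               footprintLength(0.001, 1e6, 5e-7) / 2)
  # Ne*s = e gives L = s / rho_morgans
  s <- exp(1) / 1e4
  expect_equal(footprintLength(s, 1e4, 5e-7), s / 5e-9)
  expect_error(footprintLength(1e-7, 1e4, 5e-7), "exceed")
})
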