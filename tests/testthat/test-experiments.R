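test_that("origin counts map deterministically to hard/soft labels", {
  set.seed(8)
  p <- simParams(300, "autosome", thetaA = 0.4, s = 0.05, h = 0.5)
  for (i in 1:12) {
    o <- runRecurrentSweep(p, sampleK = 50)
    expect_identical(o$category, if (o$nOrigins >= 2) "soft" else "hard")
    expect_gte(o$nOrigins, 1)
    expect_false(is.na(o$fixationGeneration))
  }
})

test_that("theta_A -> 0 limit gives a single origin", {
  set.seed(15)
  # with a vanishing mutation rate the first (and only) establishing origin
  # sweeps alone; engineered by stopping mutation once one copy exists
  p <- simParams(200, "autosome", s = 0.05, h = 0.5)
  repeat {
    pop <- wfPopulation(200, "autosome")
    pop <- wfAddCopy(pop, "female")
    pop <- wfStep(pop, 1e5, sF = p$s, hF = p$h, mu = 0,
                  stop = "fixation_or_loss")
    if (pop$status == "fixed") break
  }
  smp <- wfSampleOrigins(pop, 50)
  expect_equal(smp$nOrigins, 1)
})

test_that("dominance-shift outcomes partition into the documented categories", {
  set.seed(22)
  p <- simParams(200, "autosome")
  sh <- shiftParams(sD = -0.05, hD = 0, sB = 0.05, hB = 1, thetaDel = 0.4)
  cats <- replicate(40, runDominanceShift(p, sh)$category)
  expect_true(all(cats %in% c("no_sgv", "lost", "hard", "soft", "not_fixed")))
  # theta_del = 0 gives no standing variation with probability 1
  sh0 <- shiftParams(sD = -0.05, hD = 0, sB = 0.05, hB = 1, thetaDel = 0)
  expect_identical(runDominanceShift(p, sh0)$category, "no_sgv")
})

test_that("recurrent-after-shift reports the standing-origin fraction", {
  set.seed(60)
  p <- simParams(200, "autosome")
  sh <- shiftParams(sD = -0.05, hD = 0.1, sB = 0.05, hB = 0.9,
                    thetaDel = 2, recurrentAfterShift = TRUE)
  for (i in 1:30) {
    o <- runDominanceShift(p, sh)
    if (o$category %in% c("hard", "soft")) {
      expect_true(o$originsFromSgvFraction >= 0 && o$originsFromSgvFraction <= 1)
      break
    }
  }
})

test_that("single-origin SGV sweeps report at least one carrier haplotype", {
  set.seed(41)
  p <- simParams(100, "autosome", thetaNeutralPerBp = 0.004, locusBp = 4000)
  sh <- shiftParams(sD = -0.01, hD = 0.5, sB = 0.1, hB = 1, pf = 0.02)
  o <- runSgvSingleOrigin(p, sh, sampleK = 40)
  expect_gte(o$nDistinctHaplotypes, 1)
  expect_identical(o$category, "fixed_unclassified")
})

test_that("sexual antagonism runs fix and classify, or report not_fixed at cap", {
  set.seed(33)
  p <- simParams(300, "X", thetaA = 0.4, s = 0.05, h = 0.5)
  o <- runSexualAntagonism(p, "female", k = 0.1, sampleK = 50)
  expect_true(o$category %in% c("hard", "soft", "not_fixed"))
  if (o$category != "not_fixed") expect_gte(o$nOrigins, 1)
  # seeded determinism
  set.seed(44); a <- runSexualAntagonism(p, "male", sampleK = 50)
  set.seed(44); b <- runSexualAntagonism(p, "male", sampleK = 50)
  expect_identical(a, b)
})

test_that("outcome summaries count categories and average origins", {
  outs <- list(
    SweepScanX:::newSweepOutcome("hard", nOrigins = 1L),
    SweepScanX:::newSweepOutcome("hard", nOrigins = 1L),
    SweepScanX:::newSweepOutcome("hard", nOrigins = 1L),
    SweepScanX:::newSweepOutcome("soft", nOrigins = 3L)
  )
  s <- summarizeOutcomes(outs)
  expect_equal(s$meanOrigins, 1.5)
  expect_equal(sum(s$categories$proportion), 1)
  expect_equal(s$categories$proportion[s$categories$category == "hard"], 0.75)
  expect_equal(categoryProportion(outs, "soft"), 0.25)
  # all hard
  s1 <- summarizeOutcomes(outs[1:3])
  expect_equal(s1$categories$proportion, 1)
})
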