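test_that("rescaling preserves theta and Ne*s and scales rates by Q", {
  p <- simParams(1e6, "autosome", thetaA = 0.4, s = 1e-4, h = 0.5,
                 thetaNeutralPerBp = 0.004, rhoCmPerBp = 5e-7)
  r <- rescaleParams(p, 50)
  expect_equal(r$Ne, 2e4)
  expect_equal(r$s, 5e-3)
  expect_equal(r$muA, p$muA * 50)
  expect_equal(r$rhoCmPerBp, 2.5e-5)
  expect_equal(r$thetaA, p$thetaA, tolerance = 1e-12)
  expect_equal(r$Ne * r$s, p$Ne * p$s, tolerance = 1e-12)
  expect_equal(4 * r$Ne * r$muNeutralLocus, 4 * p$Ne * p$muNeutralLocus,
               tolerance = 1e-12)
  # identity at Q = 1
  expect_equal(rescaleParams(p, 1)$Ne, p$Ne)
  # validity warning when rescaled selection becomes strong
  expect_warning(rescaleParams(simParams(1e6, s = 0.05), 50), "0.1")
})

test_that("copy-number conservation holds every generation on X and autosome", {
  set.seed(12)
  for (cls in c("autosome", "X")) {
    pop <- wfPopulation(200, cls)
    pop <- wfAddCopy(pop, "female")
    for (i in 1:25) {
      pop <- wfStep(pop, 1, sF = 0.02, hF = 0.5, mu = 1e-3)
      nf <- sum(pop$femDos)
      nm <- sum(pop$maleDos)
      expect_equal(nf + nm, 200)
      held <- sum(pop$femOriginCnt) + sum(pop$maleOriginCnt)
      # female-held derived copies consistent with female genotype counts
      expect_equal(sum(pop$femOriginCnt), pop$femDos[2] + 2 * pop$femDos[3])
      total <- if (cls == "X") 2 * nf + nm else 400
      expect_lte(held, total)
    }
  }
})

test_that("a fixed allele with no mutation stays fixed", {
  set.seed(3)
  pop <- wfPopulation(50, "autosome")
  pop$femDos <- c(0, 0, sum(pop$femDos))
  pop$maleDos <- c(0, 0, sum(pop$maleDos))
  pop$femOriginId <- 1L; pop$femOriginCnt <- 2 * 25
  pop$maleOriginId <- 1L; pop$maleOriginCnt <- 2 * 25
  pop <- wfStep(pop, 20, sF = 0.05, mu = 0)
  expect_equal(wfDerivedCount(pop), wfCopyCount(pop))
})

test_that("seeded runs are bit-reproducible", {
  run <- function() {
    set.seed(99)
    pop <- wfPopulation(100, "X")
    pop <- wfStep(pop, 50, sF = 0.01, mu = 5e-3)
    c(pop$femDos, pop$maleDos, pop$femOriginCnt, pop$maleOriginCnt)
  }
  expect_identical(run(), run())
  set.seed(77)
  a <- neutralForwardSample(simParams(50, locusBp = 2000), gens = 100, k = 10)
  set.seed(77)
  b <- neutralForwardSample(simParams(50, locusBp = 2000), gens = 100, k = 10)
  expect_identical(haplotypes(a), haplotypes(b))
  expect_identical(positions(a), positions(b))
})

test_that("single-mutant fixation probability matches the diffusion prediction", {
  # h = 0.5, Ne*s = 100 at N = 2000 -> per-copy u ~ (1-exp(-2hs)) ~ 0.0488
  set.seed(2024)
  N <- 2000; s <- 0.05; h <- 0.5
  reps <- 3000
  fixed <- 0
  for (i in seq_len(reps)) {
    pop <- wfPopulation(N, "autosome")
    pop <- wfAddCopy(pop, if (runif(1) < 0.5) "female" else "male")
    pop <- wfStep(pop, 50 * N, sF = s, hF = h, stop = "fixation_or_loss")
    fixed <- fixed + (pop$status == "fixed")
  }
  u <- fixed / reps
  expected <- 1 - exp(-2 * h * s)
  se <- sqrt(expected * (1 - expected) / reps)
  expect_lt(abs(u - expected), 3 * se + 0.002)
})

test_that("neutral forward samples match Watterson and Tajima expectations", {
  set.seed(314)
  Ne <- 100; L <- 10000; theta <- 0.004; n <- 20
  p <- simParams(Ne, "autosome", thetaNeutralPerBp = theta, locusBp = L)
  reps <- 30
  S <- numeric(reps); pi <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- neutralForwardSample(p, gens = 10 * Ne, k = n)
    S[i] <- nSites(x)
    h <- haplotypes(x)
    q <- colMeans(h)
    pi[i] <- sum(2 * q * (1 - q) * n / (n - 1)) / L
  }
  thetaL <- theta * L
  expS <- thetaL * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - expS), 3 * sd(S) / sqrt(reps))
  expect_lt(abs(mean(pi) - theta), 3 * sd(pi) / sqrt(reps))
})

test_that("origin sampling is a faithful census subsample", {
  set.seed(5)
  pop <- wfPopulation(100, "autosome")
  pop <- wfStep(pop, 80, sF = 0.05, hF = 0.5, mu = 2e-3, stop = "fixation")
  smp <- wfSampleOrigins(pop, wfCopyCount(pop))
  # census sample: exact counts
  combined <- tapply(c(pop$femOriginCnt, pop$maleOriginCnt),
                     c(pop$femOriginId, pop$maleOriginId), sum)
  expect_equal(sort(smp$count), sort(as.numeric(combined)))
  expect_error(wfSampleOrigins(pop, wfCopyCount(pop) + 1), "exceeds")
})
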