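test_that("haplotype spectrum groups identity classes and applies the 1/N rule", {
  # four identical complete haplotypes
  s <- haplotypeSpectrum(hm(matrix(1L, 4, 5)))
  expect_equal(s$frequencies, 1)
  # N = 10: one haplotype 20% missing -> its own 1/N class
  m <- matrix(0L, 10, 5)
  m[1, 1] <- NA  # 20% of 5 sites
  s <- haplotypeSpectrum(hm(m))
  expect_equal(sort(s$frequencies), c(0.1, 0.9))
  expect_equal(s$nForced, 1)
  # classes of size 3, 2, 1 by construction
  m <- rbind(
    matrix(rep(c(0L, 0L, 0L, 0L, 0L), 3), 3, byrow = TRUE),
    matrix(rep(c(1L, 0L, 0L, 0L, 0L), 2), 2, byrow = TRUE),
    c(1L, 1L, 0L, 0L, 0L)
  )
  s <- haplotypeSpectrum(hm(m))
  expect_equal(s$frequencies, c(3, 2, 1) / 6)
  # residual missing calls are a distinct state: differs-only-by-NA splits
  m <- rbind(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
             c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, NA))
  s <- haplotypeSpectrum(hm(m))
  expect_equal(s$frequencies, c(0.5, 0.5))
})

test_that("h-statistics match hand arithmetic and ordering invariants", {
  e <- hStats(c(1))
  expect_equal(e$h1, 1); expect_equal(e$h12, 1); expect_equal(e$h2h1, 0)
  e <- hStats(rep(0.01, 100))
  expect_equal(e$h1, 0.01)
  expect_equal(e$h12, 0.02^2 + 98 * 1e-4)
  expect_equal(e$h2h1, 0.99)
  e <- hStats(c(0.5, 0.3, 0.2))
  expect_equal(e$h1, 0.38)
  expect_equal(e$h12, 0.68)
  expect_equal(e$h2, 0.13)
  expect_equal(e$h2h1, 0.13 / 0.38)
})

test_that("h-statistics agree with the brute-force pair-matching oracle", {
  set.seed(101)
  for (i in 1:200) {
    counts <- randomSpectrumCounts()
    got <- hStats(sort(counts / sum(counts), decreasing = TRUE))
    want <- bruteForceHStats(counts)
    expect_equal(got$h1, want$h1, tolerance = 1e-12)
    expect_equal(got$h2, want$h2, tolerance = 1e-12)
    expect_equal(got$h12, want$h12, tolerance = 1e-12)
    expect_equal(got$h2h1, want$h2h1, tolerance = 1e-12)
    # ordering invariants
    expect_gte(got$h12, got$h1)
    expect_true(got$h2h1 >= 0 && got$h2h1 < 1)
  }
})

test_that("merging two haplotype classes strictly increases H1 and H12", {
  set.seed(7)
  for (i in 1:25) {
    counts <- randomSpectrumCounts(40)
    if (length(counts) < 3) next
    merged <- c(counts[1] + counts[2], counts[-(1:2)])
    a <- hStats(sort(counts / sum(counts), decreasing = TRUE))
    b <- hStats(sort(merged / sum(merged), decreasing = TRUE))
    expect_gt(b$h1, a$h1)
    expect_gte(b$h12, a$h12 - 1e-12)
  }
})

test_that("diversity matches closed-form cases and bootstrap brackets them", {
  # 2 haplotypes, 10 bp window, 1 difference
  m <- rbind(c(0L), c(1L))
  d <- diversityEstimate(hm(m, pos = 5), windowBp = 10, bootstrapReps = 0)
  expect_equal(d$sPerBp, 0.1)
  expect_equal(d$piPerBp, 0.1)
  # monomorphic
  d <- diversityEstimate(hm(matrix(0L, 4, 3), pos = c(2, 5, 9)),
                         windowBp = 10, bootstrapReps = 50)
  expect_equal(d$sPerBp, 0)
  expect_equal(d$piPerBp, 0)
  expect_equal(unname(d$piCI), c(0, 0))
  # 4 haplotypes, one site at frequency 0.5: pi = 2*0.25*(4/3)/10
  m <- matrix(0L, 4, 1); m[1:2, 1] <- 1L
  d <- diversityEstimate(hm(m, pos = 5), windowBp = 10, bootstrapReps = 0)
  expect_equal(d$piPerBp, 2 * 0.25 * 4 / 3 / 10)
  # missing-aware: site-specific callable count
  m <- rbind(c(0L), c(1L), c(NA))
  d <- diversityEstimate(hm(m, pos = 5), windowBp = 10, bootstrapReps = 0)
  expect_equal(d$piPerBp, 2 * 0.25 * 2 / 10)
})

test_that("pairwise R2 matches 2x2 table arithmetic and filters apply", {
  # perfect coupling
  m <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 0L), c(0L, 0L))
  r <- ldR2(hm(m, pos = c(10, 20)), mafRange = c(0.05, 0.95))
  expect_equal(r$r2, 1)
  expect_equal(r$dist, 10)
  # independence at equal frequencies
  m <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  r <- ldR2(hm(m, pos = c(10, 20)))
  expect_equal(r$r2, 0)
  # {11 x4, 10 x1, 01 x1, 00 x4}: R2 = (0.4 - 0.25)^2 / 0.25^2 = 0.36
  m <- rbind(
    matrix(rep(c(1L, 1L), 4), 4, byrow = TRUE), c(1L, 0L), c(0L, 1L),
    matrix(rep(c(0L, 0L), 4), 4, byrow = TRUE)
  )
  r <- ldR2(hm(m, pos = c(10, 20)))
  expect_equal(r$r2, 0.36)
  # MAF filter removes rare SNPs
  m <- cbind(c(1L, rep(0L, 24)), rep(c(0L, 1L), length.out = 25))
  expect_equal(nrow(ldR2(hm(m, pos = c(10, 20)))), 0)
  # min complete-haplotype rule
  m <- rbind(c(1L, 1L), c(0L, 0L), c(1L, NA), c(0L, NA))
  expect_equal(nrow(ldR2(hm(m, pos = c(10, 20)), minPairs = 4)), 0)
})

test_that("LD smoothing bins 20 bp to 300 bp then 150 bp, preserving means", {
  prof <- data.frame(dist = c(5, 15), r2 = c(0.2, 0.4))
  class(prof) <- c("LDProfile", "data.frame")
  sm <- smoothLd(prof)
  expect_equal(nrow(sm), 1)
  expect_equal(sm$r2, 0.3)
  expect_equal(sm$binEnd, 20)
  # a single pair at 310 falls in (300, 450]
  prof <- data.frame(dist = 310, r2 = 0.7)
  sm <- smoothLd(prof)
  expect_equal(sm$binEnd, 450)
  expect_equal(sm$r2, 0.7)
  # empty in, empty out
  expect_equal(nrow(smoothLd(ldR2(hm(matrix(0L, 4, 2), pos = c(1, 5))))), 0)
  # equally populated bins preserve the global mean
  d <- rep(c(10, 30, 50), each = 4)
  r2 <- runif(12)
  sm <- smoothLd(data.frame(dist = d, r2 = r2))
  expect_equal(mean(sm$r2), mean(r2))
})
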