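#' Synthetic region configuration
#'
#' Describes one DGRP-like phased haplotype panel: sample size, region
#' length, SNP density, chromosome class, optional embedded sweep and
#' missingness model.  Defaults emulate the study panel: n = 100 phased
#' haplotypes and a sample SNP density (segregating sites per bp) of 0.0345
#' for autosome-like regions or 0.0227 for X-like regions; the per-bp
#' population-scaled mutation rate handed to the coalescent generator is
#' the density divided by the harmonic number a_{n-1}.
#'
#' @param nHaplotypes sample size (default 100)
#' @param regionBp region length in bp
#' @param sPerBp target segregating-site density in the sample; default by
#'   chromosome class (0.0345 autosome, 0.0227 X)
#' @param chromClass "autosome" or "X"
#' @param chromLabel label for the arm
#' @param sweep optional list from \code{\link{sweepSpec}}
#' @param missingness list: \code{hapBeta} (shape1, shape2 of the Beta
#'   distribution of per-haplotype missing fractions; default Beta(1, 19),
#'   mean 5\%), \code{siteDropFraction} (columns made heavily missing)
#' @param chunkBp coalescent chunk size (independent non-recombining
#'   segments; default 400, matching the few-hundred-bp scale over which
#'   linkage disequilibrium decays in D. melanogaster panels)
#' @return list of class \code{SynthConfig}
#' @export
synthConfig <- function(nHaplotypes = 100, regionBp = 1e6,
                        sPerBp = NULL,
                        chromClass = c("autosome", "X"),
                        chromLabel = NULL,
                        sweep = NULL,
                        missingness = list(hapBeta = c(1, 19), siteDropFraction = 0),
                        chunkBp = 400) {
  chromClass <- match.arg(chromClass)
  if (is.null(sPerBp)) sPerBp <- if (chromClass == "X") 0.0227 else 0.0345
  if (is.null(chromLabel)) chromLabel <- if (chromClass == "X") "X" else "2R"
  structure(
    list(
      nHaplotypes = nHaplotypes, regionBp = regionBp, sPerBp = sPerBp,
      chromClass = chromClass, chromLabel = chromLabel, sweep = sweep,
      missingness = missingness, chunkBp = chunkBp
    ),
    class = "SynthConfig"
  )
}

#' Embedded-sweep specification
#'
#' @param type "hard" (one core haplotype) or "soft" (k core haplotypes
#'   with symmetric-Dirichlet-distributed frequencies)
#' @param positionBp sweep center
#' @param pf total frequency of the core haplotypes (partial frequency)
#' @param nOrigins number of cores for a soft sweep
#' @param widthBp footprint width over which cores are identical; defaults
#'   to a selection footprint of roughly 30 kb
#' @param noiseMutations expected number of private derived mutations per
#'   carrier haplotype within the footprint, emulating the mutation load a
#'   sweeping haplotype accumulates during and after the sweep (default 5,
#'   the during-sweep load of a desk-scale forward sweep; keeps embedded
#'   sweeps on the same signature scale as forward-simulated ones)
#' @param concentration symmetric Dirichlet concentration for the core
#'   frequencies (default 1, an uninformative split; larger values give
#'   near-equal cores, i.e. unambiguously soft spectra)
#' @export
sweepSpec <- function(type = c("hard", "soft"), positionBp, pf = 1,
                      nOrigins = if (match.arg(type) == "hard") 1 else 3,
                      widthBp = 30000, noiseMutations = 5,
                      concentration = 1) {
  type <- match.arg(type)
  if (type == "hard") nOrigins <- 1
  list(
    type = type, positionBp = positionBp, pf = pf, nOrigins = nOrigins,
    widthBp = widthBp, noiseMutations = noiseMutations,
    concentration = concentration
  )
}

#' Generate a neutral synthetic region
#'
#' Chunked-coalescent neutral sample at the configured density.  The per-bp
#' theta handed to the coalescent is \code{sPerBp / a_\{n-1\}} so that the
#' expected sample segregating-site density matches \code{sPerBp}.
#'
#' @param cfg a \code{\link{synthConfig}}
#' @return a \code{\link{HaplotypeMatrix}}
#' @export
generateNeutralRegion <- function(cfg) {
  n <- cfg$nHaplotypes
  a <- sum(1 / seq_len(n - 1))
  reg <- chunkedCoalescentRegion(n, cfg$regionBp, cfg$sPerBp / a, cfg$chunkBp)
  HaplotypeMatrix(reg$haplotypes, reg$positions,
    chromLabel = cfg$chromLabel, chromClass = cfg$chromClass
  )
}

#' Embed a parametric sweep into a neutral matrix
#'
#' Replaces the region of width \code{widthBp} around the sweep position
#' with sweep-structured haplotypes: a fraction \code{pf} of the sample
#' (the carriers) receive one of \code{nOrigins} core haplotypes (core
#' frequencies symmetric-Dirichlet for soft sweeps), then each carrier gains
#' a Poisson(\code{noiseMutations}) number of private derived alleles
#' within the footprint.  Non-carriers keep their neutral haplotypes.
#'
#' @param x neutral HaplotypeMatrix
#' @param sweep a \code{\link{sweepSpec}}
#' @return the modified HaplotypeMatrix
#' @export
embedSweep <- function(x, sweep) {
  h <- haplotypes(x)
  p <- positions(x)
  n <- nrow(h)
  nCar <- round(sweep$pf * n)
  if (nCar < 1) stop("pf * n < 1: no carrier haplotypes")
  inw <- which(p >= sweep$positionBp - sweep$widthBp / 2 &
    p <= sweep$positionBp + sweep$widthBp / 2)
  if (length(inw) == 0) return(x)
  carriers <- sample.int(n, nCar)
  k <- sweep$nOrigins
  # symmetric Dirichlet split of carriers among cores
  conc <- if (is.null(sweep$concentration)) 1 else sweep$concentration
  w <- rgamma(k, shape = conc)
  w <- w / sum(w)
  coreOf <- sample.int(k, nCar, replace = TRUE, prob = w)
  cores <- matrix(rbinom(k * length(inw), 1, 0.5), nrow = k)
  if (k > 1) {
    # cores must differ somewhere; force distinct leading entries
    for (i in 2:k) {
      if (all(cores[i, ] == cores[1, ])) cores[i, 1] <- 1L - cores[i, 1]
    }
  }
  for (ci in seq_len(nCar)) {
    h[carriers[ci], inw] <- cores[coreOf[ci], ]
    nz <- rpois(1, sweep$noiseMutations)
    if (nz > 0) {
      j <- sample(inw, min(nz, length(inw)))
      h[carriers[ci], j] <- 1L - h[carriers[ci], j]
    }
  }
  # drop columns that became monomorphic-with-no-calls impossible here;
  # but all-missing cannot occur, rebuild object directly
  new("HaplotypeMatrix",
    haplotypes = h, positions = p, chromLabel = x@chromLabel,
    chromClass = x@chromClass, sampleIds = x@sampleIds
  )
}

#' Apply residual-heterozygosity style missingness
#'
#' Per haplotype, contiguous missing tracts are placed at random positions
#' until a drawn per-haplotype missing fraction is reached (tracts emulate
#' masked runs of residual heterozygosity in inbred genomes); then an
#' optional fraction of sites is made heavily missing (dropout) so that the
#' site call-rate filter has something to remove.
#'
#' @param x a HaplotypeMatrix
#' @param cfg a \code{\link{synthConfig}} (its \code{missingness} entry is
#'   used), or a list with the same fields
#' @param tractSites expected tract length in sites (default 50)
#' @return the HaplotypeMatrix with NA entries added
#' @export
applyMissingness <- function(x, cfg, tractSites = 50) {
  ms <- if (inherits(cfg, "SynthConfig")) cfg$missingness else cfg
  h <- haplotypes(x)
  n <- nrow(h)
  m <- ncol(h)
  if (m == 0) return(x)
  shp <- ms$hapBeta
  fracs <- if (is.null(shp)) rep(0, n) else rbeta(n, shp[1], shp[2])
  for (i in seq_len(n)) {
    target <- round(fracs[i] * m)
    done <- 0
    guard <- 0
    while (done < target && guard < 1000) {
      len <- max(1, rpois(1, tractSites))
      s <- sample.int(m, 1)
      e <- min(m, s + len - 1)
      fresh <- sum(!is.na(h[i, s:e]))
      h[i, s:e] <- NA_integer_
      done <- done + fresh
      guard <- guard + 1
    }
  }
  sd <- ms$siteDropFraction
  if (!is.null(sd) && sd > 0) {
    drop <- sample.int(m, round(sd * m))
    for (j in drop) {
      # leave a few calls so the column stays valid pre-filter
      keep <- sample.int(n, max(1, round(0.3 * n)))
      h[-keep, j] <- NA_integer_
    }
  }
  # guarantee every column keeps >= 1 call
  bad <- which(colSums(!is.na(h)) == 0)
  for (j in bad) h[sample.int(n, 1), j] <- 0L
  new("HaplotypeMatrix",
    haplotypes = h, positions = positions(x), chromLabel = x@chromLabel,
    chromClass = x@chromClass, sampleIds = x@sampleIds
  )
}

#' Build a piecewise-constant recombination map with cold spots
#'
#' @param regionBp region length
#' @param baselineRate background rate in cM/bp (default 5e-7)
#' @param lowRhoIntervals data.frame or list of c(start, end, rate) triples
#'   for cold spots (half-open, within the region, non-overlapping)
#' @param chrom chromosome label
#' @return a \code{\link{RecombinationMap}}
#' @export
makeRecombinationMap <- function(regionBp, baselineRate = 5e-7,
                                 lowRhoIntervals = NULL, chrom = "chr") {
  if (is.null(lowRhoIntervals) || length(lowRhoIntervals) == 0) {
    return(RecombinationMap(chrom, 0, regionBp, baselineRate))
  }
  if (is.data.frame(lowRhoIntervals)) {
    cold <- lowRhoIntervals
  } else {
    cold <- as.data.frame(do.call(rbind, lowRhoIntervals))
    names(cold) <- c("start", "end", "rate")
  }
  cold <- cold[order(cold$start), ]
  if (any(cold$start < 0 | cold$end > regionBp)) {
    stop("cold-spot interval outside the region")
  }
  if (nrow(cold) > 1 && any(cold$start[-1] < cold$end[-nrow(cold)])) {
    stop("overlapping cold-spot intervals")
  }
  ch <- character(0); st <- numeric(0); en <- numeric(0); ra <- numeric(0)
  cur <- 0
  for (i in seq_len(nrow(cold))) {
    if (cold$start[i] > cur) {
      ch <- c(ch, chrom); st <- c(st, cur); en <- c(en, cold$start[i]); ra <- c(ra, baselineRate)
    }
    ch <- c(ch, chrom); st <- c(st, cold$start[i]); en <- c(en, cold$end[i]); ra <- c(ra, cold$rate[i])
    cur <- cold$end[i]
  }
  if (cur < regionBp) {
    ch <- c(ch, chrom); st <- c(st, cur); en <- c(en, regionBp); ra <- c(ra, baselineRate)
  }
  RecombinationMap(ch, st, en, ra)
}
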