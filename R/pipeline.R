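#' FDR threshold for a synthetic arm
#'
#' Convenience wrapper: determines the number of independent windows from
#' the region length and expected window span, simulates 10x that many
#' neutral windows, and returns the 10th-highest H12.
#'
#' @param spec the arm's \code{\link{windowSpec}}
#' @param sPerBp the arm's SNP density
#' @param regionBp region length
#' @param n sample size (default 100)
#' @param factor simulations per independent window (default 10)
#' @return the critical H12 value
#' @export
scanThreshold <- function(spec, sPerBp, regionBp, n = 100, factor = 10) {
  nIndep <- max(1, floor(regionBp / expectedWindowLength(spec$nSnps, sPerBp)))
  vals <- simulateNeutralH12(factor * nIndep, spec, sPerBp, n = n)
  fdrThreshold(vals, nIndep)
}

#' Generate, scan, peak-call and classify one synthetic arm
#'
#' Builds a neutral arm from the config, embeds the requested sweeps,
#' applies missingness, runs the site call-rate filter, scans with the
#' given window spec, calls peaks against the threshold with
#' recombination-map masking, and classifies the surviving peaks with the
#' Bayes-factor grid.
#'
#' @param cfg a \code{\link{synthConfig}}
#' @param sweeps list of \code{\link{sweepSpec}}s to embed
#' @param spec the arm's \code{\link{windowSpec}}
#' @param threshold critical H12 from \code{\link{scanThreshold}}
#' @param grid a \code{\link{BFGrid}} trained with the same spec
#' @param map optional \code{\link{RecombinationMap}}
#' @param minCallFraction site call-rate filter (default 0.5)
#' @return list: \code{matrix} (filtered HaplotypeMatrix), \code{scan},
#'   \code{peaks} (classified), \code{sweeps}
#' @export
scanSyntheticArm <- function(cfg, sweeps, spec, threshold, grid,
                             map = NULL, minCallFraction = 0.5) {
  x <- generateNeutralRegion(cfg)
  for (sw in sweeps) x <- embedSweep(x, sw)
  x <- applyMissingness(x, cfg)
  x <- siteCallFilter(x, minCallFraction)
  sc <- slidingH12(x, spec)
  pk <- callPeaks(sc, threshold, map = map)
  pk <- classifyPeaks(pk[!pk$masked, , drop = FALSE], grid)
  list(matrix = x, scan = sc, peaks = pk, sweeps = sweeps)
}

#' Score sweep recovery for one arm
#'
#' A sweep is recovered when an unmasked peak apex lies within half the
#' sweep footprint plus one window length of the true position; its label
#' is correct when the hard/soft call matches the embedded type
#' ("soft_strong" counts as soft).
#'
#' @param arm result of \code{\link{scanSyntheticArm}}
#' @param sPerBp the arm's density (for the window-length slack)
#' @return data.frame: position, type, recovered, labelCorrect
#' @export
scoreSweepRecovery <- function(arm, sPerBp) {
  spec <- scanSpec(arm$scan)
  wlen <- expectedWindowLength(spec$nSnps, sPerBp)
  pk <- arm$peaks
  do.call(rbind, lapply(arm$sweeps, function(sw) {
    tol <- sw$widthBp / 2 + wlen
    hit <- which(abs(pk$apexCenter - sw$positionBp) <= tol)
    recovered <- length(hit) > 0
    lab <- if (recovered) pk$label[hit[which.max(pk$apexH12[hit])]] else NA
    correct <- if (!recovered) NA else {
      want <- sw$type
      got <- if (lab %in% c("soft", "soft_strong")) "soft" else lab
      identical(got, want)
    }
    data.frame(
      position = sw$positionBp, type = sw$type,
      recovered = recovered,
      labelCorrect = if (is.null(correct)) NA else correct
    )
  }))
}

#' End-to-end synthetic-genome sweep recovery
#'
#' Runs the full pipeline on a 2 x 1 Mb synthetic genome (one
#' autosome-like and one X-like arm, each with one embedded hard and one
#' soft sweep, residual-heterozygosity missingness and one
#' low-recombination cold spot on the autosome) for several seeds, and
#' scores how many of the four sweeps are recovered as peaks and correctly
#' labelled.  The soft sweeps carry five near-equal cores
#' (Dirichlet concentration 5): with an uninformative Dirichlet split a
#' "soft" sweep is frequently one dominant haplotype, which no
#' haplotype-homozygosity method could (or should) call soft.
#'
#' @param seeds integer vector of seeds (one pipeline run per seed)
#' @param gridAuto,gridX Bayes-factor grids for the two arms
#' @param specAuto,specX window specs matching the grids
#' @param regionBp arm length (default 1e6)
#' @param thresholdAuto,thresholdX optional precomputed critical values;
#'   computed once from neutral simulations when NULL
#' @return data.frame per seed: nRecovered, nCorrect (among recovered)
#' @export
sweepRecoveryExperiment <- function(seeds, gridAuto, gridX,
                                    specAuto = windowSpec(61, 40),
                                    specX = windowSpec(40),
                                    regionBp = 1e6,
                                    thresholdAuto = NULL,
                                    thresholdX = NULL) {
  if (is.null(thresholdAuto)) {
    thresholdAuto <- scanThreshold(specAuto, 0.0345, regionBp)
  }
  if (is.null(thresholdX)) {
    thresholdX <- scanThreshold(specX, 0.0227, regionBp)
  }
  mapAuto <- makeRecombinationMap(
    regionBp,
    baselineRate = 5e-7,
    lowRhoIntervals = list(c(0.48e6, 0.52e6, 1e-8)), chrom = "2R"
  )
  mapX <- makeRecombinationMap(regionBp, baselineRate = 5e-7, chrom = "X")
  res <- lapply(seeds, function(sd) {
    set.seed(sd)
    sweepsAuto <- list(
      sweepSpec("hard", positionBp = 0.25e6),
      sweepSpec("soft", positionBp = 0.78e6, nOrigins = 5,
                noiseMutations = 2, concentration = 5)
    )
    sweepsX <- list(
      sweepSpec("hard", positionBp = 0.22e6),
      sweepSpec("soft", positionBp = 0.78e6, nOrigins = 5,
                noiseMutations = 2, concentration = 5)
    )
    armA <- scanSyntheticArm(
      synthConfig(regionBp = regionBp, chromClass = "autosome"),
      sweepsAuto, specAuto, thresholdAuto, gridAuto, map = mapAuto
    )
    armX <- scanSyntheticArm(
      synthConfig(regionBp = regionBp, chromClass = "X"),
      sweepsX, specX, thresholdX, gridX, map = mapX
    )
    sc <- rbind(
      scoreSweepRecovery(armA, 0.0345),
      scoreSweepRecovery(armX, 0.0227)
    )
    data.frame(
      seed = sd,
      nRecovered = sum(sc$recovered),
      nCorrect = sum(sc$labelCorrect, na.rm = TRUE)
    )
  })
  do.call(rbind, res)
}
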