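#' Window specification for the H12 scan
#'
#' @param nSnps SNPs per analysis window
#' @param downsampleTo optional number of SNPs to draw (without
#'   replacement, fresh per window) from each window before computing the
#'   spectrum; used to equalise autosome and X windows
#' @param stepSnps window step in SNPs (the scan iterates one SNP at a
#'   time; kept for interface completeness)
#' @export
windowSpec <- function(nSnps, downsampleTo = NULL, stepSnps = 1) {
  if (!is.null(downsampleTo) && downsampleTo > nSnps) {
    stop("downsampleTo must be <= nSnps")
  }
  structure(
    list(nSnps = as.integer(nSnps),
         downsampleTo = if (is.null(downsampleTo)) 0L else as.integer(downsampleTo),
         stepSnps = as.integer(stepSnps)),
    class = "WindowSpec"
  )
}

#' Expected genomic length of an n-SNP window
#'
#' At a segregating-site density of \code{sPerBp}, an \code{nSnps}-SNP
#' window spans about nSnps / sPerBp base pairs (rounded half-up).  At the
#' DGRP autosomal median density 0.0345/bp a 401-SNP window is 11,623 bp;
#' at the X median 0.0227/bp it would be 17,665 bp.
#'
#' @param nSnps SNPs per window
#' @param sPerBp segregating sites per bp
#' @return window length in bp
#' @export
expectedWindowLength <- function(nSnps, sPerBp) {
  if (sPerBp <= 0) stop("sPerBp must be > 0")
  roundHalfUp(nSnps / sPerBp)
}

#' Calibrate the X-chromosome window size from SNP densities
#'
#' Returns the number of X SNPs spanning the same expected base-pair length
#' as an \code{nSnpsAuto}-SNP autosomal window:
#' round(sPerBpX * nSnpsAuto / sPerBpAuto), rounded half-up.
#'
#' @param nSnpsAuto autosomal window size in SNPs
#' @param sPerBpAuto autosomal SNP density
#' @param sPerBpX X-chromosome SNP density
#' @return X window size in SNPs
#' @export
calibrateXWindow <- function(nSnpsAuto, sPerBpAuto, sPerBpX) {
  if (sPerBpAuto <= 0 || sPerBpX <= 0) stop("densities must be > 0")
  roundHalfUp(sPerBpX * nSnpsAuto / sPerBpAuto)
}

#' Sliding-window H12 scan
#'
#' Slides an \code{nSnps}-SNP window one SNP at a time across the matrix.
#' Within each window, haplotypes with more than \code{maxMissingFraction}
#' missing calls are assigned a frequency of 1/N; the rest are grouped by
#' exact identity (missing calls a distinct state) and H12 and H2/H1 are
#' recorded.  When the spec requests down-sampling, a fresh draw of
#' \code{downsampleTo} of the window's SNPs is taken per window from the
#' current RNG stream (use \code{set.seed} or \code{seed} for
#' reproducibility).
#'
#' @param x a \code{\link{HaplotypeMatrix}}
#' @param spec a \code{\link{windowSpec}}
#' @param maxMissingFraction per-window missing threshold (default 0.10)
#' @param seed optional integer seed applied before the scan
#' @return a \code{\link{ScanResult}}
#' @export
slidingH12 <- function(x, spec, maxMissingFraction = 0.10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- haplotypes(x)
  if (ncol(h) < spec$nSnps) stop("window spec larger than the data")
  w <- cpp_sliding_h12(h, positions(x), spec$nSnps, spec$downsampleTo,
                       maxMissingFraction)
  new("ScanResult",
    windows = w,
    spec = list(
      nSnps = spec$nSnps, downsampleTo = spec$downsampleTo,
      maxMissingFraction = maxMissingFraction
    ),
    chromLabel = x@chromLabel, chromClass = x@chromClass
  )
}

#' Neutral H12 null distribution
#'
#' Simulates neutral windows under the same generative model as the
#' synthetic data -- a chunked coalescent at the arm's SNP density -- takes
#' the central \code{nSnps} segregating sites, applies the scan spec's
#' down-sampling, and returns one H12 value per simulation.  Simulations
#' with fewer than \code{nSnps} sites are redrawn (at the configured
#' density this is rare).
#'
#' @param nSims number of neutral windows
#' @param spec a \code{\link{windowSpec}}
#' @param sPerBp sample SNP density of the arm being scanned
#' @param n sample size (default 100)
#' @param chunkBp coalescent chunk size, as in \code{\link{synthConfig}}
#' @param maxMissingFraction as in the scan (default 0.10)
#' @return numeric vector of H12 values
#' @export
simulateNeutralH12 <- function(nSims, spec, sPerBp, n = 100, chunkBp = 400,
                               maxMissingFraction = 0.10) {
  a <- sum(1 / seq_len(n - 1))
  regionBp <- ceiling(1.4 * spec$nSnps / sPerBp)
  vapply(seq_len(nSims), function(i) {
    for (try in 1:20) {
      reg <- chunkedCoalescentRegion(n, regionBp, sPerBp / a, chunkBp)
      m <- reg$haplotypes
      if (ncol(m) >= spec$nSnps) break
    }
    if (ncol(m) < spec$nSnps) stop("neutral simulation too sparse for the window spec")
    lo <- (ncol(m) - spec$nSnps) %/% 2
    cols <- (lo + 1):(lo + spec$nSnps)
    w <- cpp_sliding_h12(m[, cols, drop = FALSE], as.numeric(seq_len(spec$nSnps)),
                         spec$nSnps, spec$downsampleTo, maxMissingFraction)
    w$h12[1]
  }, 0.0)
}

#' Simulation-based FDR threshold for the H12 scan
#'
#' The critical value H12_o is the 10th highest H12 among neutral
#' simulations, run 10 times the number of independent analysis windows.
#'
#' @param neutralH12 vector of neutral-simulation H12 values
#' @param nIndependentWindows number of independent windows in the data
#'   (used only to warn when too few simulations are supplied)
#' @return the 10th largest value
#' @export
fdrThreshold <- function(neutralH12, nIndependentWindows = NULL) {
  if (length(neutralH12) < 10) stop("need at least 10 neutral H12 values")
  if (!is.null(nIndependentWindows) &&
      length(neutralH12) < 10 * nIndependentWindows) {
    warning("fewer than 10x the independent window count; using what is given")
  }
  sort(neutralH12, decreasing = TRUE)[10]
}

#' Call peaks from a scan
#'
#' Windows with H12 above the threshold are grouped by contiguity into
#' candidate peaks whose apex carries the peak's H12.  Candidates are
#' visited highest apex first (ties: smaller coordinate) and any candidate
#' whose apex lies within \code{exclusionBp} of an already accepted apex is
#' dropped.  Accepted peaks overlapping recombination-map intervals with
#' rate below \code{minRho} are flagged \code{masked}; the reported peak
#' set is the unmasked rows.
#'
#' @param scan a \code{\link{ScanResult}}
#' @param threshold critical H12 value (peaks require H12 > threshold)
#' @param map optional \code{\link{RecombinationMap}} for masking
#' @param minRho masking rate threshold in cM/bp (default 5e-7)
#' @param exclusionBp minimum distance between peak apexes (default 5e5)
#' @return data.frame: rank, apexCenter, apexH12, apexH2H1, startBp, endBp,
#'   nWindows, masked
#' @export
callPeaks <- function(scan, threshold, map = NULL, minRho = 5e-7,
                      exclusionBp = 5e5) {
  w <- scanWindows(scan)
  empty <- data.frame(
    rank = integer(0), apexCenter = numeric(0), apexH12 = numeric(0),
    apexH2H1 = numeric(0), startBp = numeric(0), endBp = numeric(0),
    nWindows = integer(0), masked = logical(0)
  )
  above <- which(w$h12 > threshold)
  if (length(above) == 0) return(empty)
  runs <- split(above, cumsum(c(1, diff(above) != 1)))
  cand <- do.call(rbind, lapply(runs, function(idx) {
    apex <- idx[order(-w$h12[idx], w$center[idx])][1]
    data.frame(
      apexCenter = w$center[apex], apexH12 = w$h12[apex],
      apexH2H1 = w$h2h1[apex], startBp = min(w$start[idx]),
      endBp = max(w$end[idx]), nWindows = length(idx)
    )
  }))
  cand <- cand[order(-cand$apexH12, cand$apexCenter), , drop = FALSE]
  acceptedCenters <- numeric(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (all(abs(cand$apexCenter[i] - acceptedCenters) > exclusionBp)) {
      keep[i] <- TRUE
      acceptedCenters <- c(acceptedCenters, cand$apexCenter[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out$masked <- FALSE
  if (!is.null(map)) {
    iv <- mapIntervals(map)
    low <- iv[iv$rate < minRho, , drop = FALSE]
    if (nrow(low)) {
      for (i in seq_len(nrow(out))) {
        ov <- any(out$startBp[i] < low$end & out$endBp[i] > low$start)
        out$masked[i] <- ov
      }
    }
  }
  out$rank <- NA_integer_
  if (any(!out$masked)) out$rank[!out$masked] <- seq_len(sum(!out$masked))
  rownames(out) <- NULL
  out[, c("rank", "apexCenter", "apexH12", "apexH2H1", "startBp", "endBp",
          "nWindows", "masked")]
}

#' Selective-sweep footprint length
#'
#' The heuristic footprint of a sweep with selection coefficient s in a
#' population of size Ne and recombination rate rho:
#' L = s / (ln(Ne*s) * rho_Morgans), with rho converted from cM/bp to
#' Morgans/bp.  A heuristic guide only.
#'
#' @param s selection coefficient (> 1/Ne)
#' @param Ne effective population size
#' @param rhoCmPerBp recombination rate in cM/bp
#' @return footprint length in bp
#' @export
footprintLength <- function(s, Ne, rhoCmPerBp) {
  if (Ne * s <= 1) stop("Ne*s must exceed 1")
  if (rhoCmPerBp <= 0) stop("rho must be > 0")
  s / (log(Ne * s) * rhoCmPerBp / 100)
}
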