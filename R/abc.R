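#' Priors for ABC sweep training
#'
#' Nuisance parameters are drawn per replicate: selection coefficient
#' s ~ U[sRange], dominance h ~ U[hRange], partial frequency at which
#' selection ceases PF ~ U[pfRange], and a post-sweep drift (decay) time
#' T_E ~ U[0, tDecayMax4Ne] * 4Ne generations.  The decay bound maps the
#' U[0, 1e-3] x 4Ne start-of-selection prior onto the desk-scale window so
#' that the expected post-sweep erosion (theta_window x T in units of 4Ne)
#' is preserved.  Hard sweeps are trained at thetaHard = 0.01 and soft
#' sweeps at thetaSoft = 10.
#'
#' @param sRange,hRange,pfRange uniform prior supports
#' @param tDecayMax4Ne upper bound of the decay time in units of 4Ne
#' @param thetaHard,thetaSoft adaptive theta for the two training models
#' @export
abcPriors <- function(sRange = c(0, 1), hRange = c(0, 1),
                      pfRange = c(0, 1), tDecayMax4Ne = 0.007,
                      thetaHard = 0.01, thetaSoft = 10) {
  structure(
    list(
      sRange = sRange, hRange = hRange, pfRange = pfRange,
      tDecayMax4Ne = tDecayMax4Ne, thetaHard = thetaHard,
      thetaSoft = thetaSoft
    ),
    class = "ABCPriors"
  )
}

# (H12, H2/H1) for the window of `spec` SNPs centred on the selected site
trainingWindowStats <- function(res, locusBp, spec, maxMissingFraction) {
  mat <- res$haplotypes
  pos <- res$positions
  m <- length(pos)
  if (m < 2) {
    # sweep erased all variation: one haplotype class
    return(c(h12 = 1, h2h1 = 0))
  }
  o <- order(pos)
  mat <- mat[, o, drop = FALSE]
  pos <- pos[o]
  nw <- min(spec$nSnps, m)
  ctr <- which.min(abs(pos - locusBp / 2))
  lo <- max(1, min(ctr - floor(nw / 2), m - nw + 1))
  cols <- lo:(lo + nw - 1)
  down <- if (spec$downsampleTo > 0) min(spec$downsampleTo, nw) else 0L
  w <- cpp_sliding_h12(mat[, cols, drop = FALSE], as.numeric(seq_len(nw)),
                       nw, down, maxMissingFraction)
  c(h12 = w$h12[1], h2h1 = w$h2h1[1])
}

#' Simulate ABC training points
#'
#' Each replicate seeds a population with coalescent standing variation,
#' draws the nuisance parameters from the priors, runs the forward engine
#' with recurrent adaptive mutation (theta 0.01 for the hard model, 10 for
#' the soft model) until the adaptive allele first reaches PF, lets the
#' population drift for the decay time, samples n haplotypes, and records
#' (H12, H2/H1) on the window of \code{spec} SNPs centred on the selected
#' site -- the same window specification as the data scan.
#'
#' @param nSims replicates
#' @param sweepClass "hard" or "soft"
#' @param spec the scan's \code{\link{windowSpec}}
#' @param chromClass "autosome" (diploid transmission) or "X" (hemizygous
#'   forward model)
#' @param priors an \code{\link{abcPriors}}
#' @param Ne training population size (desk scale; default 200 diploids)
#' @param locusBp simulated locus (default 10000)
#' @param sPerBp target sample SNP density; default 0.0345 (autosome) or
#'   0.0227 (X)
#' @param rMorgansLocus recombination (Morgans per gamete per locus,
#'   default 0.02)
#' @param sampleK sampled haplotypes (default 100)
#' @param maxMissingFraction as in the scan (default 0.10)
#' @param maxGens sweep-phase cap (default 10 * Ne)
#' @param muNSweepFactor neutral-mutation scaling during the selective
#'   phase (default 0.05): desk-scale per-generation rates are inflated by
#'   the rescaling factor while sweep durations shrink only
#'   logarithmically, so the per-sweep mutation load mu_window x duration
#'   would be orders of magnitude above its full-scale value; the reduced
#'   rate restores that invariant while the decay phase keeps the full
#'   rate
#' @return matrix with columns h12, h2h1 and one row per replicate;
#'   attributes record the drawn parameters
#' @export
simulateTraining <- function(nSims, sweepClass = c("hard", "soft"), spec,
                             chromClass = c("autosome", "X"),
                             priors = abcPriors(), Ne = 200,
                             locusBp = 10000, sPerBp = NULL,
                             rMorgansLocus = 0.02, sampleK = 100,
                             maxMissingFraction = 0.10,
                             maxGens = 10 * Ne, muNSweepFactor = 0.05) {
  sweepClass <- match.arg(sweepClass)
  chromClass <- match.arg(chromClass)
  if (nSims < 100) warning("fewer than 100 training simulations: unstable grid")
  if (is.null(sPerBp)) sPerBp <- if (chromClass == "X") 0.0227 else 0.0345
  aH <- sum(1 / seq_len(sampleK - 1))
  thetaNeutralPerBp <- sPerBp / aH
  theta <- if (sweepClass == "hard") priors$thetaHard else priors$thetaSoft
  isX <- chromClass == "X"
  nf <- Ne %/% 2
  copies <- if (isX) 2 * nf + (Ne - nf) else 2 * Ne
  muA <- theta / (2 * copies)
  muN <- thetaNeutralPerBp * locusBp / (2 * copies)
  # standing-variation panels are pooled (the sweep phase, sampling and all
  # nuisance draws stay replicate-specific); the hard model conditions on
  # the sweep starting at generation 0 (introduceFirst)
  nPool <- max(20L, min(200L, ceiling(nSims / 10)))
  pool <- lapply(seq_len(nPool), function(i) {
    standingVariation(Ne, chromClass, locusBp, thetaNeutralPerBp)
  })
  introduceFirst <- theta < 1
  out <- matrix(NA_real_, nSims, 2, dimnames = list(NULL, c("h12", "h2h1")))
  pars <- matrix(NA_real_, nSims, 4,
                 dimnames = list(NULL, c("s", "h", "pf", "tDecay")))
  for (i in seq_len(nSims)) {
    s <- runif(1, priors$sRange[1], priors$sRange[2])
    h <- runif(1, priors$hRange[1], priors$hRange[2])
    pf <- runif(1, priors$pfRange[1], priors$pfRange[2])
    tDec <- runif(1, 0, priors$tDecayMax4Ne * 4 * Ne)
    sv <- pool[[1 + (i - 1) %% nPool]]
    res <- cs_training_run(
      as.integer(Ne), isX, locusBp, muN, rMorgansLocus, muA, s, h, pf,
      tDec, maxGens, as.integer(sampleK), introduceFirst, 100L,
      muNSweepFactor, sv$haplotypes, sv$positions
    )
    out[i, ] <- trainingWindowStats(res, locusBp, spec, maxMissingFraction)
    pars[i, ] <- c(s, h, pf, tDec)
  }
  attr(out, "params") <- pars
  attr(out, "sweepClass") <- sweepClass
  attr(out, "chromClass") <- chromClass
  out
}

#' Build a Bayes-factor grid from training points
#'
#' For every node of a regular grid on the (H12, H2/H1) unit square, count
#' hard and soft training points within a strict Euclidean radius and form
#' BF = nSoft / nHard (\code{Inf} when only soft neighbours exist,
#' \code{NaN} when neither class is represented).  Classification of
#' observed points recomputes counts at the observed coordinates
#' (\code{\link{bayesFactorAt}}); the grid is for visualisation and
#' caching.
#'
#' @param hardPoints,softPoints two-column (h12, h2h1) matrices
#' @param radius strict Euclidean neighbourhood radius (default 0.1)
#' @param gridStep node spacing (default 0.025)
#' @param meta optional metadata list stored with the grid
#' @return a \code{\link{BFGrid}}
#' @export
buildBFGrid <- function(hardPoints, softPoints, radius = 0.1,
                        gridStep = 0.025, meta = list()) {
  hp <- as.matrix(hardPoints)[, 1:2, drop = FALSE]
  sp <- as.matrix(softPoints)[, 1:2, drop = FALSE]
  if (nrow(hp) == 0 || nrow(sp) == 0) stop("both training sets must be non-empty")
  g <- expand.grid(h12 = seq(0, 1, by = gridStep),
                   h2h1 = seq(0, 1, by = gridStep))
  cnt <- function(pts, x, y) {
    sum((pts[, 1] - x)^2 + (pts[, 2] - y)^2 < radius^2)
  }
  g$nHard <- vapply(seq_len(nrow(g)), function(i) cnt(hp, g$h12[i], g$h2h1[i]), 0)
  g$nSoft <- vapply(seq_len(nrow(g)), function(i) cnt(sp, g$h12[i], g$h2h1[i]), 0)
  g$bf <- ifelse(g$nHard > 0, g$nSoft / g$nHard,
                 ifelse(g$nSoft > 0, Inf, NaN))
  meta$nHard <- nrow(hp)
  meta$nSoft <- nrow(sp)
  new("BFGrid", hardPoints = hp, softPoints = sp, grid = g,
      radius = radius, meta = meta)
}

#' Bayes factor and label at an observed point
#'
#' Counts the grid's training points within its strict radius of the
#' observed (H12, H2/H1) coordinates.  BF = nSoft / nHard; BF <= 1 is
#' labelled "hard", BF > 1 "soft", BF >= 30 "soft_strong"; a point with no
#' training neighbours is "unclassified".
#'
#' @param grid a \code{\link{BFGrid}}
#' @param h12,h2h1 observed coordinates
#' @return list: nHard, nSoft, bf, label
#' @export
bayesFactorAt <- function(grid, h12, h2h1) {
  r2 <- grid@radius^2
  hp <- grid@hardPoints
  sp <- grid@softPoints
  nH <- sum((hp[, 1] - h12)^2 + (hp[, 2] - h2h1)^2 < r2)
  nS <- sum((sp[, 1] - h12)^2 + (sp[, 2] - h2h1)^2 < r2)
  if (nH == 0 && nS == 0) {
    return(list(nHard = 0, nSoft = 0, bf = NaN, label = "unclassified"))
  }
  bf <- if (nH > 0) nS / nH else Inf
  label <- if (bf >= 30) "soft_strong" else if (bf > 1) "soft" else "hard"
  list(nHard = nH, nSoft = nS, bf = bf, label = label)
}

#' Classify called peaks as hard or soft sweeps
#'
#' @param peaks a peak data.frame from \code{\link{callPeaks}} (columns
#'   apexH12, apexH2H1)
#' @param grid a \code{\link{BFGrid}} built with the same window spec as
#'   the scan that produced the peaks
#' @return the peaks data.frame with bf and label columns appended
#' @export
classifyPeaks <- function(peaks, grid) {
  if (nrow(peaks) == 0) {
    peaks$bf <- numeric(0)
    peaks$label <- character(0)
    return(peaks)
  }
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    bayesFactorAt(grid, peaks$apexH12[i], peaks$apexH2H1[i])
  })
  peaks$bf <- vapply(res, function(r) r$bf, 0.0)
  peaks$label <- vapply(res, function(r) r$label, "")
  nU <- sum(peaks$label == "unclassified")
  if (nU > 0) warning(nU, " peak(s) had no training neighbours")
  peaks
}
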