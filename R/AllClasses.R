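#' @useDynLib SweepScanX, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rbinom rpois runif rexp rmultinom rhyper quantile
#'   wilcox.test prop.test sd setNames rbeta qnorm rgamma median
#' @importFrom utils head tail
NULL

#' Phased haplotype matrix
#'
#' The universal unit of analysis: \code{n} phased haplotypes typed at
#' \code{m} biallelic sites on one chromosome arm.  Entries are 0 (ancestral
#' or reference allele), 1 (derived or alternate), or \code{NA} for missing
#' calls (residual heterozygosity in inbred panels is represented only as
#' missing data; no heterozygous state exists).  Positions are strictly
#' increasing 1-based base-pair coordinates.  \code{chromClass} records
#' whether the arm is autosomal or X-linked, which changes how downstream
#' simulation and window calibration treat it.
#'
#' @slot haplotypes integer matrix, n x m, entries in \{0, 1, NA\}
#' @slot positions numeric vector of length m, strictly increasing, >= 1
#' @slot chromLabel single character, e.g. "2R" or "X"
#' @slot chromClass "autosome" or "X"
#' @slot sampleIds character vector of length n
#' @export
setClass("HaplotypeMatrix",
  representation(
    haplotypes = "matrix",
    positions = "numeric",
    chromLabel = "character",
    chromClass = "character",
    sampleIds = "character"
  )
)

setValidity("HaplotypeMatrix", function(object) {
  h <- object@haplotypes
  p <- object@positions
  msg <- character()
  if (!is.numeric(h) && !is.integer(h)) msg <- c(msg, "haplotypes must be a numeric matrix")
  if (ncol(h) != length(p)) msg <- c(msg, "positions must match the number of sites")
  if (length(p) > 0 && (any(p < 1) || any(diff(p) <= 0)))
    msg <- c(msg, "positions must be strictly increasing and >= 1")
  ok <- h %in% c(0L, 1L, NA)
  if (!all(ok)) msg <- c(msg, "haplotype entries must be 0, 1 or NA")
  if (ncol(h) > 0 && any(colSums(!is.na(h)) == 0))
    msg <- c(msg, "every site must have at least one non-missing call")
  if (!object@chromClass %in% c("autosome", "X"))
    msg <- c(msg, "chromClass must be 'autosome' or 'X'")
  if (nrow(h) != length(object@sampleIds))
    msg <- c(msg, "sampleIds must match the number of haplotypes")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeMatrix
#'
#' @param haplotypes integer matrix (n haplotypes x m sites), entries 0/1/NA
#' @param positions strictly increasing 1-based bp coordinates
#' @param chromLabel chromosome arm label
#' @param chromClass "autosome" or "X"
#' @param sampleIds haplotype identifiers; defaults to \code{hap1..hapn}
#' @return a \code{HaplotypeMatrix}
#' @export
HaplotypeMatrix <- function(haplotypes, positions,
                            chromLabel = "chr",
                            chromClass = c("autosome", "X"),
                            sampleIds = NULL) {
  chromClass <- match.arg(chromClass)
  haplotypes <- matrix(as.integer(haplotypes), nrow = nrow(haplotypes))
  if (is.null(sampleIds)) sampleIds <- paste0("hap", seq_len(nrow(haplotypes)))
  new("HaplotypeMatrix",
    haplotypes = haplotypes, positions = as.numeric(positions),
    chromLabel = chromLabel, chromClass = chromClass,
    sampleIds = as.character(sampleIds)
  )
}

#' @rdname HaplotypeMatrix-class
#' @param x a HaplotypeMatrix
#' @export
haplotypes <- function(x) x@haplotypes

#' @rdname HaplotypeMatrix-class
#' @export
positions <- function(x) x@positions

#' @rdname HaplotypeMatrix-class
#' @export
chromClass <- function(x) x@chromClass

#' @rdname HaplotypeMatrix-class
#' @export
sampleIds <- function(x) x@sampleIds

#' @rdname HaplotypeMatrix-class
#' @export
nHaplotypes <- function(x) nrow(x@haplotypes)

#' @rdname HaplotypeMatrix-class
#' @export
nSites <- function(x) ncol(x@haplotypes)

setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf(
    "HaplotypeMatrix: %d haplotypes x %d sites (%s, %s)\n",
    nrow(object@haplotypes), ncol(object@haplotypes),
    object@chromLabel, object@chromClass
  ))
  if (ncol(object@haplotypes) > 0) {
    cat(sprintf(
      "  positions %s..%s bp, %.2f%% missing\n",
      format(object@positions[1], big.mark = ","),
      format(object@positions[length(object@positions)], big.mark = ","),
      100 * mean(is.na(object@haplotypes))
    ))
  }
})

#' Recombination map
#'
#' Piecewise-constant recombination rates over half-open genomic intervals
#' \code{[start, end)} in cM/bp.  Used for masking scan peaks in
#' low-recombination regions and for parameterising simulations.
#'
#' @slot intervals data.frame with columns chrom, start, end, rate
#' @export
setClass("RecombinationMap", representation(intervals = "data.frame"))

setValidity("RecombinationMap", function(object) {
  iv <- object@intervals
  msg <- character()
  need <- c("chrom", "start", "end", "rate")
  if (!all(need %in% names(iv))) {
    return("intervals must have columns chrom, start, end, rate")
  }
  if (any(iv$rate < 0)) msg <- c(msg, "rates must be >= 0")
  if (any(iv$end <= iv$start)) msg <- c(msg, "intervals must have end > start")
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      msg <- c(msg, sprintf("overlapping intervals on %s", ch))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RecombinationMap
#'
#' @param chrom,start,end,rate interval columns; coordinates are half-open
#'   \code{[start, end)} in bp, rate in cM/bp
#' @return a \code{RecombinationMap}
#' @export
RecombinationMap <- function(chrom, start, end, rate) {
  new("RecombinationMap", intervals = data.frame(
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), rate = as.numeric(rate),
    stringsAsFactors = FALSE
  ))
}

#' @rdname RecombinationMap-class
#' @param x a RecombinationMap
#' @export
mapIntervals <- function(x) x@intervals

#' Total genetic length of a map in cM
#' @param x a RecombinationMap
#' @export
geneticLength <- function(x) {
  iv <- x@intervals
  sum(iv$rate * (iv$end - iv$start))
}

setMethod("show", "RecombinationMap", function(object) {
  iv <- object@intervals
  cat(sprintf(
    "RecombinationMap: %d intervals on %d chromosome(s), %.4g cM total\n",
    nrow(iv), length(unique(iv$chrom)), geneticLength(object)
  ))
})

#' H12 scan result
#'
#' Per-window (H12, H2/H1) series from \code{\link{slidingH12}}, ordered by
#' window center, together with the window specification that produced it.
#'
#' @slot windows data.frame: start, end, center, h1, h2, h12, h2h1, nForced
#' @slot spec list: nSnps, downsampleTo, maxMissingFraction
#' @slot chromLabel,chromClass provenance of the scanned arm
#' @export
setClass("ScanResult",
  representation(
    windows = "data.frame", spec = "list",
    chromLabel = "character", chromClass = "character"
  )
)

#' @rdname ScanResult-class
#' @param x a ScanResult
#' @export
scanWindows <- function(x) x@windows

#' @rdname ScanResult-class
#' @export
scanSpec <- function(x) x@spec

setMethod("show", "ScanResult", function(object) {
  w <- object@windows
  cat(sprintf(
    "ScanResult (%s, %s): %d windows of %d SNPs%s; max H12 = %.4f\n",
    object@chromLabel, object@chromClass, nrow(w), object@spec$nSnps,
    if (!is.null(object@spec$downsampleTo) && object@spec$downsampleTo > 0) {
      sprintf(" (downsampled to %d)", object@spec$downsampleTo)
    } else "",
    if (nrow(w)) max(w$h12) else NA_real_
  ))
})

#' Bayes-factor grid for hard/soft classification
#'
#' Training (H12, H2/H1) points for the hard- and soft-sweep models plus a
#' visualisation grid of Bayes factors BF = #soft / #hard within a strict
#' Euclidean radius.  Classification of observed points recomputes counts at
#' the observed coordinates, not at the nearest node.
#'
#' @slot hardPoints,softPoints two-column matrices of (H12, H2/H1)
#' @slot grid data.frame: h12, h2h1, nHard, nSoft, bf
#' @slot radius strict Euclidean neighbourhood radius
#' @slot meta list of training metadata (n per class, model, seed)
#' @export
setClass("BFGrid",
  representation(
    hardPoints = "matrix", softPoints = "matrix",
    grid = "data.frame", radius = "numeric", meta = "list"
  )
)

setMethod("show", "BFGrid", function(object) {
  cat(sprintf(
    "BFGrid: %d hard + %d soft training points, radius %.3g, %d grid nodes\n",
    nrow(object@hardPoints), nrow(object@softPoints),
    object@radius, nrow(object@grid)
  ))
})
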