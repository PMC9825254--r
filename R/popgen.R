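#' Haplotype frequency spectrum
#'
#' Groups haplotypes into identity classes over all sites.  A haplotype with
#' more than \code{maxMissingFraction} missing calls is not grouped: it is
#' assigned its own class of frequency 1/N, where N is the sample size.
#' Residual missing calls in the remaining haplotypes are treated as a
#' distinct allele state, so two haplotypes that differ only by a missing
#' call fall in different classes (conservative against inflating
#' homozygosity).
#'
#' @param x a \code{\link{HaplotypeMatrix}} (n >= 2)
#' @param maxMissingFraction threshold above which a haplotype is forced to
#'   a singleton class of frequency 1/N (default 0.10)
#' @return list of class \code{HaplotypeSpectrum}: \code{frequencies}
#'   (descending, summing to 1), \code{n}, \code{singletonCount}, and
#'   \code{nForced} (haplotypes assigned 1/N)
#' @export
haplotypeSpectrum <- function(x, maxMissingFraction = 0.10) {
  h <- haplotypes(x)
  n <- nrow(h)
  if (n < 2) stop("need at least two haplotypes")
  if (ncol(h) == 0) stop("empty matrix")
  missFrac <- rowMeans(is.na(h))
  forced <- missFrac > maxMissingFraction
  freqs <- numeric(0)
  if (any(!forced)) {
    keys <- apply(h[!forced, , drop = FALSE], 1, function(r) {
      r[is.na(r)] <- 2L
      paste(r, collapse = "")
    })
    freqs <- as.numeric(table(keys)) / n
  }
  freqs <- c(freqs, rep(1 / n, sum(forced)))
  freqs <- sort(freqs, decreasing = TRUE)
  structure(
    list(
      frequencies = freqs, n = n,
      singletonCount = sum(abs(freqs - 1 / n) < 1e-12),
      nForced = sum(forced)
    ),
    class = "HaplotypeSpectrum"
  )
}

#' Haplotype homozygosity statistics H1, H2, H12, H2/H1
#'
#' H1 = sum(p_i^2) is the probability that two haplotypes drawn with
#' replacement match.  H12 pools the two most frequent classes:
#' H12 = (p1 + p2)^2 + sum_\{i>=3\} p_i^2, boosting power for soft sweeps in
#' which two haplotypes are at high frequency.  H2 = H1 - p1^2 excludes the
#' most frequent class, and the ratio H2/H1 is low for hard sweeps (one
#' dominant haplotype) and rises monotonically with the softness of the
#' sweep.
#'
#' @param spectrum a \code{HaplotypeSpectrum} from
#'   \code{\link{haplotypeSpectrum}}, or a numeric vector of class
#'   frequencies summing to 1
#' @return list with \code{h1}, \code{h2}, \code{h12}, \code{h2h1}
#' @export
hStats <- function(spectrum) {
  p <- if (is.list(spectrum)) spectrum$frequencies else spectrum
  if (length(p) == 0) stop("empty spectrum")
  if (abs(sum(p) - 1) > 1e-9) stop("frequencies must sum to 1")
  p <- sort(p, decreasing = TRUE)
  h1 <- sum(p^2)
  p1 <- p[1]
  p2 <- if (length(p) > 1) p[2] else 0
  h12 <- (p1 + p2)^2 + if (length(p) > 2) sum(p[-(1:2)]^2) else 0
  h2 <- h1 - p1^2
  list(h1 = h1, h2 = h2, h12 = h12, h2h1 = if (h1 > 0) h2 / h1 else 0)
}

#' Segregating sites and nucleotide diversity per base pair
#'
#' S/bp counts sites polymorphic among non-missing calls; pi/bp uses the
#' unbiased per-site estimator 2*p*q*nc/(nc-1) with the site-specific
#' callable count nc, summed over sites and divided by window length.
#' Both are computed in non-overlapping windows and the window estimates are
#' bootstrapped (resampling windows with replacement) for percentile
#' confidence intervals.
#'
#' @param x a HaplotypeMatrix spanning at least one window
#' @param windowBp window length in bp (default 10000)
#' @param bootstrapReps bootstrap replicates (default 1000)
#' @param level confidence level (default 0.95)
#' @return list: \code{sPerBp}, \code{piPerBp}, \code{sCI}, \code{piCI},
#'   \code{nWindows}, and the per-window table \code{windows}
#' @export
diversityEstimate <- function(x, windowBp = 10000, bootstrapReps = 1000,
                              level = 0.95) {
  h <- haplotypes(x)
  p <- positions(x)
  lo <- windowBp * (floor((min(p) - 1) / windowBp))
  hi <- windowBp * ceiling(max(p) / windowBp)
  starts <- seq(lo, hi - windowBp, by = windowBp)
  perSite <- function(col) {
    v <- col[!is.na(col)]
    nc <- length(v)
    if (nc < 2) return(c(seg = 0, pi = 0))
    q <- mean(v)
    seg <- as.numeric(q > 0 && q < 1)
    c(seg = seg, pi = 2 * q * (1 - q) * nc / (nc - 1))
  }
  tab <- do.call(rbind, lapply(starts, function(s) {
    inw <- which(p > s & p <= s + windowBp)
    if (length(inw) == 0) {
      return(data.frame(start = s + 1, end = s + windowBp, s_per_bp = 0, pi_per_bp = 0))
    }
    st <- vapply(inw, function(j) perSite(h[, j]), c(seg = 0, pi = 0))
    data.frame(
      start = s + 1, end = s + windowBp,
      s_per_bp = sum(st["seg", ]) / windowBp,
      pi_per_bp = sum(st["pi", ]) / windowBp
    )
  }))
  nW <- nrow(tab)
  sHat <- mean(tab$s_per_bp)
  piHat <- mean(tab$pi_per_bp)
  a <- (1 - level) / 2
  if (nW > 1 && bootstrapReps > 0) {
    bs <- vapply(seq_len(bootstrapReps), function(i) {
      j <- sample.int(nW, nW, replace = TRUE)
      c(mean(tab$s_per_bp[j]), mean(tab$pi_per_bp[j]))
    }, c(0, 0))
    sCI <- quantile(bs[1, ], c(a, 1 - a), names = FALSE)
    piCI <- quantile(bs[2, ], c(a, 1 - a), names = FALSE)
  } else {
    sCI <- c(sHat, sHat)
    piCI <- c(piHat, piHat)
  }
  list(
    sPerBp = sHat, piPerBp = piHat, sCI = sCI, piCI = piCI,
    nWindows = nW, windows = tab
  )
}

#' Pairwise linkage disequilibrium (R-squared)
#'
#' For each pair of SNPs separated by at most \code{windowBp},
#' R^2 = D^2 / (p1 q1 p2 q2) computed over haplotypes non-missing at both
#' sites.  SNPs outside the allele-frequency range and pairs with fewer than
#' \code{minPairs} complete haplotypes are skipped.
#'
#' @param x a HaplotypeMatrix
#' @param windowBp maximum pair separation in bp (default 10000)
#' @param mafRange admissible allele-frequency range (default c(0.05, 0.95))
#' @param minPairs minimum complete haplotypes per pair (default 4)
#' @return data.frame of class \code{LDProfile}: dist, r2
#' @export
ldR2 <- function(x, windowBp = 10000, mafRange = c(0.05, 0.95),
                 minPairs = 4) {
  h <- haplotypes(x)
  p <- positions(x)
  f <- colMeans(h, na.rm = TRUE)
  use <- which(f >= mafRange[1] & f <= mafRange[2])
  out <- list()
  for (ii in seq_along(use)) {
    i <- use[ii]
    for (j in use[use > i]) {
      d <- p[j] - p[i]
      if (d > windowBp) break
      ok <- !is.na(h[, i]) & !is.na(h[, j])
      if (sum(ok) < minPairs) next
      a <- h[ok, i]
      b <- h[ok, j]
      p1 <- mean(a)
      p2 <- mean(b)
      if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) next
      D <- mean(a * b) - p1 * p2
      out[[length(out) + 1]] <- c(d, D^2 / (p1 * (1 - p1) * p2 * (1 - p2)))
    }
  }
  res <- if (length(out)) {
    m <- do.call(rbind, out)
    data.frame(dist = m[, 1], r2 = m[, 2])
  } else {
    data.frame(dist = numeric(0), r2 = numeric(0))
  }
  class(res) <- c("LDProfile", "data.frame")
  res
}

#' Distance-binned smoothing of an LD profile
#'
#' Mean R^2 per distance bin: bins of 20 bp out to 300 bp
#' ([1,20], (20,40], ..., (280,300]), then bins of 150 bp
#' ((300,450], (450,600], ...).  Empty bins are omitted.
#'
#' @param profile an \code{LDProfile} from \code{\link{ldR2}}
#' @return data.frame: binStart, binEnd, dist (bin midpoint), r2 (mean), n
#' @export
smoothLd <- function(profile) {
  if (nrow(profile) == 0) {
    return(data.frame(
      binStart = numeric(0), binEnd = numeric(0),
      dist = numeric(0), r2 = numeric(0), n = integer(0)
    ))
  }
  d <- profile$dist
  bin <- ifelse(d <= 300, ceiling(d / 20) * 20, 300 + ceiling((d - 300) / 150) * 150)
  agg <- tapply(profile$r2, bin, mean)
  cnt <- tapply(profile$r2, bin, length)
  be <- as.numeric(names(agg))
  bs <- ifelse(be <= 300, be - 20, pmax(300, be - 150))
  o <- order(be)
  data.frame(
    binStart = bs[o] + ifelse(bs[o] == 0, 1, 0), binEnd = be[o],
    dist = (bs[o] + be[o]) / 2, r2 = as.numeric(agg)[o],
    n = as.integer(cnt)[o]
  )
}
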