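#' Neutral coalescent haplotype sample
#'
#' Standard-coalescent sample of n haplotypes for one non-recombining locus.
#' Coalescence times are exponential with rate k(k-1)/2 (units of 2N
#' generations); mutations are Poisson with rate theta/2 per lineage per
#' unit time under the infinite-sites model, so E[S] = theta * a_{n-1} with
#' a_{n-1} = sum(1/1..1/(n-1)).  If \code{fixedS} is given, exactly that
#' many mutations are placed on the genealogy proportional to branch
#' lengths instead.
#'
#' @param n sample size (haplotypes)
#' @param thetaLocus population-scaled mutation rate 4*Ne*mu for the locus
#' @param fixedS place exactly this many segregating sites (overrides
#'   \code{thetaLocus} for the mutation count)
#' @return list: \code{haplotypes} (n x S 0/1 matrix, columns unordered by
#'   position until placed), \code{nSites}
#' @export
coalescentHaplotypes <- function(n, thetaLocus, fixedS = NULL) {
  stopifnot(n >= 2)
  # lineages own index sets; record (duration, members) per coalescent level
  members <- as.list(seq_len(n))
  lev <- vector("list", n - 1)
  for (k in n:2) {
    t_k <- rexp(1, rate = k * (k - 1) / 2)
    lev[[n - k + 1]] <- list(t = t_k, members = members)
    pick <- sample.int(k, 2)
    merged <- c(members[[pick[1]]], members[[pick[2]]])
    members <- c(members[-pick], list(merged))
  }
  # branch length carried by each lineage at each level is t_k
  durs <- vapply(lev, function(l) l$t, 0.0)
  ks <- n:2
  if (is.null(fixedS)) {
    S <- rpois(1, thetaLocus / 2 * sum(ks * durs))
  } else {
    S <- fixedS
  }
  hap <- matrix(0L, nrow = n, ncol = S)
  if (S > 0) {
    # choose a level proportional to total length, then a uniform lineage
    w <- ks * durs
    levIdx <- sample.int(length(w), S, replace = TRUE, prob = w)
    for (s in seq_len(S)) {
      l <- lev[[levIdx[s]]]
      lin <- sample.int(length(l$members), 1)
      hap[l$members[[lin]], s] <- 1L
    }
    # drop mutations on the root lineage if all sampled carry them
    poly <- colSums(hap) < n & colSums(hap) > 0
    hap <- hap[, poly, drop = FALSE]
  }
  list(haplotypes = hap, nSites = ncol(hap))
}

# neutral region built from independent non-recombining chunks; returns
# haplotypes + integer positions (collision-free, strictly increasing)
chunkedCoalescentRegion <- function(n, regionBp, thetaPerBp, chunkBp = 400) {
  starts <- seq(0, regionBp - 1, by = chunkBp)
  mats <- list()
  pos <- numeric(0)
  for (s in starts) {
    len <- min(chunkBp, regionBp - s)
    cs <- coalescentHaplotypes(n, thetaPerBp * len)
    if (cs$nSites == 0) next
    pp <- sort(runif(cs$nSites, s, s + len))
    mats[[length(mats) + 1]] <- cs$haplotypes
    pos <- c(pos, pp)
  }
  if (length(mats) == 0) {
    return(list(haplotypes = matrix(0L, n, 0), positions = numeric(0)))
  }
  hap <- do.call(cbind, mats)
  ip <- makePositionsInteger(pos, regionBp)
  list(haplotypes = hap, positions = ip)
}

# map real-valued positions to strictly increasing integer bp in [1, L]
makePositionsInteger <- function(pos, L) {
  ip <- pmax(1, pmin(L, ceiling(pos)))
  for (i in seq_along(ip)[-1]) {
    if (ip[i] <= ip[i - 1]) ip[i] <- ip[i - 1] + 1
  }
  if (length(ip) && ip[length(ip)] > L) {
    # extremely dense tail: push back down keeping strict order
    ip <- seq_along(ip) + max(0, L - length(ip))
  }
  ip
}
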