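#' Simulation parameters for the forward Wright-Fisher engine
#'
#' \code{thetaA} is the autosomal population-scaled adaptive mutation rate
#' 4*Ne*muA; the per-copy mutation probability muA = thetaA / (4*Ne) is the
#' same on the X, so an X-linked locus automatically receives the reduced
#' input thetaA_X = 0.75 * thetaA under an equal sex ratio (three X copies
#' per four autosomal copies).  \code{thetaNeutralPerBp} is the per-bp
#' neutral rate (0.004 corresponds to mu = 1e-9/bp at Ne = 1e6).
#'
#' @param Ne diploid population size of the simulation
#' @param chromClass "autosome" or "X"
#' @param thetaA autosomal 4*Ne*muA for the selected site
#' @param s selection coefficient per generation (signed)
#' @param h dominance coefficient in [0, 1]
#' @param thetaNeutralPerBp per-bp neutral 4*Ne*mu (default 0.004)
#' @param rhoCmPerBp recombination rate in cM/bp (default 5e-7)
#' @param locusBp simulated locus length (default 10000)
#' @param Q rescaling constant already applied (bookkeeping; default 1)
#' @return list of class \code{SimParams} with derived per-copy rates
#'   \code{muA}, \code{muNeutralLocus} and \code{rMorgansLocus}
#' @export
simParams <- function(Ne, chromClass = c("autosome", "X"), thetaA = 0,
                      s = 0, h = 0.5, thetaNeutralPerBp = 0.004,
                      rhoCmPerBp = 5e-7, locusBp = 10000, Q = 1) {
  chromClass <- match.arg(chromClass)
  if (Ne < 10) stop("Ne must be >= 10")
  if (h < 0 || h > 1) stop("h must be in [0, 1]")
  if (thetaA < 0 || thetaNeutralPerBp < 0) stop("theta values must be >= 0")
  structure(
    list(
      Ne = Ne, chromClass = chromClass, thetaA = thetaA, s = s, h = h,
      thetaNeutralPerBp = thetaNeutralPerBp, rhoCmPerBp = rhoCmPerBp,
      locusBp = locusBp, Q = Q,
      muA = thetaA / (4 * Ne),
      muNeutralLocus = thetaNeutralPerBp * locusBp / (4 * Ne),
      rMorgansLocus = rhoCmPerBp / 100 * locusBp
    ),
    class = "SimParams"
  )
}

#' Rescale simulation parameters by a constant Q
#'
#' Ne -> Ne/Q, s -> s*Q, mutation rates -> *Q, per-bp recombination -> *Q;
#' the compound parameters theta = 4*Ne*mu and Ne*s are invariant.  Valid
#' while selection stays weak; a warning is raised when the rescaled
#' |s| reaches 0.1.
#'
#' @param params a \code{\link{simParams}} object
#' @param Q rescaling constant >= 1
#' @return the rescaled \code{SimParams}
#' @export
rescaleParams <- function(params, Q) {
  if (Q < 1) stop("Q must be >= 1")
  if (params$Ne / Q < 10) stop("Ne/Q must be >= 10")
  s2 <- params$s * Q
  if (abs(s2) >= 0.1) {
    warning("rescaled |s| >= 0.1: outside the validity range of rescaling")
  }
  simParams(
    Ne = params$Ne / Q, chromClass = params$chromClass,
    thetaA = params$thetaA, s = s2, h = params$h,
    thetaNeutralPerBp = params$thetaNeutralPerBp,
    rhoCmPerBp = params$rhoCmPerBp * Q, locusBp = params$locusBp,
    Q = params$Q * Q
  )
}

#' Initialise a count-engine population
#'
#' Monomorphic sexed population of N diploids.  Females always carry two
#' copies of the focal chromosome; males carry two (autosome) or one (X).
#'
#' @param N diploid population size
#' @param chromClass "autosome" or "X"
#' @return a \code{WfPopulation} state list
#' @export
wfPopulation <- function(N, chromClass = c("autosome", "X")) {
  chromClass <- match.arg(chromClass)
  isX <- chromClass == "X"
  nf <- floor(N / 2)
  nm <- N - nf
  structure(
    list(
      isX = isX, N = as.numeric(N), gen = 0, nextId = 1L,
      femDos = c(nf, 0, 0),
      maleDos = if (isX) c(nm, 0) else c(nm, 0, 0),
      femOriginId = integer(0), femOriginCnt = numeric(0),
      maleOriginId = integer(0), maleOriginCnt = numeric(0),
      status = "init", fixGen = NA_real_, gensRun = 0
    ),
    class = "WfPopulation"
  )
}

#' Number of focal-chromosome copies in the population
#' @param pop a \code{WfPopulation}
#' @export
wfCopyCount <- function(pop) {
  nf <- sum(pop$femDos)
  nm <- sum(pop$maleDos)
  if (pop$isX) 2 * nf + nm else 2 * (nf + nm)
}

#' Derived-allele copy count
#' @param pop a \code{WfPopulation}
#' @export
wfDerivedCount <- function(pop) {
  sum(pop$femOriginCnt) + sum(pop$maleOriginCnt)
}

#' Place one derived copy in the population
#'
#' Adds a single new mutational origin on one copy: in a female
#' heterozygote or, for \code{sex = "male"}, on a male-held copy.
#'
#' @param pop a \code{WfPopulation}
#' @param sex "female" or "male"
#' @return the updated population
#' @export
wfAddCopy <- function(pop, sex = c("female", "male")) {
  sex <- match.arg(sex)
  id <- pop$nextId
  pop$nextId <- id + 1L
  if (sex == "female") {
    if (pop$femDos[1] < 1) stop("no wildtype female available")
    pop$femDos[1] <- pop$femDos[1] - 1
    pop$femDos[2] <- pop$femDos[2] + 1
    pop$femOriginId <- c(pop$femOriginId, id)
    pop$femOriginCnt <- c(pop$femOriginCnt, 1)
  } else {
    if (pop$maleDos[1] < 1) stop("no wildtype male available")
    pop$maleDos[1] <- pop$maleDos[1] - 1
    pop$maleDos[2] <- pop$maleDos[2] + 1
    pop$maleOriginId <- c(pop$maleOriginId, id)
    pop$maleOriginCnt <- c(pop$maleOriginCnt, 1)
  }
  pop
}

#' Advance the count-engine population
#'
#' Runs the sexed Wright-Fisher recursion.  Selection acts through parent
#' sampling weights: female genotype fitness (1, 1+hF*sF, 1+sF) by derived
#' dosage, autosomal male fitness likewise with (sM, hM), and hemizygous X
#' males (1, 1+sM) -- dosage compensation.  Adaptive mutation converts each
#' transmitted wildtype copy with probability \code{mu} and assigns a fresh
#' origin id.
#'
#' @param pop a \code{WfPopulation}
#' @param generations generations to run (cap when a stop rule is set)
#' @param sF,hF selection and dominance in females
#' @param sM,hM selection and dominance in males (default: same as females)
#' @param mu adaptive mutation probability per transmitted wildtype copy
#' @param stop "none" (run exactly \code{generations}), "fixation", or
#'   "fixation_or_loss"
#' @return the updated population; \code{$status} is "ran", "fixed",
#'   "lost" or "cap", and \code{$fixGen} records the fixation generation
#' @export
wfStep <- function(pop, generations = 1, sF = 0, hF = 0.5, sM = sF,
                   hM = hF, mu = 0,
                   stop = c("none", "fixation", "fixation_or_loss")) {
  stop <- match.arg(stop)
  mode <- match(stop, c("none", "fixation", "fixation_or_loss")) - 1L
  out <- cc_run(pop, sF, hF, sM, hM, mu, generations, mode)
  class(out) <- "WfPopulation"
  out
}

#' Sample chromosome copies and report their origin labels
#'
#' Draws k copies uniformly without replacement from the population census
#' (X: females contribute two copies, males one) and returns the origin
#' composition of the sample.
#'
#' @param pop a \code{WfPopulation}
#' @param k copies to sample (default 100)
#' @return list: \code{originId}, \code{count} (per sampled origin),
#'   \code{nWildtype}, \code{nOrigins} (distinct origins in the sample)
#' @export
wfSampleOrigins <- function(pop, k = 100) {
  total <- wfCopyCount(pop)
  if (k > total) stop("k exceeds the chromosome copy count")
  ids <- c(pop$femOriginId, pop$maleOriginId)
  cnt <- c(pop$femOriginCnt, pop$maleOriginCnt)
  if (length(ids)) {
    agg <- tapply(cnt, ids, sum)
    ids <- as.integer(names(agg))
    cnt <- as.numeric(agg)
  }
  classes <- c(cnt, total - sum(cnt)) # last class = wildtype
  # sequential multivariate hypergeometric
  take <- numeric(length(classes))
  rem <- k
  left <- sum(classes)
  for (i in seq_along(classes)) {
    if (rem <= 0) break
    x <- rhyper(1, classes[i], left - classes[i], rem)
    take[i] <- x
    rem <- rem - x
    left <- left - classes[i]
  }
  nw <- take[length(take)]
  take <- take[-length(take)]
  keep <- take > 0
  list(
    originId = ids[keep], count = take[keep], nWildtype = nw,
    nOrigins = sum(keep)
  )
}

#' Neutral forward-simulated haplotype sample
#'
#' Runs the sequence-level engine with s = 0 from a monomorphic start for
#' \code{gens} generations (>= 10 Ne for equilibrium) and samples k copies.
#' Useful for checking the engine against Watterson/Tajima expectations.
#'
#' @param params a \code{\link{simParams}}
#' @param gens generations to run (default 10 * Ne)
#' @param k haplotypes to sample
#' @return a \code{\link{HaplotypeMatrix}} (integer positions on the locus)
#' @export
neutralForwardSample <- function(params, gens = 10 * params$Ne, k = 100) {
  isX <- params$chromClass == "X"
  res <- cs_neutral_run(
    as.integer(params$Ne), isX, params$locusBp,
    params$muNeutralLocus, params$rMorgansLocus, gens, as.integer(k),
    matrix(0, 0, 0), numeric(0)
  )
  seqSampleToMatrix(res, params$locusBp, params$chromClass)
}

# convert a sequence-engine sample to a HaplotypeMatrix (+ origin labels)
seqSampleToMatrix <- function(res, locusBp, chromClass) {
  mat <- res$haplotypes
  pos <- res$positions
  if (length(pos)) {
    ip <- makePositionsInteger(pos, locusBp)
  } else {
    ip <- numeric(0)
    mat <- matrix(0L, nrow(mat), 0)
  }
  hm <- HaplotypeMatrix(mat, ip,
    chromLabel = "sim", chromClass = chromClass
  )
  attr(hm, "selOrigin") <- res$selOrigin
  hm
}

# standing neutral variation for seeding sweep-phase populations:
# a coalescent sample of one haplotype per chromosome copy
standingVariation <- function(N, chromClass, locusBp, thetaNeutralPerBp,
                              chunkBp = 400) {
  isX <- chromClass == "X"
  nf <- N %/% 2
  nm <- N - nf
  copies <- if (isX) 2 * nf + nm else 2 * N
  thetaEff <- thetaNeutralPerBp * copies / (2 * N)
  reg <- chunkedCoalescentRegion(copies, locusBp, thetaEff, chunkBp)
  list(haplotypes = reg$haplotypes, positions = as.numeric(reg$positions),
       copies = copies)
}
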