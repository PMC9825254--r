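#' Shift / standing-variation experiment parameters
#'
#' @param sD,hD selection and dominance while the mutation is deleterious
#' @param sB,hB selection and dominance after it becomes beneficial
#' @param thetaDel autosomal 4*Ne*mu_del for the recurrent deleterious input
#' @param pf conditioning frequency for the single-origin design
#' @param recurrentAfterShift keep the recurrent mutation running after the
#'   environmental shift (multiple-origin design only)
#' @param k deleterious scalar for sexual antagonism (s_d = -k * s_b)
#' @return list of class \code{ShiftParams}
#' @export
shiftParams <- function(sD = 0, hD = 0.5, sB = 0, hB = 0.5, thetaDel = 0,
                        pf = 0.001, recurrentAfterShift = FALSE, k = 0.1) {
  if (sD > 0 || sB < 0) stop("need sD <= 0 <= sB")
  structure(
    list(
      sD = sD, hD = hD, sB = sB, hB = hB, thetaDel = thetaDel, pf = pf,
      recurrentAfterShift = recurrentAfterShift, k = k
    ),
    class = "ShiftParams"
  )
}

newSweepOutcome <- function(category, nOrigins = NA_integer_,
                            nDistinctHaplotypes = NA_integer_,
                            fixationGeneration = NA_real_,
                            originsFromSgvFraction = NA_real_) {
  structure(
    list(
      category = category, nOrigins = nOrigins,
      nDistinctHaplotypes = nDistinctHaplotypes,
      fixationGeneration = fixationGeneration,
      originsFromSgvFraction = originsFromSgvFraction
    ),
    class = "SweepOutcome"
  )
}

classifyOrigins <- function(nOrigins) {
  if (nOrigins >= 2) "soft" else "hard"
}

#' Recurrent-mutation sweep to fixation
#'
#' Beneficial mutations enter the population recurrently at rate thetaA;
#' the run continues until the adaptive allele is fixed on every chromosome
#' copy, then k haplotype copies are sampled and the sweep is classified
#' hard (one mutational origin in the sample) or soft (two or more).
#'
#' @param params a \code{\link{simParams}} with s > 0 and thetaA > 0
#' @param sampleK copies to sample at fixation (default 100)
#' @param maxGens generation cap (default 100 * Ne)
#' @return a \code{SweepOutcome}
#' @export
runRecurrentSweep <- function(params, sampleK = 100,
                              maxGens = 100 * params$Ne) {
  if (params$s <= 0) stop("recurrent sweeps need s > 0")
  pop <- wfPopulation(params$Ne, params$chromClass)
  pop <- wfStep(pop, maxGens,
    sF = params$s, hF = params$h, mu = params$muA, stop = "fixation"
  )
  if (pop$status != "fixed") {
    stop("generation cap exceeded before fixation (", pop$gen, " generations)")
  }
  smp <- wfSampleOrigins(pop, sampleK)
  newSweepOutcome(classifyOrigins(smp$nOrigins),
    nOrigins = smp$nOrigins, fixationGeneration = pop$fixGen
  )
}

#' Multiple-origin adaptation from standing variation (dominance shifts)
#'
#' Recurrent deleterious mutations (sD, hD) enter at rate thetaDel during a
#' burn-in of 10 Ne generations.  At the environmental shift, if no copies
#' segregate the outcome is "no_sgv"; otherwise selection becomes (sB, hB)
#' and recurrent mutation stops (unless \code{recurrentAfterShift}).  If
#' all copies are lost the outcome is "lost"; on fixation k copies are
#' sampled, origins counted, and the sweep classified hard or soft.  With
#' \code{recurrentAfterShift} the fraction of sampled copies descending
#' from pre-shift (standing) origins is also reported.
#'
#' @param params a \code{\link{simParams}} (its s, h are ignored; the shift
#'   object carries selection)
#' @param shift a \code{\link{shiftParams}} with thetaDel, sD, hD, sB, hB
#' @param sampleK copies to sample (default 100)
#' @param burnGens burn-in length (default 10 * Ne)
#' @param maxGens post-shift cap (default 100 * Ne)
#' @return a \code{SweepOutcome}
#' @export
runDominanceShift <- function(params, shift, sampleK = 100,
                              burnGens = 10 * params$Ne,
                              maxGens = 100 * params$Ne) {
  muDel <- shift$thetaDel / (4 * params$Ne)
  pop <- wfPopulation(params$Ne, params$chromClass)
  pop <- wfStep(pop, burnGens,
    sF = shift$sD, hF = shift$hD, mu = muDel, stop = "none"
  )
  if (wfDerivedCount(pop) == 0) {
    return(newSweepOutcome("no_sgv"))
  }
  sgvMaxId <- pop$nextId - 1L
  muPost <- if (shift$recurrentAfterShift) muDel else 0
  pop <- wfStep(pop, maxGens,
    sF = shift$sB, hF = shift$hB, mu = muPost, stop = "fixation_or_loss"
  )
  if (pop$status == "lost") {
    return(newSweepOutcome("lost"))
  }
  if (pop$status != "fixed") {
    return(newSweepOutcome("not_fixed"))
  }
  smp <- wfSampleOrigins(pop, sampleK)
  sgvFrac <- if (shift$recurrentAfterShift) {
    sum(smp$count[smp$originId <= sgvMaxId]) / sum(smp$count)
  } else {
    NA_real_
  }
  newSweepOutcome(classifyOrigins(smp$nOrigins),
    nOrigins = smp$nOrigins,
    fixationGeneration = pop$fixGen,
    originsFromSgvFraction = sgvFrac
  )
}

#' Single-origin sweep from standing variation
#'
#' A single deleterious mutation (sD, hD) is introduced at the center of
#' the locus on a coalescent-seeded background; losses restart the attempt
#' until the variant reaches the conditioning frequency PF.  Selection then
#' switches to (sB, hB) and the run continues to fixation or loss.  Whole
#' runs are retried until one fixes (the design conditions on fixed
#' sweeps).  Softness is proxied by the number of distinct haplotypes
#' bearing the adaptive allele in the sample.
#'
#' @param params a \code{\link{simParams}} (thetaNeutralPerBp, locus, rho)
#' @param shift a \code{\link{shiftParams}} with sD, hD, pf, sB, hB
#' @param sampleK haplotypes to sample (default 100)
#' @param maxRestarts pre-PF restart cap per attempt (default 1e6)
#' @param maxAttempts cap on fixed-sweep retries (default 200)
#' @return a \code{SweepOutcome} with \code{nDistinctHaplotypes}
#' @export
runSgvSingleOrigin <- function(params, shift, sampleK = 100,
                               maxRestarts = 1e6, maxAttempts = 200) {
  if (shift$pf <= 0 || shift$pf >= 1) stop("PF must be in (0, 1)")
  sv <- standingVariation(
    params$Ne, params$chromClass, params$locusBp, params$thetaNeutralPerBp
  )
  for (attempt in seq_len(maxAttempts)) {
    res <- cs_single_origin_run(
      as.integer(params$Ne), params$chromClass == "X", params$locusBp,
      params$muNeutralLocus, params$rMorgansLocus,
      shift$sD, shift$hD, shift$pf, shift$sB, shift$hB,
      100 * params$Ne, as.integer(maxRestarts), as.integer(sampleK),
      sv$haplotypes, sv$positions
    )
    if (res$status == "fixed") {
      carriers <- res$selOrigin > 0
      mat <- res$haplotypes[carriers, , drop = FALSE]
      nDist <- if (nrow(mat)) {
        length(unique(apply(mat, 1, paste, collapse = "")))
      } else {
        0L
      }
      return(newSweepOutcome("fixed_unclassified",
        nOrigins = 1L, nDistinctHaplotypes = nDist
      ))
    }
  }
  stop("no fixation within ", maxAttempts, " attempts")
}

#' Sexually antagonistic sweep
#'
#' Recurrent mutations enter at rate thetaA and are beneficial in one sex
#' (s_b) and deleterious in the other (s_d = -k * s_b), with the same
#' dominance h in both sexes; hemizygous X males experience the homozygous
#' effect of their sex's coefficient.  Runs to fixation and classifies by
#' sampled origins; generation-cap hits return category "not_fixed".
#'
#' @param params a \code{\link{simParams}}; \code{params$s} is the
#'   beneficial coefficient s_b
#' @param advantagedSex "female" or "male"
#' @param k deleterious scalar (default 0.1)
#' @param sampleK copies to sample (default 100)
#' @param maxGens generation cap (default 100 * Ne)
#' @return a \code{SweepOutcome}
#' @export
runSexualAntagonism <- function(params, advantagedSex = c("female", "male"),
                                k = 0.1, sampleK = 100,
                                maxGens = 100 * params$Ne) {
  advantagedSex <- match.arg(advantagedSex)
  sB <- params$s
  sD <- -k * sB
  sF <- if (advantagedSex == "female") sB else sD
  sM <- if (advantagedSex == "female") sD else sB
  pop <- wfPopulation(params$Ne, params$chromClass)
  pop <- wfStep(pop, maxGens,
    sF = sF, hF = params$h, sM = sM, hM = params$h,
    mu = params$muA, stop = "fixation"
  )
  if (pop$status != "fixed") {
    return(newSweepOutcome("not_fixed"))
  }
  smp <- wfSampleOrigins(pop, sampleK)
  newSweepOutcome(classifyOrigins(smp$nOrigins),
    nOrigins = smp$nOrigins, fixationGeneration = pop$fixGen
  )
}

#' Summarise replicate sweep outcomes
#'
#' @param outcomes list of \code{SweepOutcome}s
#' @param level confidence level for binomial (Wilson) category CIs
#' @return list: \code{meanOrigins}, \code{meanDistinctHaplotypes},
#'   \code{categories} (data.frame: category, n, proportion, ciLow,
#'   ciHigh), \code{n}
#' @export
summarizeOutcomes <- function(outcomes, level = 0.95) {
  if (length(outcomes) == 0) stop("no outcomes to summarise")
  cat_ <- vapply(outcomes, function(o) o$category, "")
  org <- vapply(outcomes, function(o) as.numeric(o$nOrigins), 0.0)
  dh <- vapply(outcomes, function(o) as.numeric(o$nDistinctHaplotypes), 0.0)
  n <- length(outcomes)
  z <- qnorm(1 - (1 - level) / 2)
  tab <- table(cat_)
  wilson <- function(x) {
    p <- x / n
    den <- 1 + z^2 / n
    c <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, c - hw), min(1, c + hw))
  }
  cis <- t(vapply(as.numeric(tab), wilson, c(0, 0)))
  list(
    meanOrigins = mean(org, na.rm = TRUE),
    meanDistinctHaplotypes = mean(dh, na.rm = TRUE),
    categories = data.frame(
      category = names(tab), n = as.integer(tab),
      proportion = as.numeric(tab) / n,
      ciLow = cis[, 1], ciHigh = cis[, 2]
    ),
    n = n
  )
}

#' Proportion of a given outcome category
#' @param outcomes list of \code{SweepOutcome}s
#' @param category category name, e.g. "soft"
#' @export
categoryProportion <- function(outcomes, category) {
  mean(vapply(outcomes, function(o) o$category, "") == category)
}
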