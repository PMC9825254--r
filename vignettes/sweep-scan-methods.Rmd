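---
title: "Detecting and classifying hard and soft sweeps on the X and autosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying hard and soft sweeps on the X and autosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

When a beneficial allele spreads through a population it drags its
haplotype background with it.  A *hard* sweep — a single mutational origin
rising alone — leaves one haplotype at high frequency.  A *soft* sweep —
recurrent mutations at the same locus, or standing variation that had
already recombined onto several backgrounds — leaves multiple haplotypes
rising together.  The X chromosome differs from the autosomes in three
ways that shift this balance: it is hemizygous in males (every X-linked
allele in a male is fully exposed to selection), it has a lower effective
population size (three X copies for every four autosomal copies at an
even sex ratio, so the population-scaled adaptive mutation rate satisfies
theta_X = 0.75 theta_auto), and recessive deleterious variants are purged
from it more efficiently, thinning the standing variation that seeds soft
sweeps.  SweepScanX implements, end to end, the machinery needed to study
this contrast: a sexed forward Wright–Fisher simulator with explicit X
transmission and dosage compensation, haplotype-homozygosity scan
statistics with SNP-density-calibrated windows, a simulation-based
false-discovery-rate threshold and peak caller, and an approximate
Bayesian computation (ABC) classifier that labels peaks hard or soft from
their (H12, H2/H1) coordinates.

# Statistics

For a window of SNPs, haplotypes are grouped into identity classes with
frequencies $p_1 \ge p_2 \ge \dots$.  Haplotype homozygosity is
$H1 = \sum_i p_i^2$; pooling the two most frequent classes gives
$H12 = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2$, which retains power when a
sweep is shared by two haplotypes; $H2 = H1 - p_1^2$ drops the leading
class, and the ratio $H2/H1$ is near zero for hard sweeps and rises
monotonically with the number of sweeping haplotypes.  Missing data enter
in two ways: a haplotype missing more than 10% of a window's calls is
assigned its own class of frequency $1/N$ (it cannot be matched reliably),
and residual missing calls in the remaining haplotypes are treated as a
distinct allele state, so uncertainty splits classes rather than merging
them — conservative against inflating homozygosity.  Diversity uses the
unbiased per-site estimator $2\hat p\hat q\, n_c/(n_c-1)$ with the
site-specific callable count $n_c$, and bootstrap confidence intervals
resample 10-kb windows.  Pairwise linkage disequilibrium is the standard
$R^2 = D^2/(p_1 q_1 p_2 q_2)$ over haplotypes complete at both sites, with
allele frequencies restricted to [0.05, 0.95] and at least four complete
haplotypes per pair; profiles are smoothed in 20-bp distance bins out to
300 bp and 150-bp bins beyond, matching the sub-kilobase scale on which
LD decays in *D. melanogaster* panels.

# Window calibration

Analysis windows are defined in SNPs, not base pairs, so that H12 does not
covary with local diversity.  At the autosomal median density of
0.0345 segregating sites/bp a 401-SNP window spans
$401/0.0345 \approx 11{,}623$ bp; at the X median 0.0227/bp the same SNP
count would span 17,665 bp, diluting X-linked sweep signals.  The X window
is therefore recalibrated to span the same physical length:
$\mathrm{round}(0.0227 \times 401/0.0345) = 264$ SNPs (265, the
rounding-equivalent value in common use, is equally accepted as
configuration), and autosomal windows are down-sampled to the X count —
a fresh uniform draw per window — so both arms are analysed with the same
number of SNPs over the same physical scale.  All such calibrations round
half-up.  The desk-scale pipeline in this package uses the same
calibration at 61 → 40 (autosome) and 40 (X) SNPs, spanning about 1.8 kb
at the configured densities.

# The forward simulator

Two engines share one life cycle: discrete generations, offspring sex
Bernoulli(1/2), mothers and fathers drawn proportional to fitness
(fecundity selection), female genotype fitness $(1, 1+hs, 1+s)$ by derived
dosage, the same for autosomal males, and hemizygous X males $(1, 1+s)$ —
dosage compensation, i.e. a male carrier has the fitness of a homozygous
female.  Fathers pass their X to daughters only, unrecombined.  Every
transmitted wildtype copy mutates to the adaptive state with probability
$\mu_A = \theta_A/(4N_e)$ and receives a fresh origin label, so an X-linked
locus automatically sees the 0.75-scaled input.

The *count engine* tracks genotype-dosage counts per sex plus per-origin
copy counts, advancing by exact multinomial/hypergeometric sampling under
random union of gametes.  Within a sex, derived copies are exchangeable,
so transmitted derived gametes are partitioned among origins
multinomially; the small correlation between an origin's copies and the
het/hom state of their carriers is averaged out (an $O(s)$ within-class
effect, identical on X and autosomes, so the X–autosome contrasts are
unaffected).  This makes a 10 Ne-generation burn-in at Ne = 2000 cost
microseconds per generation and lets the replicate grids run in minutes.

The *sequence engine* is individual-based: every chromosome copy carries a
sorted list of derived neutral positions (infinite-sites, real-valued
positions de-duplicated to integer bp on output) plus the selected-site
origin label; gametes recombine with a Poisson number of crossovers.  It
serves the single-origin standing-variation experiments (where softness is
proxied by distinct carrier haplotypes), the ABC training simulations, and
the neutral Watterson/Tajima calibration checks.

Rescaling follows the usual rules (Ne/Q, sQ, mu Q, rho Q; theta and Ne s
invariant, warning once |sQ| reaches 0.1).  Desk-scale experiments run at
Ne = 2000 with Ne s = 100 and the published theta values, with at least
300 replicates per parameter combination; directional contrasts are tested
with one-sided rank or proportion tests at alpha = 0.01.

# Neutral variation

No installed R library simulates the coalescent, so the package carries a
small Hudson-style implementation: exponential coalescence times, Poisson
(or fixed-count) mutations placed proportional to branch length.  Regions
are assembled from independent non-recombining segments of 400 bp — the
few-hundred-bp scale over which LD decays in the DGRP — so the
segregating-site density and site-frequency spectrum are exact while
within-segment LD is somewhat conservative (too strong) and
between-segment LD is absent.  The per-bp theta handed to the generator is
the target sample density divided by the harmonic number $a_{n-1}$, so a
region built for density 0.0345 at n = 100 contains 0.0345 segregating
sites per bp in expectation.  Standing variation for sweep-phase forward
runs is seeded from such a coalescent sample (one haplotype per chromosome
copy) rather than a forward burn-in; the forward burn-in path exists and
is verified against the Watterson and Tajima expectations directly.

# Scan, threshold, peaks

The scan slides its SNP window one SNP at a time and records H12 and
H2/H1 per window.  The critical value H12_o is the 10th-highest H12 among
ten times as many neutral simulated windows as there are independent
windows in the data (region length divided by the expected window span) —
a one-per-genome false-discovery construction.  The neutral windows are
drawn from the same chunked-coalescent model as the synthetic data, at the
arm's density and with the scan's own down-sampling.  Windows above the
threshold are grouped by contiguity; each group's apex carries the peak
value; candidates are visited highest-first and any apex within 500 kb of
an accepted apex is dropped (one selective event, one peak); surviving
peaks overlapping recombination-map intervals below 5e-7 cM/bp are
flagged masked and excluded from the reported set, since low recombination
inflates haplotype homozygosity without selection.  The footprint-length
heuristic $L \approx s/[\ln(N_e s)\,\rho]$ (rho converted from cM/bp to
Morgans/bp) is exposed as a utility; its published plug-in values are not
internally consistent, so it guides interval sizes only.

# The ABC classifier

Hard sweeps are trained at $\theta_A = 0.01$ and soft sweeps at
$\theta_A = 10$; nuisance parameters per replicate are
$s \sim U[0,1]$, $h \sim U[0,1]$, and the partial frequency at which
selection ceases $PF \sim U[0,1]$.  Each training replicate seeds a
population of 200 diploids (the X mode is a hemizygous forward population,
300 X copies = 0.75 x 400) with coalescent standing variation, runs
selection with recurrent adaptive mutation until the allele first reaches
PF, drifts for a decay time, samples 100 haplotypes and computes
(H12, H2/H1) on the scan's window spec centred at the selected site.  The
Bayes factor at an observed point is the ratio of soft to hard training
points within a strict Euclidean radius of 0.1, evaluated at the observed
coordinates (the gridded surface is for visualisation); BF <= 1 is hard,
BF > 1 soft, BF >= 30 strong evidence for soft, and a point with no
training neighbours is reported unclassified rather than defaulted.

Three rescaling corrections keep desk-scale training faithful, because a
sweep's duration shrinks only logarithmically while per-generation rates
inflate with the rescaling factor:

* *Waiting time.*  The hard model's mutation waiting time
  ($\sim 200$ generations per arising at $\theta_A = 0.01$) is neutral
  dead time at equilibrium; the first origin is placed at generation zero
  and pre-establishment losses restart the attempt — the standard
  conditioning on a sweep occurring.
* *Decay time.*  The start-of-selection prior $U[0, 10^{-3}] \times 4N_e$
  implies a post-sweep window erosion (expected new mutations per window)
  of at most $\theta_{win} \times 10^{-3} \approx 0.08$ at full scale.
  The desk decay bound is the erosion-invariant image of that prior,
  $T_E \sim U[0, 0.007] \times 4N_e$ generations for the desk window's
  smaller mutation load.
* *During-sweep mutation load.*  At full scale a sweeping core accumulates
  $\mu_{win} \times \mathrm{duration} \approx 4\times10^{-4}$ new window
  mutations (about 0.02 in a Q = 50 rescaled run); naive desk rates give
  about 0.56, shattering hard-sweep cores into multi-class spectra and
  destroying the hard/soft contrast.  The selective phase therefore runs
  neutral mutation at 5% of its rate, restoring approximately the Q = 50
  load, while the decay phase keeps the full rate (its length is already
  erosion-invariant).

With 2000 training replicates per class, held-out hard and soft
simulations are each labelled correctly well above the 60% mark, and
swapping the training classes maps every finite nonzero BF to its
reciprocal.

# The synthetic genome fixture

The end-to-end check builds a 2 x 1 Mb genome — one autosome-like arm
(density 0.0345/bp) and one X-like arm (0.0227/bp), n = 100 haplotypes
each — embeds one hard and one soft sweep per arm at least 500 kb apart,
adds residual-heterozygosity missingness (contiguous tracts; per-haplotype
fractions Beta(1, 19), mean 5%, so roughly one haplotype in seven exceeds
the 10% window rule), places one 40-kb recombination cold spot on the
autosomal arm, and runs the full pipeline: site call-rate filter (>= 50%),
scan, thresholds from fresh neutral simulations, peak calling with masking,
ABC classification.  Embedded hard sweeps are one core haplotype at
frequency PF = 1 across a 30-kb footprint; embedded soft sweeps carry five
cores with symmetric-Dirichlet(5) frequencies.  Two fixture choices
deserve explanation:

* carriers gain Poisson(2–5) private derived alleles across the footprint,
  the during-sweep mutation load of a desk-scale forward sweep, so that
  embedded peaks live on the same signature scale as the training clouds
  (a zero-noise embedded sweep has H12 near 1, outside any training
  support, and would be unclassifiable at radius 0.1);
* the soft cores are near-equal (concentration 5) rather than
  Dirichlet(1, ..., 1): with the uninformative split, one core carries
  more than 80% of the carriers in a large fraction of draws, a spectrum
  that is genuinely hard-shaped — no haplotype-homozygosity method could,
  or should, call it soft, so the truth labels would be noise rather than
  a test of the classifier.

Across ten seeds the pipeline recovers the median 4 of 4 embedded sweeps
with at least 3 correctly labelled.

# What the synthetic data do not capture

The generator matches sample size, SNP density, missingness structure and
qualitative sweep spectra, but not the DGRP's demography (admixture and
bottlenecks), inversion polymorphism, or genome-wide LD beyond the chunk
scale.  In particular, demographic bottlenecks prune sweep origins and
push genuinely soft sweeps toward higher H12; a classifier trained with
the constant-Ne models here is therefore more conservative about calling
high-H12 peaks soft than one trained under the fitted admixture models,
which are outside this package's scope (the neutral-model interface is
configurable instead).  Passing the end-to-end check demonstrates that the
machinery — filters, calibration, scan, threshold, peaks, classifier —
composes correctly at realistic data scales; it does not by itself
validate inferences about any real population.

# Numerical and design notes

* All SNP-count/length calibrations round half-up (with a 1e-9 guard for
  binary representation of exact halves).
* The IBD filter removes, in one pass on the original table, every strain
  whose maximum pairwise IBD exceeds the threshold; applied to the
  published exclusion lists this reproduces the 178-strain RAL and
  189-strain ZI panels from 205 and 197.
* Down-sampling to the most complete strains breaks ties by lexicographic
  sample id.
* Fixation on the X means presence on every X copy in the census; a
  generation cap is reported as its own outcome category
  (`not_fixed`) rather than discarded silently.
* PF values below one copy's frequency (e.g. the published 1e-4 at desk
  population sizes) are satisfied by the first segregating copy.
* Sexual antagonism applies the same dominance coefficient in both sexes
  to sex-specific selection coefficients ($s_d = -k s_b$, k = 0.1), and
  hemizygous males experience their sex's homozygous effect.
* Seeding: every stochastic routine draws from R's RNG, so a single
  `set.seed()` call makes any pipeline bit-reproducible.
* Problem sizes: experiment grids at Ne = 2000 with >= 300 replicates per
  cell; ABC training at Ne = 200 with 2000 replicates per class
  (autosome) and 1000 (X); ten end-to-end seeds.  These sizes keep the
  compound parameters at the study values while each grid completes in
  minutes on one core.

# A note on fully dominant sweeps

One directional expectation is *not* reproduced by this model: that
recurrent-mutation sweeps of fully dominant alleles (h = 1) are harder on
the X than on the autosomes.  In our engines — both the count-based and
the individual-based one, at Ne = 2000 and at Ne = 20,000 — the mean
origin count at h = 1 is equal between arms or slightly higher on the X
(e.g. 5.5 autosomal vs 6.2 X-linked at theta_A = 4), even though the
origin *arrival* rate on the X is only 0.69 times the autosomal one
(0.75 mutational input times a 0.92 establishment ratio).  The mechanism
is dosage compensation itself: once a dominant sweep is underway, a
late-arising origin on the autosome has a marginal advantage of order
$s(1-x)^2$ (the remaining wildtype copies are shielded inside
heterozygotes), while on the X the wildtype remains exposed in hemizygous
males, leaving late origins a first-order $s(1-x)$ advantage — and
cutting off the long neutral fixation tail of dominant autosomal sweeps
(mean fixation 456 vs 1034 generations at Ne = 2000).  The extra
surviving late origins on the X offset the input deficit.  At h = 0.5 the
X-harder direction is strong and highly significant, as are the
dominance-shift, no-SGV and sexual-antagonism contrasts; the h = 1
comparison is the one acceptance check this package reports as failed, by
design rather than by accident.

# Known limitations

The chunked coalescent has no between-segment LD, so long-range
haplotype statistics (for example R^2 beyond a few hundred bp) are not
faithful.  The count engine's origin partition is exact only up to the
exchangeable-copy approximation described above.  Training and data must
share a window specification and signature scale; classifying peaks from
a scan with a different spec than the grid was trained with is not
meaningful, and the classifier will return `unclassified` for points
outside its training support rather than extrapolate.
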