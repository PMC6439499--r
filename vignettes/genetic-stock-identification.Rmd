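---
title: "Genetic stock identification of mechanically mixed populations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic stock identification of mechanically mixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gsimix)
```

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and where the design was genuinely open and a choice had to be
made. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## 1. The scientific problem

Two reproductively isolated fish populations — call them *eastern* and
*western* — co-occur in a contact zone. Management needs to know, haul by
haul, what fraction of the catch belongs to each population, whether the
co-occurrence is *mechanical mixing* (pure individuals side by side) or
*hybridization* (interbreeding), and how the mixing proportion varies with
longitude, life stage and environment. All three questions are answered
from diploid biallelic SNP genotypes referenced against baseline samples
collected on the spawning grounds.

## 2. Panel selection

**FST ranking.** Candidate loci (~1,200) are ranked by the two-population
Weir–Cockerham θ̂, computed from the 1984 variance components *a*, *b*, *c*
with *observed* heterozygote counts — not Hardy–Weinberg expectations — so
that inbreeding-like departures propagate correctly. Per-locus estimates may
be negative (sampling noise around zero differentiation); loci monomorphic
in both samples have no defined θ̂ and are excluded with a flag. The
multilocus summary is the ratio of sums Σa/Σ(a+b+c), not the mean of
ratios.

**LD pruning.** The assignment model assumes loci contribute independent
information, so a candidate enters the panel only if its genotypic r²
against every already accepted locus is below 0.01 (same linkage group) or
0.25 (different groups); both thresholds are strict inequalities. Because
genotypes are unphased, r² is the squared Pearson correlation of 0/1/2
dosages (composite LD); this is phase-free and standard for pruning.
Two deliberate details:

* *Within-population LD.* Pooling two divergent baselines manufactures
  mixture LD between every pair of differentiated loci — precisely the loci
  the ranking favours — so the filter would veto the whole panel. LD is
  therefore measured within each baseline sample and the maximum of the two
  r² values is tested. Undefined r² (a pair member monomorphic in both
  samples, or fewer than two shared genotyped individuals) conservatively
  fails the filter.
* *Greedy order.* The selection algorithm is greedy in descending-FST order
  with ties broken by locus id. A globally optimal subset search is a
  non-goal: greedy is the simplest procedure consistent with "rank, then
  admit if independent", and it makes the audit trail (why every considered
  locus was accepted or rejected) well defined.

**Map-spread selection.** The hybrid-discrimination panel instead maximises
genomic coverage: a greedy scan along each linkage group keeps loci at
least 1 cM apart (first locus of each group always kept).

## 3. Assignment

Genotype likelihoods follow the Rannala–Mountain posterior-predictive form:
the baseline's allele frequency gets a Dirichlet prior with per-allele
parameter 1/k (k = 2, i.e. Beta(½, ½)), and the probability of a diploid
genotype is the Dirichlet-multinomial mass given the observed baseline
counts. The prior matters at the edges: an allele absent from a baseline
still has positive probability, so a single unexpected allele cannot send a
log-likelihood to −∞. Scores are 100·L_b/ΣL computed via log-sum-exp, so
score arithmetic is exact even when baselines differ by thousands of log
units. Exact score ties are labelled *ambiguous*; individuals with zero
usable loci are *unusable*; both are excluded from downstream proportions.

Power is estimated by leave-one-out self-assignment: each baseline fish's
own two allele copies are removed from its own population's counts at every
locus before its own-baseline likelihood is computed. Running this on
*hold-out* samples (not the samples that selected the panel) avoids
high-grading bias. The report gives per-population misassignment rates and
the distribution of log10 likelihood ratios; the "average fish" ratio is
the geometric mean — the only average consistent with ratios of
likelihoods (an open point in the source material, flagged as such).

## 4. Hybridization versus mechanical mixing

The admixture coefficient q (fraction of eastern ancestry) is estimated by
the conditional two-population admixture likelihood with *fixed* baseline
sample frequencies: every allele copy is eastern with probability q. This
replaces a full MCMC clustering run (the tool being emulated) with the same
quantity restricted to known parental frequencies: deterministic, seconds
per thousand fish, and exactly the statistic the parental-vs-F1 figure
compares. The posterior is evaluated on a uniform grid (default 1001
points) under a Uniform(0, 1) prior with trapezoid normalization; q̂ is the
posterior mode and the interval is the equal-tailed 95% credible interval,
widened to include the mode when the mode sits on a boundary. Flat
likelihoods (p_E = p_W everywhere, or no usable loci) are flagged
`uninformative` and classified ambiguous.

**Boundary-overlap tolerance.** Pure/admixed calls follow the
credible-interval logic: pure if the CI overlaps exactly one of {0, 1},
admixed if it excludes both. A subtlety the naive rule misses: an
equal-tailed interval from a continuous posterior *never* reaches the
boundary exactly. Even when the posterior mode of a truly pure fish sits at
q = 1, the 97.5% quantile falls short of 1 by roughly 0.025 × the posterior
width — about 1e-3 to 1e-2 at a few hundred loci of moderate divergence. A
tolerance of essentially zero would therefore call *every* pure fish
admixed. The default tolerance is eps = 0.025, the interval's own tail
mass: a posterior that piles its upper tail against the boundary is counted
as overlapping it. The classification is still sharp in practice: simulated
F1s at the spread panel have intervals ending near 0.7, two orders of
magnitude away from the tolerance.

Even so, the parental-vs-F1 dichotomy is *knife-edge* at the calibrated
divergence (Section 6): a few percent of truly pure fish genuinely look
non-boundary at ~460 informative loci, so the "≥95% of parental CIs touch a
boundary" expectation sits within a percentage point of its bound — the
acceptance suite documents this rather than hiding it.

**The F1 score screen.** At the 39-locus assignment panel there is too
little information for per-fish admixture intervals, but F1 hybrids have
expected assignment scores of 50, so a surplus of intermediate scores
flags hybridization. `f1_median_score()` packages the calibration
experiment: in an exactly symmetric world (mirrored baseline samples) the
true median F1 score is exactly 50, yet the sample median of 1,000 iid
hybrids is surprisingly noisy (MC sd ≈ 8 score points, because individual
F1 log-likelihood-ratios have sd of several nats and the score distribution
is thin near 50). The function therefore simulates 500 hybrids plus their
allele-swapped mirrors — in the mirrored world each mirror is itself a
correctly distributed F1 draw — an antithetic coupling that pins the median
to its true value within a fraction of a point while every likelihood is
still computed through the ordinary assignment machinery.

## 5. Mixing models M0–M4

Haul-level counts East_ip of N_ip fish (per trawl haul and life stage) are
binomial with probability π_ip and

logit(π_ip) = β·(salinity, oxygen, temperature)_std [+ Area] [+ Juvenile]
[+ F(utmX) or F_stage(utmX)] + u_haul.

* Covariates are standardized ((x − mean)/SD) inside the fitter; means and
  SDs are stored for back-transformation.
* `F` is a second-order random-walk (RW2) smoother over binned longitude
  knots (default 20 equally spaced knots spanning the observed range). The
  RW2 penalty's null space (constant + linear trend) is handled by the
  mixed-model decomposition: the penalised eigenbasis carries the wiggles
  with prior precisions τλ_j, the sum-to-zero constraint is automatic
  (eigenvectors are orthogonal to the constant), and the linear trend is
  estimated as an ordinary fixed effect. M4 fits one smoother per life
  stage plus a Juvenile main effect.
* `u_haul` is an exchangeable Gaussian random intercept per haul. This is a
  declared simplification of a period-replicated spatially correlated
  Matérn field: the scientific quantities compared here (fixed effects,
  smoother shapes, WAIC ranking) are testable under the simpler latent
  structure at desk scale, and exact SPDE machinery is a non-goal.
* Priors: Normal(0, sd 10) on fixed effects (diffuse on the logit scale),
  half-normal(scale 2) on both variance-component scales σ_rw and σ_u.

**Inference engine.** The latent field (β, smoother coefficients, u) has a
log-concave conditional posterior, so for fixed variance hyperparameters
its mode and curvature come from a dozen Newton steps; the hyperparameters
get a Laplace-approximated marginal explored on a small grid (5 points per
dimension around the optimum); posterior draws are Gaussian draws mixed
over the grid. Draws are *antithetic* (z and −z in pairs), which halves
Monte-Carlo error for symmetric functionals and makes the east/west label
symmetry exact: recoding the response to N − y negates every fixed effect
and reproduces the WAIC to numerical precision. This engine was chosen over
the also-considered random-walk Metropolis because the acceptance studies
require ~70 model fits on one CPU in minutes, which a 150-dimensional
pure-R sampler cannot deliver reliably; the Laplace route is deterministic
given the seed and still yields proper posterior draws for WAIC.

**WAIC.** WAIC = −2·Σ_ip [log mean_draws p(East_ip | draw) −
var_draws log p(East_ip | draw)], with the per-draw likelihood including
the random intercept. Conditional-likelihood WAIC with per-haul intercepts
is intrinsically noisy under misspecification (the intercepts absorb
structure the fixed part misses, inflating the variance penalty); the
default 2,000 draws keep ranking-relevant differences (hundreds of units
in the recovery studies) far above that noise, but single-model WAIC values
should not be over-read.

**Diagnostics and prediction.** Pearson residuals are computed at the
population level (random intercept excluded). `predict_longitude_profile()`
gives the posterior median and equal-tailed 95% band of π along the knots
with covariates at their means, and reports where the median crosses 0.5 —
the operational "transition longitude". `before_after_comparison()` pools
counts on either side of a cutoff period (e.g. a major inflow event) with
Wilson 95% intervals; it is deliberately descriptive.

**Unsupported combination.** The Area × Juvenile interaction is not
fittable — sparse sampling of adults in the western area makes it
untestable in the motivating design, and the package mirrors that
restriction explicitly.

## 6. The synthetic-data generator

`generator_config()` states the world the analyses assume:

* **Baselines.** Ancestral frequencies Uniform(0.05, 0.95); population
  frequencies Balding–Nichols Beta draws with divergence F = 0.03 for the
  background and F = 0.05 for a random 5% tail (the rankable outliers);
  Hardy–Weinberg genotypes; 150 diploids per population, ~1,200 loci on 23
  linkage groups of 33 cM (so that the ≥1 cM spread selection keeps ~460 of
  them, the scale of the map-spread panel). The divergence defaults were
  calibrated once, by the scan in `scripts/calibrate_fst.R`, so that the
  top-39 high-graded panel yields a hold-out leave-one-out misassignment
  rate of the order of 1% with a likelihood-ratio separation of the
  published order (geometric means in the 10^5–10^6 range); they are not
  revisited by any test.
* **LD blocks.** 20 blocks of 4 adjacent loci; members copy the focal
  locus's haplotype indicators with per-copy flip probability
  (1 − sqrt(r²))/2, targeting r² = 0.8. Blocks exercise the pruning logic
  (at most one member may survive selection).
* **Survey.** 120 hauls uniform over 12–14.5° longitude across a
  year-quarter grid, 30 fish per haul, half juveniles; the true eastern
  proportion follows a logistic curve in longitude with steepness 8,
  centred at 13.0° for adults and 13.5° for juveniles; fish origins are
  Bernoulli draws, genotypes drawn from the origin baseline's *sample*
  frequencies (F1 hybrids, at the configured rate, draw one allele from
  each). Environmental covariates follow longitude trends plus noise with
  zero true effect on mixing by default — mirroring the motivating
  negative finding — with non-zero settings available for power studies.
* **Length stub.** Juveniles get lengths below 20 cm from cohort offsets
  (two eastern year-classes, one western) plus noise; adults above 20 cm.
  This exists to exercise the "under 20 cm = juvenile" rule, not to model
  growth.

What the generator does **not** emulate: linkage between the survey fish's
loci (mixture genotypes are drawn locus-independently; blocks exist only in
the baselines), coalescent ancestry, selection, genotyping error and
missingness patterns, oceanographic drift, or spatially correlated haul
effects. A green test therefore establishes that the estimators recover the
stated world — not that real data meet these assumptions.

## 7. Numerical choices and degenerate inputs

* Assignment scores and admixture posteriors are computed in log space;
  likelihood floors (1e-300) only guard exact zeros on the admixture grid
  boundary.
* Admixture CI inversion interpolates the trapezoid CDF; exact plateaus
  (regions of zero density) are broken by a monotone 1e-15 ramp so the
  inverse is defined.
* The Newton solver floors binomial weights at 1e-10, halves steps until
  the objective is non-decreasing, and flags non-convergence (warning by
  default, error under `strict`).
* FST ties rank by locus id; spread selection orders ties by locus id;
  identical map positions keep the first locus. All selection output is
  therefore reproducible byte for byte.
* Genepop "0000" is missing; allele codes orient numerically (smallest
  observed code = ref) so dosage orientation is stable across files sharing
  a locus list.

## 8. Known limitations

* Only two baselines are supported end to end; the score machinery is
  written for ≥2 but nothing beyond two is tested.
* The random intercept is exchangeable, not spatial: WAIC differences
  between models that differ mainly in spatial structure should be read
  qualitatively.
* The admixture model conditions on baseline sample frequencies; for very
  small baselines its intervals are anti-conservative relative to a full
  joint posterior over frequencies.
* Real cM maps are denser and more heterogeneous than the uniform synthetic
  map; spread-panel sizes on real maps will differ.
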