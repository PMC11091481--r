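---
title: "Estimating selection coefficients from enclosure experiments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating selection coefficients from enclosure experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enclosabc)
```

# The inference problem

Seminatural enclosure experiments compete a wildtype (WT) allele against an
engineered knockout (ko) allele in freely breeding mouse populations with
overlapping generations.  Replicate rooms are founded with homozygotes of
both genotypes in equal numbers and censused at monitoring points; older
cohorts are removed on a fixed schedule to mimic natural turnover.  The data
are genotype counts of the alive adults per room and monitoring point, and
the question is whether the observed allele-frequency trajectories require
selection, and of what strength.

The likelihood of such an experiment is intractable: population sizes are
small and externally driven, generations overlap, and reproduction couples
fitness, mating and Mendelian segregation.  `enclosabc` therefore pairs an
individual-based forward simulator that reproduces the experiment's exact
demography with approximate Bayesian computation (ABC).

# The simulator

## Demography is a schedule, not a model

All demographic events are taken as known and encoded in a *demography
schedule*: per room and monitoring step, the number of new adult females and
males that enter, and the cohorts removed.  The simulator must reproduce
those numbers exactly, so population size and sex composition after every
step are functions of the schedule alone — this is enforced by construction
(offspring sexes are assigned to match the scheduled per-sex counts, not
drawn) and verified by tests across fitness models and seeds.  Selection
can therefore act only on *which* genotypes fill the scheduled slots, never
on how many animals exist.

Each monitoring interval is treated as one reproduction event: the
scheduled number of new adults at a step is exactly the number of offspring
created in that step.  Within a step, offspring are produced first (all
adults alive during the interval are eligible parents, including cohorts
removed at that step), then scheduled removals are applied, then the census
is taken.

## Fitness and mating

Fitness follows the standard one-locus parameterisation: ko/ko has fitness
1, WT/WT has $1 + s$, and the heterozygote $1 + hs$ with dominance
$h \in [0,1]$.  Three variants control how $(s, h)$ act across the sexes:
`males_only` (all females have fitness 1 — the biologically motivated
default, since the gene is expressed in testis), `sex_averaged` (same
coefficients in both sexes) and `sex_specific` (independent coefficients
per sex).  Two optional components extend any variant:

* **Non-genetic fitness variance** `g`: each individual's realised fitness
  is drawn from a Normal centred on its genotype-determined value with
  standard deviation `g`, truncated below at zero (sampling weights must be
  non-negative; the truncation point is a numerical necessity the model
  itself does not specify).  With `g = 0` the noisy model reduces *exactly*
  to the base model, same seed giving the same trajectory.
* **Non-random mating** `lambda`: a candidate pairing's weight is
  multiplied by $1-\lambda$ when the two parents' allele sets are identical
  (both heterozygous, or the same homozygote), $1-\lambda/2$ when exactly
  one allele is shared, and 1 when none is (opposite homozygotes).

For every offspring, a mother is drawn with probability proportional to
female fitness, then a father proportional to male fitness times the mating
modifier against that mother; the offspring genotype follows Mendelian
segregation of the parental genotypes.  Parents are drawn independently per
offspring with replacement, so a prolific male can sire many offspring in
one interval.  Sequential (mother-first) sampling was chosen over joint
pair sampling: it costs $O(F + M)$ per step rather than $O(FM)$, and
because the modifier is symmetric in the pair, the two schemes induce the
same pairing distribution up to the (female-side) marginal, which the
modifier leaves uniform across mothers of a given genotype mix.  A joint
sampler would be the natural alternative if the female marginal itself were
to be distorted.

## Initial conditions

Founders are homozygotes only, so the first monitoring points are far from
Hardy–Weinberg proportions and dominated by founder sampling noise.  The
analysis therefore drops the first two time points, uses the third as the
initial condition, and fits the statistics from the fourth onward.  The
initial population is realised *deterministically* from the observed
third-point genotype frequencies by largest-remainder rounding of
frequency × cell size within every (sex, cohort) cell of the
schedule-implied composition — per-cohort because later removals must know
which individuals belong to which cohort, and deterministically so that a
reference table is reproducible from its seed alone.

# The ABC machinery

## Priors

The selection coefficient has a shifted-Gamma prior,
$s \sim \mathrm{Gamma}(\text{shape}=3,\ \text{rate}=3) - 1$: support
$(-1, \infty)$, mean 0, placing substantial mass on both deleterious and
beneficial effects.  (A Gamma with shape and *scale* both 3 would have
shifted mean 8, inconsistent with a prior centred on neutrality; the rate
parameterisation is the one consistent with a zero-mean prior and is used
throughout.)  The dominance coefficient and the mating penalty are
Uniform(0, 1); the noise standard deviation is Uniform(0, 0.5), i.e. up to
half the baseline fitness.  Variants with an extra nuisance parameter
(`g`, or `lambda` in the two-parameter mating variant) sample it from its
prior but do not estimate it — it is integrated out.

## Rejection and regression adjustment

A reference table pairs $N$ prior draws with their simulated summary
statistics — either the WT allele frequency (`mode = "A"`) or all three
genotype frequencies (`mode = "G"`) per room and included time point, in a
frozen order (rooms ascending, time ascending, genotypes WT/WT, WT/ko,
ko/ko).  The redundant third genotype frequency is kept for
interpretability; it inflates Euclidean distances by at most a constant
factor and leaves acceptance ranks unchanged.

The rejection step scales each statistic by its median absolute deviation
computed on the *full* table (zero-MAD columns are dropped with a warning),
accepts the `ceiling(tolerance * N)` simulations closest to the
observation in Euclidean distance (ties broken by row index), and weights
them with an Epanechnikov kernel in relative distance.  The default
tolerance is 0.1; estimates are insensitive across 0.01–0.2, which the
test suite verifies on a conjugate toy model.

The accepted draws are then sharpened by local-linear regression
adjustment with a ridge penalty: each parameter, on a transformed scale
($\log(1+s)$ for selection coefficients, logit for $h$ and $\lambda$,
$\log$ for $g$ — so adjusted draws stay inside their supports), is
regressed on the obs-centred scaled statistics with the Epanechnikov
weights, and each draw is replaced by the prediction at the observation
plus its residual.  A heteroscedasticity correction rescales every
residual by the ratio of local residual standard deviations (at the
observation versus at the simulation), both estimated by a second weighted
ridge regression of the log squared residuals on the same design.  The
ridge penalty is chosen by generalised cross-validation over the grid
$10^{-4}, \ldots, 1$ on the accepted set; an untransformed fit is
available via `transform = FALSE`.  If the adjustment fails numerically
the rejection-only posterior is returned with a warning.  Posterior
summaries are the weighted mean and weighted equal-tailed 2.5/97.5
percentiles (not highest-posterior-density intervals).

Correctness anchors: on the conjugate model $\theta \sim N(0,1)$,
$S = \theta + N(0, 0.1^2)$, the adjusted posterior mean matches the
analytic posterior within 0.05 posterior standard deviations at
$N = 50{,}000$; with equal weights and a vanishing penalty the engine
reproduces ordinary least squares exactly; with uninformative statistics
the adjustment leaves the rejection posterior (≈ the prior) unchanged.

## Model choice, cross-validation, goodness of fit

*Model choice* pools the candidate models' tables, applies the rejection
step to the pooled scaled statistics, fits a multinomial logistic
regression of the model label on the statistics over the accepted rows and
evaluates it at the observation.  Following the study's protocol, the
selection side of the comparison pins $s$ at its posterior point estimate
while $h$ (and any nuisance parameter) is drawn from its prior.

*Cross-validation* repeatedly holds one simulation out, treats its
statistics as a pseudo-observation, and reports per parameter the mean
squared estimation error normalised by the variance of the true values —
about 1 for an unidentifiable parameter, near 0 for a perfectly identified
one.

*Goodness of fit* has no canonical definition in this setting; the
implemented choice is a distance-based posterior predictive check: the
statistic is the mean scaled distance from the target to its accepted set,
the null distribution is built from pseudo-observations drawn from the
table itself (each excluded from its own reference set), and the p-value
is the upper-tail fraction.  It is calibrated (approximately uniform under
the null) and has power against observations shifted far outside the
simulated cloud; both properties are tested.

A note on confusion matrices for *indistinguishable* models: conditional
on one realised pair of reference tables the classifier retains a small
spurious preference (the fitted decision boundary is displaced by a fixed
amount given the tables, and winners are correlated across
pseudo-observations), so per-row assignment proportions fluctuate around
0.5 by a few percentage points even for arbitrarily large tables.  The
"off-diagonals ≈ 0.5" property therefore holds in expectation over table
realisations, and the test suite asserts it on the mean over independent
fixture pairs.

## The seven-model grid

`run_suite()` orchestrates the full experiment grid — sex-averaged,
sex-specific, males-only, males-only + non-genetic variance, and three
non-random-mating variants — against allele- or genotype-frequency
statistics.  Non-random-mating variants are restricted to genotype
frequencies: the mating penalty reshuffles genotypes at nearly constant
allele frequency, so allele-frequency statistics carry almost no
information about it.  The "three parameter" mating variant estimates
$(s, h, \lambda)$ jointly; the two-parameter variant integrates $\lambda$
over its prior.  Both readings of the grid row are implemented because the
row label alone does not fix one; the flag `males_only_lambda3` versus
`males_only_lambda` selects between them.  The default table size is
100,000 simulations, doubled when a nuisance parameter is active.

# The synthetic-data generator

`synthetic_design()` emulates the experimental structure so every module
is testable without the study's supplementary data: three rooms founded by
10 WT + 10 ko homozygotes at equal sex ratio, nine monitoring points,
growth from 20 to several hundred adults per room (rooms 1–2 ramp to 440,
room 3 to 260 — roughly the published two-to-one size ratio), founders
removed at point 4, and two later cohorts removed near the end.  The exact
per-point censuses of the real experiment live only in its supplementary
file, so the default ramp is a parameterised stand-in shaped like the
published growth curves, not a reconstruction.  `make_schedule()` converts
census targets into birth/removal events whose replayed bookkeeping hits
the targets exactly; `make_pseudo_observed()` simulates the full
experiment under a known fitness model and emits counts in the observed
data format plus a truth sidecar, so downstream validation never guesses
the generating parameters.

What passing tests on these data do and do not show: the generator
reproduces the demographic skeleton (census sizes, sex ratios, cohort
turnover, founder disequilibrium) and the sampling noise that the model
itself implies, but not real-data features outside the model — spatial
and social structure of the rooms, litter clustering, heterozygote excess
from mating preferences beyond the $\lambda$ penalty, genotyping error, or
deaths between monitoring points.  Recovery of known parameters on
synthetic data therefore validates the inference machinery, not the
biological adequacy of the model; on the real data that adequacy is what
the goodness-of-fit test probes.

# Numerical choices and problem sizes

* Random numbers: every public entry point takes one root seed; replicate
  $i$ of a reference table uses a seed derived deterministically from
  (root, $i$, retry), so tables are reproducible and independent of
  evaluation order.
* Extinction: a replicate in which a room loses all members of one sex is
  resampled with a fresh derived seed up to 30 times; persistent failure
  (more than ~1% of attempts) aborts with a diagnostic rather than
  silently biasing the table.
* Degenerate inputs: empty censuses, monomorphic samples (Hardy–Weinberg
  test undefined), ragged time grids, and infeasible growth targets all
  raise typed conditions naming the offending room/row.
* The test suite runs at desk scale: reference tables of 2,000–10,000
  rows, 20 coverage repetitions at truth $s \in \{0, 0.5\}$ with
  10,000-row tables each (the dominant cost, about six minutes), 1,000
  neutral-conservation replicates, and 50,000-row tables only for the
  analytic toy model where simulation is free.  The acceptance script uses
  a 10,000-row table, 100 cross-validation folds and 100 goodness-of-fit
  null draws.  At these sizes the posterior-mean Monte-Carlo error for $s$
  is a few hundredths; study-scale runs (100,000+ simulations) use the
  same code paths unchanged.

# Known limitations

* The simulator has no age structure beyond cohort removal, no litter
  structure, no spatial territories, and no mortality other than scheduled
  removals; dead juveniles never enter the fitted frequencies (censuses
  count alive adults only).
* The goodness-of-fit procedure is one defensible choice among several;
  its p-values should be read as a calibrated outlier score, not a test of
  a sharp null hypothesis.
* Whether the mating penalty should multiply both parents' weights, and
  whether pairs should be sampled jointly, are open modelling questions;
  only the sequential mother-first scheme is implemented.
* The dominance coefficient is weakly identified by design (cross-validated
  prediction error near 1); its posterior is reported but should not be
  over-interpreted.
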