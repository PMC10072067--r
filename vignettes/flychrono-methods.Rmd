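---
title: "Methods: sleep scoring, circadian profiling and survival statistics in flychrono"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep scoring, circadian profiling and survival statistics in flychrono}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flychrono)
```

`flychrono` analyses *Drosophila* Activity Monitor (DAM) recordings:
per-fly infrared beam-break counts in fixed 5-minute bins under a
light:dark cycle. This vignette explains the scoring rules, the statistics,
the synthetic-data model used to validate them, and the design decisions
taken where the conventions of the field leave room.

## Time base and the light schedule

All analysis is expressed in Zeitgeber time: ZT0 is lights-on, and under
the default 12:12 LD cycle lights-off falls at ZT12 (720 min). A
`light_schedule()` requires an explicit lights-on clock time — there is no
default, because ZT anchoring is meaningless if guessed; the simulator
starts its recordings at lights-on and supplies it itself. Bins are indexed
by row order; timestamp monotonicity and uniform spacing are validated at
parse time, but time zones and DST are ignored (incubator recordings are
wall-clock monotone). Monitor rows with a non-OK status code are retained
but **masked**: masked bins never enter a scoring denominator, break sleep
runs conservatively, and cannot veto a death call (their counts are
untrusted in both directions).

## Sleep, bouts and death

- **Sleep**: a bin is asleep iff it belongs to a maximal run of zero-count,
  unmasked, pre-death bins whose length is at least the sleep threshold
  (default 5 min = 1 bin at native resolution). Scoring is at bin
  resolution; there is no sub-bin interpolation, matching the 5-min
  acquisition of the instrument. Lowering the threshold can only add sleep
  (a tested monotonicity property).
- **Rest bouts**: maximal runs of consecutive asleep bins. A plausible
  alternative reading — counting qualifying bins rather than runs — is not
  used; the run interpretation is standard and is what `find_bouts()`
  returns (start, length). When day and night bouts are counted separately,
  a bout spanning the ZT12 boundary is split at the boundary and counts
  once on each side, keeping 12-h windows self-consistent (an all-sleep day
  yields exactly one day bout and one night bout).
- **Death**: a fly is dead iff the terminal run of silent bins is strictly
  longer than 24 h ("more than 24 hours": exactly 24 h does not qualify).
  Death is placed at the *start* of that run — the bin after the last
  movement — so the silent tail is not counted as lived time. Deaths after
  the 30-day analysis horizon revert to censoring at the horizon;
  recordings ending with a sub-threshold silent tail censor at the
  recording end. The call is idempotent under truncation at the death bin,
  and appending activity after a sub-threshold tail cancels it.
- **Dead-on-arrival** flies (death on day 1) stay in the survival tables —
  survival must not drop events — but are excluded from behavioural
  averages, with a message.

**Wake activity** is counts per waking minute: window counts divided by
5 × (awake bins), reported as missing (never 0) for an all-asleep window.
Daily summaries run ZT0→ZT0, exclude the partial day of death, and satisfy
the conservation identity sleep + wake minutes = 5 × living unmasked bins
(asserted over every simulated fly-day in the tests). Age strata follow the
1–13-day ("young") / 14–30-day ("old") convention, configurable.

## Circadian profiles and anticipation

Population profiles average within fly across days first, then across
flies, so long-lived flies do not dominate — the fly, not the fly-day, is
the biological replicate; pooling all fly-days is available as a switch.
SEM uses the sample standard deviation across flies with $n-1$. For sleep,
fly-first averaging of the 0/1 sleep state equals the mean "percent of
flies sleeping" per bin when all flies are alive (a tested identity).

The field marks anticipation of light transitions on profile plots but
rarely defines it; `flychrono` adopts the standard ratio index: activity in
the last 3 h before the transition divided by activity in the last 6 h,
averaged over cycles (windows configurable). Flat activity gives 0.5, full
packing into the final 3 h gives 1.0, and a linear ramp across the window
gives 0.75; the index is invariant to rescaling all counts. Cycles with
incomplete, masked, or post-death windows are skipped; if no cycle has
nonzero 6-h activity the index is missing.

Actograms are double-plotted: row $d$ holds day $d$ beside day $d+1$, so
consecutive rows overlap by one day (the structural identity is tested);
with fewer than two complete days a single-plot matrix is returned with a
warning.

## Survival and count statistics

The Kaplan–Meier estimator and the two-group log-rank test are implemented
directly from the product-limit and hypergeometric formulas (the `survival`
package serves only as an independent cross-check in the test suite).
Ties are handled with the standard correction
$V_j = d_j \frac{n_{Aj}}{n_j}(1-\frac{n_{Aj}}{n_j})\frac{n_j-d_j}{n_j-1}$;
censored flies tied with deaths remain at risk for that time. "Median
survival" is the smallest event time with $\hat S(t)\le 0.5$ (boundary
inclusive). Because even-sized cohorts can sit exactly on $\hat S = 0.5$,
`median_survival(..., interpolate = TRUE)` offers the midpoint rule used by
common graphing software, which is how fractional medians such as 22.5 days
arise; the default stays with the step-function definition.

Group comparisons (eclosion percentages over replicate vials, haemocyte or
glia counts per unit) use the unpaired two-tailed Student t-test with
pooled variance, Welch behind a flag. When both groups are degenerate
(zero variance, different means) the t statistic is undefined; rather than
divide by zero, an exhaustive (or Monte-Carlo) label-permutation test on
the mean difference is reported and labelled as such — for 3 vs 3
replicates the exhaustive two-sided p is 0.1, the smallest attainable.
Haemocytometer counts convert to cells/mL as count ÷ squares × 10⁴ ×
dilution, with dilution 2 by default for the usual equal-volume
trypan-blue mix.

## DEG thresholds and overlaps

The differential-expression module consumes result tables (gene, log2
fold-change, adjusted p, read sum); it does not fit the DE model itself —
that is off-the-shelf upstream work, and the bespoke part is the
bookkeeping. Filters are inclusive at their boundaries: genes with read
sums **< 10** are removed (exactly 10 is kept); DEGs satisfy
|log2FC| **≥ 1** and padj **≤ 0.05**. Genes with missing padj (independent
filtering upstream) are excluded from both sets and tallied as untested.
Venn regions are exact set-algebra cardinalities, up- and down-regulated
genes separately, for two or three comparisons; inclusion–exclusion and
threshold monotonicity are tested properties.

## The synthetic-data model

The generator produces what the pipeline consumes — genuine
TriKinetics-dialect monitor files — with ground truth attached:

- **Sleep** is a two-state Markov chain with per-ZT-bin transition
  probabilities, piecewise constant over day and night. Defaults
  (wake→sleep 0.15/bin by day, 0.35 by night; sleep→wake 0.35 by day,
  0.12 by night) give a stationary sleep fraction near 0.30 by day and
  0.74 by night — a pronounced siesta plus consolidated night sleep,
  typical of male flies. `programmed_sleep_fraction()` computes the exact
  periodic stationary marginal of the configured chain by iterating the
  one-step marginal recursion to its fixed point; recovery tests compare
  scored sleep against this quantity, not against a simulation path.
- **Activity** is Poisson in awake bins, with a bimodal ZT template:
  Gaussian bumps (σ = 60 min) at ZT0 and ZT12 over a day baseline of 18
  counts/bin and a night baseline at 35% of it, damped by an ageing factor
  of 0.99 per day. The baselines are deliberately high enough that an
  awake bin is almost never silent (P(zero) ≤ e⁻⁶ at the night baseline),
  so sleep gates the activity process cleanly and scored sleep is
  recoverable to well within the 0.02 tolerance used in the tests. An
  optional noise rate adds false beam breaks during sleep to stress the
  scorer; it defaults to 0.
- **Lifespans** default to a Weibull with shape 4, parameterised by median
  (`lifespan_weibull()`). Fly mortality shows an ageing-type increasing
  hazard and sigmoid survival curves; a constant-hazard exponential at
  realistic medians would make cohorts of 24–28 flies nearly
  indistinguishable by log-rank (noncentrality ≈ 1 for medians 17 vs
  24.5 d censored at 30 d, power ≈ 0.19), which is not how such cohorts
  behave. The exponential remains available and is used for null
  calibration, where both groups share a median of 20 d.
- **Reproducibility**: each fly's RNG stream derives from
  (cohort seed, fly index), so enlarging a cohort never reshuffles
  existing flies; all generators are bit-reproducible given (config,
  seed). Post-death bins are hard-asserted silent.

What the simulator does *not* emulate: false beam breaks by default,
position within the tube, light-intensity or temperature effects,
inter-fly correlation, or monitor failures beyond status masking. Passing
recovery tests therefore demonstrates correctness of the scoring rules
under the model's assumptions, not robustness to every artefact of real
recordings — the noise knob and the masking path cover the first-order
deviations.

### Death-bin recovery and sleep

Death is observable only as the onset of terminal silence. If a fly falls
asleep and then dies, its last movement precedes the programmed death by
the length of that final sleep bout, so exact recovery of the death bin is
only a property of flies awake at death. Recovery tests therefore use a
wake-forcing chain (recovered bin within 1 of truth for every dying fly),
while for sleeping cohorts the tested property is the convention itself:
the recovered death bin never falls after the programmed one.

## Numerical and scale choices

Tolerances and sizes used by the test-suite simulations: sleep recovery
uses 3 chain settings × 24 flies × 30 days against the exact chain
marginal at tolerance 0.02; null log-rank calibration uses 2,000
two-cohort draws (n = 24 each, exponential median 20 d, censored at 30 d)
against the nominal 5% level; the lifespan-discrimination power check uses
200 simulated cohort pairs at 28 vs 24 flies; oracle-equivalence checks
use 10⁴ random vectors (bouts) and 10³ random cohorts (KM). These sizes
give Monte-Carlo error comfortably inside each tolerance while keeping a
full test run around a minute on one core. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch under
a caller-supplied seed and writes each resulting quantity with its problem
size.

## Known limitations

- Sleep latency, P(doze)/P(wake) transition statistics and other
  architecture metrics beyond bouts/duration/wake-activity are out of
  scope, as are period estimation and free-running (DD) analysis — the
  supported design is entrained 12:12 LD.
- The log-rank implementation is the two-group test; no stratification,
  trend test or Cox regression.
- No multiple-testing correction is applied across genotype-pair
  comparisons; raw pairwise p-values are reported.
- The DE fixture generator's p-values come from a Wald test that uses the
  generator's own known dispersion — adequate for exercising threshold
  bookkeeping, but it is not a DE method and should not be used as one.
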