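# flychrono

Sleep, circadian activity and survival analysis for *Drosophila* Activity
Monitor (DAM) data.

## What it is for

Infrared beam-break monitors (TriKinetics DAM systems) record the activity of
individual flies as counts per 5-minute bin, around the clock, for weeks.
From that single stream a behavioural lab extracts most of its phenotypes:

- **sleep** — the field's convention scores any ≥5 min of uninterrupted
  inactivity as sleep, so at 5-min acquisition a zero bin is a sleep bin;
- **rest bouts** — maximal runs of consecutive inactive bins;
- **death** — more than 24 h of terminal inactivity, with death placed at the
  fly's last movement; living flies are analysed over a 30-day horizon;
- **circadian structure** — population activity/sleep profiles in Zeitgeber
  time (ZT0 = lights-on; 12:12 LD by default), the bimodal morning/evening
  peaks separated by a midday siesta, anticipation of the light transitions,
  and double-plotted actograms;
- **survival statistics** — Kaplan–Meier curves, median survival, and the
  two-group Mantel–Haenszel (log-rank) test;
- plus the common companion assays: eclosion (larva-to-adult survival)
  percentages over replicate vials, haemocyte/glia count comparisons, and
  threshold-based differential-expression set overlaps.

`flychrono` implements this whole workflow as composable, tested R
functions, together with a synthetic-data generator that writes genuine
TriKinetics-format monitor files with known ground truth (programmed sleep
states and death times), so every scoring rule can be validated against what
was simulated.

## The models and statistics at the core

**Sleep/death scoring.** For counts $c_1,\dots,c_n$ in 5-min bins, bin $i$
is asleep iff it lies in a maximal run of zero-count bins of length
$\geq k$ (default $k=1$ bin $=$ 5 min). The fly is dead iff the terminal
zero run exceeds 24 h; the death bin is the first bin of that run.

**Kaplan–Meier.** With distinct event times $t_i$, $d_i$ deaths and $n_i$
at risk, $\hat S(t)=\prod_{t_i\le t}(1-d_i/n_i)$; median survival is the
smallest $t$ with $\hat S(t)\le 0.5$ (an optional midpoint rule handles
exact 0.5 plateaus, which is how fractional medians like 22.5 days arise).

**Log-rank (Mantel–Haenszel).** At each event time, observed group-A deaths
are compared with the hypergeometric expectation $E_j=n_{Aj}d_j/n_j$ and
variance $V_j=d_j\frac{n_{Aj}}{n_j}\left(1-\frac{n_{Aj}}{n_j}\right)
\frac{n_j-d_j}{n_j-1}$; then
$\chi^2=\left(\sum_j(O_j-E_j)\right)^2/\sum_j V_j$ on 1 df.

**The simulator.** Each fly is a two-state (wake/sleep) Markov chain with
per-ZT-bin transition probabilities; awake bins emit Poisson counts with a
bimodal ZT template (peaks at ZT0/ZT12, siesta trough, lower night
baseline) damped by a daily ageing factor; sleeping and post-death bins are
silent. Lifespans default to a Weibull with shape 4 (increasing,
ageing-type hazard) parameterised by median lifespan.

## Worked example

Simulate a short-lived genotype (median lifespan 17 d, n = 28) against a
control (median 24.5 d, n = 24), score the cohort, and compare survival:

```r
library(flychrono)
sch <- light_schedule("08:00")                       # ZT0 = 08:00, 12:12 LD
ctl <- sim_genotype_config("control", n_flies = 24,
                           lifespan = lifespan_weibull(24.5), schedule = sch)
mut <- sim_genotype_config("short_lived", n_flies = 28,
                           lifespan = lifespan_weibull(17), schedule = sch)
recs <- c(simulate_cohort(ctl, 101, n_days = 30)$recordings,
          simulate_cohort(mut, 102, n_days = 30, monitor = "M2")$recordings)

scored <- score_cohort(recs)     # death calls, sleep scoring, daily summaries
km_estimate(subset(scored$vitals, genotype == "control"))
#> <km_curve> control: n = 24, 20 events, median survival = 23.70486 days
km_estimate(subset(scored$vitals, genotype == "short_lived"))
#> <km_curve> short_lived: n = 28, 28 events, median survival = 15.05208 days

lr <- logrank_test(subset(scored$vitals, genotype == "short_lived"),
                   subset(scored$vitals, genotype == "control"))
#> log-rank chi-square = 24.80 (df 1), p = 6.37e-07
```

The scored cohort also feeds the circadian layer:

```r
prof <- population_profile(scored$bins, "sleep")  # 288 ZT bins per genotype
head(subset(prof, genotype == "control"), 3)
#>   genotype zt_bin zt_minutes      mean        sem  n
#> 1  control      0          0 0.5190309 0.01966504 24
#> 2  control      1          5 0.3907542 0.02448687 24
#> 3  control      2         10 0.3430872 0.02380748 24

anticipation_index(recs[[1]], "lights_off", vitals = call_death(recs[[1]]))
#> [1] 0.64   # 64% of the 6-h pre-ZT12 activity fell in the last 3 h
```

The KM medians recover the programmed 24.5/17-day lifespans up to sampling
noise at these group sizes, the log-rank test separates the genotypes
decisively, and the sleep profile shows the high-sleep night bins and the
morning dip after lights-on. `run_pipeline(run_config(seed = 1), out_dir =
"out/")` runs the same analysis end to end and writes tidy CSVs plus a
`summary.json`.

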