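---
title: "Models and design choices in ethosleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in ethosleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ethosleep quantifies sleep and behavior in single flies from epoch-level
positional tracking (10-s epochs of position `x` in mm from the food end and
maximal within-epoch velocity `vmax` in mm/s), and provides the population
statistics used in high-throughput sleep-restriction studies. This vignette
explains the models behind each stage, the tunable parameters, and the design
choices made where more than one reasonable definition exists. It states no
empirical result beyond what the package's test suite and
`scripts/acceptance.R` compute.

## Sleep scoring

**Immobility.** An epoch is immobile when `vmax < t_v`, with a *strict*
inequality. `t_v` has no universal value — it is a property of the upstream
tracker's validation — so every function takes it explicitly; the package
default is 1 mm/s.

**Stimulus masking.** During closed-loop deprivation the tube rotation itself
produces a velocity artifact, so epochs overlapping the 6 s after each
rotation onset (`mask_s = 6`) are masked. Masked epochs are *neutral*: they
neither count toward sleep nor break an immobility run, and a bout's duration
is the summed unmasked immobile time. Treating masked epochs as mobile would
abolish every immobility run under deprivation by construction, which
contradicts the residual sleep that imperfectly deprived animals retain;
treating them as immobile would manufacture sleep out of the artifact.

**The five-minute rule.** Maximal immobility runs strictly longer than
`min_bout_s = 300` s are sleep bouts, the whole bout counting (including its
first 300 s). Exactly 300 s is not sleep. The implementation is run-length
based and is checked exactly against a brute-force epoch-walking enumerator
on a thousand random sequences.

**Minute-level states.** Each complete minute is classified by an ordered
rule: *quiescence* if all of its epochs are immobile; otherwise
*micromovement* if the within-minute distance (sum of absolute position
differences at epoch resolution, i.e. five differences over six 10-s epochs)
is below `t_d = 15` mm; otherwise *walking*. The 15-mm threshold reflects the
bimodal distribution of per-minute distance separating in-place movement
(grooming, feeding, egg laying) from locomotion. Two conventions are fixed
here: the minute grid is anchored at recording start with incomplete trailing
minutes dropped, and quiescence requires sub-threshold velocity only (no
additional zero-displacement condition — velocity already implies it at this
resolution).

**Position normalization.** Positions are mapped to the food--cotton axis as
`(x - Q0.01(x)) / Q0.99(x - Q0.01(x))` using each animal's full recording
(per session, not pooled across tube changes). First and last percentiles
replace min/max so that rare tracking artifacts beyond the physical tube do
not stretch the scale; a few values fall slightly outside `[0, 1]` by
construction. A constant trace has no positional scale and is an error.

**Virtual beam monitor.** `vdam_rescore()` re-scores a trace the way a legacy
infrared device would see it: activity is a sign change of `x - midline`
between consecutive epochs, and the five-minute rule is applied to
crossing-free runs. Since a crossing requires movement, crossings are a
subset of mobile epochs, every velocity-based immobility run is contained in
a crossing-free run, and beam-based sleep can only overestimate
velocity-based sleep — a dominance the suite verifies per animal.

## The synthetic tracking generator

No processed recordings ship with the package, so every analysis is exercised
against a simulator that emulates the statistical structure the pipeline
assumes. It is a first-class, tested module, not a fixture.

**Bout process.** A fly alternates bouts of quiescence, micromovement and
walking (a semi-Markov alternating-renewal process). Bout *state* is drawn
with weights modulated by a circadian drive; bout *duration* is lognormal per
state. Quiescence durations are heavy-tailed (`meanlog = log(400)`,
`sdlog = 1.1` seconds) so that sleep bouts beyond the 300-s rule — and beyond
the 1000-s triggers of deprivation protocols, which select on bout length —
occur naturally. Micromovement and walking bouts are short
(`log(60)`/`log(30)`, `sdlog = 0.6`). A bout-level rather than epoch-level
Markov model was chosen precisely because trigger-ladder experiments are
sensitive to the full bout-duration distribution.

**Circadian drive.** Activity weights are multiplied by
`1 + A * (vm(zt; 0) + vm(zt; 12))`, two von Mises-shaped peaks at lights-on
and lights-off with concentration `peak_kappa = 4` and amplitude
`circadian_amplitude` (default 1). Amplitude 0 emulates a clock mutant in
constant darkness: state choice becomes time-homogeneous and the activity
profile is flat. No functional form is canonical for this drive; the bimodal
von Mises sum is the simplest shape with the right crepuscular peaks.

**Calibration.** The long-run scored-sleep fraction of the process has a
closed renewal-theory form: with embedded-chain stationary probabilities
$\pi_s$ and lognormal partial expectations,
$f = \pi_q\,E[D\,1\{D>300\}] / \sum_s \pi_s E[D_s]$, averaged quasi-statically
over the circadian cycle (bouts are minutes, the modulation is hours, so the
approximation is good — the suite checks it against long bout-level
simulations to 0.02). `calibrate_quiescence_weight()` inverts this map, and
`sim_config()` uses it so that default configurations hit the baseline means
of the population being emulated: 618.5 min/day for males, 299.2 for females.
The calibration targets the *median* individual; the per-animal lognormal
effect (below) spreads the population around it.

**Individuals.** Each fly draws one multiplicative lognormal factor
(`indiv_quiescence_scale = 0.8` on the log scale) applied to its quiescence
durations. This single knob produces both the wide sleep distribution —
near-sleepless to near-continuous sleepers — and the stability of an
individual's sleep across recordings (week-to-week R² above 0.6 in the
acceptance suite, with 0.96 observed at the tested sizes).

**Sex and mating.** Females get a higher micromovement weight than males
(1 vs 0.55) and a lower sleep target, reproducing the direction of the
sexual dimorphism in micromovement time. `mated = TRUE` multiplies the
micromovement weight by 2.5 and shifts `food_attraction` (probability that a
micromovement bout sits within 4 mm of the food) up by 0.3 from its default
0.5 — the mating switch as a feeding/egg-laying shift toward the food end.

**Emission.** Quiescent epochs draw `vmax` uniformly below 0.25 mm/s with
constant position. Micromovement epochs draw 1.2–3 mm/s with ±0.5 mm jitter
around the bout's base position. Walking epochs draw 5–20 mm/s and bounce
between tube ends, always landing opposite the previous sample — so walking
is visible to the virtual beam monitor. Positions are sampled at epoch ends;
`vmax` is the maximum over everything active in the epoch, so an epoch is
mobile as soon as any active bout touches it.

**Closed-loop deprivation.** A monitor accumulates continuous immobility;
at `trigger_s` it logs a 1-s rotation (position unchanged — the tube spins
about its axis — velocity spiking, hence masked downstream). With probability
`compliance` the quiescence bout terminates and the startled fly walks for
`startle_s = 25` s; otherwise the bout continues and the clock restarts.
Compliance 1 is the perfect-deprivation limit in which any trigger below
300 s provably abolishes scored sleep; the default 0.95 leaves the realistic
near-total-loss regime reachable. `trigger_s = Inf` is the exact
no-deprivation sentinel. `startle_s = 0` gives the idealized animal that
re-enters quiescence immediately, whose rotation count per hour is exactly
`floor(3600 / (trigger + 1))`.

**Cohorts and lifespans.** `simulate_cohort()` splits per-fly seeds from the
master seed with a counter (reproducible under appending flies), scores each
fly's sleep over its first 10 days from the latent bout sequence, and draws
lifespans from sex-specific Weibulls (shape 5; scales put control medians at
46.0/41.0 days for males/females) shifted by `sleep_effect` days per hour of
daily sleep — default 0, the null under which the lifespan regression should
find nothing. For large replicated designs, `method = "analytic"` draws each
fly's sleep from the generator's own renewal-theory marginal instead of
simulating bouts; the two paths agree (r > 0.9 on matched seeds) and the
analytic one is orders of magnitude faster.

**What the generator does not emulate.** No video, no biomechanics of the
rotation, no mechanistic feeding or egg-laying model, no social interaction,
and no homeostatic feedback: deprived simulated flies do not rebound, which
is deliberate — rebound tests instead *inject* a known sleep surplus
(`inject_sleep_surplus()`, which overwrites leading window epochs with
quiescence after accounting for the sleep the animal would have obtained
anyway, so the surplus is exact per fly up to a ceiling effect when the
window is already nearly full). Passing tests therefore show that the
pipeline measures correctly on data with the assumed structure, not that
real flies behave this way.

## Homeostatic rebound

Rebound is estimated against a control-calibrated expectation: on controls,
ordinary least squares of rebound-window sleep `R` on baseline-window sleep
`B` (`beta = Cov(R,B)/Var(B)`, `alpha = mean(R) - beta*mean(B)`; covariance
normalization cancels as long as it is consistent). Each treated animal's
excess is `H = R - (alpha + beta B)`; control residuals average exactly zero.
Windows are ZT 0–3, extracted through the shared ZT mapping with half-open
intervals; the baseline day defaults to the last pre-treatment day. The group
mean `H` carries a basic-bootstrap CI; when the control pairs are supplied,
the bootstrap resamples controls and treated jointly so the interval carries
the calibration uncertainty — without this the interval is conditionally too
narrow and its null coverage drops well below nominal (observed ~0.79 vs
~0.96 at n = 60 + 60). Significance is the CI excluding zero; no p-values,
matching estimation-based practice. Multi-day rebound is reported
descriptively per day, not modeled.

## Behavioral fingerprints

For each animal, the 96 quarter-hour ZT intervals get an empirical
distribution over the three minute-states, pooled over complete days
(average-then-distance; distributions are built from minute states, not
epoch flags). The distance between animals is the mean over intervals of the
Bhattacharyya distance `BD = -log(sum(sqrt(p q)))`. BD is symmetric with
`BD(p,p) = 0` but violates the triangle inequality — a divergence, not a
metric — and the suite documents a concrete violation. Disjoint supports give
`BC = 0`; BD is capped at `-log(1e-6)` so clustering stays finite while
preserving order. Trees come from classical UPGMA (leaf-count-weighted
arithmetic-mean linkage), implemented here with a deterministic tie-break
(lexicographically smallest leaf label of the candidate pair) and checked
against an independent reference implementation; node heights are half the
merge distance, so cophenetic distances equal merge distances, which is also
the convention of the Newick writer. Ternary coordinates for the
"time × simplex" trajectory use vertices (0,0), (1,0), (1/2, √3/2) with an
exact inverse.

A note on phenotype-separation scenarios: at moderate sleep levels the
alternating-bout structure makes the quiescence initiation weight small
(quiescence bouts are long, hence rare), so any appreciable third-state
weight routes activity through it and different phenotype parameterizations
collapse onto similar minute-state compositions. The packaged
cluster-separation scenario therefore contrasts a mated-like pure micromover
with a pure walker (minority activity weight zero, shorter quiescence bouts),
which is what "well-separated behavioral parameters" means once that
coupling is understood.

## Circadian variance decomposition

Rotation logs are binned on ZT-aligned half-open bins (default 30 min,
matching the resolution of sleep traces) and decomposed additively by the
classical moving-average method (`stats::decompose`): trend = centered moving
average over one 24-h period; periodic = per-phase mean of the detrended
series, re-centered; residual = remainder; `observed = periodic + trend +
residual` exactly on the support where the trend is defined. Variance
fractions are `Var(component)/Var(observed)` on that trimmed support — the
only definition under which the three fractions can sum near one. The
routine behind the original figures is unnamed in the literature this
package serves, so the classical decomposition was chosen for its exactness
and testability (a LOESS variant would be a drop-in extension); fractions on
real data are consequently not reproduction targets, only synthetic recovery
is. Note an identifiability limit: the per-phase mean retains residual
variance of order 1/(number of cycles), so `f_periodic` has a noise floor of
about 0.1 for a 9.5-day series; the constant-darkness emulation scenario
runs 12 days (pooled over 8 flies) so that a genuinely flat clock yields
`f_periodic` clearly below that floor.

## Population statistics

**Basic bootstrap.** `(2θ̂ - q_hi, 2θ̂ - q_lo)` with 1000 resamples by
default, deterministic under a fixed RNG state; checked against the boot
package and for nominal coverage (93–97% band at n = 50).

**Kaplan–Meier.** Product-limit estimation via the survival package with
log-log transformed Greenwood bands (the band transform is unstated in the
practice this mirrors; log-log is the standard censoring-aware choice). The
median is the first time S(t) ≤ 0.5; its CI comes from intersecting the
bands with 0.5 (Brookmeyer–Crowley style). With no censoring the curve
equals the empirical survivor function exactly.

**Lifespan regression.** `lifespan ~ sleep * sex` by OLS after the inclusion
filters: untreated animals only, lifespan ≥ 20 days (removing moribund data),
right-censored animals excluded; sleep is the mean over the first 10 days.
Removed counts are reported per filter. Per-sex slopes (days of life per
hour of daily sleep) carry basic-bootstrap CIs from row resampling. The "×"
is the full factorial interaction, so per-sex slopes equal the within-sex
simple regressions.

## Problem sizes and numerical conventions

The test suite runs the analyses at sizes chosen to make each property
decisive yet quick: 1000 random sequences for the sleep-rule oracle; 60 + 60
flies × 2 days for rebound recovery (±10 min on an injected 40-min surplus);
500 pair-level replicates for bootstrap coverage; 30 flies × 5 days per
sleep-fraction target (±0.05); 60 flies × 14 days for week-to-week
persistence; 50 flies × 2 days for beam-monitor dominance; 100 replicated
cohorts of 60 + 60 (analytic path) for regression-null coverage; and a
five-trigger ladder (20–1000 s, 16 flies per trigger plus 16 shared mock
controls, three days each) for the deprivation directions, where sleep lost
is paired against each fly's own baseline night to remove between-individual
sleep-propensity variance. All time handling is 0-based seconds with
half-open `[start, end)` intervals, ZT0 day boundaries, quantile type 7, and
single-stream seeding (per-fly seeds split from a master seed by a counter).

## Known limitations

Scored sleep at epoch resolution loses up to two epochs per bout at bout
boundaries relative to the latent process (about 1–2% at typical bout
lengths). The renewal calibration is quasi-static in the circadian drive and
exact only at amplitude 0. The simulator's mating switch changes rates and
position, not temporal fine structure. The ladder's rebound column estimates
`H` for a generator without a homeostat, so its expectation is zero there by
design. Native tracker databases are not read; the CSV interchange format is
the only input dialect.
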