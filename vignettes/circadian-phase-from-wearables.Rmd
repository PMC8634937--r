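---
title: "Estimating circadian phase from wearable data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating circadian phase from wearable data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Consumer wearables record two physiological streams almost continuously:
heart rate and step counts. Each carries circadian information of a different
provenance. The ~24-h rhythm in heart rate (CRHR) originates largely in the
sinoatrial node and reflects peripheral circadian physiology; activity, used
as a surrogate for light exposure, drives models of the *central* pacemaker
whose phase is conventionally reported as dim light melatonin onset (DLMO).
When the two estimates are derived independently from the same recording,
their agreement — or growing disagreement after a behavioural disruption such
as a lockdown — measures internal circadian desynchrony in the field, without
a laboratory visit.

`circwear` implements both estimators and the alignment analysis end to end,
together with a synthetic cohort generator that provides known ground truth
for every stage.

## The heart-rate model

Heart rate in each 5-min bin is modelled as

$$\mathrm{HR}(t) = a - b\cos\!\Big(\frac{\pi}{12}(t - c)\Big) + d\,A(t) + \epsilon(t),$$

where $a$ is the basal (mesor) heart rate in bpm, $b \ge 0$ the circadian
amplitude, $c$ the clock time of the circadian HR minimum (the phase marker,
treated circularly modulo 24 h), $d$ the heart-rate increment per step of
in-bin activity $A(t)$, and the error follows a first-order autoregression
$\epsilon_{t+1} = k\,\epsilon_t + N(0, \sigma^2)$. Within each contiguous run
of usable bins the first residual is scored under the stationary marginal
$N(0, \sigma^2/(1-k^2))$; the AR chain resets across any gap (missing data,
sleep, day boundary), since carrying noise memory across a multi-hour gap has
no physical meaning.

Usable bins are those that are worn, not flagged as sleep, and carry both
streams. Sleep exclusion matters: without it the fitted "circadian" dip
simply mirrors the sleep-wake pattern.

### Sequential Bayesian fitting

The six parameters are estimated per day with an affine-invariant ensemble
sampler (stretch move, scale $a=2$). The daily budget is 100,000 target
evaluations with the first half of each chain discarded (the `"full"`
profile: 50 walkers); a `"fast"` profile (5,000 evaluations, 20 walkers) is
used throughout the test suite and calibration studies. Walkers start in a
small ball around the deterministic cosinor least-squares estimate — the
linearisation $-b\cos(\omega(t-c)) = A\cos\omega t + B\sin\omega t$ makes
$a, b, c, d$ an ordinary regression — which is standard practice for
ensemble samplers and shortens burn-in without biasing the equilibrium
distribution.

Day 1 uses a weakly informative prior scale-matched to human heart rate:
$a \sim N(70, 15^2)$ bpm, $b \sim \mathrm{HalfNormal}(10)$ bpm,
$c \sim U[0, 24)$, $d \sim N(0, 0.5^2)$ bpm/step, $k \sim U[0,1)$,
$\sigma \sim \mathrm{HalfNormal}(10)$ bpm. Each subsequent day's prior is a
moment-matched multivariate normal approximation of the previous posterior
(phase unwrapped about its circular mean), with all standard deviations
inflated by 1.5 so the chain retains enough freedom to track genuine phase
drift. The prior family, walker count, transfer mechanism and gap handling
are design choices of this package; they are exposed in `crhr_config()` and
`moment_match_prior()` rather than hard-coded.

The daily phase estimate is the circular mean of the posterior `c` samples;
uncertainty is the equal-tailed 80% interval computed by unwrapping the
samples about their circular mean, taking plain quantiles, and re-wrapping.
Intervals may straddle midnight.

## The pacemaker model

The central clock is modelled by the established limit-cycle oscillator of
the human circadian pacemaker,

$$\dot x = \frac{\pi}{12}\Big[x_c + \mu\Big(\frac{x}{3} + \frac{4x^3}{3} - \frac{256 x^7}{105}\Big) + B\Big],$$
$$\dot x_c = \frac{\pi}{12}\Big\{q B x_c - \Big[\Big(\frac{24}{0.99729\,\tau_x}\Big)^2 + k B\Big] x\Big\},$$
$$\dot n = 60\,[\alpha(1-n) - \beta n],$$

with photic drive $\hat B = G\alpha(1-n)$, state gating
$B = (1-0.4x)(1-0.4x_c)\hat B$, and activation rate
$\alpha = \alpha_0 (I/I_0)^p$. Parameter values: $\mu = 0.13$, $G = 19.875$,
$\alpha_0 = 0.16$, $I_0 = 9500$ lux, $p = 0.6$, $\tau_x = 24.2$ h,
$k = 0.55$, $\beta = 0.013$. The factor 60 converts the per-minute
photoreceptor rates onto the hour time base, and the 0.99729 correction
makes the realized free-running period equal $\tau_x$ (verified to
24.200 h by the test suite). The coefficient $q$ is not part of the printed
parameter set; we use $q = 1/3$, the value in the established lineage of
this model, and flag it prominently in `clock_params()`.

Integration is fixed-step RK4 at the 5-min data grid with illuminance held
constant within each bin, which makes trajectories bit-reproducible and
exactly aligned with the binned input; step-halving changes a 30-day
endpoint by under $10^{-6}$, and the dark dynamics agree with an adaptive
reference solver to $10^{-5}$.

Because wearables do not measure light, activity stands in for it:
illuminance = 1 lux per step per bin, capped at 1000 lux, with sleep-flagged
and missing bins dark. This linear-capped map is a declared stand-in — the
true activity-light relation is unknown — and is configurable
(`activity_to_light()`); every pipeline run records the mapping used.
Initial conditions come from entraining the oscillator to the subject's own
mean daily light template until the daily state map reaches a fixed point
(`limit_cycle_ic()`, tolerance $10^{-6}$, cap 90 days).

The phase marker is extracted per day as the time of the minimum of $x$
(CBTmin, refined parabolically between samples); predicted
DLMO = CBTmin − 7 h, the conventional phase relation for this model family,
also configurable.

## Alignment and desynchrony

CRHR and DLMO phases differ systematically; a fixed −4.4 h offset (the mean
laboratory DLMO-minus-CRHR difference) is applied to the CRHR interval
before containment is tested. A day is *aligned* when the predicted DLMO
time falls inside the shifted 80% CRHR interval, with circular containment
that handles midnight-wrapping intervals. Per subject we report the percent
of days aligned and the mean circular absolute DLMO-CRHR difference in the
35 days before and after the disruption date (the event day belongs to
neither window).

The paired pre/post comparison uses a two-sided paired t-test with the
Wilcoxon signed-rank test reported alongside; group phase shifts (circular
mean of post-window phases minus pre-window, per subject, unweighted) are
summarised by mean ± SEM with one-sample t-tests and Welch tests between
groups; no multiplicity correction is applied. The data-quantity/uncertainty
relation is the Pearson correlation between per-day usable-bin counts and
interval half-widths (wear hours are available as an alternative metric).
Whether the source analyses used exactly these tests is not documented; we
state ours explicitly and report exact p-values.

## The synthetic cohort

The generator emulates the structure of a social-distancing wearable cohort
with known truth: 35 days on each side of the event; a smooth mid-afternoon
activity bump totalling ~7,000 steps/day, 18% lower after the event; an
8-h sleep window with zero steps; heart rate sampled at irregular intervals
(log-uniform 1-10 min, as consumer watches report) from the cosinor model
with AR(1) noise; a nightly 6-8 h charging gap inside the sleep window; and
10% random daytime dropout of HR readings. After the event the whole
schedule shifts by a per-subject amount drawn from
$N(\text{group mean}, \text{group sd})$ with defaults
(−0.93, +1.26, +0.05) ± (0.85, 0.45, 0.53) h for the under-30, 30-45 and
over-45 groups, and in a configurable fraction of subjects (default 51/72)
the HR phase additionally drifts away from the schedule at 0.05-0.25 h/day
(capped at 6 h) — the internal-desynchrony signal.

What the generator does *not* emulate: heart-rate variability, exercise
bouts, meals, seasonality, timezone travel, or device-specific sampling
quirks beyond irregular intervals. Passing tests on synthetic cohorts
therefore demonstrate the *computational* correctness and calibration of the
estimators under the stated noise model, not their physiological validity on
real recordings.

## Numerical choices and problem sizes

* Binning: half-open 5-min bins, HR averaged, steps summed (counts add;
  averaging partial-interval counts would depend on device cadence). Fits
  evaluate the cosinor at bin centers, since a bin mean represents its
  midpoint — using left edges would bias the phase by 2.5 min.
* Sleep detection: per noon-to-noon window (so an episode straddling
  midnight stays whole), the longest run of missing-or-zero-activity bins,
  at least 4 h, ties to the earliest start. The 4-h threshold and
  zero-activity criterion are configurable choices.
* Calibration study: 200 synthetic days drawn from the fitting prior, fast
  sampler profile; empirical 80%-interval coverage is 82% (seeded run,
  binomial s.e. ≈ 2.8 points). Reproduce with
  `phase_calibration_study(200, seed = 1)`.
* Group-shift recovery: a seeded 30-subject cohort (10 per group, 10 days
  per window, no desynchrony, reduced sampler budget) recovers each imposed
  group shift within 2 SEM. Window length and budget are the package's own
  test-scale choices; `cohort_spec()` defaults remain 35/35 days.
* Degenerate inputs: a day with under 24 usable bins is skipped and its
  prior carried forward (flagged in the phase track); a point-mass posterior
  yields a zero-width interval; an all-missing day is an error for the
  likelihood and a skip for the fit.

## Known limitations

The activity-light mapping and the CBTmin-DLMO offset are fixed conventions,
not fitted; individual differences in intrinsic period or light sensitivity
are not modelled. The −4.4 h CRHR offset is taken as given rather than
re-estimated. Heart-rate phase estimates degrade gracefully but markedly
with wear time (the package reproduces the negative data-quantity/
uncertainty correlation); sparse wearers yield intervals too wide to be
informative. AR(1) innovations are Gaussian; heavy-tailed sensor artifacts
beyond the (20, 250) bpm plausibility gate are not handled.
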