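# circwear

Circadian phase estimation and internal-desynchrony analysis from consumer
wearable data.

Wearables record heart rate and step counts around the clock. `circwear`
derives two *independent* circadian phase markers from one recording:

* **CRHR** — the circadian rhythm in heart rate. Each day's heart rate is
  modelled as
  `HR = a − b·cos(π/12·(t − c)) + d·Activity + ε`, with AR(1) errors
  `ε(t+1) = k·ε(t) + N(0, σ²)`. The six parameters are sampled daily with an
  affine-invariant ensemble MCMC (Goodman–Weare stretch move; 100,000 target
  evaluations per day, burn-in 0.5), each day's posterior feeding the next
  day's prior. The phase marker is `c`, the clock time of the circadian HR
  minimum, with an equal-tailed circular 80% credible interval.
* **Predicted DLMO** — dim light melatonin onset predicted by a limit-cycle
  oscillator model of the human circadian pacemaker (state `x`, `x_c`, `n`;
  intrinsic period τₓ = 24.2 h) driven by activity as a light surrogate.
  The daily minimum of `x` (CBTmin) minus 7 h gives the predicted DLMO.

A fixed −4.4 h offset reconciles the two markers' mean difference; a day is
*aligned* when the predicted DLMO falls inside the shifted CRHR interval.
Tracking percent-days-aligned before and after a disruption date (e.g. a
self-reported social-distancing onset) quantifies internal desynchrony
between peripheral and central circadian rhythms — per subject and per age
group. A synthetic cohort generator with full ground truth (phase
trajectories, group shifts, desynchrony drift, charging gaps, irregular
sampling) makes every stage testable end to end.

Intended users: chronobiology and digital-health researchers working with
heart-rate/actigraphy exports who need field estimates of circadian phase
and their uncertainty.

## Worked example

```r
library(circwear)

# a small synthetic cohort: 3 subjects, 8 days either side of the event
spec <- cohort_spec(n_per_group = c(under30 = 1, `30to45` = 1, over45 = 1),
                    days_pre = 8, days_post = 8, seed = 101, dropout = 0.05)
cohort <- generate_cohort(spec)

cfg <- run_config(seed = 101, profile = "fast", inclusion_policy = NA,
                  crhr = crhr_config("fast", seed = 101,
                                     n_total_evals = 2000, n_walkers = 15),
                  alignment = alignment_config(pre_window_days = 8,
                                               post_window_days = 8,
                                               min_days_per_window = 3))
report <- run_cohort(cohort, cfg)

head(report$subjects$S001$crhr$track[, 1:6], 4)
#>         date phase_h ci_low_h ci_high_h half_width_h n_bins
#> 1 2020-02-08    4.37     3.97      4.88        0.455    155
#> 2 2020-02-09    4.40     4.15      4.62        0.233    159
#> 3 2020-02-10    4.28     4.07      4.53        0.229    151
#> 4 2020-02-11    4.48     4.31      4.68        0.185    157
```

Subject S001 was generated with a true HR-minimum time of 4.20 h; the daily
estimates sit within a few tenths of an hour and the interval narrows as the
day-chained prior accumulates information (0.46 h on day 1, ~0.2 h after).

```r
report$group_shifts$groups
#>     group n mean_shift_h sem_h
#> 1  30to45 1        1.015    NA
#> 2  over45 1        0.060    NA
#> 3 under30 1       -0.290    NA
```

The recovered post-event phase shifts track each subject's drawn shift
(group defaults −0.93, +1.26, +0.05 h; SEM needs more than one subject per
group).

The −4.4 h CRHR offset is the *laboratory* population constant; a synthetic
cohort has its own CRHR-DLMO geometry (here the measured mean DLMO-minus-CRHR
offset is −8.4 h, because the activity-as-light surrogate is dim and the
generated sleep schedule late). Re-running the alignment with the cohort's
measured offset:

```r
offset <- mean(sapply(report$subjects, function(s) {
  tr <- s$crhr$track; dl <- s$dlmo_track
  common <- intersect(as.character(tr$date), as.character(dl$date))
  mean(circular_diff(dl$dlmo_h[match(common, as.character(dl$date))],
                     tr$phase_h[match(common, as.character(tr$date))]))
}))                                            # -8.36 h
cfg$alignment$crhr_shift_h <- offset
report2 <- run_cohort(cohort, cfg)
report2$headline
#> $pct_aligned_pre   25.0
#> $pct_aligned_post   4.76
#> $p_paired           0.314
#> $r_uncertainty_data -0.059
```

Alignment drops after the event — the generator gave most subjects a
post-event heart-rate phase drift, and the analysis detects the resulting
desynchrony (the paired p-value is limited by n = 3 here).

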