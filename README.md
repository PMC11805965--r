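# reeftrack

Movement analysis for acoustic telemetry studies of site-attached reef fish.

Fisheries researchers tracking reef fish (snappers, groupers and kin) on
dense receiver arrays face the same chain of questions study after study:
how accurate are my triangulated positions, and which should I discard?
Where was each fish, hour by hour? Which fish died, which were caught, which
were eaten, and which left? How long do fish stay — and what does that imply
for marine protected areas and local depletion? How far do the leavers go?
reeftrack implements that chain as composable, tested R functions: every
stage takes a data frame and returns a tibble, so analyses read as ordinary
dplyr pipelines.

## What is inside

* **Position-error calibration** — per-bin 2DRMS against vendor HPE from
  known-location reference tags,
  `2DRMS_i = 2 * sqrt(mean(dx^2 + dy^2))`, with upper-5% HPE censoring,
  AICc-based selection between pooled and region-specific relationships,
  and threshold filtering (`compute_2drms_bins()`, `fit_2drms()`,
  `filter_positions()`).
* **Detection range** — maximum-likelihood logistic range curves
  `p(d) = p0 / (1 + exp(s (d - d50)))` from Bernoulli range trials
  (`estimate_range()`).
* **Centers of activity** — receiver-mean COAs in 30-min or 4-h bins with
  spurious-detection removal and the final-date retention exception
  (`compute_coas()`), plus residence indices and daily detection gaps.
* **Fate assignment** — rule-based terminal classification (survived,
  emigrated, mortality, predated, captured, unknown) from depth-variance
  stationarity, predator-like movement signatures, edge-exit runs,
  recaptures and glider relocations, with a 3-day tagging-recovery window
  (`classify_fates()`).
* **Site fidelity** — right-censored event-history analysis with emigration
  as the event: Kaplan-Meier product-limit and Weibull
  `S(t) = exp(-(t/lambda)^k)` estimators, residence quantiles, and a
  binomial daily-emigration-probability GLM
  (`E_i ~ Binom(n_i, p_i)`, `logit(p_i) = X_i beta`) with atmospheric
  pressure forcing and the projection
  `S(t) = (1 - p_r)^(t - D_L) (1 - p_l)^(D_L)`
  (`product_limit()`, `fit_weibull()`, `fit_dep()`, `project_fidelity()`).
* **Space use** — Brownian-bridge utilization distributions on a 10 m grid
  at daily and tracking-duration scales, isopleth areas, high-use centroids
  (90% contour, >= 100 m^2) and shift detection (`daily_ud()`,
  `tracking_ud()`, `ud_contour()`, `find_centroids()`, `detect_shifts()`).
* **Movement** — per-step rates with worst-case error correction, and
  long-distance movements (> 2,000 m within 48 h) from positions or COAs
  (`movement_rates()`, `detect_ldm()`).
* **Dispersal** — per-fish maximum pairwise distance with right-censoring of
  unrelocated emigrants, and censored maximum-likelihood fits of Burr XII
  (`S(x) = (1 + (x/s)^c)^(-k)`), Weibull, lognormal, gamma and exponential
  kernels ranked by AIC, with exceedance probabilities (`max_dispersal()`,
  `fit_kernels()`, `exceedance()`).
* **A seeded synthetic-telemetry generator** — receiver grids, true
  Ornstein-Uhlenbeck tracks with competing terminal fates, logistic
  detections, and HPE-scaled position error (`sim_config()`,
  `simulate_telemetry()`), so every estimator above is validated against
  known ground truth.

Fitted objects carry `tidy()`, `glance()`, `predict()` and `autoplot()`
methods.

## Worked example

Simulate a 30-fish, 90-day study, then run the fate and fidelity chain:

```r
library(reeftrack)
library(dplyr)

cfg <- sim_config(seed = 42, n_fish = 30, study_days = 90,
                  transmission = list(delay_min_s = 300, delay_max_s = 900),
                  hazards = list(base_emigration_per_day = 0.004,
                                 mortality_per_day = 0.002,
                                 capture_per_day = 0.002,
                                 predation_per_day = 0.001,
                                 low_pressure_multiplier = 1))
sim <- simulate_telemetry(cfg)

coas  <- compute_coas(sim$detections, sim$receivers, bin_minutes = 30)
fates <- classify_fates(coas, NULL, sim$receivers)
count(fates, fate)
#> # A tibble: 4 × 2
#>   fate          n
#>   <chr>     <int>
#> 1 captured      5
#> 2 emigrated     8
#> 3 mortality     4
#> 4 survived     13

eh <- build_event_histories(fates, unknown_treatment = "censored")
product_limit(eh)
#> product_limit site-fidelity curve: n = 30, events = 8
#>   S(365) = 0.690 [0.468, 0.835]

estimate_range(simulate_range_trials(cfg, n = 5000))
#> Logistic detection range: p0 = 0.977, d50 = 341.9 m, steepness = 0.0119 (n = 5000)
```

Reading the output: 8 of 30 fish emigrated within the 90-day window; the
product-limit curve estimates that 69% [47%, 84%] of fish remain at the end
of tracking (the step curve is flat past the last event, so the printed
S(365) equals S at 90 d here — extrapolation beyond the data is what
`fit_weibull()` is for). The fitted 50% detection range of 342 m recovers
the generator's true 346 m within sampling error.

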