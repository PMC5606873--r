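# intervalmix

Estimating the mean and variance of event intervals from time-ordered
observations in which some events were missed.

## The problem

Many field protocols record the times of recurring, short events on a focal
individual — defecations of grazing geese, dives, nest visits — and the
quantity of interest is the mean inter-arrival interval μ and its SD σ (or
their inverse, the event rate). When the observer or recording device misses
an arrival with probability *p*, the intervals on either side of the missed
arrival merge, so observed intervals accumulate at multiples of the true
interval. Sample statistics of the observed intervals are then biased upward
— at *p* = 0.3 by a factor ≈ 1.3 for the mean and ≈ 3 for the SD — and
apparent differences between sites or groups may reflect nothing more than
differences in observation conditions.

## The model

Fundamental (zero-miss) intervals are gamma with mean μ and SD σ. An
observed interval spans exactly *i* consecutively missed arrivals with
geometric probability πᵢ = pⁱ − pⁱ⁺¹, giving the constrained mixture density

φ_obs(x | μ, σ, p) = Σᵢ πᵢ · Gamma(x | mean (i+1)μ, SD √(i+1)·σ)

in which every component mean, width and weight is tied to (μ, σ, p).
Extensions: a within/between-subject split of σ (component widths
√(iσ_w² + σ²)), a random Poisson background fraction *f* of arrivals
(an exponential-limit component sharing μ and p), a normal component family
for near-regular processes, and truncation/renormalization of the whole
mixture at the observation bout length. Parameters are estimated by maximum
likelihood with log/logit links; nested models are compared by deviance
tests, so "was anything missed?" is itself a statistical test (p free vs
p = 0).

## Worked example

Simulate one observation session (100 observed intervals, true μ = 250 s,
σ = 50 s, missed-event probability 0.3, 900 s bouts), then fit and correct:

```r
library(intervalmix)

cfg <- sim_config(mu = 250, sigma = 50, p = 0.3, n_intervals = 100,
                  n_runs = 1, seed = 7)
set.seed(cfg$seed + 1)
obs <- simulate_observed_intervals(cfg)
c(mean(obs$interval), sd(obs$interval))
#> 340.3 169.1        # naive statistics: badly inflated

fit <- fit_intervals(obs$interval, spec = interval_spec(trunc = 900))
fit
#> Observed-interval model fit (gamma family)
#>   mu            255.2
#>   sigma         49.41
#>   p            0.2946
#>   f                 0 (fixed)
#>   log-likelihood -607.792 on 100 observations (3 free parameters)
```

The corrected estimates recover the generating values (μ̂ = 255, σ̂ = 49,
p̂ = 0.29) from data whose raw mean was 340. The observer-effect test
confirms detections were missed:

```r
null <- fit_intervals(obs$interval,
                      spec = interval_spec(trunc = 900, fixed = list(p = 0, f = 0)))
deviance_test(fit, null)
#> Deviance test: D = 57.348, df = 1, p = 3.651e-14
```

Classify each interval by its most likely missed count, fold multiples back
to fundamentals, and convert to a rate:

```r
cls <- classify_intervals(fit)
table(cls$i_star)
#>  0  1  2
#> 73 21  6

interval_to_rate(fit, time_unit = 3600)
#> rate 14.10 events per hour, sd 2.73
```

With repeated measures per subject, `fit_intervals_within()` additionally
partitions σ into within- and between-subject components, iterating the fit
with a σ_w estimate from the classified fundamental intervals.
`compare_means()` / `compare_variances()` test two fitted groups with
effective sample sizes discounted by the background fraction, and
`run_recovery_study()` runs full simulation-based validation studies. A
command-line front end covering fit / simulate / classify / compare / rate
ships at `inst/cli/intervalmix.R`.

## Vignette

`vignettes/interval-models-with-missed-detections.Rmd` documents the model,
the estimation and classification procedures, the simulator design, the
numerical choices, and known limitations (notably the upward bias of the
fundamental-subset σ_w estimator when σ_w is small relative to the
between-subject spread).
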