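Package: intervalmix
Title: Interval Analysis of Time-Ordered Event Data with Missed Observations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the mean and variance of inter-arrival intervals from
    time-ordered event observations in which a fraction of events is missed
    by observers or recording devices. Missed detections produce observed
    intervals at multiples of the true interval; the observed-interval
    distribution is modelled as a constrained gamma (or normal) mixture whose
    components correspond to 0, 1, 2, ... consecutively missed events, with
    geometric mixing weights governed by a single missed-event probability.
    Provides maximum-likelihood fitting with link functions, likelihood-ratio
    model comparison, classification and folding of intervals onto their most
    likely fundamental value, within/between-subject variance partitioning,
    group comparison of interval means and variances with detection-adjusted
    degrees of freedom, interval-to-rate conversion, and a simulator of
    Bernoulli-thinned arrival processes for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
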