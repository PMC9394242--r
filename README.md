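# dictime

Dictation-time analysis from Radiology Information System (RIS) timestamps.

Most RIS installations with integrated speech recognition log, for every
report, the time the dictation started and the time the report was first
saved. The interval between the two — the *dictation time* — is a free,
large-sample proxy for radiological reading time, but it is riddled with
contextual outliers: an urgent phone call forces an immediate save (a
too-short entry), a report paused and resumed overnight produces a too-long
one. `dictime` is for radiology workflow and health-economics analysts who
want robust per-region reading-time estimates from such exports, e.g. to
quantify the effect of a workflow change (structured reporting, AI triage)
on reporting practice.

## The model

Observed dictation times `x` (minutes, per anatomical region) are modeled as
a two-component contaminated-normal mixture

```
x ~ λ · N(μ, σ²) + (1 − λ) · c(x)
```

where `N(μ, σ²)` is the true reading time, `λ` its weight, and `c` a fixed
contamination density (by default a uniform background on `(0, max x]`
absorbing interrupts, overnight continuations and entries of unknown cause).
Two fitters are provided:

* `fit_em()` — reference expectation-maximization, monotone in
  log-likelihood;
* `fit_stochastic_search()` — an iterative stochastic parameter-vector
  search: each of 1000 iterations draws 100 candidate values per parameter
  around the current best `(μ, σ, λ)`, keeps the best-scoring triple and
  shrinks the search ranges.

Records are retained as "norm" when the posterior probability of the normal
component is ≥ 0.5; summaries report `n total`, `n norm`, and the retained
subset's mean/SD/median. A sample-size calculator
`N = 4σ²(z_crit + z_pwr)²/D²` supports planning a prospective stopwatch
validation, and Welch-t / Mann-Whitney-U helpers compare groups (readers,
periods).

## Worked example

```r
library(dictime)

# synthetic world with known truth: lambda = 0.9, N(16, 5), uniform contamination
cfg <- generator_config(n = 5000, seed = 42, weights = c(0, 0.9, 0, 0.1),
                        normal_mu = 16, normal_sigma = 5, unknown_range = c(0, 240))
d <- generate_durations(cfg)

fit <- fit_stochastic_search(d$durations, seed = 7)
#> <mixture_fit method=search> mu=15.969 sigma=5.081 lambda=0.8934  logLik=-17889.48  NOT converged (1000 iterations)

cls <- classify_records(d$durations, fit)
#> <classified_sample> n_norm=4537 / n_total=5000 (90.7% retained), threshold=0.50

ks_normality_of_retained(cls)
#> <One-sample Kolmogorov-Smirnov test> D = 0.01146, p = 0.5908 (n = 4537)

required_sample_size(sigma = 4.2, power = 0.9, alpha = 0.05, D = 1.5)
#> <sample_size_spec> N = 329 (raw 329.51) for sigma=4.2 min, power=0.9, alpha=0.05, D=1.5 min
```

Reading the output: the search recovers the generating parameters
(μ̂ = 15.97 vs 16, σ̂ = 5.08 vs 5, λ̂ = 0.893 vs 0.9); the "NOT converged"
flag only means rare sub-0.1-min improvements still occurred in the last 50
iterations — the estimate matches the EM optimum. Classification retains
90.7% of records (λ plus the contaminants that fall inside the normal bulk),
and the retained subset is compatible with the fitted normal (KS p = 0.59).
The planner says 329 stopwatch measurements suffice to pin a mean reading
time to a 1.5-minute confidence window at power 0.9.

End-to-end on a CSV export (columns `exam_id, region_code, dictation_start,
first_save`, ISO 8601):

```r
run <- run_pipeline(run_config("ris_export.csv", method = "search",
                               seed = 7, out_dir = "results"))
run$summary   # region | n_total | n_norm | mean_min | sd_min | median_min (+ All row)
```

or from the shell via the CLI wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "dictime.R", package = "dictime"))') \
  run --input ris_export.csv --method search --seed 7 --out results
```

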