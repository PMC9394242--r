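---
title: "Modeling dictation times: contaminated-normal outlier reduction for RIS timestamps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dictation times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dictime)
```

## The problem

Radiology Information Systems log two timestamps per report when speech
recognition is used: the start of dictation and the first save. Their
difference — the dictation time — tracks actual reading effort far better
than report turnaround time does, and it comes for free at the scale of a
whole archive. But the raw intervals are contaminated by workflow events.
Four kinds of entries coexist in practice:

1. **Too short** — an interruption (urgent call, fast-track stroke read)
   forces an immediate save;
2. **True reading time** — well approximated by a normal distribution, with
   scatter from case complexity;
3. **Too long** — a report left open and resumed later, e.g. overnight;
4. **Unknown cause** — anything else.

Only component 2 is of interest. Simple cutoffs (e.g. "drop everything over
60 min") discard genuinely difficult cases; `dictime` instead fits a mixture
and removes records probabilistically.

## Model and estimation

Durations `x > 0` within one anatomical region are modeled as

$$x \sim \lambda\, \mathcal{N}(\mu, \sigma^2) + (1-\lambda)\, c(x),$$

with `λ ∈ (0, 1]` the weight of the true-reading component. The
contamination density `c` is **fixed**, not estimated: the default is a
uniform background on `(0, max x]`. This single background absorbs
components 1, 3 and 4; it is deliberately minimal, because the data carry
no information to separate three contamination shapes reliably, and a
uniform background keeps the normal component identifiable. A three-part
alternative (`contamination_threepart()`: truncated-exponential shorts,
shifted-exponential overnight continuations, uniform unknown) mirrors the
generator's taxonomy for sensitivity analyses, but is not the default fit
target.

Two fitters maximize the same likelihood:

* **`fit_em()`** — standard EM with closed-form M-steps (posterior-weighted
  moments). The observed-data log-likelihood is non-decreasing per
  iteration, which the tests assert. Convergence: relative parameter change
  below `tol` (default 1e-6), usually within ~10 iterations.
* **`fit_stochastic_search()`** — the procedure the timestamp literature
  describes: per iteration, `vector_size = 100` candidate values are drawn
  for each of `μ`, `σ`, `λ` uniformly in `[best − w, best + w]`; the i-th
  values form a candidate triple scored by the mixture log-likelihood; the
  best triple is kept and the widths shrink by 0.995 per iteration from
  initial widths `(μ₀, σ₀, 0.5)`, with `λ` clipped to `(0.01, 1]`. Defaults
  are 1000 iterations × 100 candidates. The hot loop is compiled (Rcpp) and
  draws from R's RNG, so a single integer seed reproduces the whole search.
  A KS-distance objective (`objective = "ks"`) is available as a
  sensitivity check; the likelihood remains the default because it is the
  statistically efficient choice and makes the two fitters directly
  comparable.

Initialization (`"auto"`) is robust by design — `μ₀` = median, `σ₀` =
1.4826 × MAD, `λ₀` = 0.8 — so the starting normal ignores contamination.

### Convergence semantics

The search is declared converged when the best triple changes by less than
1e-3 relative over the final 50 iterations. At the default shrink rate the
final half-widths are still ≈ 0.7% of the initial ones, so occasional
sub-0.1-min improvements keep occurring and the flag is often `FALSE` even
though the estimates coincide with the EM optimum to two decimals. The flag
is reported with a warning rather than silently relaxed; treat it as "the
search was still polishing", not "the fit failed". The oracle-equivalence
tests (search vs EM within ±0.5 min / ±0.05 across seeds) are the
meaningful check.

### Classification and adequacy

`classify_records()` applies Bayes' rule with the fitted weights and labels
a record "norm" when the posterior probability of the normal component is
≥ 0.5 (maximum a posteriori; no retention rule is standard in this
literature, so the MAP rule is the package's choice and the threshold is a
parameter). `ks_normality_of_retained()` then tests the retained subset
against `N(μ̂, σ̂)`. Because the reference uses estimated parameters the
asymptotic p-value is conservative; `lilliefors = TRUE` recalibrates it by
parametric simulation when that matters.

The normal component is *not* truncated at zero. For realistic regimes
(μ/σ ≳ 3) the sub-zero mass is negligible; a warning fires if the fitted
normal puts more than 1% mass below zero, which signals that plain
normality is a poor description of that region.

## Timestamp handling

Dictation time = first save − dictation start, in fractional minutes at
full float precision (rounding only at presentation). Records with
duration ≤ 0 are excluded: a save preceding the dictation is a logging
artifact, and a zero-length interval cannot be a report — the boundary case
is excluded by the package's own convention. Timestamps are treated as
timezone-naive local times pinned to UTC; an interval spanning a
daylight-saving change is taken at face value because the export carries no
zone information to do better (noted in the load report). Region pooling is
config-driven (regex patterns → canonical labels) since protocol-code
vocabularies are institution-specific; the shipped default map is
illustrative only, and unmatched codes pool into `"other"`.

## The synthetic generator: what a green test establishes

`generate_durations()` realizes exactly the four-component taxonomy above:
exponential shorts (scale 2 min) truncated below the normal mean, the
normal reading time (defaults μ = 16, σ = 5 min — the post-reduction
overall mean reported for a large single-center archive, and a prospective
per-region SD; archive-wide post-reduction SDs are not usable as they
exceed their means, which is incompatible with positive, normal durations),
shifted-exponential continuations (shift 300 min ≈ overnight, scale
200 min), and uniform unknowns on (0.2, 480) min. Component magnitudes for
shorts and continuations are qualitative inventions — the field describes
the mechanisms, not their distributions — chosen once as plausible clinical
values and not tuned. Default weights (0.05, 0.85, 0.07, 0.03).

Two stated worlds appear in the tests:

* **Uniform-contamination world** — weights (0, 0.9, 0, 0.1), unknowns on
  (0, 240]: matches the model's default assumption exactly, so parameter
  recovery (MAE(μ̂), MAE(σ̂) < 0.5 min, MAE(λ̂) < 0.05 over 20 replicates at
  n = 5000) and retained-subset normality are sharp, honest checks of the
  estimator.
* **Four-component world** — the full taxonomy. Here the model is
  *misspecified by construction*: exponential shorts sit 1.6–2.8σ inside
  the normal bulk, where a uniform background cannot claim them, so the
  fitted normal absorbs them and the retained mean underestimates the
  generating μ by about `w_short · (μ − E[short]) / λ ≈ 0.7` min at the
  default weights. The end-to-end test pins this bias's direction and
  bound instead of pretending it away. Ground-truth norm/outlier accuracy
  still exceeds 90% because shorts are only 5% of records.

A green suite therefore establishes that the estimator recovers a
correctly-specified contaminated normal and degrades predictably under the
realistic misspecification — not that any institution's archive follows
these densities. The generator makes no attempt to match a real deposit's
empirical shape.

## Reporting and planning statistics

`summarize_durations()` reports mean, SD (n−1), median, adjusted
Fisher-Pearson skewness and excess kurtosis with exact small-sample
standard errors (`SE_skew = sqrt(6n(n−1)/((n−2)(n+1)(n+3))`,
`SE_kurt = 2·SE_skew·sqrt((n²−1)/((n−3)(n+5)))`). The exact formulas are
the single convention used throughout; the crude `sqrt(24/n)` kurtosis SE
is sometimes seen in applied reports but mixes conventions, so it is not
offered.

`required_sample_size()` implements `N = 4σ²(z_crit + z_pwr)²/D²` with `D`
the *total* CI width and floors the raw value (matching the published
planning example, 329.5 → 329; the raw value is always returned so a user
preferring a ceiling can apply one).

Group comparisons: Welch's t (the safer default when group sizes and
variances differ, e.g. two readers) and a Mann-Whitney U with midranks —
exact null distribution when both groups are ≤ 20 and tie-free
(configurable switch), otherwise a tie-corrected, continuity-corrected
normal approximation. The exact path is validated against brute-force
enumeration of all rank assignments in the tests. No multiple-testing
correction is applied anywhere.

## Pipeline determinism

`run_pipeline()` derives one child seed per (region, method) from the
master seed, stamps every artifact with the seed and a config hash, and
writes deterministic CSVs — reruns with an identical config are
byte-identical. Regions below `min_n = 30` durations are skipped with a
warning (mixture fitting below that is folly) but stay in the counts table.
The summary's `n_total` counts valid durations entering the fit; the
save-before-start exclusions are accounted separately in the load report,
since published tables are ambiguous about which denominator they use.

## Known limitations

* λ and the contamination density are confounded when contamination
  concentrates inside the normal bulk; the uniform default makes the fit
  identifiable but cannot recover interrupt-shaped shorts (bias quantified
  above).
* One mixture per region; reader experience and case mix are acknowledged
  confounders but no hierarchical structure is fitted.
* The KS adequacy test has low power for small deviations — e.g. a uniform
  sample needs n ≈ 5000 before its misfit to a moment-matched normal drops
  below p = 0.001.
* File-based only: no RIS/PACS/HL7 integration, no turnaround-time
  analytics.
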