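---
title: "Disproportionality signal detection: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect case
reports in which a reporter suspects that a drug caused an adverse event.
They have no denominator: nothing says how many patients took the drug
without incident. Disproportionality analysis works around this by asking a
within-database question: is the drug-event pair reported *more often than
expected* given how often the drug and the event are each reported overall?
For a target drug and one MedDRA Preferred Term (PT), every deduplicated
report falls into one cell of a 2x2 table:

|                    | PT reported | PT not reported |
|--------------------|------------|-----------------|
| target drug (PS)   | a          | b               |
| all other reports  | c          | d               |

with `N = a + b + c + d` and the independence expectation
`E = (a+b)(a+c)/N` for cell `a`. A report counts once per PT regardless of
repeated reaction rows, exposure means the target drug was coded *primary
suspect* (PS), and the comparator is every other report in the same
universe — the whole database in a pooled analysis, the stratum in a
subgroup analysis.

## The four statistics

Two frequentist measures:

* **ROR** (reporting odds ratio) `= ad/bc`, with the log-method 95% interval
  `exp(log(ROR) ± 1.96·sqrt(1/a+1/b+1/c+1/d))`. Any zero cell makes it
  non-estimable; we deliberately apply no Haldane 0.5 correction, because the
  signal rule already requires at least three reports and a correction would
  manufacture estimates exactly where the data are weakest.
* **PRR** (proportional reporting ratio) `= (a/(a+b)) / (c/(c+d))`, interval
  `exp(log(PRR) ± 1.96·sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d)))`, accompanied by
  the Yates-continuity-corrected Pearson chi-square
  `Σ (|O−E_cell|−0.5)²/E_cell` (correction clamped to zero when
  `|O−E_cell| < 0.5`; a zero margin yields 0). Yates correction is the
  dominant convention in this literature; `add_chi2(correct = FALSE)` gives
  plain Pearson.

Two Bayesian shrinkage measures, which damp the wild ratios that tiny counts
produce:

* **BCPNN information component**: the default is the widely used shrunk
  closed form `IC = log2((a+0.5)/(E+0.5))` with delta-method standard
  deviation `sqrt(1/(a+0.5))/ln 2` and `IC025 = IC − 1.96·sd`. The original
  moment-based variant with Dirichlet/beta priors is available via
  `add_ic(variant = "moment")`, and `z = 2` selects the alternative
  lower-bound convention. The two variants agree closely (within about 0.1
  bit) once `a ≥ 10` *and* `E ≥ 5`; at small expected counts the moment
  variant shrinks harder — asymptotically the gap is
  `log2((a+1)(E+0.5)/((E+1)(a+0.5)))` — so we do not claim agreement below
  that regime.
* **MGPS / EBGM**: DuMouchel's gamma-Poisson shrinker. Each pair's count is
  modelled as `a ~ Poisson(λE)` with the relative reporting rate drawn from
  a two-component gamma mixture prior
  `λ ~ w·Gamma(α₁,β₁) + (1−w)·Gamma(α₂,β₂)`. Marginally `a` is a mixture of
  negative binomials, and the five hyperparameters are fitted by maximising
  the marginal likelihood over *all* drug-PT pairs of the universe —
  including the zero cells of the complete drug-by-PT grid
  (`contingency_scan(complete = TRUE)`); fitting only observed pairs would
  truncate the zeros and bias the prior upward. The optimiser is
  deterministic: log/logit transforms enforce the parameter ranges,
  Nelder-Mead from the canonical start (0.2, 0.1, 2, 4, 1/3) is polished by
  BFGS, and convergence requires a relative log-likelihood change below
  1e-8. The posterior given `(a, E)` is again a two-component gamma mixture
  with parameters `(αⱼ+a, βⱼ+E)` and weights proportional to prior weight
  times negative-binomial evidence; `EBGM = 2^{E[log2 λ | a,E]}` has a
  closed form via the digamma function, and `EBGM05` (5th posterior
  percentile) is found by monotone root-finding on the mixture CDF to
  absolute tolerance 1e-10. Tests verify both against brute-force numerical
  integration of the posterior.

## Signal criteria

A PT is a *signal* when all four methods agree, each at its established
threshold:

* ROR: `n ≥ 3` and the lower 95% bound above 1;
* PRR: `n ≥ 3`, `PRR ≥ 2` and `χ² ≥ 4` (the Evans rule; the chi-square
  companion can be dropped with `use_chi2 = FALSE`);
* BCPNN: `IC025 > 0`;
* MGPS: `EBGM05 > 2`.

`rank_by_frequency()` orders flagged PTs by report count (ties by EBGM, then
PT), surfacing common signals; `rank_by_intensity()` orders by EBGM,
surfacing rare but strongly disproportionate ones. No multiplicity
correction is applied: in this field, shrinkage plus minimum-count
thresholds are the accepted guard against random fluctuation, and the output
is a ranked hypothesis list, not confirmatory inference.

## Preprocessing rules

* **Deduplication**: one report per `caseid` — the submission with the
  highest `FDA_DT` wins, ties broken by the highest `PRIMARYID`. A pure
  argmax, hence idempotent and independent of row order.
* **Age normalisation** to years by unit code (decades x10, months /12,
  weeks /52.18, days /365.25, hours /8766). Implausible ages (a real
  phenomenon in these databases — unit entry errors produce five-digit
  "years") are retained in tabulations by default; `clean_age = TRUE`
  excludes values above 120 years from the quantitative summary only, so
  both the as-reported and cleaned conventions are available.
* **Time to onset** = event date − earliest target-drug therapy start
  date + 1 day, so a same-day event is day 1, never 0. Reports with partial
  (`YYYYMM`/`YYYY`) or missing dates are excluded, not imputed — imputation
  would fabricate precision; events preceding therapy start are excluded as
  inconsistent. Latency bins use inclusive upper edges
  (0-30, 31-60, ..., 181-360, >360 meaning ≥ 361).
* **Percentage conventions**: every categorical block of
  `demographic_summary()` uses its own denominator (the block's count sum).
  Two conventions deserve emphasis because they differ from naive
  expectations and are the only ones that reproduce published demographic
  tables for this class of analysis: country shares are computed on the
  top-k subtotal, not on all reports, and outcome shares on the total
  number of outcome codes. Death counting is likewise convention-dependent:
  the outcome block tabulates DE *codes* while the mortality comparison
  classifies *reports* by DE presence; both are emitted and deliberately
  not reconciled.
* **Subgroups**: sex (F/M), age, or region; missing values form an
  `Unknown` stratum that is tabulated but marked untested. Age bins default
  to `<18, 18-44, 45-64, >64` (the scheme of published stratified signal
  tables); `age_scheme = "methods"` selects the coarser `<18, 18-60, >60`
  alternative. Within each stratum the universe, the shrinkage prior, and
  all statistics are rebuilt from scratch; a stratum with fewer than 100
  pairs falls back to the diffuse canonical prior, with a message.

## What the synthetic generator emulates

`generate_faers()` draws an entire multi-table universe with known ground
truth. Design choices, and what they are meant to exercise:

* One primary-suspect drug per case from a popularity distribution whose
  target share defaults to 2% — the order of magnitude of one widely
  prescribed drug in a large national database, and small enough that an
  injected signal barely contaminates its own PT margin (the contamination
  factor on the realized observed/expected rate is roughly
  `1 + share·(λ−1)`).
* A zero-truncated Poisson number of PT draws per case (mean 2.5) from
  Zipf-weighted background PT probabilities; signals multiply the weight of
  the pair's PT by λ with renormalisation, keeping the per-case PT count
  rate-stable. Because a case reports each PT at most once, very common
  PTs saturate; realized rates track λ faithfully only for modest per-case
  probabilities, which the validation designs respect.
* Sex shares 63.8/25.0/11.2 (F/M/unknown), age normal(47.4, 18) with a
  0.2% rate of implausible outliers (150-25,000 years) to force an explicit
  retention/cleaning policy downstream, and field-level missingness
  matching the rough missingness profile of real extracts (e.g. 35% of
  ages, half of therapy dates).
* Onset drawn from a two-component log-normal mixture — weight 0.45 on a
  short-latency component (median 12 days) and 0.55 on a long one (median
  300 days) — emulating the bimodal latency pattern of real reporting:
  an early post-initiation peak and a long late tail.
* Duplicates: a configurable fraction of cases is re-submitted with a new
  `primaryid`, a strictly later `fda_dt`, and possibly a filled-in
  previously-missing sex — exercising the "keep the most current
  submission" rule.

What it does **not** emulate: drug co-medication (exactly one suspect drug
per case), real MedDRA structure (PTs map round-robin onto synthetic SOCs),
reporting-year drift, country-specific reporting cultures, or correlated
missingness. Passing tests on this generator therefore demonstrate that the
statistical machinery is correct and calibrated under known ground truth —
not that any particular real-data finding is right.

## The two validation designs

`validation_config("null")` is the global null: no injected pairs, no
duplicates. On such universes the criteria should flag (almost) nothing;
the acceptance suite requires at most 1% of pairs with n ≥ 3 flagged by all
four methods across 20 replicates of 20,000 cases. In practice the fitted
prior collapses toward a point mass at λ = 1 — the empirically correct
answer on truly null data — and the flagged fraction is essentially zero.

`validation_config("recovery")` injects two target-drug signals (λ = 8 on a
moderately common PT, λ = 4 on a commoner one; both with expected report
counts well above 50 at 20,000 cases) *plus* a broad background of 150
elevated pairs (λ between 1.5 and 8) spread over the other drugs. The
background is not decoration: a real spontaneous-report database contains
abundant true associations, and it is exactly this heterogeneity that keeps
the empirical-Bayes prior non-degenerate. Without it the marginal-likelihood
fit concentrates the prior at 1 and correctly shrinks everything — including
the injected pairs — to EBGM ≈ 1, and no shrinkage-based method could be
validated. With it, the acceptance suite requires each injected pair to be
flagged by all four criteria in at least 95% of 20 replicates with mean
EBGM within [0.5λ, 1.5λ]. Note that the EBGM target is the *realized*
relative rate, which margin contamination and PT-multiset saturation place
somewhat below λ (around 6 for λ = 8); the shrinkage estimate tracks that
quantity, as it should.

## Numerical choices and degenerate inputs

* Likelihood computations use log-space negative-binomial densities with
  log-sum-exp mixing; the EBGM05 root-finder brackets the quantile with the
  component gamma quantiles and tolerates extreme posterior shapes.
* A boundary-pinned mixture weight (w within 1e-6 of 0 or 1) raises a
  warning: the prior is effectively one-component, which on null data is
  expected rather than an error.
* Non-estimable statistics propagate as `NA` with a reason column, and a
  non-estimable ROR fails the ROR criterion rather than erroring.
* Shrinkage is direction-guaranteed only where it should be: each posterior
  component mean lies between `a/E` and that component's prior mean, so
  `1 < EBGM < a/E` is asserted (and holds) for pairs whose observed ratio
  exceeds every prior component mean; small counts can legitimately be
  pulled *toward* an elevated prior component instead.
* An empty analysis universe (no primary-suspect cases) produces a
  complete, explicitly empty run with a flow report, not an error.
* Quantile summaries use the standard linear-interpolation definition;
  standard deviations use the n−1 denominator; a single observation reports
  sd 0 with a degeneracy flag.

## Problem sizes

The packaged validation experiments use 20 replicates of 20,000-case
universes (40 drugs, 150 PTs) for both the null-calibration and recovery
studies, 50 random `(a, E)` pairs for the EBGM-vs-quadrature comparison,
and 1,000 random tables for the estimator-agreement properties. These sizes
give the calibration fractions and recovery rates stable second-decimal
behaviour while keeping a full validation run in the minutes range on a
single core.

## Known limitations

* The comparator is "all other drugs" with an unstratified independence
  expectation; Mantel-Haenszel-type stratified expectations are a config
  extension point, not implemented.
* Exact supplementary formulas behind published interval constructions vary
  between programmes (e.g. IC025 via 1.96 vs 2 standard deviations); both
  are offered, and defaults follow the most common convention, so
  third-party numbers may differ in the second decimal.
* Report-level counting is assumed throughout; if a published table counted
  PT rows instead of reports, its `n` would differ for reports with
  repeated PT rows.
* Signals are hypotheses about reporting, not incidence or causation; the
  package deliberately produces no causal quantities.
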