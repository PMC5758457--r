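---
title: "A decision-analytic model of Cap-Score-guided management of unexplained infertility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic model of Cap-Score-guided management of unexplained infertility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captree)
```

## The clinical question

Couples with unexplained infertility are conventionally managed with up to
three cycles of intrauterine insemination (IUI) followed, if none succeeds, by
up to three cycles of IVF with ICSI — the standard of care (SOC). The
Cap-Score is a sperm-capacitation assay: a low score (below one standard
deviation under the fertile-population mean) flags impaired capacitation, in
which case IUI is unlikely to work and the couple can go straight to IVF-ICSI.
The guided strategy (CS-TI) therefore routes low-score couples directly to
three IVF-ICSI cycles and offers the rest three *timed* IUI cycles — with a
per-cycle success probability that is notably higher than the population IUI
rate, because the low-capacitation couples have been screened out — followed
by three IVF-ICSI cycles.

`captree` evaluates this decision tree in closed form, simulates it at the
patient level, and quantifies parameter uncertainty, so that the two
strategies can be compared on cumulative clinical-pregnancy and live-birth
probabilities and on expected IUI/IVF spending. Because the test itself is
unpriced, the package reports *cost offsets* — the downstream savings a guided
strategy would generate — rather than a cost-effectiveness ratio.

## The model

Each treatment modality is a capped sequence of independent Bernoulli cycles
with a constant per-cycle conception probability $p$; over $n$ cycles the
chance of conceiving is $1-(1-p)^n$ and the expected number of cycles
attempted is $\sum_{k=0}^{n-1}(1-p)^k = (1-(1-p)^n)/p$. Writing $q = 1-p$ and
age-band-specific probabilities where relevant:

* **SOC**: cumulative pregnancy $1 - q_\mathrm{iui}^{n_\mathrm{iui}}
  q_\mathrm{ivf}^{n_\mathrm{ivf}}$.
* **CS-TI**: with probability $p_\mathrm{lowCS}$ the couple is low-score and
  faces $1 - q_\mathrm{ivf}^{n_\mathrm{ivf}}$; otherwise
  $1 - q_\mathrm{tiui}^{n_\mathrm{iui}} q_\mathrm{ivf}^{n_\mathrm{ivf}}$,
  where the timed-IUI probability $p_\mathrm{tiui}$ is age-independent.

Live birth is Bernoulli conditional on clinical pregnancy, with a probability
that depends on the conceiving modality and the age band; timed-IUI
conceptions use the IUI live-birth probability (the parameter table carries no
separate timed-IUI row). Costs are unit cost times expected cycles; couples
who never conceive consume every cycle; the Cap-Score test contributes no
cost. IVF attempts are weighted by the probability of reaching the IVF stage.

These closed forms are a reconstruction — the source analysis prints its
results but not its equations. At the default parameter values the
reconstruction reproduces the published baseline rate and cost cells to their
printed precision for every cell that is arithmetically consistent with its
own row (see *Known limitations*), which is the strongest available check
that the reconstruction is the intended model.

## Parameters

`default_parameters()` loads the bundled table (`inst/extdata/
table1_parameters.csv`), which is the published parameter set verbatim:

| group | meaning | default |
|---|---|---|
| `c_iui`, `c_ivf` | unit cost per IUI / IVF-ICSI cycle, 2016 USD | \$2,550 / \$17,651 |
| `p_low_cs` | probability of a low Cap-Score | 0.336 |
| `p_iui[age]` | per-cycle pregnancy, IUI under SOC | 0.161 → 0.035 |
| `p_tiui` | per-cycle pregnancy, timed IUI (age-independent) | 0.400 |
| `p_ivf[age]` | per-cycle pregnancy, IVF-ICSI | 0.506 → 0.121 |
| `l_iui[age]`, `l_ivf[age]` | live birth given pregnancy, by modality | see table |
| `n_iui`, `n_ivf` | cycle caps | 3 / 3 |

Each uncertain entry carries a `low`–`high` sensitivity range, read
consistently as a 95% interval (the published footnote describes the ranges
as 95% confidence intervals where data exist), so the implied standard
deviation is $(\mathrm{high}-\mathrm{low})/(2\times1.96)$. The same endpoints
are used directly by the one-way sensitivity analysis. The five age bands
(<35, 35–37, 38–40, 41–42, >42 years) are fixed; the cycle caps are
parameters only so the engine generalizes — 3 + 3 is the modelled scenario.

## Uncertainty analyses

**PSA.** `run_psa()` samples every uncertain parameter independently (no
correlation structure is published): probabilities from beta distributions
matched to (mean, sd) by the method of moments, costs from normals truncated
at zero. Truncation is by resampling and is negligible for the bundled costs
(zero sits ~3.9 sd below each mean; the test suite asserts the truncated mass
is < 10⁻³), so the sampled mean stays at the baseline. Each of the (by
convention 10,000) draws is pushed through the closed form; outcomes are
summarized by the Monte Carlo mean and the percentile 95% credibility
interval (empirical 2.5th/97.5th quantiles, linear interpolation — standard
PSA practice; the source states only "95% credibility intervals"). For
nonlinear outcomes the Monte Carlo mean need not equal the baseline
evaluation, so the summary carries both, labelled `mean` and `baseline`.

**OWSA.** `run_owsa()` varies one parameter at a time across its range with
all else at baseline and ranks parameters by the absolute outcome swing
(tornado ordering). Age-banded parameters vary only the analyzed band's
value. Ties are broken by the canonical parameter-table order. `owsa_grid()`
tallies the top-ranked parameter over an outcome × age grid; the published
"20 outcomes" tally has an ambiguous grid composition, so the grid here is
configurable and defaults to the five delta outcomes × five bands.

## The cohort microsimulator

`simulate_cohort()` is the package's synthetic-data generator and brute-force
oracle: `n` couples traverse the tree with Bernoulli draws (Cap-Score
classification, per-cycle conception up to the cap, live birth conditional on
modality) and per-cycle cost accrual. It emulates exactly the world the
closed form describes — constant per-cycle probabilities, independence across
cycles and couples, no dropout, no per-attempt decline, no
miscarriage-timing or multiple-gestation structure. A green
oracle-equivalence test therefore establishes that the algebra and the
simulator agree about that stated world, not that the world resembles any
particular clinic's case mix.

Stream discipline: one seeded generator per cohort, consumed in a fixed
order — Cap-Score draws for all couples, then the IUI-stage cycle uniforms
column by column, then the IVF-stage uniforms, then the live-birth draws —
with unused draws still consumed, so any cohort replays bit-identically from
its seed. `simulate_couple()` follows the same logical order per couple for
trajectory-level inspection.

## Numerical choices

* Expected attempts use the analytic form $(1-(1-p)^n)/p$ with the $p\to0$
  limit handled explicitly ($=n$).
* All model outputs are kept at full precision; rounding (percent to two
  decimals, dollars to the nearest integer, both half-up away from zero)
  happens only in the formatting layer. Half-up was chosen because the
  published cells are consistent with either truncation or rounding;
  comparisons against printed values use ±0.01 percentage points / ±\$1.
* Beta fitting refuses ranges whose implied variance reaches the Bernoulli
  bound $m(1-m)$ rather than silently clipping.
* A zero-width range is a point mass; a degenerate PSA then reproduces the
  baseline tables exactly, which the tests assert.

## Known limitations

* A handful of published cells are not arithmetically consistent with their
  own rows or with any tree reconstruction: the guided-strategy IUI-cost
  column (printed \$5,889/\$6,019; the expectation implied by the stated
  parameters is an age-independent \$3,319) and the cells downstream of it;
  the >42 guided-strategy pregnancy/live-birth/IVF-cost cells; the >42 SOC
  live-birth cell; and three printed deltas that do not equal the difference
  of their neighbours. The package reproduces every internally consistent
  cell and documents rather than imitates the rest.
* Parameters are sampled independently; correlated uncertainty (e.g. between
  IUI and IVF success) is not modelled.
* No willingness-to-pay analysis, ICER, acceptability curves, or value of
  information; no price for the Cap-Score test exists, so only cost offsets
  are reported.
* The simulator has no time axis — cycle counts only.

## A worked example

```{r example}
params <- default_parameters()
tabs <- baseline_tables(params)
data.frame(age = tabs$rates$age,
           soc = format_percent(tabs$rates$soc_pregnancy),
           csti = format_percent(tabs$rates$csti_pregnancy),
           d_total_cost = format_dollars(tabs$costs$d_cost_total))
```

```{r psa}
psa <- run_psa(params, n_draws = 2000, seed = 1)
head(subset(psa$summary, outcome == "soc_pregnancy"))
most_influential(run_owsa(params, "d_pregnancy", "<35"))
```
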