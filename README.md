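# captree

A decision-analytic model comparing two ways of managing unexplained
infertility: the **standard of care** (SOC — up to three IUI cycles, then up
to three IVF-ICSI cycles) against a **Cap-Score-guided strategy** (CS-TI — a
sperm-capacitation test routes low-scoring couples straight to three IVF-ICSI
cycles, while the rest get three *timed* IUI cycles at a higher per-cycle
success rate, then three IVF-ICSI cycles). The package is for health-economic
and reproductive-medicine analysts who want the model as reusable, tested
code: closed-form tree evaluation, patient-level cohort microsimulation (the
brute-force oracle), probabilistic sensitivity analysis, tornado (one-way)
sensitivity analysis, and a small CLI.

## The model in brief

Each modality is a capped run of independent Bernoulli cycles with constant
per-cycle conception probability *p*; over *n* cycles, conception probability
is 1 − (1−p)ⁿ and expected attempts are (1 − (1−p)ⁿ)/p. With q = 1 − p and
age-banded parameters:

* SOC cumulative pregnancy: 1 − q_iui³ · q_ivf³
* CS-TI: p_lowCS · (1 − q_ivf³) + (1 − p_lowCS) · (1 − q_tiui³ · q_ivf³)

Live birth is Bernoulli conditional on pregnancy with a modality- and
age-specific probability; costs are unit cost × expected cycles (the
Cap-Score test itself is unpriced and costs nothing in the model, so results
for spending are *cost offsets*). Parameters (2016 USD costs, five maternal
age bands from <35 to >42) ship with the package and carry sensitivity
ranges, read as 95% intervals, that drive beta (probabilities) and
zero-truncated normal (costs) PSA distributions.

## Worked example

```r
library(captree)
params <- default_parameters()
tabs <- baseline_tables(params)
data.frame(age = tabs$rates$age,
           soc_preg  = format_percent(tabs$rates$soc_pregnancy),
           csti_preg = format_percent(tabs$rates$csti_pregnancy),
           soc_lb    = format_percent(tabs$rates$soc_live_birth),
           csti_lb   = format_percent(tabs$rates$csti_live_birth),
           d_ivf_cost = format_dollars(tabs$costs$d_cost_ivf))
#>     age soc_preg csti_preg soc_lb csti_lb d_ivf_cost
#> 1   <35   92.88%    94.22% 68.54%  66.16%    -$3,410
#> 2 35-37   88.97%    91.80% 61.90%  58.72%    -$5,444
#> 3 38-40   78.43%    84.93% 50.81%  49.42%    -$7,817
#> 4 41-42   62.17%    77.60% 33.23%  35.99%   -$13,858
#> 5   >42   38.97%    67.44% 18.21%  27.72%   -$19,621
```

Reading the rows: guidance always raises the cumulative pregnancy rate
(modestly for young couples, +15 and +28 percentage points for the two oldest
bands, where population IUI rarely works but timed IUI still succeeds at
40%/cycle), slightly lowers live births under 40 (screened-out couples lose
IUI-conceived births with their higher IVF live-birth odds not fully
compensating), raises them over 40, and saves thousands of dollars of IVF
spending per couple in every band.

Uncertainty and influence:

```r
psa <- run_psa(params, n_draws = 10000, seed = 1)
s <- subset(psa$summary, outcome == "soc_pregnancy" & age == "<35")
sprintf("SOC pregnancy <35: mean %s, 95%% CI %s-%s",
        format_percent(s$mean), format_percent(s$lo), format_percent(s$hi))
#> "SOC pregnancy <35: mean 92.57%, 95% CI 86.65%-96.60%"
most_influential(run_owsa(params, "d_pregnancy", "<35"))
#> [1] "p_iui"
```

The pregnancy advantage of guidance is most sensitive to the population IUI
success rate (`p_iui`) for women under 42; cost deltas over 40 are dominated
by the corresponding unit cost.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "captree.R", package = "captree"))')
Rscript "$CLI" baseline --out out/
Rscript "$CLI" psa --n-draws 10000 --seed 7 --out out/
Rscript "$CLI" owsa --outcome d_cost_ivf --age ">42" --out out/
Rscript "$CLI" simulate --cohort-size 200000 --strategy SOC --out out/
```

Outputs are plain CSV (one age band per row) plus a timestamped run log
recording the seed, sizes, and parameter-file digest. Custom parameter files
(CSV or JSON; see `inst/extdata/table1_parameters.csv` for the schema) go via
`--params`.

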