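# vertispend

Claims-based comparison of annual spending and care quality for patients
attributed to **hospital-owned versus physician-owned physician practices**
("vertical integration" of physicians into hospitals).

Health-services researchers repeatedly find that when hospitals acquire
physician practices, spending per patient rises. Testing that on commercial
insurer claims requires a chain of non-trivial steps: attributing each
member to a physician organization from visit patterns, summing allowed
amounts into clinically meaningful categories, separating price from
utilization, constructing claims-based quality measures, and fitting models
whose standard errors respect the clustering of patients within physician
organizations. `vertispend` implements that chain as a tested, reusable R
pipeline. Because real insurer claims are proprietary, the package includes
a synthetic claims generator with *known ground-truth effects*, so every
stage — and the pipeline end to end — is verifiable without any data
download.

## What the package computes

For members *i* attributed to physician organization *g(i)* with annual
allowed spending *y_i*:

- **Attribution**: each member-year is assigned to the primary-care
  physician (family practice, general practice, geriatrics, internal
  medicine, pediatrics) with the plurality of evaluation-and-management
  visits in a 24-month window (the calendar year ± 6 months), and hence to
  that PCP's organization. Cohort filters: ages 19–64, continuous
  enrollment, annual spending ≤ $100,000.
- **Spending decomposition**: per member-year totals and breakdowns by
  BETOS clinical category (evaluation & management, procedures, imaging,
  tests, DME, other, unclassified) and by site of care (professional,
  outpatient facility, inpatient facility), conserving totals exactly in
  cents.
- **Price standardization**: every claim's price is replaced by the median
  price in its BETOS category × year, so spending differences on
  standardized claims reflect utilization only; the price effect is the
  difference between the actual and standardized differentials.
- **Quality**: 30-day all-cause readmission, HbA1c / LDL / retinal-exam
  testing for diabetics, and screening mammography for women 50–64, all
  detected from claim codes.
- **Estimation**: the spending model is a quasi-likelihood GLM with log
  link (variance ∝ mean),

  `E[y_i | x_i] = exp(β·Hosp_{g(i)} + γ'x_i)`,

  with covariates for year, age bands, sex, risk-score deciles, CDHP
  enrollment, wage index and its square, practice-size category, attributed
  PCP specialty, and MSA×year cells. The ownership effect is reported as
  `100(e^β − 1)` percent. A dollar-scale linear model and logistic quality
  models (odds ratios) share the same inference machinery: CR0 sandwich
  covariance clustered by physician organization with a `G/(G−1)` factor
  and t(G−1) inference.

## Worked example

```r
library(vertispend)

# a two-year scenario: 2,000 members, 52 physician organizations,
# a true ownership effect of 0.058 on log spending, ~15% via prices
cfg <- sim_config(n_members = 2000, years = 2014:2015, seed = 42)
ds  <- generate_claims_dataset(cfg)
res <- estimate_scenario(ds, dollars = TRUE)

effect_estimate(res$actual)
#>                  term     estimand    point    ci_low  ci_high   p_value n_obs n_clusters
#> 1: ownership_hospital percent_diff 3.722281 -1.765286 9.516392 0.1830457  3755         52

price_utilization_decomposition(res$actual, res$standardized)
#>      component     point    ci_low  ci_high      p_value
#> 1:      actual  3.722281 -1.765286 9.516392 0.1830457041
#> 2: utilization  5.041138  2.438880 7.709502 0.0002517699
#> 3:       price -1.318858        NA       NA           NA
```

Reading the output: patients of hospital-owned practices in this simulated
world spend an estimated 3.7% more per year (95% CI −1.8 to 9.5) than
patients of physician-owned practices, adjusted for case mix, region and
practice characteristics. Re-estimating on median-price-standardized
claims gives 5.0% — the utilization component — so this particular draw
attributes a (noisy) −1.3 percentage points to prices. The generator's
true values are 5.97% overall with about 0.9 points via price; a single
replicate of this size estimates them with a cluster-driven standard
error of a few points, and the parameter-recovery tests average 200
replicates to verify unbiasedness. The dollar-scale model estimates a
$234 adjusted difference (95% CI −$116 to $583) for the same sample.

`run_pipeline(cfg, out_dir)` executes the whole chain and writes analogues
of the study-style display tables (descriptives; spending differentials
overall, by BETOS category and by site of care; claims per member and
percent billed in the outpatient setting for crosswalked test families;
quality odds ratios) plus stage outputs and a reproducibility manifest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full pipeline on the default scenario against the installed
package (simulation, attribution, spending decomposition and
standardization, quality measures, and all clustered model fits) and
writes the machine-readable target report to `--out`.
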