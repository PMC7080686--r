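---
title: "Methods: spending and quality by practice ownership from claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spending and quality by practice ownership from claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vertispend)
```

`vertispend` measures the association between hospital ownership of
physician practices and two outcomes — annual allowed spending per patient
and claims-computable quality of care — from commercial insurer claims.
This vignette records the model, the conventions, and every place where a
design decision was genuinely open, so a reader can judge exactly what a
green test establishes.

## The estimand and the models

The target quantity is the adjusted multiplicative difference in expected
annual spending between patients attributed to hospital-owned and
physician-owned organizations. Spending is non-negative, right-skewed, and
has a point mass at zero within clinical categories, so the primary model
is a quasi-likelihood GLM with a log link:

$$E[y_i \mid x_i] = \exp(\beta\,\mathrm{Hosp}_{g(i)} + \gamma'x_i),$$

fit by IRLS to a relative-deviance tolerance of $10^{-8}$ (at most 100
iterations). The ownership effect is reported as $100(e^\beta - 1)$
percent. Zero-spending observations stay in the sample — the attraction of
this model over OLS on log dollars.

**Variance function.** Quasi-likelihood requires only a variance
assumption. We default to variance proportional to the mean
(quasi-Poisson), the standard choice for spending with zeros; a
gamma-type variance ($\propto \mu^2$) is available via
`fit_glm_log(variance = "mu2")`. The point estimate of a saturated
two-group contrast is identical under both (the log of the group-mean
ratio); the choice matters only for weighting under covariates.

**Clustered inference.** Patients of one physician organization share
unobserved practice style, so all standard errors use a CR0 sandwich
clustered by organization: bread = inverse expected information, meat =
sum of per-cluster score outer products, multiplied by $G/(G-1)$, with
$t(G-1)$ reference distribution. The cluster id is the attributed
organization, held constant across years. The covariance is computed in
the factored form $(A^{-1}S')(A^{-1}S')'$, which is positive semi-definite
by construction even for ill-conditioned category-level fits. With one row
per cluster and the small-sample factor off, the estimator reduces exactly
to HC0 (a tested invariant).

A dollar-scale OLS model and logistic quality models (reported as odds
ratios) reuse the same covariance machinery. Logistic fits refuse to
report under separation rather than returning a diverged coefficient;
penalization is deliberately not applied by default.

**Covariates.** Year indicators; age bands 19–29 / 30–39 / 40–54 / 55–64
(or age + age² as a sensitivity specification); sex; deciles of the
concurrent risk score, cut on the estimation sample (not per group);
CDHP enrollment; the regional wage index and its square; practice-size
categories (≤500, 501–10,000, 10,001–15,000, ≥15,001 attributed patients
per organization-year, with decile bins as a sensitivity option); the
attributed PCP's specialty; and MSA×year interaction cells. Reference
levels are physician-owned, the youngest age band, the first year, the
first MSA, and the first level of the remaining factors. In our synthetic
world the wage index is constant within MSA-year, so the MSA×year block
loses two columns to aliasing; `build_design()` drops aliased columns by
QR rank detection and records every drop in its book-keeping. An
open question in this design is whether "specialty" should mean the
attributed PCP's specialty or a practice-level mix; we use the attributed
PCP's specialty, which is well-defined per member-year.

**Ownership coding.** The primary contrast pools local-hospital and
multi-hospital-system ownership against physician-owned. A three-level fit
plus a Wald test of equality of the two hospital coefficients
(`test_hospital_equality()`) provides the standard justification for
pooling.

## Attribution

A member-year is attributed to the primary-care physician with the
plurality of professional evaluation-and-management visits — claims with
an E&M BETOS category billed by a PCP-specialty physician — in a 24-month
window, and through that PCP to an organization. Claims carry no explicit
"visit" marker, so E&M professional claims are the visit proxy.

- **Window.** The window is the calendar year plus six flanking months on
  each side (July 1 of the prior year to June 30 of the following year),
  exposed as `flank_months`. Attribution windows of this kind are usually
  described only loosely — a calendar year plus the months closest to it —
  so the symmetric-flanking rule is our documented, deterministic
  interpretation of "closest".
- **Plurality, not majority.** A strict majority rule would silently drop
  members splitting visits across PCPs; plurality (the mode) keeps them.
- **Ties** break by most recent visit date, then lexicographically
  smallest `pcp_id` — deterministic and clinically sensible (recency).
- The attributed organization is the one on the plurality PCP's most
  recent in-window claim, which also resolves mid-window organization
  switches.

Cohort filters precede attribution: ages 19–64, continuously enrolled,
annual raw spending ≤ $100,000 (strictly greater excluded; exactly
$100,000.00 is retained). Reasons are applied in the order age,
enrollment, spending cap, so exclusions partition the dropped
member-years.

## Spending decomposition and price standardization

Allowed amounts are summed per member-year in exact integer cents, so the
conservation identities (BETOS categories sum to the total; settings sum
to the total) are testable bit-exactly. Professional claims map to BETOS
through the HCPCS crosswalk; facility claims map through a packaged
revenue-code map in which operating- and recovery-room codes are
`unclassified`. Unmapped codes go to `unclassified` with a warning rather
than being dropped, because conservation must hold.

Median prices are computed within BETOS category × year, pooled across
ownership types; an even claim count takes the mean of the central pair.
Whether medians should pool years is a genuinely open choice; we chose
per-year medians to avoid conflating inflation with price differences,
and flag the choice in the pipeline's model card. Standardization replaces
each claim's price with its category-year median and re-aggregates; claim
counts are untouched, so the procedure is idempotent and permuting prices
within a category-year cell cannot change any member's standardized total
(both are tested invariants).

## Quality measures

Five member-year measures, each with an eligibility flag and a numerator:

- **30-day readmission**: overlapping or same-day-transfer stays are
  merged into episodes first; a member-year is eligible if it contains an
  episode discharge, and the numerator is an admission 1–30 days after a
  discharge ("within 30 days" read inclusively: day 30 counts, day 31
  does not). Readmission is all-cause and any-facility.
- **Diabetes processes** (HbA1c, LDL, retinal exam): the denominator is
  any claim flagged with a diabetes diagnosis in the measurement year —
  the full HEDIS lookback logic is out of scope — and numerators are
  claims bearing codes from config-supplied code sets with packaged
  defaults.
- **Screening mammography**: women aged 50–64 in the year (49 is not
  eligible; 50 is).

The measurement window is the calendar year throughout. The set of five
measures is readmission plus four HEDIS-style process measures — the
quantities such claims analyses actually report.

## The synthetic world

The generator is the package's substitute for proprietary claims, and its
defaults are the stated world of the analysis:

- 5,000 members over 2014–2016 in four MSAs; 40 physician-owned, 8
  local-hospital, and 4 multi-hospital-system organizations, giving
  hospital-owned organizations ~23% of members (the rough member share in
  the population the package emulates).
- `ownership_log_effect = 0.058` on the log mean of annual spending, and
  `price_share = 0.155`: the stated world has roughly one percentage
  point of a 5.8% differential operating through prices, the rest through
  utilization.
- Per BETOS category, claim counts are Poisson with mean
  `lambda × risk`, and per-claim prices are lognormal; `betos_mix`
  defaults put mean annual spending near $4,500 with the category
  composition of commercially insured adults and a large zero mass in
  low-rate categories. The risk score is lognormal with mean ≈ 1.24, and
  utilization scales proportionally with it.
- The ownership effect enters *exactly*: hospital members' per-claim
  prices are multiplied by `exp(price_share × effect)` and their expected
  claim counts by `exp((1 − price_share) × effect)`, so the total
  expected-spending ratio is `exp(effect)` and the price/utilization
  decomposition is identifiable by construction.
- MSA×year level shifts (SD 0.05) and organization-level intercepts
  (SD 0.08) act on prices, producing regional confounding structure and
  within-organization correlation — the reason clustered inference is
  needed at all.
- Every member has at least one E&M claim per year from a single home
  PCP, so attribution recovery is checkable against ground truth; quality
  events are generated *as claims with codes* (not flags), so the quality
  module is tested on its real detection path. Extra outpatient routing
  for hospital members (`hosp_outpatient_shift`, default 0.08) shifts the
  billing setting without touching prices, keeping the spending effect
  calibrated.
- Risk is independent of ownership by default; `confound_risk` exposes a
  confounding knob for robustness experiments.

What the generator does **not** emulate: realistic ICD/CPT vocabularies
(a ~60-code crosswalk stands in for the full CMS BETOS file, which can be
loaded via `read_betos_crosswalk()`); actuarial price levels; pharmacy
claims (excluded from the emulated analysis); member churn across
organizations; and correlated disease trajectories. A green test
establishes that the pipeline's logic and inference are correct in a world
with known truth — not that the synthetic spending levels are actuarially
realistic.

Three small intentional impurities are worth knowing about: quality-event
claims and readmission stays add small amounts of spending that are not
scaled by the utilization channel (≈0.5% of totals; negligible against
the Monte-Carlo tolerances used in calibration tests), coincidental
second admissions put the realized readmission rate slightly above the
configured rate (the rate-recovery test allows for this), and always-
professional lab claims from quality events dilute the chemistry family's
outpatient-share difference by ~2% relative.

## Numerical and testing choices

- Currency arithmetic is exact in integer cents internally; medians are
  left unrounded (idempotence still holds because a constant's median is
  itself).
- Determinism: a single master seed with per-stage derived substreams;
  identical configs produce byte-identical serialized datasets.
- Two-proportion comparisons (positive-spending shares, percent billed in
  the outpatient setting) use pooled-variance z-tests without continuity
  correction; claims-per-member rates use a two-sample z on member-level
  counts. These test choices are conventions of this package and are
  recorded here because nothing forces them.
- The type-I-error calibration of the clustered t-test uses a null world
  with 150 organizations (~20 members each): the size of a cluster-robust
  test is meaningful in the many-cluster regime that the estimator's
  theory assumes — and that a full-scale claims analysis, with thousands
  of physician organizations, occupies.
  In our measurements the test holds its nominal 5% size there and stays
  close to it at 100 organizations; CR0 with genuinely few clusters (or
  few *treated* clusters) is nonetheless known to under-cover, and users
  in that regime should prefer more conservative corrections.
- Per-stage substreams are derived from the master seed by a Lehmer-style
  mix rather than `seed + stage`: with additive offsets, consecutive
  master seeds share identical stage RNG states, which silently correlates
  Monte-Carlo replicates run over a seed range (we observed rejection-rate
  estimates swinging between 4.75% and 8% across 400-replicate streams
  before the fix, and ~5% uniformly after it).
- Parameter-recovery tests average 200 replicates of the full pipeline at
  n = 5,000 members (one calendar year per replicate, to keep the suite
  inside its time budget); decomposition identities use 100 replicates at
  n = 1,500.

## Known limitations

- The 24-month attribution window is one reasonable reading of a loosely
  specified convention; other flanking rules are defensible and are
  supported through `flank_months`.
- The diabetic denominator is one-year claims-based, not full HEDIS
  continuous-enrollment logic.
- CR0 with few clusters (or few *treated* clusters) under-covers; no
  wild-cluster bootstrap is provided.
- The pipeline estimates associations in a world where ownership is
  randomly assigned; it provides no instrument for causal identification
  in observational data.
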