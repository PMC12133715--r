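# recurrisk

Population-based estimation of breast-cancer recurrence from linked
cancer-registry and administrative-claims data.

Cancer registries record diagnoses and deaths, but not recurrences. For
women living many years after a breast-cancer (BC) diagnosis, the
long-term frequency of recurrence must therefore be reconstructed by
linking the registry to administrative healthcare databases — hospital
discharge data (HDD) and outpatient services (OPS), coded in ICD-9-CM —
and reading treatment and admission codes as recurrence indicators.
`recurrisk` implements this whole analysis as a tested, reusable R
pipeline for epidemiologists working with pseudonymized linked data:

1. **Eligibility cascade** — eight ordered registry exclusions (prior or
   synchronous cancer except C44, DCO/autopsy cases, zero survival,
   death within 6 months, missing stage, stage IV, age > 74), with a
   count-conserving exclusion log.
2. **Covariate derivation** — surrogate intrinsic subtype from ER/PR/HER2
   (HR+/HER2−, HER2+, triple negative), age bands, period of diagnosis.
3. **Claims-based recurrence ascertainment** — the earliest of four
   indicator classes (new chemotherapy; new radiotherapy; breast
   surgery or malignant-breast admission; secondary malignant
   neoplasm admission) at or after a subtype-specific surveillance
   start: 12 months after diagnosis for HER2− tumours, 24 months for
   HER2+, so primary-treatment codes are never misread as recurrence.
4. **Competing-risks estimation** — the Aalen–Johansen cumulative
   incidence function with second primaries and deaths as competing
   events, Aalen-type variances, log(−log) confidence intervals, crude
   rates per 1000 person-years, and conditional probabilities.
5. **Ten-year status tabulation** — each woman classified into six
   mutually exclusive states (alive/dead × event-free / after
   recurrence / after second tumour).

A multi-state **simulator** generates linked registry + HDD + OPS tables
from configurable constant cause-specific hazards, together with the
latent truth, so every stage is testable end to end without access to
confidential registry data.

## The estimator

Follow-up runs from diagnosis to the first of: recurrence (event),
second primary cancer (competing), death from any cause (competing),
emigration (censoring) or the administrative cutoff (censoring). With
distinct event times *t₁ < t₂ < …*, *nⱼ* at risk and *d₍kj₎* cause-*k*
events at *tⱼ*, the all-cause event-free survival is the product-limit

  S(tⱼ) = ∏᙮≤ⱼ (1 − dᵢ/nᵢ),  dᵢ = Σₖ d₍ki₎,

and the cumulative incidence of cause *k* is

  F̂ₖ(t) = Σ₍tⱼ≤t₎ S(tⱼ₋₁) · d₍kj₎ / nⱼ.

At every step Σₖ F̂ₖ(t) + S(t) = 1. Under constant cause-specific
hazards the estimator converges to the closed form
(λₖ/λ₊)(1 − e^{−λ₊t}), which `analytic_cif()` provides as an oracle.

## Worked example

```r
library(recurrisk)
cfg <- run_config(simulation = simulation_config(3000, seed = 7))
report <- run_pipeline(cfg)
report
```

```
Cohort: 2982 eligible of 3000 registry records

Cumulative incidence of recurrence (competing risks):
  all        all        n= 2982   5y 8.4% (7.4%-9.4%)    10y 16.8% (15.5%-18.2%)
  ...
  stage      I          n= 1504   5y 5.5% (4.5%-6.8%)    10y 12.0% (10.5%-13.8%)
  stage      II         n= 1072   5y 9.6% (7.9%-11.5%)   10y 19.1% (16.8%-21.6%)
  stage      III        n=  406   5y 15.6% (12.3%-19.3%) 10y 28.4% (24.1%-32.9%)

Crude recurrence rates per 1000 person-years:
  all        all        649 events / 32114.4 py = 20.2
  ...

Follow-up status at 10 years (all cohort):
  alive_event_free             1984 (66.5%)
  alive_after_recurrence        257 (8.6%)
  alive_after_second_tumour      87 (2.9%)
  dead_without_recurrence       321 (10.8%)
  dead_after_recurrence         238 (8.0%)
  dead_after_second_tumour       95 (3.2%)
```

Of 3000 simulated registry records, 2982 survive the eligibility
cascade (the rest died within 6 months of diagnosis). The 10-year
cumulative incidence of recurrence is 16.8% overall and rises steeply
with stage (12.0% → 19.1% → 28.4%), the expected clinical gradient; at
10 years two thirds of the cohort is alive and event-free. With an
`output_dir` set, the same call writes `exclusions.csv`,
`outcomes.csv`, `cif_*.csv`, `rates.csv`, `status10y.csv` and a
human-readable `summary.txt`; identical configuration and seed give
byte-identical outputs.

Individual stages are plain functions over data frames —
`apply_eligibility()`, `assign_subtype()`, `ascertain_recurrence()`,
`aalen_johansen()` (with `tidy()`, `glance()`, `autoplot()` methods),
`status_at_10y()` — and compose with the pipe.

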