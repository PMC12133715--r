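---
title: "Estimating breast-cancer recurrence from linked registry and claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating breast-cancer recurrence from linked registry and claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(recurrisk)
library(dplyr)
```

## The problem

Population-based cancer registries follow vital status but do not
record recurrences. When a registry can be linked, through a
pseudonymous identifier, to hospital-discharge (HDD) and
outpatient-service (OPS) claims, a recurrence can be operationalised as
the first claim that indicates the disease has returned after a
disease-free interval: restart of chemotherapy or radiotherapy, breast
surgery or an admission for a malignant breast neoplasm, or an
admission for a secondary malignant neoplasm. `recurrisk` implements
that design as a pipeline of small, testable stages, and ships a
simulator of the full linked-data structure so the pipeline can be
validated without confidential data.

This vignette documents the modelling choices, the tunable parameters,
what the simulator does and does not emulate, and the numerical
conventions, so that results can be interpreted — and the package
re-used on real extracts — without reading the source.

## Cohort construction

Eligibility is an ordered cascade of eight exclusions; each woman is
counted against the **first** criterion she matches, so the
per-criterion counts depend on the order while the final cohort does
not (a property the test suite asserts on randomised toy registries):

1. prior cancer before the breast diagnosis (non-melanoma skin cancer
   C44 excepted);
2. synchronous cancer (C44 excepted);
3. diagnosis by autopsy or death certificate only;
4. no survival time — implemented as death on the diagnosis date, since
   "zero follow-up" has no sharper operational definition;
5. death within 6 months of diagnosis — implemented as
   `death_date < diagnosis_date + 183` days (half of 365.25, rounded up);
6. missing stage;
7. stage IV (de novo metastatic disease);
8. age over 74 at diagnosis.

Age at diagnosis uses completed years, `floor(days / 365.25)`. The
surrogate intrinsic subtype follows the standard immunohistochemical
rule: HER2-positive ⇒ HER2+ whatever ER/PR; HER2-negative with ER or PR
positive ⇒ HR+/HER2−; HER2-negative with both receptors negative ⇒
triple negative (TN); any combination left undecided by missing markers
⇒ not available. Two age groupings coexist in descriptive practice: a
five-band one (20–39/40–49/50–59/60–69/70–74, the default, used by the
status tables) and a coarser four-band one merging 50–69 for incidence
strata; `derive_strata(age_bands =)` selects between them.

## Recurrence ascertainment

The surveillance window opens 12 months after diagnosis for
HER2-negative tumours and 24 months for HER2-positive ones — covering
primary treatment (longer under a year of anti-HER2 therapy) plus a
6-month disease-free interval — and a sensitivity switch applies
12 months to every subtype. Tumours with missing HER2 use the 12-month
default, reading the 24-month rule as the HER2-positive exception.
Months convert to days as `round(m * 30.4375)`, so the boundaries are
days 365 and 731; the boundary day itself is **inclusive**.

Indicator codes are data, not logic. `default_code_set()` maps the four
classes to ICD-9-CM prefixes (stored undotted): 99.25/V58.1x
(chemotherapy), 92.2x/V58.0 (radiotherapy), 85.4x/174.x (mastectomy or
malignant-breast admission), 196.x–198.x (secondary malignant
neoplasm). These defaults are standard oncology claim codes consistent
with the four indicator descriptions; site-specific lists load from
YAML via `read_code_set()`. A claim carrying codes of several classes
is reported once, under the lowest class number — a deterministic
tie-break that cannot affect recurrence timing. Malformed code strings
(outside the 3–5 character, optional V/E-prefix lexical form) skip the
code with a warning rather than failing the run. The HDD claim date is
the admission date; the OPS claim date is the service date.

Each woman's outcome is the earliest of: ascertained recurrence date,
registry second-primary date, death date, emigration date,
administrative cutoff. Same-day ties resolve by recurrence > second
primary > death > censoring, on the reasoning that a recurrence claim
on the day of death implies the event preceded death within the day's
resolution.

## Competing-risks estimation

`aalen_johansen()` estimates the cause-specific cumulative incidence
functions. With $n_j$ at risk and $d_{kj}$ cause-$k$ events at the
$j$-th distinct event time,

$$S(t_j) = \prod_{i \le j}\Bigl(1 - \tfrac{d_i}{n_i}\Bigr), \qquad
\hat F_k(t) = \sum_{t_j \le t} S(t_{j-1})\,\frac{d_{kj}}{n_j},$$

with all causes pooled in $S$. Tied event times are processed
simultaneously within the step ($d_{kj}$ per cause at $t_j$), the
standard convention. Variances use the Aalen-type delta-method
estimator — the test suite verifies it agrees with
`survival::survfit()`'s multi-state standard errors to machine
precision, while point estimates also match `cmprsk::cuminc()` —
and 95% intervals use the log(−log) transformation, clamped to [0, 1];
no interval is reported where $\hat F_k = 0$. Years convert to days by
365.25 and reported percentages round half-up to one decimal, the
precision at which such tables are conventionally printed.

Two readings of the time origin are defensible when events are only
ascertainable after the surveillance start. The default counts risk
time from diagnosis for every woman (recurrences simply cannot occur
before the window opens, which the upstream ascertainment enforces).
The alternative — delayed entry at the window start, dropping women
whose competing event precedes it — is exposed as
`left_truncation = TRUE` and handled in the estimator through
`entry_days` (at risk at $t$ when $entry < t \le time$). Neither mode
is asserted as the canonical one; the default follows the plain reading
of "followed from the date of diagnosis", and the flag exercises the
other.

Crude rates are $1000 \cdot \text{events} / \text{person-years}$, with
person-years accumulated from diagnosis to outcome in days/365.25.
Conditional incidence between horizons is
$(\hat F_k(t_2) - \hat F_k(t_1))/S(t_1)$, flagged undefined when
$S(t_1) = 0$.

## Ten-year status

`status_at_10y()` partitions the cohort into six states by crossing the
first-event pathway before the horizon (none / recurrence / second
primary) with vital status at the horizon. The horizon is
$10 \times 365.25$ days and the boundary is **strict**: events or
deaths on or after the horizon day are ignored, so a woman dying at 11
years after a 3-year recurrence is *alive after recurrence* at 10
years. "Alive/dead after second tumour" means the first event was a
second primary — a recurrence never preceded it. Deaths with no
preceding ascertained recurrence, including early progression without a
disease-free interval, land in *dead without recurrence*. Women
emigrating before the horizon are carried at their last known vital
status (alive), appropriate when vital follow-up is near-complete;
with substantial emigration the states would be better treated as a
competing-risks quantity in their own right, which this tabulation does
not attempt.

## The simulator

`simulate_cohort()` draws, per woman, independent exponential latent
clocks for recurrence, second primary, death and emigration, with
constant cause-specific hazards per (subtype, stage); the earliest
clock or the administrative cutoff wins. Independence and the
minimum-wins construction are the simplest structure matching the
estimator's assumptions — the cause-specific cumulative incidence is
identified without modelling dependence between causes. After a
recurrence or second primary, survival continues under a single
post-event death hazard (0.15/year by default). The claims layer then
emits, for **every** woman, primary-treatment codes (surgery admission,
chemotherapy and radiotherapy services) inside her initial treatment
window — 12 months, doubled for HER2+ — creating exactly the
false-positive pressure the surveillance window must absorb; and, for
each true recurrence not suppressed by `p_missed_recurrence`, one
indicator claim of a sampled class after a configurable delay (default
30 days), exercising the "recurrence date = first claim date"
convention. Claims never postdate death or the cutoff. Second primaries
emit no claims: they enter the analysis through their registry date, as
competing events, which keeps the latent truth and the ascertained
outcome comparable in recovery tests.

Default marginals (age, stage, subtype mix; diagnoses 2004–2010;
follow-up to end-2021) reflect the composition of a population-based
non-metastatic cohort of that era, and the default hazard table is
calibrated only so the 10-year incidence *ordering* follows the
clinical gradient (stage III > II > I, TN > HER2+ > HR+/HER2−) with an
overall level around 20%; no published estimate is a calibration
target. Claim-noise magnitudes (delay, class mix, missed-claim
probability) are conventions, not measured facts. The simulator does
**not** emulate screening-driven stage migration, treatment-era effects,
non-exponential (e.g. subtype-specific late-recurrence) hazard shapes,
second-primary treatment claims, or coding error beyond the malformed
strings the matcher tolerates — so passing recovery tests demonstrate
the pipeline's logic is correct under its stated assumptions, not that
the indicator algorithm is clinically valid; that requires external
validation against chart review.

Registry rows produced by the simulator are eligible by construction
(except early deaths and over-74 tails of no band); the eligibility
cascade is instead exercised on hand-built registries via
`registry_skeleton()`, which returns clean rows to be mutated into
specific violations.

## Numerical conventions and test design

* Reproducibility: one integer seed per configuration; identical
  configurations give byte-identical output tables (asserted at the
  file level).
* Percentages round half-up (`floor(x·10 + 0.5)/10`), matching printed
  epidemiological tables; base `round()` would round half-even.
* Right-continuity: `cif_at()` at an event time returns the post-jump
  value; lookups beyond the last follow-up return the last value with
  an `extrapolated` flag.
* Degenerate inputs: events at time 0 are rejected (no time at risk);
  an empty risk set under delayed entry is an error, not an NaN.
* Problem sizes: the estimator is checked against a brute-force
  product-limit oracle on 200 randomised datasets of up to 8 subjects
  (exact to 1e−10), against `survival`/`cmprsk` on datasets of ~120,
  and against the constant-hazard closed form
  $(\lambda_k/\lambda_+)(1-e^{-\lambda_+ t})$ on a 20,000-woman
  simulation with no censoring before 30 years (absolute deviation at
  10 years below 0.01). Detection recovery uses 2,000–4,000 women with
  zero claim delay and no missed claims, where ascertained recurrence
  dates must equal the latent truth for every woman whose recurrence
  falls at or after her surveillance start. These sizes keep each
  property statistically sharp at the tolerance asserted.

## Limitations

Local, regional and distant recurrences are not distinguished — claims
cannot separate them. Cause of death is not modelled, so "death after
recurrence" is not "death from recurrence". The indicator code lists
are configurable defaults, not validated instruments; single claims
trigger classes 1–2, with no persistence requirement. Probabilistic
record linkage is out of scope: inputs are assumed pre-linked on the
pseudonymous identifier.
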