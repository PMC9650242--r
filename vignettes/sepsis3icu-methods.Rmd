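---
title: "Methods: operationalising Sepsis-3 on ICU event tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operationalising Sepsis-3 on ICU event tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The phenotype

Sepsis-3 defines sepsis as life-threatening organ dysfunction caused by a
dysregulated host response to infection, operationalised clinically as an
acute rise of at least 2 points in the Sequential Organ Failure Assessment
(SOFA) score together with a suspected or documented infection. Septic shock
is the subset additionally requiring vasopressor support and an elevated
lactate. Neither "suspected infection" nor "acute rise" is directly recorded
in an ICU database, so any retrospective cohort needs an explicit, auditable
operationalisation. This package implements one such rule engine over
long-format ICU event tables (admissions, drug administrations, numeric
measurements, list observations) and documents every decision below.

```{r, eval = FALSE}
library(sepsis3icu)
gen <- generate_cohort(tables23_fixture(), tempfile())
store <- read_tables(gen$paths)
out <- run_pipeline(store, day_range = c(-3L, 1L))
out$sepsis
```

## Time windows

All timestamps are integer milliseconds relative to the admission instant
(the convention of the source tables this package targets), which removes
calendar and timezone logic entirely. A "day" `d` is the half-open interval
`[d*24h, (d+1)*24h)`; `assign_window()` is floor division, so day 0 starts at
admission and negative days index the pre-admission period (pre-admission
events occur because patients are monitored in the emergency department or
operating theatre before the ICU admission record opens). Windows are
anchored at admission time, not midnight: the alternative (calendar days)
would make the first window's length depend on the admission hour, and
nothing in the data model requires wall-clock alignment.

## Daily SOFA scores

Each of the six components (respiration, coagulation, liver, cardiovascular,
central nervous system, renal) is scored 0–4 per window from
*worst-in-window* aggregates — minimum for PaO2, platelets, mean arterial
pressure (MAP) and Glasgow Coma Scale; maximum for FiO2, bilirubin,
creatinine and vasopressor doses; total for urine output. Worst-value
aggregation (not mean, not last observation) is how SOFA is defined; urine
output is summed because its cut-offs are mL per day while events record
partial volumes. The PaO2/FiO2 ratio is formed as min(PaO2)/max(FiO2) within
the window — a worst-case pairing; FiO2 recorded as a percentage (value > 1)
is divided by 100.

Default cut-offs follow the 1996 consensus score in the source database's
units and live in `inst/extdata/sofa_thresholds.yaml`, not in code:

| component | input (unit) | score 1 | 2 | 3 | 4 |
|---|---|---|---|---|---|
| respiration | PaO2/FiO2 (kPa) | < 53.3 | < 40 | < 26.7 (vent.) | < 13.3 (vent.) |
| coagulation | platelets (10⁹/L) | < 150 | < 100 | < 50 | < 20 |
| liver | bilirubin (µmol/L) | ≥ 20 | ≥ 33 | ≥ 102 | ≥ 204 |
| cardiovascular | MAP (mmHg), doses (µg/kg/min) | MAP < 70 | dopamine ≤ 5 or dobutamine | dopamine > 5 or norepi/epi ≤ 0.1 | dopamine > 15 or norepi/epi > 0.1 |
| cns | GCS | 13–14 | 10–12 | 6–9 | < 6 |
| renal | creatinine (µmol/L), urine (mL/day) | ≥ 110 | ≥ 171 | ≥ 300, or urine < 500 | ≥ 440, or urine < 200 |

Two conventions worth making explicit:

* respiration scores 3–4 additionally require a ventilation event in the
  window and are capped at 2 otherwise (standard SOFA respiratory
  convention);
* vasopressor *use* is inferred from the presence of a dose event, under the
  assumption that vasopressors are given when required to hold MAP at or
  above 65 mmHg with adequate fluids — no fluid-adequacy modelling is
  attempted.

`daily_sofa()` emits one row per (admission, window) with at least one
relevant event, plus day 0 for every admission, over a configurable
`day_range` extending the single post-admission day to arbitrarily many
windows before and after admission.

### Missing data

Missing components contribute zero to the total (the total is the sum of the
non-missing components), consistent with assuming unmeasured pre-admission
scores are zero. No imputation and no carry-forward across windows is done:
a bilirubin drawn on day 0 says nothing about day 1 here. Carrying labs
forward would raise apparent completeness at the cost of inventing
measurements; since the missing-count feeds a discard rule (below), we
prefer honest gaps. The per-window `n_missing` is retained so that sepsis
detection can refuse to call a verdict on windows that are mostly
unmeasured.

## Suspected infection via antibiotic escalation

Infection is proxied by *antibiotic escalation*: a rise, relative to the
previous window, in the maximum rank of the antibiotics administered — or,
at an unchanged maximum rank, in the number of distinct agents at that rank
— with at least one agent given intravenously. The rank map (narrow = 1 …
reserve = 4) is data, not code: `inst/extdata/antibiotic_ranks.yaml` ships an
illustrative classification that sites replace with their own. Name
normalisation is case-insensitive exact matching plus a synonym table; no
fuzzy matching, so misspellings surface in the unknown-drug report rather
than being guessed. Two boundary decisions:

* a first-ever intravenous course (previous window antibiotic-free, or never
  observed) counts as an escalation from rank "none";
* "number of antibiotics of maximum rank" counts distinct agents, not
  administrations — four doses of one drug are one agent.

A window with no administrations has no determination and serialises as
`NaN` rather than `False`.

### Prophylaxis

Two routine practices would otherwise masquerade as escalation:

* **Selective digestive decontamination (SDD)**: cefotaxime given routinely
  on admission is disregarded by escalation detection within the first four
  post-admission windows (days 0–3). Ceftriaxone — the agent it is exchanged
  for on actual suspicion of infection — is never excluded. Pre-admission
  cefotaxime is retained, since SDD is an admission protocol. A window whose
  administrations were all excluded is flagged prophylactic.
* **Elective surgery**: for admissions that are planned (`urgency` false)
  and surgical, the earliest window in day −1/0 containing any antibiotic
  administration is treated as perioperative prophylaxis; infection is
  suppressed in that window and the next, while any later window meeting the
  criteria is still identified. Anchoring on the first perioperative
  antibiotic window (rather than day 0 unconditionally) reflects that
  surgical prophylaxis is typically started in theatre, before the ICU clock
  opens.

## Sepsis episodes

A window `d` is a sepsis episode when all of the following hold:

1. escalation in `d` is `TRUE` and the window is not prophylactic/suppressed;
2. the total SOFA score rises by ≥ 2 between `d−1` and `d`, `d−1` and `d+1`,
   or `d` and `d+1` (days inside the computed range with no rows count 0;
   comparisons with days outside the range are skipped);
3. the window is not *indeterminate*: a post-admission window (day ≥ 0) with
   three or more missing SOFA components never yields a verdict.

The indeterminacy rule is deliberately asymmetric in time. For pre-admission
windows, absent components are assumed zero — that assumption is what makes
the pre-admission baseline usable at all, and discarding those windows would
make pre-admission sepsis (a common and clinically real presentation:
deterioration in the emergency department before ICU transfer) undetectable.
Post-admission, an ICU patient with three or more unmeasured organ systems
is an information problem, not a healthy patient, so no verdict is issued.
The serialised table has no indeterminate state (`sepsis_episode` is
`False`), but the API returns an `indeterminate` column so that "no" and
"could not say" are not conflated downstream.

Septic shock is the subset of sepsis episodes with cardiovascular SOFA ≥ 3
(vasopressor support) and worst-in-window lactate ≥ 2 mmol/L; a missing
lactate yields `False`. The comparator (`>=` by default) and both thresholds
are exposed in `shock_criteria()`.

Consecutive flagged windows are *not* merged into episodes-as-events;
deduplication is left to the analyst because the right merging rule depends
on the study question.

## Baseline comparison

`compare_definitions()` implements the pre-existing admission-oriented
criteria — admission-form sepsis flag; severe-infection admission diagnosis
(configurable list, defaults: gastrointestinal perforation, cholangitis,
meningitis); non-prophylactic antibiotics after surgery (reusing the
pipeline's prophylaxis classification, one source of truth); antibiotics
plus cultures drawn within 6 h of admission — and cross-tabulates them
against Sepsis-3 at admission (a sepsis episode at day −1 or day 0) over
unique first admissions, reporting the confusion matrix with Sepsis-3 as the
reference plus sensitivity and specificity (reported as `NaN` when a
denominator is empty).

## The synthetic cohort generator

Because the target database is access-restricted, the package ships a
generator (`scenario_spec()`, `random_scenario()`, `generate_cohort()`) that
emits schema-compatible CSV tables with *planted* per-window component
scores and antibiotic schedules. Raw values are drawn uniformly inside the
scoring band of the planted score, shrunk away from the band edges by a 5%
margin so recovered scores never sit on a threshold; GCS is drawn from the
integer band. Ground truth (expected scores and flags) is derived at
generation time by direct rule application in a second, separate
implementation of the escalation/delta logic, making label-recovery tests a
genuine two-implementation cross-check rather than a tautology.

What the generator does **not** emulate: physiological autocorrelation
(draws are independent per window), realistic dosing or pharmacokinetics,
the real item vocabulary or identifiers, inter-hospital practice variation,
and measurement noise beyond band placement. Passing recovery tests
therefore demonstrates that the rule engine implements its stated rules
exactly — not that those rules are clinically optimal on real data, where
concept mapping and unit handling dominate the error budget.

## Numerical and degenerate-input choices

* Threshold comparisons use the inclusivities in the table above; all
  cut-offs are config so a site can flip a boundary without touching code.
* An empty store yields header-only output files, not an error.
* Ties and duplicate events are harmless: aggregation is by extremum/total
  and agents are deduplicated by normalised name, so permuting input rows
  never changes any output (tested).
* Output CSV dialect: comma-separated, header row, `NaN` for missing,
  `True`/`False` for booleans, rows sorted by (admissionid, time).

## Problem sizes used in the shipped checks

The test-suite and acceptance script verify: the 4-admission worked-example
fixture cell-for-cell; the SOFA-rise rule against brute force on all 15,625
integer triples in [0,24]³; escalation against brute force on all 6,561
pairs of agent sets (≤ 4 agents, ranks ≤ 3, per-agent IV/oral/absent);
component scoring against an exhaustive band-scan oracle on 10,000 random
windows; planted-label recovery and byte-identical reruns on a seeded
200-admission cohort; the logical chain (septic_shock ⇒ sepsis_episode ⇒
infection ⇒ escalation ∧ ¬prophylaxis) on every generated row; and
sensitivity = specificity = 1 on a 200-admission cohort whose baseline flags
are planted to match Sepsis-3.

## Known limitations

* Escalation-based infection is a proxy reliant on prescribing behaviour,
  not confirmed infection; culture results are not adjudicated.
* The shipped rank map and severe-infection diagnosis list are illustrative
  defaults, not validated clinical content.
* No carry-forward means sparsely sampled labs can inflate `n_missing` on
  real data with daily labs drawn just across a window boundary.
* Population-level counts from the original restricted database are out of
  reach by construction; the baseline comparison is validated structurally
  on synthetic cohorts only.
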