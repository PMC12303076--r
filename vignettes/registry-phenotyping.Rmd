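---
title: "Registry-ready phenotyping from a harmonized EHR common data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registry-ready phenotyping from a harmonized EHR common data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncocdm)
```

## The problem

Population-based cancer registries abstract diagnoses, treatments and
outcomes from hospital EHRs by hand, months after the fact. An automated
alternative harmonizes the structured part of the EHR — ICD-10 diagnosis
codes, ATC-coded prescriptions, LOINC-coded laboratory results, admission
records, transplant events — into a common data model (CDM) and derives
registry facts from it by explicit rules. `oncocdm` implements that
derivation layer together with a synthetic cohort generator, so the rules
can be validated quantitatively without any access to patient data.

## The common data model

Nine flat tables (patients, care trajectories, diagnoses, prescriptions,
labs, admissions, imaging reports, stem-cell transplants, registry extract)
with opaque string identifiers. Design choices worth spelling out:

* Birth is recorded as a **year only**. Age enters the model solely through
  the adult-registry invariant (age ≥ 18 at diagnosis) and coarse age-band
  composition, so a full birth date would add synthetic-PII realism without
  analytic value.
* All dates are pure calendar dates; only labs and imaging reports carry
  timestamps (UTC, second resolution). No timezone arithmetic anywhere.
* A prescription with a missing `end_date` is a single administration on
  its start date.
* Serialization is RFC 4180 CSV (UTF-8, ISO-8601) with fixed file names;
  JSON-lines is an equivalent alternate. Code lists inside a cell
  (secondary admission diagnoses) are semicolon-joined.
* `validate_dataset()` returns violations as data rather than raising,
  because a registry pipeline wants to report on an inconsistent extract,
  not crash on it.

## Inclusion decisions

A candidate case is a (patient, tumor group) pair whose earliest trajectory
start is at least **28 days** old at the evaluation date — four weeks of
maturation so the diagnostic work-up is complete; the boundary is closed
(day 28 surfaces). Inclusion requires a new oncological diagnosis and Dutch
residency. The three exclusion reasons are evaluated in fixed precedence —
residency, then relapsed/refractory trajectory (a confirmed same-group
diagnosis strictly predating the trajectory start), then preliminary-only
diagnosis — because the reasons are otherwise not mutually exclusive;
precedence makes each decision single-valued and therefore scorable. Two
open points were decided as follows: the relapse lookback is unlimited
within the dataset (no horizon is defensible a priori), and a candidate
with no diagnosis rows at all is included (the trajectory itself evidences
the diagnosis; the generator never produces this case).

Retrospective matching classifies each registry record as matched in the
same year, year mismatch, or tumor-group mismatch, partitioning the
extract. A registry patient wholly absent from the CDM is a fourth,
flagged category: the generator never produces it, real data could.

## Regimen inference

Prescriptions are normalized to drug classes via an editable ATC map.
Corticosteroids (dexamethasone, prednisone, prednisolone) share one class —
forced by the observation that a lenalidomide–prednisone combination must
match the lenalidomide–dexamethasone (Rd) catalog entry. "Within the same
week" is implemented as a **7-day half-open rolling window anchored at the
earliest unassigned prescription**, not an ISO calendar week: a calendar
week would make the same-week merge failure depend on which weekday therapy
started, whereas the rolling window reproduces it whenever co-starts fall
within 7 days.

Matching is largest-subset search over the catalog (ties: larger class set,
then catalog order), with one dose-based disambiguation: an episode whose
only anti-myeloma class is lenalidomide is maintenance if the daily dose is
≤ 10 mg **and** no corticosteroid co-occurs, else Rd. The 10 mg threshold is
the standard maintenance dose; a 15 mg prescription therefore upgrades to
Rd, which is exactly the documented misreading. Whether the original
system split on dose, steroid co-prescription or both is underdetermined by
its published behaviour; this package uses both, and the threshold is a
parameter. Consecutive same-name episodes with a gap ≤ 60 days merge into
one course (a re-prescription is not a new line of therapy); the 60-day gap
is likewise a parameter. Transplants are event-based regimens taken from
the sct table. Episodes of at most 6 classes are verified against an
exhaustive-search oracle in the test suite.

## Toxicity signaling

Toxicity is attributed to treatment inside the window from the first
treatment day to 30 days after the last, truncated to the day before a
stem-cell transplantation; one window per patient (overlapping courses
merge). Ten CTCAE categories are signaled through four channels, each
deliberately simple:

* **Laboratory indicators** at CTCAE grade boundaries — creatinine
  > 1.5× a pre-treatment baseline (most recent value within 90 days before
  the window), bilirubin > 51.3 µmol/L (3× ULN), ALT > 250 U/L (5× ULN).
* **Indicator drugs**: trigger sets of ATC codes all started within 3 days
  (carbapenems/piperacillin-tazobactam for sepsis, voriconazole for
  aspergillosis, echinocandins for candidiasis, IV metronidazole for
  typhlitis, therapeutic anticoagulation for venous thrombosis). These
  drugs are also prescribed for other indications; false positives are an
  expected property of the channel, not a bug.
* **Report keywords**: case-insensitive whole-word matching with **no
  negation handling** — "no evidence of aspergillosis" signals. The channel
  is kept naive on purpose; replacing it with NLP is out of scope.
* **Admission diagnoses**: listed ICD-10 codes (prefix match) as main or
  secondary diagnosis on an admission overlapping the window; ICU admission
  is its own category via the ICU flag.

The shipped thresholds, trigger sets, keyword and code lists are labeled
reconstructions (built on public CTCAE, WHO ATC and ICD-10 material) in an
editable YAML file; they are defaults, not claims about any particular
hospital's definitions. The default typhlitis trigger deliberately does not
overlap the sepsis trigger so that a planted event of one category never
cross-fires another — multi-drug trigger sets are still exercised in tests.
Channels are defined independently of each other; whether keyword and lab
channels should share definitions for some categories is unknown, so they
do not.

## Laboratory cross-validation

Items pair on the exact key (patient, LOINC code, timestamp); a timestamp
typo therefore surfaces as an unpaired item rather than a value mismatch,
by design. Value comparison is exact numeric equality (tolerance 0) so any
typographical perturbation is caught. The mismatch report emits the
percentage three ways: exact, rounded half-up to two decimals, and a
*display* value rounded **upward** at the second decimal. The display
convention is deliberate: a data-quality report should never understate a
nonzero discrepancy rate, and conservative rounding is the only simple
convention under which 7 mismatches in 1,689 items reads as 0.42% rather
than 0.41%.

## Accuracy semantics

Every accuracy in the score tables is a positive predictive value: correct
predictions over predictions, rounded half-up to a whole percent, with a
blank (never 0%) where nothing was predicted. For regimens the denominator
question is real — a same-week merge turns two true regimens into one wrong
prediction — so `score_regimens()` returns both the PPV table (strata =
predicted category) and a recall table (strata = truth category). A
prediction is correct when it matches a truth regimen of the same patient
on name and both dates within ±3 days; the tolerance absorbs the one-day
staggering of co-started drugs and is a parameter.

## The synthetic generator

The generator's defaults are the study conditions: the four-group case mix
with its sex and age-band composition, trajectory starts over 2021–2023,
and — in `run_validation_study()` — the published sub-study scales: 1,287
prospective candidates with 68 exclusions (11/27/30), a 384-record registry
extract (342/14/28), 117 myeloma patients carrying 198 derived regimens
including the six misclassification scenarios, 254 treated AML patients
with 215 planted toxicity events across the ten categories, and 1,689 lab
items with 7 injected typos. Within those totals, the per-regimen counts of
the myeloma plan are a reconstruction consistent with the published
category totals (the full per-regimen table is not public), and clean
regimen episodes of one patient are spaced 75 days apart so distinct
episodes never collide with the 7-day window or the 60-day merge.

What the generator emulates: coding systems, co-start patterns, evidence
channels, manual-registration typos (single-digit substitutions and decimal
shifts on the manual copy only), benign background prescriptions, and a low
rate (2% of treated patients) of spurious indicator triggers. What it does
not emulate: clinical narratives beyond template sentences, dose tapering
and cycle structure, outcome/survival, coding errors in diagnoses, or
inter-hospital heterogeneity. Passing tests therefore demonstrate that the
engines implement their rules exactly and recover everything those rules
can express — not that the rules themselves would achieve the same
accuracies on real hospital data, where the failure modes are richer.

## Numerical and degenerate-input choices

Half-up rounding everywhere a whole percent is printed (matching how such
tables are conventionally prepared in spreadsheets), ties in catalog
matching broken by catalog order, empty datasets flow through every engine
as empty results, an attribution window may be empty when a transplant
precedes the treatment end (then nothing can signal), and all engines are
pure functions of their inputs — shuffling input rows or re-running never
changes a result. Determinism is tested end to end: one seed, byte-identical
reports.

## Known limitations

Rule-based extraction of facts that are not structurally recorded (regimen
names, toxicity) inherits the ambiguity of its rules; the package makes
those rules explicit and parameterized rather than pretending they are
complete. The unstructured-text channel is keyword matching only. The
catalogs ship as starter files and are meant to be replaced per deployment.
Accuracies measured on synthetic cohorts are upper bounds of a kind: they
verify mechanism, not real-world performance.
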