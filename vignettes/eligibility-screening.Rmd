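---
title: "Automated perioperative eligibility screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated perioperative eligibility screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-volume perioperative services cannot manually screen every surgical
patient for study eligibility. An EHR-embedded alternative computes a
deterministic *computable phenotype* over structured chart data, fires a
best-practice-advisory (BPA) alert inside the clinical workflow when a
patient qualifies, and lets the ordering clinician respond — or not — with
no coordinator in the loop. This package re-implements that architecture as
an offline batch pipeline so the phenotype logic, the alerting rules and
the adherence analytics can be audited, property-tested and stress-tested
on synthetic data.

The pipeline has five stages, each a pure function of the previous stage's
artifact:

1. **simulate** — generate a synthetic EHR cohort plus a ground-truth ledger;
2. **screen** — evaluate the inclusion/exclusion phenotype per case;
3. **alerts** — decide, at discrete polling instants, which eligible cases fire a BPA;
4. **classify** — map each alerted case to one of five enrollment outcomes;
5. **report** — compute accuracy/adherence metrics, provider distributions,
   bias comparisons and the multivariable adherence model.

## The phenotype

A case is *included* when it meets at least one major criterion or at
least two minor criteria (`majors_met >= 1 || minors_met >= 2`). The 11
criteria and 9 exclusion flags are listed in `criterion_definitions()` and
the README; their thresholds, lookback windows and token lists are
externalized in `inst/extdata/criteria.yaml` and
`inst/extdata/code_sets.yaml` so an audit can diff the configuration
against its clinical source without reading code.

Decisions that shape the semantics:

* **Strict inequalities throughout.** "Greater than 2 hours" is
  `> 120` minutes; a 120-minute case does not qualify. Mean SpO2 of exactly
  95 %, BMI of exactly 35 or 40, hemoglobin of exactly 10 g/dL, GFR of
  exactly 30 and a single prior intubation attempt all fall on the
  non-qualifying side. The generator deliberately produces such
  boundary-sitting negatives at a configurable rate so the tests pin the
  boundaries down.
* **Calendar windows are fixed day counts.** "Within 1 month" is 30 days
  and "past 6 months" is 183 days, both measured backward from the
  scheduled case start. Phrase-based windows would make results depend on
  the calendar month of surgery; fixed counts make every evaluation
  reproducible.
* **The SpO2 criterion is false on an empty window.** The rule reads
  "average SpO2 in the 12 hours prior", which is undefined when no samples
  exist; absence of evidence is not treated as risk.
* **Admission BMI** is operationalized as the latest BMI observation at or
  before the scheduled start. Admission encounters are not modeled, and
  latest-before-start is the closest computable surrogate.
* **ICD-10 code sets** use three token forms: a bare root (`J40`) covers
  itself and every descendant; `J09.x` is an explicit all-descendants
  wildcard; `J41-J41.8` is a per-category inclusive range covering `J41`,
  `J41.0`–`J41.8` and descendants of the upper endpoint, but not `J41.9`.
  Matching is case- and dot-insensitive. Tests compare the matcher against
  an arithmetic interval oracle over every 3–5 character code in the
  relevant categories. Only ICD-10 is implemented; legacy ICD-9 matching is
  out of scope.
* **The head-and-neck disqualifier** follows the literal reading of its
  source: a head-and-neck case is disqualified only when the procedure name
  contains *both* "Mastoid" and "Tympano" (case-insensitive substrings).
  Because either-token-suffices is a defensible alternative reading, the
  rule is configurable (`head_neck_rule: both | either`) and the literal
  `both` is the default.
* **Multiple intubation attempts** counts prior cases only (the
  `prior_max_intubation_attempts` history field), not the current case's
  own induction — at screening time the current induction has not happened.
* **Preop-evaluation flags suffice on their own.** Each diagnosis-driven
  criterion has a structured preop-evaluation flag as a second source
  (COPD, supplemental O2, lung transplant, recent URI, sleep apnea); a flag
  without a coded diagnosis still satisfies the criterion, mirroring the
  two-source layout of the source definitions.

### Exclusions and documentation latency

Age is computed in full calendar years at the scheduled start (the 18th
birthday itself is age 18 and not excluded). An absent GFR never excludes.
A *planned* direct ICU admission excludes at alert time; an *unplanned*
ICU transfer cannot be known preoperatively and is therefore not an
exclusion at screening time — it is handled downstream by the outcome
classifier.

Patient-level exclusion attributes (pregnancy/lactation, neuromuscular
disease, sugammadex allergy, GFR) carry an optional documentation
timestamp, `exclusion_documented_at`. Screening at time `t` only sees
attributes documented at or before `t`; `NA` means always known. This
models EHR documentation latency and is exactly how a correctly functioning
alert can still be *misallocated*: the exclusion was real but not yet
visible when the alert fired. The post-hoc re-screen
(`screen_exclusions(data, as_of = "post_hoc")`) sees everything.

## The alert state machine

Alerts are evaluated at discrete polling instants supplied by the caller
(`default_polls()` derives two per case: one 24 h before the scheduled
start, one 5 min after it), never from a continuous clock — replaying the
same polls yields bit-identical ledgers. An instant fires iff the case is
included with no visible exclusion, the site is covered, the instant falls
inside pharmacy hours, and it lies in the preop lead window (context
`preop`) or inside the scheduled case (context `intraop`). At most one
alert is recorded per case per context; a non-firing poll logs one stable
reason code (`ineligible`, `excluded`, `site`, `hours`, `window`,
`duplicate`).

Availability defaults are configuration, not code: pharmacy hours
07:00–22:00 and a 7-day preop lead window. Neither value is published for
the production system; these are plausible operating-room-pharmacy values
chosen once, and any deployment-specific audit should set its own.
Downstream metrics count *cases*, not alerts, so recording both contexts
never double-counts.

The pipeline screens once per case, at the scheduled start, and feeds that
decision to both polls. Re-screening at each poll instant is supported
(`as_of` accepts per-case timestamps) but is not the default, because a
single decision snapshot per case is what the downstream funnel arithmetic
assumes.

## Enrollment classification

Every alerted case maps to exactly one status under a strict precedence:

1. `misallocated_exclusion` — an exclusion was in fact satisfied (post-hoc
   re-screen with all documentation visible);
2. `icu_disposition` — ICU admission, planned or unplanned, regardless of
   medications;
3. `enrolled` — sugammadex administered through the BPA-linked study
   pathway;
4. `nonadherent_stock_sugammadex` — only standard-stock sugammadex given;
5. `nonadherent_no_study_drug` — otherwise.

Misallocation outranks ICU disposition so the two error buckets never
double-count a case. Unalerted cases are outside the classifier's domain.
A study-pathway medication that is not BPA-ordered sugammadex is a data
contradiction and a validation error, not a classification input.

## Metrics and their denominators

All proportions are reported with numerator, denominator and a 95 % CI
(Wilson score by default — it behaves well at small n and never leaves
[0, 1]; the normal/Wald interval is available for comparison with intervals
computed that way elsewhere).

* `allocation_accuracy_pacu` = appropriate alerts / alerts to non-ICU
  cases; `allocation_accuracy_all` = appropriate alerts / all alerts.
  Whenever any ICU dispositions exist the PACU-restricted accuracy is
  necessarily the larger of the two (same numerator, smaller denominator).
* `adherence_overall` = enrolled / appropriately allocated cases — the
  accuracy-then-adherence funnel. An `adherence_all_alerted` variant over
  every alerted case is always reported too, because published headline
  adherence figures have used the wider denominator and the two are not
  reconcilable after the fact unless both are printed.
* `rocuronium_share_pacu` = appropriately allocated cases that received
  rocuronium (the drug that makes reversal, and hence the intervention,
  relevant).

Provider-level analysis computes each attending's adherence over their
alerted, appropriately allocated cases, then summarizes attending-level
rates per team composition with type-7 (linear-interpolation) quartiles and
whiskers at 1.5×IQR clamped to observed values — the quartile convention
must be fixed for box statistics to be reproducible. Attendings under a
configurable minimum case count are flagged `low_volume` but retained.

The bias table compares adherent and non-adherent groups variable by
variable: Welch t-test for normal continuous variables (mean ± SD),
Mann-Whitney U for skewed ones (median [IQR]), chi-square for categorical
variables unless any expected cell is below 5, in which case Fisher's exact
test is used. No multiple-testing adjustment is applied — the table mirrors
a descriptive bias assessment, and the report says so. Mortality is
reported as bare counts only; testing a handful of events would lend false
precision to a very low-frequency outcome.

The adherence model is a maximum-likelihood logistic regression of
`enrolled` on team composition (reference: full team), the three delay
flags, long surgery, age in decades, BMI > 40, low hemoglobin and low SpO2,
fitted on the subset where the adherence question is well-posed: alerted,
appropriately allocated, PACU-recovering cases that received rocuronium.
Wald 95 % CIs are reported; complete separation (|log OR| > 10 or an
unbounded upper CI) and non-convergence are detected and surfaced as
structured warnings naming the term. An ASA-like severity score is *not*
among the covariates because the interchange schema does not carry one —
ASA status is typically not filed in time for automated preoperative use,
and the generator does not emit it.

## The synthetic cohort generator

Generation is **constructive**: the latent truth is sampled first — which
criteria and exclusions each case satisfies, each attending's adherence
propensity, the intended response to an alert — and facts are then emitted
that realize that truth. A rejection-sampling design would make
ground-truth consistency a statistical property; the constructive design
makes it an identity, so any disagreement between the generator's ledger
and the rule engine is a bug in exactly one of the two. This identity is
tested at n = 10 000 across five seeds.

Realization details that matter:

* Positives are drawn safely inside their region (e.g. SpO2 window means in
  88–94.5, durations 121–480 min); negatives are drawn safely outside,
  except that a configurable fraction (`boundary_negative_rate`, default
  0.15) sit exactly on the boundary — SpO2 samples {94, 96}, duration 120,
  BMI 35 or 40, hemoglobin 10.0, GFR 30, 24 ventilator hours — and others
  just outside a window (an infection 31–90 days old, a low hemoglobin 190+
  days old, low SpO2 samples 13+ hours before start).
* Emitted codes include dotted, dotless and lower-case variants so
  normalization is exercised end to end, plus near-miss codes (`J41.9`,
  `G47.30`) and irrelevant background diagnoses.
* One RNG stream per record type, all derived from the master seed, so
  adding a field to one block never perturbs draws in another; a fixed
  `sim_config()` reproduces the cohort bit for bit. The committed 50-patient
  fixture (`inst/extdata/fixture_cohort/`) embeds its own config and seed,
  and a test regenerates and byte-compares it, along with a golden copy of
  its screened eligibility table.
* Provider behavior: each attending draws a latent adherence propensity
  once, from a beta distribution centered on their team category's
  configured propensity (concentration `provider_concentration`, default
  10; `Inf` collapses to a point mass). Solo attendings optionally draw
  from a two-component beta mixture (component means 0.15/0.75 with weights
  solving for the configured mean) — two interpretable parameters that
  qualitatively reproduce the observed bimodality of solo-attending
  adherence. Per-case enrollment probability applies configured covariate
  effects on the log-odds scale around the provider's propensity.
* Misallocations arise mechanically from documentation latency: a fraction
  (`late_documentation_prob`) of patient-level exclusions are documented
  only after the case, so the alert-time screen cannot see them and the
  post-hoc classifier can.

### Parameter defaults

The team-conditional adherence propensities default to the reported
team-stratified rates (full team 57.4 %, attending+CRNA 56.9 %,
attending+resident 52.6 %, solo attending 42.2 %), and the rocuronium
probability to the reported 68.6 % share — these are the study conditions
the generator emulates. Criterion and exclusion prevalences in the source
cohort are unpublished; the defaults (e.g. lung disease 12 %, OSA 12 %,
long surgery 45 %, low hemoglobin 8 %) are **placeholders** chosen once to
give every criterion non-trivial representation in moderate cohorts, with
exclusion prevalences and `late_documentation_prob = 0.5` set so the
misallocated and ICU error buckets have magnitudes comparable to the
reported error classes (a few percent and ~10 % of alerts respectively).
The team mix (15/25/40/20 %) and site mix are likewise plausible
academic-center placeholders. None of these defaults should be read as
estimates of the source cohort.

### What the generator does and does not emulate

It emulates the *structure* of the data the phenotype consumes — criterion
prevalences, temporal windows, boundary cases, documentation latency,
team-dependent provider behavior — and that is what passing tests certify:
the engine implements the stated rules exactly, the funnel is internally
consistent, and injected behavioral parameters are recovered. It does not
emulate realistic ICD code frequency distributions beyond the relevant
sets, multi-admission longitudinal histories, correlated comorbidity
structure, or free-text variation beyond the listed tokens. Passing tests
therefore say nothing about how the phenotype would perform against real
charting practice — that is precisely the gap between a verified
implementation and a validated deployment.

## Test design and problem sizes

The oracle suite re-implements every rule naively (per-case base-R loops
re-reading every fact; an arithmetic interval oracle for code ranges; a
closed-form Wilson formula; a sort-based quantile reference; an independent
Monte-Carlo loop for Mann-Whitney power) and checks exact agreement with
the vectorized engine on 10 000 randomized cases, plus the boundary
catalogue above. Ground-truth consistency runs at n = 10 000 over five
seeds; the funnel-containment and metric-sanity properties at n = 5 000.

Parameter-recovery tests use degenerate provider configurations —
point-mass propensities, covariate effects zeroed except the one under
study, every case eligible, alerted, PACU-recovering and
rocuronium-treated — so the injected coefficient *is* the marginal
estimand: with provider-level heterogeneity left in, a marginal logistic
fit would attenuate the conditional coefficient and the test would measure
the attenuation, not the implementation. Team propensities are checked
within 95 % binomial bounds at 20 000 cases; an injected +0.30 log-odds
long-surgery effect must be recovered within 10 % of OR = 1.35 at the same
size; null simulations (all effects zero, propensity 0.5) must give ≥ 93 %
pooled Wald-CI coverage of OR = 1 across 200 seeds at n = 5 000. The
provider *mixture* machinery is exercised separately: a bimodal solo
configuration must produce a wider solo-team IQR than the full-team IQR at
n = 6 000.

## Known limitations

* Single-institution semantics: timestamps are timezone-naive local
  clinical time; multi-site timezone handling is out of scope.
* One surgical case per synthetic patient; the prior-intubation history is
  carried as a summary field rather than as linked prior cases.
* The alert decision snapshot is taken at the scheduled start rather than
  re-evaluated at each poll; production systems may re-evaluate
  continuously.
* Free-text procedure matching is token-based; no NLP.
* The published headline rates themselves (51.2 % adherence, 69.7 %/59.4 %
  accuracy, the reported ORs) arise from clinical data that is not
  available; this package reproduces their *arithmetic* and their
  *machinery*, not their values.
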