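# periscreen

Offline, testable re-implementation of an EHR-embedded clinical decision
support (CDS) pipeline that automates trial eligibility screening and
enrollment for high-risk perioperative patients. The package is for clinical
informaticians and implementation-science researchers who want to study,
audit or stress-test this class of automation — a computable phenotype, a
best-practice-advisory (BPA) alert layer and its adherence analytics —
without access to protected clinical data: a bundled synthetic EHR
generator produces statistically controlled cohorts with a ground-truth
ledger, so every stage of the pipeline can be verified end to end.

## The phenotype and the pipeline

A patient–case pair is **rule-eligible** when it meets at least **one major
criterion or two minor criteria**, and no exclusion applies:

| Tier | Criterion | Operationalization |
|---|---|---|
| major | obstructive / restrictive lung disease | ICD-10 sets (J40, J41–J41.8, J42, J43–J43.9, J44–J44.9, J45, J47–J47.9, J84.1, J84.9, D86) or preop COPD / supplemental O2 / lung-transplant flags |
| major | acute respiratory infection | matching diagnosis with onset ≤ 30 d before surgery, or recent-URI flag |
| major | obstructive sleep apnea | G47.33 or sleep-apnea flag |
| major | low preoperative SpO2 | mean SpO2 < 95 % over the 12 h before the scheduled start |
| major | airway pathology | > 24 h mechanical ventilation or pre-admission tracheostomy |
| major | BMI > 40 | latest BMI observation at or before the scheduled start |
| minor | multiple intubation attempts | > 1 documented attempt in a single prior case |
| minor | long surgery | scheduled duration > 120 min |
| minor | surgical site | upper abdominal / intrathoracic / head-and-neck service + procedure-name tokens, or listed CPT codes |
| minor | BMI > 35 | as BMI > 40 |
| minor | low hemoglobin | serum hemoglobin < 10 g/dL within 183 d |

Exclusions: age < 18 years, pregnancy/lactation, neuromuscular disease,
GFR < 30, documented sugammadex allergy, planned postoperative intubation,
planned direct ICU admission, non-intubated airway plan, emergency surgery.
All thresholds are strict inequalities.

Eligible cases **fire a BPA alert** at discrete polling instants, gated by
site coverage and OR-pharmacy hours; alerted cases are then **classified**
into exactly one of five enrollment outcomes (misallocated exclusion, ICU
disposition, enrolled via the study pathway, stock-sugammadex bypass, no
study drug), and the **analytics** layer computes allocation accuracy,
adherence with Wilson 95 % CIs overall and by care-team composition,
provider-level adherence distributions, adherent-vs-non-adherent bias
comparisons, and a multivariable logistic adherence model.

## Worked example

```r
library(periscreen)

fix <- system.file("extdata", "fixture_cohort", package = "periscreen")
cfg <- read_sim_config(file.path(fix, "sim_config.yaml"))
cfg$n_patients <- 2000L

res <- run_pipeline(cfg, out_dir = tempfile())
res$report$funnel
#>   stage             n
#> 1 cases          2000
#> 2 rule_eligible   833
#> 3 alerted         734
#> 4 appropriate     646
#> 5 enrolled        365
res$report$metrics
#> <cohort_metrics>
#>   alerted cases: 734
#>   accuracy (PACU)              646/  665 =  97.1% (95.6%-98.2%)
#>   accuracy (all alerts)        646/  734 =  88.0% (85.5%-90.2%)
#>   misallocation                 19/  734 =   2.6% (1.7%-4.0%)
#>   ICU share                     69/  734 =   9.4% (7.5%-11.7%)
#>   adherence (appropriate)      365/  646 =  56.5% (52.7%-60.3%)
#>   adherence (all alerted)      365/  734 =  49.7% (46.1%-53.3%)
#>   ...
```

Of 2000 simulated cases, 833 meet the phenotype; 734 alert (the rest fall
outside covered sites, pharmacy hours or carry a visible exclusion); 646
alerts are appropriate (not misallocated, PACU recovery) and 365 of those
enroll through the study pathway — 56.5 % provider adherence on the
appropriate-allocation denominator, 49.7 % on the all-alerted denominator.
Both denominators are always reported because headline adherence rates
depend on which funnel stage they are anchored to.

Single cases can be audited with full evidence:

```r
evaluate_case(res$data, "C000001")
#> <eligibility_decision> case C000001: INCLUDED (1 major, 1 minor)
#>   [major] lung_disease: preop evaluation flag: copd
#>   [minor] long_surgery: scheduled for 284 min
```

A thin CLI over the same functions lives at `inst/cli/periscreen.R`
(subcommands `simulate`, `screen`, `alerts`, `classify`, `report`,
`pipeline`).

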