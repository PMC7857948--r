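# spcddi — empirical filtering of VKA drug-drug interaction alerts

Drug-drug interaction (DDI) alerts for vitamin K antagonists (VKAs) are
numerous enough that firing all of them in a clinical decision support
system produces alert fatigue. `spcddi` implements the empirical
alternative: reuse the hospital's own inpatient records to estimate,
for every DDI rule, the odds of the predicted INR excursion — VKA
potentiation (INR ≥ 5) or inhibition (INR ≤ 1.5) — and deactivate
alerts the data do not support, while keeping alerts whose evidence
base is too thin to judge.

For each rule "VKA + drug X (initiated | discontinued) → outcome" and
each inpatient stay, the package classifies the stay as exposed or
nonexposed, builds an observation window from a 1-day onset and a 4-day
residual-action lag, searches the window for the outcome, and estimates
a three-tier odds-ratio cascade over the resulting 2×2 table:

1. the **unadjusted OR** — conditional maximum-likelihood estimate of
   the noncentral hypergeometric model with exact tail-inversion 95%
   limits (the Fisher-exact estimator);
2. the **adjusted OR** — multivariable logistic regression on exposure
   plus seven categorized covariates (age, albumin, prealbumin,
   creatinine, transaminases, TSH, Nt-proBNP), missing labs imputed to
   their reference class;
3. the **stepwise OR** — AIC-driven bidirectional covariate selection
   with the exposure term locked in.

Rules with fewer than 3 exposed stays are flagged `insufficient_data`
and their alerts stay active. Otherwise a rule is classified
`significant_risk` (lower limit > 1, alert kept), 
`significant_protective` (upper limit < 1, alert deactivated) or
`no_significant_association`.

Because the multi-hospital EHR database this analysis was designed for
is not public, the package ships a seeded synthetic-EHR generator
(`simulate_cohort()`) that emulates its structure — VKA episodes,
companion-drug exposures, INR trajectories whose excursion odds follow
a configurable logistic model, covariate labs with missingness — and
serializes the ground truth so estimators can be scored against it.

## Worked example

The `analysis/` directory is a four-step workflow over a synthetic
study-shaped cohort (4047 analyzed stays, eight companion drugs with
known injected effects):

```sh
Rscript analysis/01_simulate.R   # cohort + ground truth -> results/data/
Rscript analysis/02_describe.R   # inclusion + descriptives
Rscript analysis/03_estimate.R   # 282-rule OR cascade -> results/estimates.csv
Rscript analysis/04_report.R     # decisions + report -> results/report/
```

Step 2 prints the descriptive summary of the simulated subcohort:

```
Included: 4047 of 4047 stays (100.00%)
Analyzed subcohort: 4047 stays
  age          : mean 75.9 y (SD 12.1)
  length of stay: median 9 d (IQR 6-15)
  deaths       : 162 (4.00%)
  sex female   : 2328 (57.5%)
```

Step 3 loads the shipped rulebook fixture (149 literature entries → 7
excluded without ATC terms → one shared-ATC merge → 141 curated
entries → 282 initiation/discontinuation rules) and estimates every
rule; with the demonstration cohort, 16 rules have ≥ 3 exposed stays.
A drug injected with a true initiation OR of 2.2 (ciprofloxacin) comes
back in the step-4 report as:

```
| ciprofloxacin | INR>=5 | 164 | 2.09 (1.43, 3.02) | 2.09 (1.46, 3) | 2.11 (1.47, 3.02) |
```

classified `significant_risk` (alert kept active), while a protective
injected effect (furosemide initiation, true OR 0.4) is classified
`significant_protective` and its alert deactivated:

```
         insufficient_data no_significant_association 
                       266                         12 
    significant_protective           significant_risk 
                         2                          2 
Alerts kept active: 268 of 282 rules
```

(The demonstration cohort also shows a truly null drug, rifampicin,
reaching OR 1.75: with several non-null drugs in one cohort, stays
exposed to one drug sit in the nonexposed arm of every other rule and
shift its baseline — the cross-rule contamination the methods vignette
discusses, and the reason calibration claims are made on single-drug
cohorts.)

The programmatic interface mirrors the workflow: `read_cohort()`,
`apply_inclusion_criteria()`, `load_rulebook()` / `curate_rulebook()` /
`expand_rules()`, `assemble_table()`, `fisher_or()` / `adjusted_or()` /
`stepwise_or()`, `estimate_all_rules()`, `classify_all_rules()`,
`render_report()`, or `run_pipeline()` for the whole chain.

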