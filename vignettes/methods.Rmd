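---
title: "Empirical filtering of VKA drug-drug interaction alerts: methods"
author: "spcddi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical filtering of VKA drug-drug interaction alerts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcddi)
```

## The problem

Clinical decision support systems (CDSS) embedded in computerized order
entry fire an alert whenever a prescription matches a drug-drug
interaction (DDI) rule. For vitamin K antagonists (VKAs) the list of
potentially interacting drugs is long, and firing on all of them
produces over-alerting and alert fatigue. The idea behind a
*statistically prioritized and contextualized* CDSS (SPC-CDSS) is to
estimate, from a hospital's own electronic health records, the
empirical probability that each rule's predicted outcome actually
occurs, and to deactivate alerts whose empirical signal does not
support them — while keeping alerts whose evidence base is too thin to
judge.

`spcddi` implements that analysis end to end: longitudinal EHR tables
in, per-rule odds ratios and alert activation decisions out, plus a
seeded synthetic-EHR generator used to validate every stage against a
known ground truth.

## Data model

Three delimited tables describe the cohort. Days are integers with
day 1 = admission; the data are daily-grained, so "administered
together" means "on the same calendar day", and a drug given several
times in one day is indistinguishable from one administration.

* `stays`: one row per inpatient stay (demographics, span, death flag);
* `administrations`: one row per (stay, day, ATC code);
* `labs`: one row per (stay, day, analyte, value). Analytes are INR
  (dimensionless), albumin and prealbumin (g/L), creatinine (mg/L),
  ASAT/ALAT (IU/L), TSH (mU/L), Nt-proBNP (pg/mL).

Only stays with at least one INR result and at least one day with a
VKA administration enter the analysis. Any ATC code starting with
`B01AA` counts as a VKA, and several distinct VKA codes within one stay
are treated as continuous exposure to the class.

## DDI rules

A rulebook row is a (drug label, interaction direction) pair with its
ATC codes. Curation removes entries with no ATC term and merges entries
sharing an identical ATC code set and direction (the merge criterion
that combines, for example, two amoxicillin combination products with
one shared code). Each curated entry expands to an initiation rule and
a discontinuation rule with the *opposite* expected outcome: a
potentiator is expected to push the INR to >= 5 when started and to
<= 1.5 when stopped under continuing VKA; an inhibitor the reverse. A
drug interacting in both directions carries one entry per direction.
The shipped fixture rulebook (`synthetic_rulebook_path()`) reproduces
the bookkeeping of the literature-derived list this analysis was built
for — 149 raw entries, 7 unmappable, one merged pair, 141 curated
entries (107 potentiating, 34 inhibiting, 4 dual drugs), 282 rules —
using published drug names where available and placeholder rows marked
`synthetic` for the remainder.

ATC matching is exact by default; a per-entry `prefix` mode lets a
class-level code (e.g. `N05CA`, barbiturates) match all members.

## Observation windows

Windows translate a 1-day onset of action and a 4-day residual action
(both configurable whole-day lags) into the day interval searched for
the outcome:

* **Exposed, initiation** — the stay has at least one day with both the
  VKA and the rule's drug. Window: day after the first
  co-administration day, through 4 days after the *first uninterrupted
  co-administration run* ends, truncated at discharge. Only the first
  episode counts; re-initiations later in the stay are ignored, since
  multi-episode handling is not well defined for a single 2x2
  classification.
* **Exposed, discontinuation** — additionally the drug's last
  administration day precedes the VKA's last day (the drug stopped
  while the VKA continued). Window: day after the drug's last day,
  through 4 days later, truncated by the VKA's own residual window and
  by discharge.
* **Nonexposed** (both phases) — every other included stay. Window: day
  after the first VKA day through 4 days after the last VKA day,
  truncated at discharge. For discontinuation rules the nonexposed set
  deliberately includes stays where the drug was given but never
  stopped before the VKA: the comparison mirrors the initiation
  contrast, and excluding them would condition on post-exposure
  information.

A window whose start exceeds its end (e.g. a VKA given only on the
discharge day) drops the stay from that rule's table. The outcome is
any-occurrence within the window, thresholds inclusive: INR >= 5 for
expected potentiation, INR <= 1.5 for expected inhibition. Outcomes
occurring before the window opens are ignored.

## Covariates

Seven categorized covariates enter the adjusted models, with reference
classes marked (ref): age <70 (ref)/70–79/>=80 years; albumin
>=30 (ref)/<30 g/L; prealbumin >=0.11 (ref)/0.07–0.10/<0.07 g/L;
creatinine <=15 (ref)/16–24/>=25 mg/L; transaminases <250 (ref)/>=250
IU/L; TSH 0.5–5 (ref)/abnormal mU/L; Nt-proBNP <450 (ref)/>=450 pg/mL.
They proxy malnutrition, kidney failure, liver failure, dysthyroidism
and heart failure.

Three numerical choices deserve note. First, the printed integer class
labels leave gaps (creatinine 15.5, prealbumin 0.105); the
implementation assigns the gap to the middle class (<=15, (15,25),
>=25), which preserves the printed labels exactly on integer-valued
data while making the function total. Second, "ASAT/ALAT" is read as a
level threshold applied to the larger of the two transaminases — the
250 IU/L unit makes a ratio reading implausible. Third, the value
feeding each covariate is the **first** measurement of the stay
(deterministic, approximates admission status); a `worst`-value mode is
available through `ddi_config(covariate_value = "worst")`. Analytes
never measured during a stay are imputed with the reference class and
flagged: in routine care an unmeasured parameter is more likely normal,
so data are treated as not missing at random.

## The estimation cascade

For each rule with at least `min_exposed_stays` (default 3) exposed
stays, three odds ratios are estimated over the full included-stay
denominator:

1. **Unadjusted** — the conditional maximum-likelihood odds ratio of
   Fisher's noncentral hypergeometric model, with exact tail-inversion
   confidence limits at $\alpha/2$ per side. This is the estimator
   exact-test implementations report, and it produces the degenerate
   reporting shapes a zero cell requires: $a = 0$ gives a point
   estimate of 0 with limits $(0, U)$, $U$ finite. The implementation
   solves $\mathrm{E}_\psi[X] = a$ and inverts
   $P(X \le a \mid \psi) = \alpha/2$ with tight root tolerances; unit
   tests cross-check it against `stats::fisher.test`, and the
   acceptance suite against an independent grid-search oracle on every
   2x2 table of total at most 30.
2. **Adjusted** — multivariable logistic regression of the in-window
   outcome on exposure plus the seven covariates; the adjusted OR is
   the exponentiated exposure coefficient with a Wald interval. Wald
   was chosen over profile likelihood because it is deterministic and
   cheap at this scale, and its failure mode — separation — is detected
   explicitly: any coefficient beyond ±15 on the log-odds scale, an
   exposure standard error beyond 15, a singular information matrix or
   nonconvergence flags the result "confidence limits not computable"
   while keeping the degenerate point estimate (the footnoted `0^d`
   rendering).
3. **Stepwise** — bidirectional AIC-driven selection starting from the
   full model with the exposure term locked in (every rule must report
   an exposure OR, so the exposure cannot be dropped). The selection
   loop scores each single covariate removal or re-entry and stops when
   no move lowers the AIC; ties break deterministically toward
   removals in declaration order. AIC and the bidirectional direction
   are a design choice: the source analysis cites a stepwise procedure
   without specifying the criterion.

No multiplicity correction is applied across rules: decisions are
per-rule at a fixed type-1 error, which is how the alert-filtering
threshold is defined. Repeat admissions of one patient are counted as
independent statistical units — the CDSS is calibrated on solicitations
of its inference engine, not on persons.

## Decisions

Each estimated rule is classified on a basis estimate (stepwise by
default; a noncomputable basis falls back to the unadjusted OR):
*significant risk* if the lower confidence limit exceeds 1,
*significant protective* if the upper limit is below 1, otherwise *no
significant association*; rules below the exposed-stay minimum are
*insufficient data*. Alerts stay active for significant risk and for
insufficient data (statistical filtering is ignored when the learning
database is too small), are deactivated for significant protective
rules, and are deactivated by default for nonsignificant rules — the
rationale being that an alert should reflect a demonstrated risk; the
conservative alternative is one configuration flag away
(`deactivate_nonsignificant = FALSE`). Per-rule conditional outcome
probabilities are available from the contingency tables for users who
prefer probability thresholds to significance tests.

## The synthetic-EHR generator

`simulate_cohort()` emulates the analyzed subcohort: age
N(75.9, 12.0) years, 58.2% women, length of stay from a discretized
lognormal numerically matched to median 9 and IQR 6–15 days (three
summaries, two parameters: least-squares with the median weighted), a
fluindione-dominant VKA mix in the published proportions, one VKA
episode per stay, and covariate labs drawn class-first with per-analyte
missingness so the imputation path is exercised.

Outcomes are generated **at the window level on the logistic scale**:
for each excursion direction the latent indicator follows
$\operatorname{logit} P = \beta_0 + \beta_{\text{drug}} \cdot
\text{exposed} + \sum \text{covariate effects}$, and a realized outcome
places one INR value beyond the relevant threshold uniformly at random
inside the same observation window the analysis will construct, while
all routine INR values stay strictly between the thresholds. Injected
odds ratios are therefore exact on the analysis scale, which makes
recovery tests well-posed. The generator deliberately does not model
INR pharmacokinetics — it validates the pipeline, not coagulation
physiology — so passing recovery tests demonstrate correctness of the
data management and estimation machinery, not fidelity to real INR
dynamics, real measurement schedules, or real confounding by
indication.

Each stay is exposed to at most one companion drug. This is what makes
a drug's injected marginal OR identifiable: with overlapping non-null
drugs, stays exposed to drug B enter drug A's nonexposed arm with
shifted outcome odds and the marginal contrast no longer equals the
injected coefficient. Multi-drug configurations are supported and
useful for workflow demonstrations, but calibration claims are made on
single-drug (or all-null) cohorts. Baseline excursion probabilities
default to 0.12 (INR >= 5) and 0.20 (INR <= 1.5) for a
reference-profile stay — unreported in the source study, chosen once as
plausible for hospitalized VKA patients — and covariate effects default
to modest log-odds ratios (0.15–0.35) so adjustment matters without
creating extreme non-collapsibility.

## Validation problem sizes

The test suite validates: the exact-OR implementation against a
grid-search oracle on all ~46,000 tables of total <= 30 (point
agreement to 1e-3 on the log scale, tail inversion to 1e-6); the
exposure-only logistic identity OR = ad/bc to 1e-6 on 100 random
tables; parameter recovery on 200 replicate cohorts of 2000 stays per
injected OR in {0.5, 1, 2, 3} (mean log-OR bias < 0.1, pooled 95% CI
coverage within [0.92, 0.98] for the unadjusted and adjusted tiers);
null calibration on 500 simulated rules (significant fraction within
[0.03, 0.07] at alpha 0.05); and a hand-traced 10-stay fixture that
pins every window edge case, including INR values exactly at 5.0 and
1.5 and a rule sitting exactly on the 3-exposed-stay estimability
boundary.

## Known limitations

Dose is not modeled; windows use the same onset and residual lags for
every drug even though real pharmacokinetics differ; concomitant DDIs
are not deconfounded (an outcome can be counted for several rules);
the INR is a surrogate, not a clinical outcome; and the exposed counts
for many rules are small, which is precisely why the decision layer
keeps alerts on when data are insufficient.
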