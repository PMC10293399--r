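---
title: "A 21-item frailty index for hip-fracture registry data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 21-item frailty index for hip-fracture registry data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipfi)
```

## The deficit-accumulation model

Frailty in older adults is the loss of physiological reserve that makes a
stressor — here, a hip fracture and its surgical management — disproportionately
dangerous. The deficit-accumulation approach quantifies it without any special
instrument: count health deficits (chronic conditions, functional limitations,
care-dependence markers) from whatever a database already records, and express
frailty as the proportion present,

$$\mathrm{FI} = \frac{1}{21}\sum_{j=1}^{21} d_j, \qquad d_j \in [0,1].$$

`hipfi` implements a 21-item index tailored to national hip-fracture audit
records in which administrative discharge coding (ICD-10-AM diagnosis lists)
sits alongside audit-collected fields:

* **15 dichotomous comorbidities** flagged from diagnosis codes via a prefix
  map: ischemic heart disease, peripheral vascular disease, congestive heart
  failure, COPD, hypertension, diabetes mellitus, dementia, stroke/hemiplegia,
  chronic renal disease, cancer, Parkinson's disease, arthritis, reflux/peptic
  ulcer disease, chronic liver disease, atrial fibrillation.
* **Previous fragility fracture**, recorded by the audit as yes/no.
* **Pre-admission pressure ulcer**: a coded L89 diagnosis *without* an
  audit-recorded new in-hospital ulcer. The audit only captures ulcers that
  develop during the admission, so an L89 code with no new-ulcer record
  indicates an ulcer the patient arrived with.
* **Three New Mobility Score items** (indoor mobility, outdoor mobility,
  shopping), each recoded from its 4-level ordinal scale so that higher is
  worse: no difficulty and no aid = 0, with a walking aid = 0.33, with help
  from another person = 0.67, unable = 1.
* **Nursing-home provenance**: admitted from *or* discharged back to a nursing
  home. Residence itself is not a biological deficit, but it proxies
  care-dependence and cognitive impairment that the audit does not measure.

The NMS fractions are deliberately the two-decimal constants 0.33/0.67 rather
than exact thirds, for bit-fidelity with how the index is specified in audit
practice; `exact_thirds = TRUE` switches to 1/3 and 2/3 (the difference in the
FI is at most 0.01/21 per item).

### Code mapping

Comorbidity flags use dot-insensitive prefix matching (`"I25.1"` matches stem
`"I25"`), because ICD-10-AM dialects differ in dot usage. The shipped
`default_code_map()` uses broad, literature-standard stems (hypertension
I10–I15, diabetes E10–E14, COPD J40–J44, dementia F00–F03 + G30, cancer C00–C99,
atrial fibrillation I48, …) chosen for sensitivity. These defaults are
approximations of any particular registry's coding manual and are fully
overridable from YAML/JSON via `read_code_map()`; structural invariants
(exactly the 15 conditions, syntactically valid stems, no nested prefixes
within a condition) are enforced on load. Absence of a matching code yields a
flag of 0, never missing: under administrative coding conventions an
unrecorded condition is treated as not present, so only previous fracture and
the three NMS items can be missing.

### Missingness policy

The default policy is complete-case: a record missing any of the 21 items gets
no FI, no tertile, and is excluded from all models. This mirrors how such
registry analyses are actually run and keeps the analysable denominator
explicit (the pipeline logs records-in vs complete-FI counts at every run). A
renormalised alternative — sum of non-missing items over their count — is
available (`policy = "renormalise"`) but is never the default, because it
silently changes the measurement scale for incomplete records.

## Risk stratification

Records are stratified into low/medium/high risk tertiles. The default scheme
uses the **fixed cutpoints 0.05 and 0.15** (low: FI ≤ 0.05; medium:
0.05 < FI ≤ 0.15; high: FI > 0.15), the boundaries established in the national
cohort in which this index was derived. Fixing them makes runs on different
cohorts comparable. Empirical tertiles are opt-in
(`tertiles = "empirical"`): cutpoints are the 1/3 and 2/3 quantiles under the
inclusive-rank convention (smallest observed value v with at least ⌈kn/3⌉
observations ≤ v), and all observations equal to a cutpoint fall in the lower
group. We resolve boundary ties by value rather than by rank-splitting because
the fixed cutpoints are themselves stated as "≤" bounds; if ties swallow both
cutpoints the scheme is rejected rather than silently degenerate.

## Outcome models

Six dichotomous outcomes are derived per admission: delirium (ICD-10 F05 in a
non-first diagnosis position — the first-listed code is the primary diagnosis,
and a primary F05 is not counted), prolonged length of stay (≥ 30 days,
boundary inclusive), inpatient death by day 7, by day 14 and overall, and new
nursing-home admission (defined only for patients not admitted from a nursing
home).

Each outcome is modelled by multivariable logistic regression on FI tertile
(low reference), age in single years and sex (female reference). Adjusted odds
ratios are exponentiated coefficients with 95% Wald intervals. The fit itself
is iteratively reweighted least squares with step-halving, which guarantees a
monotone non-increasing deviance trace; convergence is declared when the
deviance changes by less than 1e-8 (configurable) within 100 iterations, and
the coefficient covariance is the inverse observed information at the optimum.
Any coefficient magnitude above 15 rejects the fit as (quasi-)separated: no
plausible clinical odds ratio approaches e^15, and under separation the
deviance flattens while coefficients diverge, so a deterministic bound is the
testable failure contract. Rank-deficient designs are rejected naming the
collinear columns.

ASA enters the comparative risk models as a linear numeric score 1–5 by
default — the most parsimonious reading of "adjusting for ASA score" — with a
categorical alternative (I/II reference, III, IV/V) behind
`asa_coding = "categorical"`, since published characteristic tables band the
classes that way. Records with unknown ASA are dropped from ASA-containing
models only. No imputation is performed anywhere (complete-covariate analysis
per model).

## AUC comparison of nested risk models

For each outcome two models are fitted on the same records: Model 1 (age, sex,
ASA) and Model 2 (age, sex, ASA + continuous FI score). In-sample predicted
probabilities score each record; the AUC is the Mann–Whitney concordance
probability over all case–control pairs (ties counted 1/2), computed by the
rank formulation, which equals the pair count exactly. Standard errors use the
DeLong structural-components variance by default (Hanley–McNeil's closed form
is available); 95% CIs are auc ± 1.96·se truncated to [0, 1], with a
logit-transformed interval behind a flag.

The default AUC difference test treats the two AUCs as **independent**
(z = Δauc/√(se₁²+se₂²)), mirroring the "independent ROC curves" command of
standard audit software, even though the two models score the same patients.
The statistically preferable **paired DeLong** test — which subtracts twice the
covariance of the paired structural components — is implemented and selectable
(`auc_test = "delong"`); on nested models it is typically more powerful.
Fidelity first, correctness available. Discrimination is banded by the usual
rule of thumb: < 0.7 poor, 0.7–0.8 fair, ≥ 0.8 good.

## The synthetic cohort generator

The real registry is not publicly deposited, so `sim_config()` /
`simulate_ihfd()` generate seeded cohorts with the statistical structure the
analysis assumes, giving every pipeline stage a testable input and known
ground truth for parameter recovery.

Defaults emulate the registry's marginal structure: 14,615 admissions, age
truncated-normal with marginal mean 80.4 (SD 8.8, floor 60; the
pre-truncation mean is offset numerically so the realized mean matches),
69.6% female. Each comorbidity follows a logistic-in-age model,
logit P = logit(prevalence at 80) + slope·(age − 80). Baseline prevalences
(hypertension 22%, dementia 12%, atrial fibrillation 8%, …, chronic liver
disease 1%) reflect *admission-episode administrative coding* — conditions are
coded only when active or relevant during the admission, so coded prevalence
sits well below community survey prevalence — and are calibrated once so the
fixed cutpoints 0.05/0.15 split the default cohort into roughly balanced risk
groups, as they did in the registry that defined them. Each present condition
emits one ICD code drawn from its *unambiguous* prefix subset (stems that do
not extend another condition's stem), so the deficit mapping provably
round-trips the generating flags; ingestion of real data still matches the
full broad map. NMS levels follow age-shifted cumulative-logit models; ASA is
drawn conditional on the comorbidity count (8.5% unknown); a noise code
matching no condition is added to 30% of records.

Item missingness uses an audit-gap model: items go unrecorded only within a
missingness-prone subset of records (default 16%), at rates that preserve the
configured marginal missingness (≈ 6.9%, 6.4%, 7.7%, 8.1% for previous
fracture and the three NMS items). Independent missingness at those marginals
would leave only ~74% of records complete; the overlap concentrates
incompleteness so the complete-FI fraction lands near the 85.5% observed in
practice.

Outcomes are then drawn from explicit ground-truth logistic models on tertile,
age and sex. The default tertile log-odds are the published adjusted odds
ratios (mortality 4.75/14.74, prolonged LOS 2.88/4.38, delirium 2.20/2.74, new
nursing-home admission 2.22/4.38 for medium/high), with intercepts calibrated
to the published low-tertile event rates at the low tertile's age/sex mix;
age and sex effects are unpublished and set to clinically plausible values
(e.g. mortality: +0.07 log-odds per year, +0.5 for male sex). Death day comes
from a truncated geometric-like distribution over days 1–60 and is capped at
the final LOS — capping the day rather than inflating the stay keeps the
configured prolonged-LOS and mortality models exact and perturbs only the
(non-configured) 7/14-day split. LOS is a lognormal short-stay component
truncated below 30 days or a 30+ geometric tail according to the
prolonged-LOS draw. New nursing-home admission is simulated only for
community-dwelling patients; returning residents are recorded as "discharged
back", never as new institutionalisation.

Outcome simulation requires an assigned tertile. In simulate mode the pipeline
feeds it the generator's ground-truth tertile (computed before missingness
masking), so every record — including FI-incomplete ones — carries outcomes, and
the complete-case attrition of a real registry run is reproduced downstream.

Generation is fully vectorised under a single seeded RNG stream
(`set.seed(seed)` for the cohort, `set.seed(seed + 1)` for outcome draws), so
identical configurations give byte-identical CSV output and record-level
draws do not depend on processing order.

### What the generator does and does not emulate

It reproduces marginal age/sex structure, age-graded deficit prevalence,
deficit–ASA correlation, registry-style missingness and attrition, and
tertile-driven outcome risks with known coefficients. It does **not** model
hospital-level clustering, calendar-time trends, fracture-type-specific risks,
or the true joint dependence among comorbidities — by default conditions are
independent given age (a shared latent frailty factor can be induced by
raising per-condition slopes, but no copula is fitted). Passing tests
therefore demonstrate that the *pipeline* is correct and that estimators
recover known generating parameters; they do not validate the index's
clinical performance on real data.

## Numerical and testing choices

* Tertile boundaries, the LOS threshold (≥ 30) and death-day windows (≤ 7,
  ≤ 14) are inclusive exactly as stated in their definitions; boundary cases
  are unit-tested.
* Logistic convergence: |Δdeviance| < 1e-8, cap 100 iterations, step-halving
  (up to 30 halvings) for a monotone trace; separation bound |β| ≤ 15.
* AUC variance: DeLong components computed via midranks (O(n log n)); the
  estimator is tested against the brute-force all-pairs oracle at n ≤ 50 and
  against an independent ROC implementation at n = 200–400.
* The 2×2 saturated logistic fit is tested to reproduce the closed-form odds
  ratio and Woolf variance to 1e-6 relative error.
* Reports are byte-identical across reruns of the same seed; wall-clock
  timestamps are therefore logged to the console, not embedded in report
  files (provenance carries seed, config hash and package version instead).
* Problem sizes in the shipped tests: parameter-recovery coverage uses a
  fixed 20,000-record design with 200 outcome replicates from the mortality
  ground-truth scenario (covariates fixed, outcomes redrawn — the standard
  conditional-coverage design); the discrimination-power property uses a
  10,000-record design with 50 replicates; distributional-fidelity checks use
  single 50,000-record cohorts.

## Worked example

```{r example}
report <- run_pipeline(config = sim_config(n = 4000, seed = 7), quiet = TRUE)
subset(report$outcome_table, outcome == "death_overall")
subset(report$auc_table, outcome == "death_overall",
       select = c(outcome, n, auc_model1, auc_model2, p))
```

## Known limitations

The default code map is a literature-informed approximation, not any
registry's official coding manual; users analysing real data should supply
their registry's map. ASA coding in the published comparator models
(linear vs categorical, handling of unknown ASA) is not documented in audit
practice; both options are surfaced and neither asserted as canonical. The
independent AUC test is anti-conservative for nested models on the same
patients — the paired DeLong option should be preferred when the goal is
inference rather than replication of audit-software output. In-sample AUCs
are optimistic; no cross-validation is performed by default.
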