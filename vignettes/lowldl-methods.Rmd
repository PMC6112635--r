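---
title: "Methods: very low LDL-C and type 2 diabetes in electronic health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: very low LDL-C and type 2 diabetes in electronic health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question and the study design

Statin trials and Mendelian randomization studies both suggest that low
circulating LDL cholesterol (LDL-C) is accompanied by a higher risk of type 2
diabetes mellitus (T2DM), but direct observational evidence in people whose
LDL-C is low *without* lipid-lowering therapy is scarce. `lowldl` implements a
two-phase, cross-sectional EHR design that addresses this: patients with very
low (median ≤ 60 mg/dl, never ≥ 80) versus normal (median 90–130 mg/dl, always
strictly between 80 and 150) LDL-C are compared for T2DM prevalence, first
with a permissive phecode-based screen on a third of the cohort (discovery),
then with a specific, abstaining diagnostic algorithm on the remaining two
thirds (validation), using adjusted logistic regression.

Because individual-level EHR data of this kind are not public, the package
pairs the analysis pipeline with a seeded synthetic EHR generator whose
latent exposure–outcome odds ratio is known. The headline empirical claims
the package can make are therefore of two kinds: *exact reproductions* of
published summary quantities (the validation contingency table and its
derived statistics), and *statistical properties* (parameter recovery,
confidence-interval coverage, type-I calibration) demonstrated on synthetic
data. Both kinds are computed by the test suite and by
`scripts/acceptance.R`; nothing in this vignette asserts a number those do
not compute.

## Pipeline stages

1. **Simulate or load** four longitudinal tables: `patients` (id, birth
   date, sex, race), `labs` (dated measurements with an inpatient flag),
   `codes` (dated ICD-9 assignments), `meds` (dated medication mentions by
   class). `generate_population()` creates them; `read_population()` loads
   the same CSV schema from disk.
2. **Per-measurement LDL filtering** (`filter_ldl_measurements()`). Every
   complete same-day lipid panel yields a Friedewald determination
   (total cholesterol − HDL-C − triglycerides/5, all mg/dl); a direct LDL-C
   assay on the same date overrides it. Determinations are excluded, with a
   fixed precedence so attrition counts are reproducible, when: performed
   inpatient; before age 5; within ±30 days of a serum albumin < 3 g/dl;
   on/after the first statin mention; or (Friedewald only, toggleable) with
   triglycerides > 400 mg/dl.
3. **Group assignment** (`assign_groups()`): per-patient median over
   eligible determinations, then the band rules above; medians in the
   60–90 gap, negative medians (a known Friedewald artifact), and
   band-violating histories are excluded with named reasons.
   `split_phases()` shuffles the included patients with a seed and sends
   the first ⌊N/3⌋ to discovery.
4. **Phenotyping.** `assign_phecode_status()` implements the
   case/control/excluded trichotomy: ≥ 2 mapped ICD-9 codes on distinct
   calendar days → case; exactly one such day → excluded; codes only in the
   phecode's exclusion ranges → excluded from controls; otherwise control.
   The hierarchy is prefix-based (250.2 parents 250.21–250.25).
   `t2dm_algorithm()` is the validation classifier: diagnosis codes plus
   medication or laboratory corroboration, abstaining when a record is
   uninformative (e.g. no glucose measurement at all).
5. **Association** (`odds_ratio_woolf()`, `fit_logistic()`,
   `discovery_screen()`, `stratified_analysis()`, `interaction_test()`,
   `sensitivity_suite()`), orchestrated by `run_pipeline()`.

## The synthetic-data generator

The generator emulates the cohort the analysis assumes, with one latent
Bernoulli T2DM liability per patient:

logit P(T2DM) = β₀ + β_LDL·1[low group] + β_age·age + β_male·1[male] +
β_afr·1[African ancestry] + β_BMI·BMI

with defaults β₀ = −7.55, β_LDL = log 2, β_age = 0.04/year, β_male = 0.3,
β_afr = 0.4, β_BMI = 0.09 per kg/m². The liability is keyed to the *latent
group*, not to continuous LDL, because the design's contrast is group-based.
Covariate distributions differ by group — the low group is younger and
leaner — so the defaults deliberately embed negative confounding: the crude
odds ratio is attenuated relative to the adjusted one, the same qualitative
pattern the two-phase design was built to handle. Consequently the
generating odds ratio is recovered by the *adjusted* model; the crude
comparison only recovers it when the covariate effects are switched off
(both properties are tested).

Distributional choices, in the absence of stated forms in the source
material, are log-normal with medians and log-scale spreads chosen once
from the published demographic table (spread = IQR width on the log scale
divided by 1.349): per-patient LDL-C anchors with medians 52 (low) and
109 mg/dl (normal); HDL-C median 51; triglycerides medians 88/101; BMI
medians 24.5/27.1 kg/m²; ages median 33/42.8 years; EHR spans median
6.6 years. Total cholesterol is emitted as LDL anchor + HDL + TG/5 plus
visit-level noise and rounding, so the pipeline must genuinely re-derive
LDL-C by Friedewald; LDL-C itself is never written (except the configured
small fraction of direct assays). Glucose thresholds follow ADA
conventions: normal < 100 mg/dl fasting, abnormal ≥ 126 mg/dl or
HbA1c ≥ 6.5%. eGFR is stored directly as a lab value.

Contamination pathways, each with a configurable rate and all exercised by
the tests, degrade records the way real EHRs do: statin mentions
mid-record, inpatient panels, low albumin near a panel, pre-age-5 panels,
non-diabetic patients with no glucose (forcing the classifier to abstain),
type-1-diabetes-pattern patients, and carriers of the cardiovascular /
renal / transplant / stroke codes the sensitivity filters key on. Passing
`contamination = 0` zeroes all of them.

What the generator does **not** model: record fragmentation across
providers, free-text medication mentions (a structured table stands in for
NLP extraction), ICD-10, informative missingness, secular drift in assay
practice, or a continuous LDL→T2DM dose–response. Passing tests therefore
demonstrate that the pipeline recovers what this generator encodes — not
that the published effect estimates are correct, which individual-level
data would be required to re-derive.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| low median threshold | 60 | mg/dl | upper bound of "very low" |
| low ceiling | 80 | mg/dl | any reading at/above excludes from low |
| normal band | [90, 130] | mg/dl | inclusive at both ends |
| normal floor/ceiling | 80 / 150 | mg/dl | every reading strictly inside |
| albumin rule | < 3, ±30 days | g/dl, days | acute-illness lipid artifacts |
| TG invalidation | > 400, on | mg/dl | Friedewald validity limit |
| discovery fraction | 1/3 | — | two-phase design |
| significance | 0.05, /6 for screen | — | Bonferroni over six phecodes |
| BMI strata | 18.5/25/30 | kg/m² | WHO categories; 25.0 → overweight, 30.0 → obese |
| LDL refinement | < 40 strict; 40–60 inclusive | mg/dl | exposure dose split |

Interval-endpoint readings: "≤ 60", "≥ 80", "≥ 150", "≤ 80" are literal;
"between 90 and 130" is taken inclusive, matching the ≤/≥ style of the
other rules. The albumin window is symmetric because "within 30 days" does
not state a direction. The source material prints two mg/dl→mmol/l
constants (0.02586 and 0.0256); the pipeline works entirely in mg/dl, and
0.02586 is the constant we would adopt if conversion were needed.

## Numerical and design choices

- **Logistic fits** use iteratively reweighted least squares
  (`stats::glm`, binomial logit) with deviance tolerance 1e−8 and at most
  50 iterations. Wald intervals from the inverse observed information are
  used everywhere, matching the normal-approximation style of the 2×2
  Woolf interval; profile likelihood is deliberately not used. Detected
  separation or non-convergence yields a flagged row (`converged = FALSE`)
  with no estimate; a single-class outcome is an error. Covariates that
  are constant within a (stratified) sample are dropped from that fit.
- **Zero cells** in the 2×2 table are an error unless the Haldane–Anscombe
  correction (+0.5 per cell) is explicitly enabled.
- **Median date tie-break**: the measurement closest in value to the
  median, earliest on ties — needed to date "age at median LDL-C" for the
  adult-only sensitivity filter.
- **Missing covariates** are complete-case per fit, with per-fit N
  reported, since per-covariate Ns legitimately differ.
- **Race "other"** stays in adjusted models as a third indicator level but
  is not reported as a stratum.
- **The stroke/TIA/PVD code list** is implemented verbatim, including
  334.9 (plausibly a typographical slip for 433.91 — 334.9 is a cerebellar
  ataxia code); `substitute_433_91 = TRUE` swaps it.
- **The T2DM classifier** is a fixed, documented proxy with the structure
  of the published high-PPV algorithms (codes + medications + labs, with
  abstention); the original algorithm's exact internals are not public, so
  its thresholds here are stated conventions, and tests verify structure
  and a PPV-dominance property (it beats the naive one-code rule), not
  equivalence to the original.
- **Determinism**: a single seed drives simulation and the phase split;
  the configuration hash stamped into every artifact excludes only the
  output directory, so identically configured reruns are byte-identical.

## Monte-Carlo problem sizes

The recovery and calibration studies are run at sizes chosen to make the
binomial acceptance bands meaningful while keeping a full run of the suite
comfortable on a single CPU: CI coverage uses 100 replicates of 20,000
patients (nominal 95% coverage, accepted band 90–99/100); interaction
type-I calibration uses 200 replicates of 3,000 patients at level 5%
(accepted band 3–8%); the group-assignment oracle cross-check uses 1,000
randomly generated patients with boundary-heavy value mixes.

## Known limitations

- At the default 20,000-patient scale the discovery screen is marginally
  powered: its age/race/sex-adjusted odds ratio is attenuated relative to
  the fully adjusted phase 2 estimate (the phase 1 model omits BMI by
  design), and the Bonferroni gate passes for some seeds and not others.
  `run_pipeline()` honors the prespecified stop; `force_validation = TRUE`
  overrides it, and the analysis scripts say so when they proceed.
- Manual chart review of extreme-LDL records (part of the original cohort
  curation) is inherently unautomatable and out of scope.
- The bundled phecode map is a miniature fixture (diabetes family,
  ischemic heart disease, CKD stages, hypertension); any full map in the
  same two-CSV schema can be supplied to `load_phecode_map()`.
- Phase 1's controls use the phecode exclusion ranges as given in the map;
  whether additional exclusions were applied in the original screen is not
  stated, and no further exclusions are invented.
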