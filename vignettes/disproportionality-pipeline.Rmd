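---
title: "Disproportionality signal detection for spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect suspected drug–adverse
event reports without exposure denominators, so absolute risks cannot be
estimated. What *can* be estimated is disproportionality: whether a given
event is reported relatively more often for one drug than for everything
else in the database. `faersignal` implements that workflow end to end for a
single MedDRA Preferred Term of interest (the default is `"Hiccups"`, a
male-predominant adverse event most prominent with nicotine replacement
therapy, chemotherapy agents and corticosteroids): table cleaning, reporting
odds ratios with exact-test significance, volcano-plot triage, and stratified
multivariate risk models over the extracted candidate drugs.

## The statistic

For each drug the analysis table is cross-tabulated into

|                  | event rows | non-event rows |
|------------------|-----------|-----------------|
| rows of the drug | $n_{11}$  | $n_{12}$        |
| all other rows   | $n_{21}$  | $n_{22}$        |

and the reporting odds ratio is
$\mathrm{ROR} = (n_{11} n_{22})/(n_{12} n_{21})$, with the Woolf/Wald 95%
interval $\exp\{\ln \mathrm{ROR} \pm 1.96\sqrt{1/n_{11}+1/n_{12}+1/n_{21}+1/n_{22}}\}$.
A *signal* is declared when the lower CI bound exceeds 1. Any zero cell
leaves the ROR undefined rather than continuity-corrected: corrections
silently shift estimates, and the report-count thresholds used for candidate
extraction make zero-cell drugs irrelevant to the downstream model anyway.

Significance comes from the two-sided Fisher exact test, computed by
hypergeometric probability-mass ordering: conditional on both margins,
$n_{11}$ is hypergeometric, and the p-value sums all outcomes whose
probability does not exceed that of the observed table. A relative tolerance
of $10^{-12}$ decides probability ties, so the test is reproducible
bit-for-bit; the suite checks it against full enumeration for every table
with total up to 60 and against `stats::fisher.test()` on larger random
tables.

The volcano plot places each drug at $(\ln \mathrm{ROR},\ -\log_{10} p)$,
coloured by the log report count, with a red baseline at $p = 0.05$:
high-signal drugs sit in the upper right.

## The unit of counting

One analysis row is one (report, drug, reaction) triple surviving the
cleaning rules; cross-tabulations count rows. This dual bookkeeping is why a
single case can contribute several "reports" of the event while case-level
statistics (demographics, gender association) collapse to one record per
case, taking demographics from the lexicographically greatest report
identifier — the latest version of the case. All four role codes (PS, SS, C,
I) count as suspect exposure; the role is carried through but deliberately
unused in counting, and the generator randomises roles so tests would catch
any accidental dependence.

## Cleaning rules

* **Deduplication.** Exact duplicate rows in DRUG, REAC, THER and INDI are
  dropped (one copy kept) before joining; removed counts are reported and,
  on synthetic data, must equal the generator's injected duplicates exactly.
* **Therapy-window filter.** A row survives only when the reaction date lies
  between the drug's start and end dates. Dates carry year, month or day
  precision, so containment is evaluated conservatively: the start is
  expanded to its earliest completion, the end to its latest, and the whole
  completion range of the event date must fall inside. A missing end date
  retains the row only when the event is on or after the start and no later
  than the end of the last loaded quarter. Missing event or start dates
  remove the row — a relationship to therapy cannot be established.
* **Demographics.** Age is converted to years from its unit code (including
  decades, months, weeks, days, hours); weights coded in pounds are converted
  to kilograms. Ages above 119 years and weights above 400 kg are treated as
  recording outliers and masked to missing — the row is kept, because
  dropping it would also distort the drug denominators, which the continuous
  outlier rule has no business touching. The boundary values themselves
  (119, 400) are retained. Gender is normalised to male/female/unknown;
  unknown-gender rows are excluded from both gender strata but stay in the
  combined table.

## Candidate extraction and the risk model

Signals are filtered to candidate drugs by three thresholds — strictly more
than `min_reports` rows for the drug, exact-test p below `max_p`, ROR above
`min_ror`. The shipped per-stratum defaults are (5000, 0.001, 1) for the
combined table, (3000, 0.001, 1) for males and (5000, 0.05, 1) for females.
The female p-threshold is stated inconsistently in the source analyses
(0.001 in one place, 0.05 in the methods that define the workflow); the
methods value is the default here and the other remains one
`candidate_criteria()` call away — nothing is silently merged.

Candidates plus patient covariates (gender coded male = 1/female = 0 in the
combined stratum only; age in years; weight in kg, both untransformed, so
reported ORs are per year and per kilogram) enter a binary logistic model of
event occurrence at the case level, on complete cases. Fitting is maximum
likelihood via IRLS (`stats::glm`), declared converged at a relative
deviance change of $10^{-12}$ — comfortably inside the $10^{-8}$ design
requirement, and tight enough that a saturated single-covariate fit
reproduces the closed-form 2×2 odds ratio to at least ten significant
digits, which the suite asserts. Wald 95% intervals $\exp(\beta \pm 1.96\,
\mathrm{se})$ match the reporting convention of the tables this pipeline
emulates; a covariate is starred exactly when its interval excludes 1.
Possible separation (any $|\beta| > 15$) raises a warning and clears the
converged flag instead of producing silent estimates.

Before fitting, pairwise Spearman $\rho^2$ on pairwise-complete observations
screens collinearity; pairs above 0.9 are flagged but never auto-dropped —
the caller decides, matching the convention that co-administered drugs
(e.g. a steroid given alongside a proteasome inhibitor) stay in the model
when no internal correlation is found. Model discrimination is summarised by
the in-sample ROC-AUC via the midrank Mann–Whitney formulation (ties give
exactly 0.5 for constant scores); no cross-validation is attempted because
the emulated analyses report a single in-sample AUC.

## The synthetic-data generator

No public accession exists for this kind of extract, so the package ships a
generator that emulates the relational structure the pipeline consumes: one
DEMO row per report, DRUG rows with role codes, THER rows with start/end
dates, REAC rows with Preferred Terms, INDI rows with indications,
configurable missingness, exact duplicate rows, and partial-precision dates.
Ground truth (planted RORs, injected duplicate counts, per-report
inside-window flags) is returned alongside and written to a key-value
sidecar, so every cleaning stage has an exact oracle.

Associations are planted on the odds scale: for reports exposed to a planted
drug the event odds are the background odds times the target ROR
($p_1 = r\,o_0/(1 + r\,o_0)$), so the planted value is an exact odds ratio,
not an approximation. Two structural choices make that planted value the
estimand of the *row-level* cross-tabulation the pipeline actually computes:

* **Sparse co-exposure.** Tracked drugs are independent Bernoulli exposures
  with their configured marginals kept exact; a report that draws none of
  them receives a single filler drug from a fixed background formulary.
  Fillers are true nulls — they never co-occur with a planted drug — and the
  default tracked-drug marginals are sparse. Dense co-exposure would let
  co-reported drugs share the event rows of planted-drug reports and
  attenuate the observed ROR (the masking bias familiar from real
  disproportionality work); at the default settings the residual attenuation
  is about 3% of the planted log-ROR, small against its sampling error, and
  parameter-recovery simulations show ~95% CI coverage of the planted value.
* **Sparse reaction lists.** Background event probabilities are small and a
  report drawing no event receives one fallback event (chosen among events
  not involved in any planted effect), so most reports carry a single
  reaction and row-level and report-level odds nearly coincide.

Therapy windows are drawn uniformly over a configurable calendar range with
log-normal durations (median 30 days); each report's drugs share one window,
so the ground-truth inside/outside flag is well defined per report. Event
dates fall uniformly inside the window except for a configured fraction
placed strictly before the start or after the end — exercising the temporal
filter in both directions. A configured fraction of dates is truncated to
month or year precision. Therapy end dates are always present in generated
data so the outside-window oracle stays exact; the missing-end code path is
exercised by hand-built fixtures instead.

What the generator does **not** emulate: stimulated reporting and the Weber
effect, country-level heterogeneity (the country field is an independent
categorical), ingredient/brand name synonymy, case versioning across
quarters, and correlated polypharmacy. Green recovery tests therefore show
that the pipeline estimates what it claims on structurally faithful data;
they do not show robustness to real-world reporting biases, which no
synthetic benchmark of this kind can certify.

## Problem sizes and numerical choices

The test-suite experiments use the sizes at which each check is sharp:
parameter recovery runs 20 replicates of 50,000 cases with a planted ROR of
90 against a background reporting probability of 0.001 (expected cells all
comfortably above 5) and 20 logistic cohorts of 50,000 with planted
coefficients $\ln 8$ (exposure) and 0.01 per year (age); CI coverage is
assessed per coefficient, because each Wald interval is a marginal 95%
interval — the joint "all coefficients inside" event has only ~90% nominal
coverage and would make the replicate bound uninterpretable. Oracle
equivalence for the exact test enumerates every 2×2 table with total at most
60. Invariant checks (duplicate accounting, outside-window fraction,
monotone stage counts) use 8,000–20,000 cases; end-to-end byte-determinism
uses 3,000. Date truncation is disabled in the outside-window experiment so
the conservative containment rule coincides with the exact one and the
ground-truth comparison is exact rather than approximate.

Ordering is made deterministic everywhere results are emitted (drugs
alphabetically within equal RORs, analysis rows by report/drug/term), TSV
numerics are written with 17 significant digits so files round-trip doubles
exactly, and SVG output has cairo's process-global surface counters
renumbered so repeated runs are byte-identical.

## Known limitations

* Verbatim drug-name matching: no ingredient mapping, so brand/generic
  splits dilute per-drug counts on real extracts.
* The exact test and ROR treat rows as independent; multi-reaction,
  multi-drug reports violate that mildly, which is inherent to the
  row-level counting convention being emulated.
* No multiplicity correction is applied — thresholds act on raw p-values,
  by design of the emulated workflow.
* Per-unit (per-year, per-kg) odds ratios for continuous covariates are
  reported untransformed; implausible published values for such covariates
  in one gender stratum suggest an undocumented rescaling upstream, which
  this package does not invent.
* The AUC is in-sample and optimistic; it summarises fit, not predictive
  performance.
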