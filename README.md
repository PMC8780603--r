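# faersignal

Disproportionality signal detection for spontaneous adverse-event reports,
built for pharmacovigilance analysts and methods researchers who work with
FAERS-style quarterly extracts. The package takes the five `"$"`-delimited
ASCII tables (DEMO, DRUG, REAC, THER, INDI), applies the standard cleaning
rules — duplicate-row removal, report/drug/reaction joining, a
therapy-window filter on partially precise dates, demographic outlier
masking — and screens every drug against one MedDRA Preferred Term of
interest (default `"Hiccups"`). Because no public deposit of such an extract
exists, a synthetic-data generator with planted, exactly defined drug–event
odds ratios is part of the package, so the whole pipeline is testable
offline against known truth.

## The statistic

For each drug, the cleaned analysis table (one row per report × drug ×
reaction) is cross-tabulated against the event:

```
ROR = (n11 · n22) / (n12 · n21)
95% CI = exp( ln ROR ± 1.96 · √(1/n11 + 1/n12 + 1/n21 + 1/n22) )
```

with a two-sided Fisher exact p-value computed by hypergeometric
probability-mass ordering. A drug is a *signal* when the lower CI bound
exceeds 1. Drugs passing per-stratum thresholds (report count, p-value, ROR)
become candidates for a case-level logistic risk model with patient
covariates (gender, age, weight), Spearman-ρ² collinearity screening, Wald
intervals and an in-sample ROC-AUC — run on the full table and separately on
the male and female strata. Volcano plots (ln ROR vs −log₁₀ p) rank the
signals visually.

## Worked example

```r
library(faersignal)

cfg <- faers_sim_config(
  n_cases = 20000, seed = 42,
  planted_effects = data.frame(drug = "NICOTINE", event = "Hiccups", ror = 60),
  drugs = c(NICOTINE = 0.03, DEXAMETHASONE = 0.01, DRUGY = 0.005, DRUGZ = 0.003)
)
ds  <- generate_faers(cfg)
ing <- ingest_faers(ds$bundle)
ing$stages
#>   raw_drug_rows   raw_reac_rows dedup_drug_rows dedup_reac_rows     joined_rows
#>           21013           21213           20013           20203           20216
#>   temporal_rows   analysis_rows
#>           13140           13140
```

About 35% of joined rows fall outside the therapy window (the generator's
default outside-window rate is 0.30, plus rows whose truncated dates cannot
be proven inside) and are removed. Signal detection then recovers the
planted association:

```r
sig <- detect_signals(ing$analysis)
#>   drug_name n11  n12    ror ci_low ci_high  p_value is_signal
#>    NICOTINE  19  393  51.23  24.70  106.27 1.79e-21      TRUE
#>       DRUGY   1   64   6.79   0.91   50.58 1.43e-01     FALSE
#> PARACETAMOL   4 2042   0.80   0.28    2.30 1.00e+00     FALSE
```

NICOTINE's estimated ROR of 51.2 carries a CI covering the planted 60; the
filler-formulary drugs sit at ROR ≈ 1 as true nulls. The candidate threshold
`candidate_criteria(100, 0.001, 1)` selects NICOTINE alone, and the
case-level risk model keeps it as an independent risk factor:

```r
res <- run_stratum(ing$analysis, "all", criteria = candidate_criteria(100, 0.001, 1))
res$report
#>          term odds_ratio ci_low ci_high star
#> 1    NICOTINE      17.26  4.203   70.89    *
#> 2   age_years       1.04  1.002    1.07    *
#> 3   weight_kg       1.00  0.963    1.04
#> 4 gender_male       0.65  0.160    2.64
res$auc
#> [1] 0.869
```

(The case-level odds ratio is smaller than the row-level ROR by
construction: exposure and outcome are collapsed to any-row-per-case and
the model conditions on covariates and complete cases.)

`faers_run(input_dir, out_dir)` executes the whole pipeline — signals,
volcano SVG/PNG, a patient-information report, age-incidence curves, the
three stratified models — and writes a manifest with stage row counts and
md5 checksums; identical inputs give byte-identical bundles. A thin CLI
wrapper lives in `inst/scripts/faers-pipeline.R`
(`simulate` and `run` subcommands).

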