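# dascreen

Validation pipeline for a brief adolescent dating-abuse screener.

Comprehensive measures of adolescent dating-abuse (DA) victimization —
here a 34-item scale with four-category past-year frequency responses —
are too long for clinical screening. `dascreen` implements, as a tested R
package plus a numbered analysis workflow, the full validation study for
a three-item screener derived from that scale's most-endorsed items:
instrument scoring, online-survey record QC and fraud filtering,
diagnostic-accuracy estimation with exact confidence intervals,
ROC-based cutpoint selection, sample-size planning, and a calibrated
synthetic-respondent generator standing in for the restricted study data.
It is aimed at researchers validating short screening instruments against
a longer reference standard, and at anyone who needs a reproducible
re-implementation of this study's analyses.

## The statistics at the core

With the full scale dichotomised at total score ≥ 6 as the reference
standard and the screener positive at score ≥ c (c ∈ {1,2,3}):

* sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
  PPV = TP/(TP+FP), NPV = TN/(TN+FN), accuracy = (TP+TN)/n — each with a
  Clopper–Pearson exact 95% CI on its own denominator;
* LR+ = sens/(1−spec), LR− = (1−sens)/spec, post-test odds = pre-test
  odds × LR+;
* ROC: sensitivity vs. 1−specificity per cutpoint; optimal cutpoint by
  closest-to-top-left-corner (default) or Youden's J; trapezoidal
  empirical AUC alongside the per-cutpoint area (sens+spec)/2;
* sample size: n_cases = Z² p̂(1−p̂)/d², total = n_cases / prevalence.

The synthetic generator is a single-factor probit latent-trait model with
thresholds calibrated by root-finding to the published item- and
category-level endorsement prevalences; see the methods vignette
(`vignettes/screener-validation.Rmd`) for the model, its calibration and
its limitations.

## Worked example

The study's full-sample 2×2 table is recoverable from its published
percentages — it is the unique integer table with n = 224 and 117
reference-positives matching all five printed metrics:

```r
library(dascreen)
tab <- reconstruct_confusion_table(
  224, 117,
  c(sensitivity = 0.838, specificity = 0.907, ppv = 0.907,
    npv = 0.836, accuracy = 0.871))
unlist(tab)
#> tp fn fp tn
#> 98 19 10 97
dx_metrics(tab)
#> Diagnostic accuracy (n = 224, 95% exact CIs)
#>   sensitivity 83.8% (75.8%-89.9%)  [98/117]
#>   specificity 90.7% (83.5%-95.4%)  [97/107]
#>   ppv         90.7% (83.6%-95.5%)  [98/108]
#>   npv         83.6% (75.6%-89.8%)  [97/116]
#>   accuracy    87.1% (81.9%-91.2%)  [195/224]
#>   LR+ 8.96, LR- 0.18, post-test odds 9.80 (prevalence 52.2%)
#>   screen-positive rate 48.2%, single-cutpoint ROC area 0.872
```

Reading: a positive screen multiplies the pre-test odds of past-year DA
by about 9; at this sample's prevalence that is a 91% chance the
respondent is a DA survivor, while a negative screen leaves an 84% chance
they are not.

A full synthetic run — generate 571 screened entries with the published
contamination profile, filter, score and validate:

```r
screened <- generate_study_sample(seed = 1)
flow <- run_flow(screened)
flow$report$final
#> [1] 224
ref <- score_marsha(flow$records)
scr <- score_marsha_c(derive_marsha_c(flow$records))
select_cutpoint(roc_curve(scr$score, ref$positive))
#> [1] 1
```

The same stages run as a narrative workflow:

```sh
Rscript analysis/01_simulate.R          # calibrated cohort + contamination
Rscript analysis/02_qc_flow.R           # eligibility/consent/fraud flow
Rscript analysis/03_validate_screener.R # accuracy tables, ROC, subgroups
Rscript analysis/04_sample_size.R       # planning calculation
```

each writing its tables under `results/`.

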