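---
title: "Validating a three-item dating-abuse screener: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a three-item dating-abuse screener: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dascreen)
```

## The problem

Dating abuse (DA) among adolescents is common and consequential, but the
comprehensive instruments that measure it — here a 34-item victimization
scale answered on a four-category past-year frequency scale ("0 times",
"1–3 times", "4–10 times", "more than 10 times") — are too long for
clinical screening. `dascreen` implements the validation pipeline for a
three-item screener derived from that scale: the three most-endorsed
victimization items, each answered yes/no, scored 0–3 by the count of
endorsed acts.

The package covers every stage of such a validation study:

1. **Instrument scoring** (`score_marsha()`, `score_marsha_c()`,
   `derive_marsha_c()`, `select_screener_items()`),
2. **Record QC** for an online survey recruited through social media
   (`eligibility_filter()`, `fraud_flags()`, `run_flow()`),
3. **Diagnostic accuracy** with exact intervals, ROC cutpoint selection
   and subgroup profiles (`dx_metrics()`, `roc_curve()`,
   `select_cutpoint()`, `subgroup_analysis()`),
4. **Sample-size planning** (`required_cases()`, `required_total()`),
5. A **synthetic-respondent generator** (`generate_cohort()` and
   friends), because the study's respondent-level data are restricted;
   every pipeline stage is testable against simulated cohorts with the
   published marginal structure.

The numbered scripts under `analysis/` run these stages in order as a
narrative workflow, writing tables under `results/`.

## Scoring model

Each of the 34 reference items is coded 0–3 for the four frequency
categories, chosen so the scale minimum is 0 and the published
dichotomisation rule "total score ≥ 6 = DA survivor" is expressible. The
source study also describes a score of 6 as "a minimum of 5 acts"; under
any simple monotone coding of the four categories the minimum act count at
score 6 is 6, not 5, so the package adopts the 0–3 coding and documents
the discrepancy rather than resolving it.

Respondents could skip any question, so `score_marsha()` treats missing
items as 0 by default (`missing_policy = "treat_as_zero"`); records
skipping more than 10 of the survey's questions are removed upstream by
the eligibility filter, and the alternative `"reject_if_over_k"` policy
enforces the same bound at scoring time.

The screener gives one point per endorsed act regardless of frequency;
`derive_marsha_c()` maps any nonzero frequency on the full instrument to
"yes". Screener candidates are the most-endorsed items
(`select_screener_items()`), with a documented deterministic tie-break
(lexicographic on the item identifier) and an exclusion list for items
whose endorsement is not necessarily abusive (the "stopped talking to me"
item, endorsed by 38% in the source study but excluded because ceasing
contact can be healthy).

## Record QC

Eligibility requires age 11–21, U.S. residence, a past-year dating
relationship, no prior completion, at most 10 skipped questions, and no
timeout. Each excluded record carries one primary reason — the first
failing rule in the fixed order `prior_completion`, `no_dating`, `age`,
`skipped_gt10`, `non_us`, `timed_out` — so per-reason counts partition the
ineligible records exactly. The source material does not state the order
in which the rules were assessed; this order is a package convention.

Five rule-based fraud checks follow consent, mirroring common practice
for social-media-recruited surveys:

* **zip/state mismatch** against an injected lookup table (a miniature
  table with one zip per covered state ships under `inst/extdata/` for
  tests and examples; deployments supply a complete one — no network
  calls);
* **blank or nonsense open text**: fires only when *all five* open-ended
  answers are blank or nonsense. "Nonsense" (undefined in the source) is:
  empty after trimming, under 2 characters, vowel-free, or a single
  repeated character;
* **foreign IP** (IP country ≠ US);
* **duplicate**: repeat occurrences of the duplicate key after the first
  are flagged — the first submission is kept, which is one reading of
  "answered the survey multiple times"; the key column is configurable;
* **geo mismatch**: great-circle distance between IP coordinates and the
  reported zip's coordinates above 300 km (default; configurable). The
  threshold is generous enough that coordinate jitter within a metro area
  never fires it.

A record is fraudulent if any rule fires; it is counted once however many
rules fire. `run_flow()` chains eligibility → consent → fraud and emits a
`flow_report` whose counts telescope (screened = final + all removals).

## Diagnostic accuracy

From the 2×2 table of screener class against reference class,
`dx_metrics()` reports sensitivity, specificity, PPV, NPV and accuracy,
each with a Clopper–Pearson exact interval on its own denominator
(`exact_binomial_ci()`, beta-quantile inversion). The exact method is the
design choice because it reproduces one-sided bounds at degenerate
estimates (e.g. a 96.6% lower bound at 107/107), which Wald or Wilson
intervals do not; it is conservative by construction, which the test
suite checks by simulation. Metrics with zero denominators are reported
as explicit `NA (zero denominator)`, never as 0 or 1.

Likelihood ratios are `LR+ = sens/(1−spec)` (`Inf` at perfect
specificity) and `LR− = (1−sens)/spec`; post-test odds multiply the
pre-test odds by LR+, with the pre-test prevalence defaulting to the
sample reference prevalence and overridable for external populations.

`roc_curve()` evaluates the integer cutpoints (default 1–3), plotting
sensitivity against the false-positive rate, and reports the trapezoidal
empirical AUC through (0,0) and (1,1). Two "area" summaries coexist and
are labelled distinctly because they differ: the single-cutpoint area
`(sens + spec)/2` reported per row of the subgroup table, and the
empirical AUC over all cutpoints. `select_cutpoint()` implements the
closest-to-top-left-corner rule (default) and Youden's J; ties resolve to
the smaller cutpoint, favouring sensitivity in a screening context.

`subgroup_analysis()` recomputes the profile within demographic groups at
a fixed cutpoint, keeps degenerate groups with `NA`-marked metrics, and
flags groups below `min_n` (default `required_total()` = 119, the
study-design threshold) as exploratory.

`reconstruct_confusion_table()` recovers an integer 2×2 table from
published rounded percentages by exhaustive search over all tables with
the given total and positive count, minimising the maximum absolute
deviation from the printed metrics and reporting whether the minimiser is
unique. For the source study's full-sample row (n = 224, 117
reference-positives, five printed percentages) the unique solution is
tp = 98, fn = 19, fp = 10, tn = 97; the acceptance script rebuilds all
headline statistics from that reconstruction at run time.

## Sample-size calculator

`required_cases()` implements
`n_cases = Z² p̂ (1−p̂) / d²` (ceiling), with Z the standard-normal
two-sided quantile — 1.96 at α = 0.05. At the study's planning inputs
(anticipated sensitivity 0.85, margin 0.10) this gives 49 cases.
`required_total()` divides by the anticipated prevalence (0.409),
truncating by default: 49/0.409 = 119.8, and only truncation reproduces
the published total of 119, so the default encodes that convention
without claiming intent; `rounding = "ceiling"` is available.

## The synthetic generator

### Model

One standard-normal latent severity `z` per respondent; item `j` is
endorsed when `a_j·z + e_j > τ_j` with independent standard-normal noise
— a single-factor probit model, the simplest structure consistent with
the published facts (high internal consistency across items and a 3-item
subset predicting the full scale well). Endorsed responses receive
frequency categories 1–3 by splitting the endorsed region of the linear
predictor into three equal-probability slices (configurable).
Demographics are drawn independently of severity from the published
full-sample margins (the source reports no survivor/non-survivor
demographic differences). Within age bands, integer ages are drawn with
weights increasing toward the band top, reproducing the published mean
age of about 18.6 years under the published band margins.

### Calibration

`calibrate_thresholds()` solves each τ_j by monotone root-finding on the
closed-form marginal `P(endorse) = 1 − Φ(τ/√(1+a²))`. Four items have
published prevalences and are pinned (28%, 28%, 25% screener items; 38%
excluded item). The remaining items' targets come from category-level
any-endorsement totals — physical 17%, sexual 25%, emotional 35%,
technology-facilitated 43% — via an outer root-find on the shared
prevalence of each category's placeholder items, with the
latent-factor integral evaluated numerically. Placeholder-to-category
assignments are heuristic (the source lists neither the 34 item texts nor
per-item prevalences); the seven social-control placeholders, which
belong to no published category total, default to 15% each.

### Tuned operating point

Loadings default to 2.4 for the three screener items and 0.7 for the
rest. These were fixed by a one-off calibration run (grid search at
n = 120,000, documented in this section) so that the derived screener's
cutpoint-1 sensitivity and specificity sit near the study's estimates —
about 0.845 and 0.907 in the tuning run. A shared loading cannot reach
that operating point with the published marginals pinned: it forces
sensitivity near 0.95, because the high-prevalence screener items are
endorsed by almost every reference-positive respondent unless the
remaining items spread endorsements more independently.

### What the generator does not emulate

* **Reference prevalence.** The dichotomised reference prevalence under
  the default generator is roughly 38–40%, not the study's 52.2%. With
  all published item and category prevalences pinned and
  equal-probability frequency splits, the single-factor model cannot push
  more than half the sample to a total of 6+; we left the published
  marginals authoritative rather than distorting them. Tests that need a
  prevalence use the one the generator actually produces.
* Real response styles, item-level missingness patterns, bot text
  content beyond rule-triggering fields, or any dependence of
  demographics on severity (a hook exists: margins are per-config).
* Per-item prevalences inside categories are spread evenly; the real
  scale surely varies.

Passing tests on synthetic cohorts therefore show that the *pipeline*
recovers the properties the generator encodes — not that the screener
itself would achieve these operating characteristics in new field data.

### Contamination

`inject_contamination()` appends records that each violate exactly one
eligibility rule, withhold consent, or trigger exactly one fraud rule,
and are otherwise clean. `study_contamination()` reproduces the published
recruitment composition (19/90/18/26/2/7 ineligible, 8 non-consenters,
177 fraudulent); the per-rule fraud split 45/40/35/30/27 is a package
convention, as only the total was published. Running `run_flow()` on
`generate_study_sample()` recovers the published flow exactly, final
n = 224 included.

## Numerical and reporting conventions

* Exact-interval endpoints: `qbeta` inversion; lower bound 0 at zero
  successes, upper bound 1 at complete success.
* Root-finding: `uniroot` to tolerance 1e−12 (thresholds) and 1e−9
  (category prevalences); latent integrals via `integrate` with relative
  tolerance 1e−10. Calibration fails loudly, listing the offending items
  or category, when a target is unattainable (e.g. a category total below
  a pinned member prevalence).
* Report rounding is half-up (not R's round-half-even): percentages to
  one decimal, areas to three, matching the publication style;
  `fmt_pct()`/`round_half_up()` are exported. CSV and JSON report files
  carry identical numbers, and identical inputs produce byte-identical
  files.
* Reproducibility: every generator entry point takes an integer seed;
  the same seed and configuration give byte-identical cohorts.

## Problem sizes used in the test suite

The suite favours a few deep checks at moderate sizes: marginal-
convergence at n = 100,000 (3 Monte-Carlo standard errors), prevalence
calibration at n = 10,000 (±0.015), subgroup homogeneity at 5,000 per
group (sensitivity spread < 0.05), chance-level screening over 50
replicates of n = 2,000, exact-interval coverage over 10,000 simulated
binomials at n = 117, p = 0.84, and 100 end-to-end replicates at the
study's n = 224 for the cutpoint-selection rate.

## Known limitations

* The reconstruction of the study's 2×2 table is exact only for the
  full-sample row; published subgroup rows are not uniquely recoverable
  from rounded percentages, so subgroup behaviour is validated by the
  shared-generator homogeneity property instead.
* The screener items are a subset of the reference scale, so even a
  zero-signal generator yields above-chance agreement between screener
  and full score; chance-level behaviour holds (and is tested) against
  the scale's disjoint remainder.
* The QC rules are deliberately simple, rule-based reproductions of the
  published procedure — no IP geolocation service, bot-detection models
  or CAPTCHA analysis.
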