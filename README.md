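# fracrisk

Short-term (1–2 year) fracture-risk prediction from longitudinal
diagnosis-code histories.

Fragility fractures due to osteoporosis and low bone mass are common,
burdensome, and widely under-treated: established calculators (FRAX-style
cross-sectional scores) estimate 5–10-year risk from manually entered risk
factors and say little about who will fracture *in the next one to two
years* — the horizon on which rapid-acting preventative therapy matters.
`fracrisk` implements an alternative approach for researchers working with
longitudinal EHR extracts: treat a patient's chronological stream of
diagnosis codes as a sentence, and ask whether its trajectory looks like
that of a patient about to fracture.

## What the package does

Given long-format diagnosis, medication and demographics tables, the
pipeline:

1. **Qualifies fracture events** with a claims-style case definition:
   site-specific code catalogs (hip, vertebral, wrist/forearm, humerus,
   pelvis), a chronological scan with a same-site washout (default 90
   days), and exclusion of ICD-10-CM aftercare/sequela coding — so
   follow-up coding of one clinical fracture is not counted again.
2. **Builds labeled sliding windows**: for each anchor event (a qualifying
   fracture, or the last recorded diagnosis for fracture-free patients),
   up to 5 windows of the 730 days of codes ending 1, 184, 367, 550 and
   733 days before the anchor. A window is labeled positive iff a
   qualifying fracture falls within the 730-day horizon after its end;
   windows with incomplete or ambiguously overlapping coverage are
   dropped. Cohort entry requires age ≥ 50 at the anchor and ≥ 2 years of
   history.
3. **Learns two representations** from pan-therapeutic training windows
   only: 100-d skip-gram (negative-sampling) vectors per code over the
   min-count-5 vocabulary, and 128-d distributed-bag-of-words vectors per
   window.
4. **Trains the risk models**: an LSTM over the embedded code sequence
   whose final state is merged with dense-transformed statics (age, sex,
   diagnosis count); gradient-boosted trees (xgboost) over the 128-d
   window vector plus the same statics; two demographic baselines (age+sex
   and age+sex+count, both xgboost); and a two-feature logistic-regression
   ensemble of the frameworks. Training uses a patient-disjoint 70:30
   split with the minority class balanced to 50:50 by oversampling
   fracture windows from a bone-health cohort; the holdout keeps its
   natural distribution.
5. **Evaluates** with AUROC, AUPRC (average precision), recall,
   specificity and precision, overall and stratified by primary vs
   subsequent fracture, and runs a **retrospective human-level-performance
   comparison**: a window counts as "physician-identified risk" when it
   contains a catalogued bone-health intervention (bone-density testing,
   osteoporosis treatment, or osteoporosis diagnosis); the *cohort
   analysis* cross-tabulates model flags against intervention status and
   outcome, and the *overlap analysis* scores each treated patient's
   history up to their first pharmacologic intervention.

Because real EHR extracts are proprietary, the package ships a calibrated
synthetic cohort generator (`generate_cohort()`) that emulates the
structure the pipeline assumes — a pan-therapeutic population with 8.5%
fracture incidence among over-50 anchor events and a bone-health
population with 39%, multi-year Zipf-distributed code streams, elevated
pre-fracture frequencies of risk-signal codes, and interventions injected
before a configurable fraction of fractures — so every stage is
exercisable and testable without any data download.

## Worked example

```r
library(fracrisk)

# a synthetic pan-therapeutic cohort, and the incidence it was calibrated to
syn <- generate_cohort(generator_config(n_patients = 2000, seed = 42))
co  <- assemble_records(syn$diagnoses, syn$medications, syn$demographics)
fr  <- qualify_fractures(co)
an  <- anchor_events(co, fr)
incidence_rate(an, co$demographics)   # 0.0861  (target 0.085 over age 50)

# the full experiment on a small simulated cohort
res <- run_pipeline(pipeline_config(seed = 7, n_patients = 1200,
                                    n_bone_health = 600,
                                    lstm = list(hidden = 32, epochs = 4)),
                    out_dir = "artifacts")
print(res$evaluation$lstm_seq$overall)
#> <evaluation_report> stratum overall (n = 1765, threshold 0.5)
#>   AUROC 0.749 | Recall 0.629 | Specificity 0.664 | Precision 0.064 | AUPRC 0.178
#>   TP 39  FP 573  TN 1130  FN 23
print(res$human_level$overlap_analysis)
#> <overlap_analysis_report>
#>   treated patients: 34; with sufficient history: 24
#>   flagged by model: 11 (45.8%)
#>   fracture within horizon among flagged: 6 (54.5%)
#>   flagged among all fracturing treated patients: 6 of 8 (75.0%)
```

Reading the output: the sequence model ranks holdout windows well above
chance (AUROC 0.749 on a cohort whose only injected sequence signal is a
set of risk-associated codes enriched before fractures), and at the 0.5
threshold on the balanced-training probability scale it recalls 63% of
fracture windows at 66% specificity — precision is low because holdout
prevalence is ~3.5%. In the overlap analysis, patients the model flags at
the moment a physician first prescribed bone-health treatment go on to
fracture far more often (54.5%) than the cohort base rate, and the model
flags most treated patients who ultimately fracture.

At larger simulated cohort sizes (see `tests/testthat/test-acceptance.R`)
the model hierarchy is stable: both sequence frameworks and their ensemble
strictly outperform both demographic baselines, and under a null generator
(no code signal, no age/sex effect) every model sits inside the
permutation band of AUROC 0.5.

A thin command-line wrapper is installed at `inst/cli/fracrisk.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fracrisk.R", package="fracrisk"))')" \
  run --seed 1 --out artifacts/
```

## Further documentation

The methods vignette (`vignettes/fracture-risk-pipeline.Rmd`) describes
the model and its assumptions, every tunable constant with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical and design choices.
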