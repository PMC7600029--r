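---
title: "Methods: short-term fracture risk from diagnosis-code sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: short-term fracture risk from diagnosis-code sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

`fracrisk` predicts whether a patient will suffer a qualifying fragility
fracture within a short horizon (default 2 years) from the chronological
sequence of diagnosis codes in the 2 years before a reference date. The
premise borrows from language modelling: each namespaced code token
(`"ICD10:M80.08"`) is a word, a 2-year window of codes is a document, and
fracture risk is a property of the document's trajectory. Two framework
families operationalise this:

* **Sequence framework** — 100-dimensional skip-gram vectors per code feed
  an LSTM; the final hidden state is concatenated with a dense transform
  of the static features (age, sex, total diagnosis count) and passed
  through a sigmoid head.
* **Summary framework** — a 128-dimensional distributed-bag-of-words
  vector summarising the whole window, concatenated with the same three
  statics, feeds gradient-boosted decision trees.

A two-feature logistic regression ensembles the frameworks' probabilities.
Two xgboost baselines (age+sex; age+sex+count) quantify the added value of
sequence information. All models treat the task as binary classification;
no survival-time modelling is attempted.

Key assumptions inherited by every model: time between consecutive codes
is ignored (codes are equally spaced within a window), sequences are
truncated/padded to a fixed length with the true count retained as a
static feature, and ICD-9/ICD-10 codes are distinct opaque tokens (no
cross-walking — merging them would inject information the data never
contained).

## Cohort construction

**Qualifying fractures.** A configurable catalog (CSV of prefix patterns
to sites; longest matching prefix wins) marks fracture codes. A
chronological per-patient scan opens a new event unless (a) the code
carries ICD-10-CM 7th-character `D`/`S` aftercare/sequela coding, or (b) a
qualifying event at the same site lies within the washout (default 90
days) before it — both are follow-up coding of an earlier clinical event.
Events at different sites are always distinct. `is_subsequent` marks any
event preceded by an earlier qualifying event of the same patient. The
washout is compared against the last *qualifying* event date, not against
absorbed follow-up codes, so a dense cluster of follow-up coding cannot
indefinitely extend the washout.

**Anchors and eligibility.** Every qualifying fracture is an anchor;
fracture-free patients contribute one anchor at their last recorded
diagnosis. Eligible anchors require age ≥ 50 years (a year is 365.25
days) and a first diagnosis at least `min_history_days` (730) before the
anchor.

**Sliding windows.** Candidate windows end at `anchor − 1 − k·stride` for
`k = 0 … 4`. Choices made where the procedure was genuinely open:

* *Stride 183 days.* With a 730-day horizon this places the five
  candidate ends 1, 184, 367, 550 and 733 days before the anchor — so
  exactly one of five fracture-anchored candidates falls outside the
  horizon and carries a nonfracture label, consistent with fracture
  patients contributing some negative windows. Configurable.
* *Window end excludes the anchor day* (`end = anchor − 1`), so a
  fracture's own codes can never leak into the window that predicts it.
* *Coverage rule.* The span `(end − 730, end]` contains 730 calendar
  days, the earliest being `end − 729`; a candidate is dropped when the
  patient's first diagnosis postdates that day. This makes an anchor with
  exactly the minimum 730 days of history yield exactly one window, so
  eligibility and windowing are mutually consistent.
* *Overlap rule.* A candidate is dropped when a different qualifying
  fracture of the same patient falls inside the span or inside the
  horizon after the end — one window must not be ambiguously attributable
  to two events. The rule is switchable; its main consequence is that
  windows anchored at subsequent fractures survive only when the
  inter-fracture gap exceeds the span.
* Window ends are de-duplicated per patient; labels are recomputable from
  the fracture list and the horizon (`horizon_days = 365` is supported
  for 1-year analyses).

**Vocabulary, split, balancing.** The vocabulary keeps tokens occurring
≥ 5 times in the reference corpus, indexed in frequency-then-lexicographic
order; rarer tokens map to the unknown token (zero vector), visible to the
models only through the diagnosis count — the stated rationale for that
static feature. The reference corpus is the pan-therapeutic *training*
windows (the same corpus the embeddings see). The 70:30 split is by
patient, never by window. Training positives are topped up to exactly
50:50 with fracture windows sampled from the bone-health cohort (with
replacement if the pool is short); the holdout is never touched, and
embedding corpora are guarded against bone-health or oversampled windows
by provenance tags.

## Representation learning

Both embedding trainers are the package's own single-threaded C++
(deterministic given a seed; RNG is a seeded xorshift, never R's global
stream).

* **Skip-gram with negative sampling** (codes): dimension 100, context
  window 10 with word2vec-style random shrinking, 5 negative samples from
  the unigram^0.75 distribution, 5 epochs, learning rate 0.025 with
  linear decay. Input vectors are initialised uniform ±0.5/dim, output
  vectors at zero. Sequences shorter than 2 in-vocabulary tokens
  contribute nothing. What this guarantees — and what the tests assert —
  is *distributional* similarity: codes sharing contexts collocate. A
  pair of codes that co-occur only with each other and share no contexts
  is not constrained to collocate.
* **Distributed bag of words** (windows): dimension 128, 20 epochs; one
  vector per training window is trained to predict the window's member
  tokens against 5 negative samples. Inference for an unseen window fits
  a fresh document vector for 40 epochs against *frozen* output weights.
  Each window's inference RNG is seeded from a hash of its token content,
  so inferred vectors are independent of batch composition and order —
  which is what makes batch prediction equal single-window prediction
  exactly. Empty sequences yield the zero vector with a warning.
* **2-d QC projection**: a principal-component projection (first two PCs,
  sign fixed so the largest-magnitude loading is positive) for eyeballing
  whether related codes collocate. It is a qualitative artifact with no
  accuracy contract.

## Classifiers

* **LSTM** (own C++): one LSTM layer (default 64 units; forget-gate bias
  initialised to 1), statics through a 32-unit ReLU layer, a 32-unit ReLU
  merge layer, sigmoid output; binary cross-entropy, Adam (lr 2e-3),
  minibatch 32. Code embeddings are frozen — no gradient flows into them.
  Statics are scaled (age/100, sex as female/unknown indicators,
  log1p(count)/5). Sequences keep the most recent `max_len` (default 200)
  tokens. A patient-level 10% carve-out selects the best epoch by
  validation AUROC. Training is single-threaded and bit-reproducible for
  a fixed seed.
* **Gradient-boosted trees** (xgboost, `nthread = 1`): the 128-d window
  vector plus age, sex (NA for unknown) and diagnosis count — 131
  features. A small grid (depth 3/5 × eta 0.1, depth 4 × eta 0.3) is
  tuned for validation AUROC with early stopping; the baselines use the
  same machinery restricted to their feature sets.
* **Ensemble**: `glm(y ~ p1 + p2, binomial)` on a 10% patient-level
  calibration fold carved out *before* the bases are trained, so the
  metaclassifier never sees probabilities the bases were fitted on.
  Constant base probabilities are an error (the sign of the combination
  would be unidentified).
* **Decision threshold**: 0.5 on the balanced-training probability scale,
  attached to the model and configurable; no published operating point
  exists to calibrate against, so no claim is made that 0.5 matches any
  external report's thresholded metrics.

## Evaluation

AUROC uses the rank (Mann–Whitney) formulation with ties counted half —
equal, on every input, to exhaustive pairwise concordance (property-tested
up to 200 rows). AUPRC is average precision (step-wise integration over
recall, ties handled as one threshold); trapezoidal interpolation would
give different small-sample values, so the choice is stated. Stratified
evaluation assigns positive windows to primary/subsequent strata by their
anchor fracture; negative windows are type-free and join both strata's
negatives (switchable; stated in the report). Single-class inputs are
errors, not silent 0.5s.

The human-level analyses scan the same half-open window span as the code
sequence, so an intervention on the anchor day itself is outside the
window. Drug matching is case-insensitive prefix matching (a base drug
name also matches its combination products); code matching is prefix-based
(`M80`, `M81`, `733.0` cover all child codes). The intervention-side cells
of the cohort analysis are reported without adjustment for treatment
effects — the caveat is carried in the report, not corrected for. In the
computed overlap analysis one fracture definition (qualifying fracture
within the horizon after the first pharmacologic intervention) drives all
three percentages, so the report's counts are internally consistent by
construction.

## The synthetic generator

The generator exists so every downstream stage is testable without data
access. It emulates: per-patient observation windows of 5–11 years inside
a 2007–2018 study period; ages 45–84 at entry (so nearly all patients are
over 50 at their events); a Poisson code stream (default 12 events per
patient-year) over a 2,000-token Zipf vocabulary — far smaller than a real
>40,000-code vocabulary, but large enough to preserve the long tail that
motivates the min-count filter at desk scale; eight mid-frequency signal
codes whose rate is multiplied (default ×6) in the 540 days before each
scheduled fracture; fracture coding as an initial-encounter code plus
aftercare codes (and, half the time, a second same-site code inside the
washout, exercising both absorption rules); second fractures at a
different site 200–1400 days later, so the overlap-drop rule both fires
and leaves survivors; and bone-health interventions injected before 30% of
fractures plus a 5% background rate, enabling the human-level analyses.

Incidence calibration is exact in expectation: given the target event
proportion `t` and subsequent-fracture probability `m`, the fracture
probability `q = t / ((1 + m)(1 − t) + t)` is solved analytically; an
age/sex/frailty multiplier (log-RR 0.45 per decade, 0.3 for female,
lognormal frailty sd 0.3) is then rescaled by root-finding (`uniroot`,
tolerance 1e-12) so the expected over-50 event-level incidence equals `t`
for the realised age mix. All randomness flows from one seeded stream;
identical config + seed gives byte-identical cohorts.

What the generator does **not** emulate: real ICD semantics, comorbidity
co-occurrence networks, care-seeking dynamics, coding-practice drift, or
clinically silent (uncoded) vertebral fractures. Passing tests therefore
demonstrate that the pipeline's machinery is correct and that the models
recover a planted sequence signal under the stated conditions — not that
any particular AUROC would be attained on real EHR data.

## Problem sizes and numerical notes

The test suite runs the full experiment at 4,000 pan-therapeutic + 2,000
bone-health patients for the signal-recovery ordering (both frameworks and
the ensemble strictly above both baselines) and 1,500 + 800 under the null
generator (all models inside a 400-permutation AUROC band around 0.5);
incidence calibration is checked at 50,000 patients per cohort against the
99% binomial interval of the target. These sizes are the package's choice
of a desk-scale experiment: large enough for the orderings to be stable
across seeds, small enough to iterate on.

Degenerate inputs are handled explicitly throughout: empty files parse to
empty tables with a zero-row summary; unparseable dates reject rows (never
the file); patients without demographics are kept with `sex = "unknown"`
and flagged; an empty oversampling pool with an imbalanced training set,
single-class training labels, out-of-vocabulary queries to
`nearest_codes()`, and zero anchor events in `incidence_rate()` are all
errors with named messages rather than silent defaults. Deterministic
tie-breaks: same-day events sort lexicographically by token; cosine
neighbours break ties by token; vocabulary indices break frequency ties
lexicographically.

## Known limitations

Inter-event time is discarded; the fracture catalog is a Wright-style
skeleton shipped as editable configuration, not a validated claims
algorithm; the LSTM trainer is deliberately minimal (one layer, frozen
embeddings, no attention); threshold-dependent metrics are reported at an
uncalibrated 0.5; and the human-level comparison is a retrospective proxy
for clinician judgment, not a clinical evaluation.
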