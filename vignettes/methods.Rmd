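---
title: "Methods: hierarchical 12-month SLE activity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical 12-month SLE activity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its modelling choices: the
outcome and feature definitions, the generative model behind the synthetic
cohort, the numerical conventions, and the places where the design was
genuinely open and a choice had to be made.

## The prediction problem

The unit of prediction is a *contact*: any recorded encounter (outpatient
visit, hospital admission, day-hospital session) of a patient with
systemic lupus erythematosus (SLE). At each contact the pipeline predicts
a binary composite outcome: does at least one *activity event* occur in
the following 12 months? An activity event is any of

* a manifestation in the neurologic, renal or vascular (N/R/V) domains;
* a newly involved organ domain, i.e. the first record of that domain in
  the patient's history (involvements are treated as persistent, so each
  domain can fire this event at most once per patient);
* a hospital admission carrying an SLE ICD-9 code (710.0 or 695.4) in a
  department closely tied to SLE activity — hematology, nephrology,
  dermatology, neurology, angiology — with admissions for *continuation*
  infusions of cyclophosphamide or rituximab excluded (only a first
  infusion indicates newly high activity).

Predictions are made independently at every contact, so one patient
contributes a whole trajectory of labelled samples.

### Window conventions (open questions resolved)

The forward window is implemented as the half-open interval
(*t*, *t* + 365 days]: events on the contact day itself do not label that
same contact, and an event exactly 365 days later still counts. Twelve
months is fixed at 365 days rather than calendar months — simpler, and
order-preserving under date shifts. Neither boundary convention is forced
by the clinical definition; both are documented package choices and
covered by boundary tests.

End-of-follow-up censoring is likewise unspecified clinically: a contact
with fewer than 365 days of subsequent observation and no recorded event
is labelled 0 but flagged `censored`, so sensitivity analyses can drop
those rows; the default pipeline keeps them, treating absence of recorded
events as absence of events (EHR semantics: events are only observable at
recorded contacts).

## Feature engineering

Each contact yields three blocks, prefixed `cur_`, `last_`, `past_`:

* **current** — integer age at contact (floor of days/365.25), sex,
  contact-type indicators, `cur_delta_contacts` (days since the previous
  contact; −1 sentinel at baseline), new-involvement flag, per-domain
  involvement and manifestation flags, per-class treatment flags,
  step-up/step-down change flags, and *dual* lab flags: for each test,
  (`normal`, `out_of_range`) is (1,0), (0,1), or (0,0) when the test was
  not recorded — missingness is informative and kept visible rather than
  imputed;
* **last 12 months** — counts of contacts by type in the trailing window
  (*t* − 365, *t*), exclusive of *t* so the blocks stay disjoint, plus
  any-admission, new-involvement counts, step-change flags, per-domain
  manifestation-any and per-lab abnormal-any flags;
* **history** — "ever" flags and counts over all strictly earlier
  contacts (ever-outpatient, ever/total step-down, per-domain
  ever-involved, contact count).

Treatments missing at a contact are carried forward from the previous
contact (therapy continuity is the clinical default); a missing baseline
record means "not treated". All features are binary or non-negative
integers, apart from the −1 delta sentinel, and the baseline row — whose
`last_`/`past_` blocks are structurally empty — is removed from training.

This is an 80-column schema covering every category of the full hospital
inventory (demographics, contact types, delta, involvements,
manifestations, treatments, therapy changes, labs, window counts), not a
reconstruction of any particular hospital's 181-feature panel: the
pipeline's logic is the artifact, not the panel.

### Univariate selection

Association with the outcome is tested feature-by-feature on training
rows only: 2×2 chi-square without continuity correction for binary
features (falling back to Fisher's exact test when an expected cell count
drops below 5), Mann-Whitney U with the normal approximation and tie
correction for counts (they are heavily tied). Constant features get
*p* = 1. Features with *p* < .05 enter the model; selection is computed
once on the training split, not per fold.

A caveat the tests make explicit: contact-level rows are clustered within
patients, and the 12-month labels of nearby contacts share most of their
forward windows. For features that are nearly constant within a patient
(sex, history flags), the row-level tests therefore overstate
significance — the design effect can be several-fold. The type-I-control
test of the selection *machinery* consequently injects i.i.d. null
features into null-generator rows (where the nominal rate is the right
reference), rather than relying on the engineered features of a clustered
cohort; on those, inflated selection under the null is expected behaviour
of the method itself, not a bug.

## Main model

Patients are split 70/30 at the patient level (all contacts of a patient
stay together), resampling until (1) outcome prevalence differs between
splits by at most 0.02 and (2) the train contact share is within 0.05 of
the train patient share; 1000 attempts before giving up. Four families
are grid-searched — ridge logistic regression (glmnet; λ ∈ {0.001, 0.01,
0.1}), decision tree (rpart; depth ∈ {3, 5, 10}), probability random
forest (ranger; 200 trees, leaf size ∈ {10, 25}), gradient-boosted trees
(xgboost; depth ∈ {3, 5}, η = 0.1, 150 rounds) — with 5-fold
cross-validation grouped by patient. Fold grouping is not forced by the
split design, but ungrouped folds would leak within-patient correlation
into model selection, so folds are grouped; degenerate folds (single
class) trigger a reseeded refold. The winner is the argmax of mean
out-of-fold AUC, ties broken by the family order above then
lexicographically by hyperparameters, refit on the full training set.

The decision cutoff maximises Youden's J (sensitivity + specificity − 1)
over candidate thresholds at the midpoints of consecutive distinct
out-of-fold probabilities, under the strict rule "positive iff PP >
cutoff". The cutoff is data-dependent; on seeded synthetic runs it lands
in the 0.43–0.47 range, but no specific value is a target.

## Risk stratification and the cascade

Among the out-of-fold training predictions, the true positives
(PP > cutoff, outcome 1) contribute their first quartile and median, the
true negatives (PP ≤ cutoff, outcome 0) their median and third quartile
(linear-interpolation quantiles). On the high side, PP ≥ TP-median is
*strong*, PP < TP-Q1 is *mild*, between is *moderate*; symmetrically on
the low side with the TN quantiles. The bands partition every prediction.

Mild *training* contacts are identified with out-of-fold probabilities
and training-derived thresholds — in-sample probabilities would be
optimistically shifted and misplace the bands. On them a single bounded
decision tree (depth ≤ 4, leaf ≥ 20 — bounds chosen so paths stay
human-auditable) is fit using only the reduced feature set: sex, age at
contact, current treatment classes. Every root-to-leaf path becomes a
rule (ordered predicate conjunction, predicted risk = leaf majority,
support and accuracy measured on the mild training rows); rules with
accuracy strictly above 60% survive selection, optionally intersected
with a clinician allow-list. Rule accuracy is measured on training mild
rows only — evaluation-set accuracy may additionally be *reported*, but
never drives selection, so no test information leaks into the ensemble.

The hierarchical model routes strong/moderate contacts to the main model
unchanged, rule-matched mild contacts to their rule (with the leaf's
positive fraction as a probability, keeping ROC analysis defined), and
unmatched mild contacts to a fallback — the main model by default,
abstention as an option. The *covered* subset (strong + moderate +
rule-matched mild) is the restricted population on which the ensemble
claims higher reliability.

## Evaluation and explanation

AUC is computed by the trapezoidal rule over the tie-grouped empirical
ROC, which equals the Mann-Whitney pairwise-win normalization exactly
(an equivalence the tests assert against a brute-force double loop).
Confidence intervals use a patient-level bootstrap — resampling patients
with replacement, keeping all their contacts — with percentile intervals,
because contact-level predictions are correlated within patients and a
row-level bootstrap would understate the variance; degenerate resamples
are skipped and counted. 500 resamples by default (2000 offers no
practical gain at these sizes). Evaluation is contact-level throughout.

Shapley attributions satisfy local accuracy (base value + a row's
attributions = the model output for that row) by construction:

* decision tree and random forest — the path-dependent TreeSHAP
  algorithm, implemented in compiled code and verified against exact
  subset-enumeration Shapley values on small trees; ranger does not store
  node covers, so covers are obtained by routing the full training table
  through each tree (in-bag rows are a subset, keeping all covers
  positive and internally consistent, which is what local accuracy
  needs);
* gradient-boosted trees — the library's native contribution predictions
  (the same algorithm, on the log-odds scale, in single precision);
* ridge logistic — the exact closed-form linear decomposition
  β<sub>j</sub>(x<sub>j</sub> − x̄<sub>j</sub>) on the link scale. A
  sampling approximation would be strictly worse here, so the closed form
  replaces it.

The longitudinal view orders one patient's attributions by date and
reports the top-k features per contact — the per-visit drill-down a
clinician would read.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis needs, with
defaults fixed once to the published marginals of the emulated cohort:
88% female; baseline age log-normal with median 43 years (IQR ≈ 33–54),
truncated to [16, 90]; follow-up log-normal, median ≈ 6 years; visit gaps
log-normal (σ = 1.0, truncated to [7, 730] days) with state-dependent
medians 95 (quiescent) / 72 (active) days, reproducing both the ~16
contacts over ~6 years and the shorter delta-to-previous-contact among
active patients; and qualifying-event base rates set so that labelled
prevalence lands near 48%.

Mechanistically, a per-patient two-state Markov chain (quiescent/active;
default transitions 0.15 in, 0.30 out, stationary activity ≈ ⅓) drives
the *feature* channels: gap lengths, contact-type mix, per-lab abnormality
and missingness, therapy step-up/step-down, infusions, and manifestations
in already-involved non-N/R/V domains. The three *outcome-qualifying*
channels (N/R/V manifestation, new involvement, qualifying SLE admission)
fire with probability `plogis(qlogis(base) + η)`, where η is a linear
predictor over the patient's current and recent features with
configurable effect sizes: younger age, recent admissions, recent new
involvements and abnormal labs raise risk; step-down history and frequent
outpatient visits protect. This split of channels is the key design
decision: it gives the latent process the correlated longitudinal
structure the feature side needs, while making the null configuration
(all effects zero) produce qualifying events that are i.i.d. coin flips —
so the outcome is independent of every feature and downstream
discrimination is chance-level, a property the test suite checks
end-to-end. Two residual couplings survive in the null and are accepted
as small: active patients visit more often, so more contacts fall inside
a forward window (more chances for an i.i.d. event), and end-of-follow-up
contacts are censored to 0; both nudge the null AUC a point or two above
0.5, within the tested band.

Per-patient, per-purpose random substreams implement common random
numbers: sweeping an effect size moves only the qualifying-event
thresholds against fixed uniforms, so sweeps are comparable and
monotonicity is testable. Infusion logic is arranged so that
*first* infusions occur at day hospitals or via the qualifying channel,
and state-driven repeat infusions present as SLE-coded continuation
admissions — exercising the exclusion rule without leaking state into the
null outcome.

What the generator does **not** emulate: real involvement prevalences per
domain, lab-specific abnormality profiles (six generic tests stand in for
the hospital panel), treatment-line semantics, seasonal or calendar
structure, and any feature-feature dependence beyond the single latent
state. A green test suite therefore shows the pipeline's machinery is
correct under a plausible longitudinal structure — not that the printed
performance of any hospital cohort is reproduced; printed AUCs from the
private data mart are explicitly not targets.

## Numerical conventions and degenerate inputs

* Quantiles: linear interpolation (R type 7) everywhere.
* Cutoff candidates: midpoints of distinct probabilities; all-identical
  probabilities fall back to 0.5 with a warning.
* Empty moderate bands (all TP probabilities equal) are legal; the
  partition stays total.
* An empty rule selection degenerates the hierarchical model to the main
  model, with a warning rather than an error.
* Single-class subsets evaluate to `n` with a null AUC instead of
  failing; single-class bootstrap resamples are skipped and counted.
* Same-day duplicate contacts are rejected by validation; an ingest
  helper merges them (union of events, heaviest contact type) for raw
  tables.
* Ages are completed years (floor of days/365.25).

## Problem sizes

The seeded end-to-end runs use 300-patient cohorts (≈ 5 800–6 300
contacts), 5-fold grouped cross-validation over a 10-combination grid,
500-resample bootstraps, and 200-row attribution samples; oracle
equivalence tests sweep 200 randomly scripted toy patients per property.
These sizes were chosen as the smallest at which the calibration bands
(prevalence, null AUC, selection rate) are comfortably inside their
Monte-Carlo tolerances.

## Known limitations

* The cascade tree on the reduced feature set can lower covered-subset
  AUC slightly when rules are coarse; the router guarantees it never
  alters strong/moderate predictions.
* The mild-band definition assumes enough true positives and negatives
  (≥ 4 each) to estimate quartiles; tiny training sets should widen folds
  or lower `n_boot` expectations.
* Path-dependent TreeSHAP inherits its known conditional-expectation
  semantics; interventional attribution is out of scope.
* The generator's effect sizes are log-odds on a per-contact event scale
  and are not calibrated to any published per-event incidence (none is
  available); only the printed marginals above are calibration targets.
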