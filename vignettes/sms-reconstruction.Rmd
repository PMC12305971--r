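---
title: "Reconstructing expert-board stroke mobility assessments from gait data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing expert-board stroke mobility assessments from gait data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

After a stroke, mobility is assessed by interdisciplinary clinical experts.
The Stroke Mobility Score (SMS) formalizes such an assessment as six ordinal
subscores — trunk posture, leg movement, arm movement, gait speed, gait
fluency, and stability/risk of falling — each rated 0 (no pathological
findings) to 3 (significant findings), summing to an SMS between 0 and 18.
A board of five experts (neurology ×2, orthopedics, physiotherapy,
orthotics) rates every patient; the board value per subscore is the **mode**
of the five recommendations, and when the mode is tied (with five raters
over four levels the only tied pattern is 2-2-1) the singleton value acts as
a tiebreaker: it is returned itself when it lies between the tied pair (a
compromise), otherwise the tied value nearer to it wins (a weight).

`strideboard` rebuilds this assessment from instrumented gait analysis. Each
patient walks while joint kinematics and gait events are recorded; every
consecutive ipsilateral/contralateral stride couple (a *stride pair*)
becomes one training observation described by **680 features**:

* 30 spatiotemporal gait parameters (15 per side): gait speed, cadence,
  stride/step times, single and double support (seconds and % cycle),
  height-normalized step width, leg-length-normalized step and stride
  lengths, limp index, start of swing, stance and swing durations;
* 648 *numerical characterizations of movement*: for each of 18 relative
  joint/segment angles per side, the min/median/max of the angle and of its
  **normalized angular velocity** (NAV — the derivative of the angle with
  respect to gait-cycle progress, in degrees per % cycle) over the stance
  phase, the swing phase, and the whole cycle (2 × 3 × 3 = 18 statistics);
* 2 walking-aid flags (cane, ankle-foot orthosis).

Per-subscore models (a CART regression tree and a multilayer perceptron)
are trained at stride-pair level, evaluated at patient level, and explained
globally through split-gain and permutation importance.

## The synthetic cohort

No public gait database accompanies the score, so the package ships a
generative stand-in whose latent structure mirrors the clinical situation:
every patient carries six latent severities $\theta_k \in [0,3]$ (uniform
marginals, equicorrelated Gaussian copula, default correlation 0.5) that
drive *everything* downstream:

* **Raters**: each of five raters recommends
  $\mathrm{clip}(\mathrm{round}(\theta_k + \varepsilon), 0, 3)$ with
  $\varepsilon \sim N(0, \sigma_\text{rater})$, i.i.d. per rater
  (default $\sigma_\text{rater} = 0.25$, giving board/rater agreement in
  the ICC range the score is used at).
* **Timing**: stride time lengthens (0.25 s per severity unit) and stride
  length shrinks (0.27 m per unit) with the Speed severity, so gait speed
  falls monotonically (sample correlation below −0.8 across a cohort);
  stance fraction rises with the Stability severity (0.02 per unit,
  cautious gait); the ipsilateral stance shortens and the contralateral
  stance lengthens with the Leg severity, creating the limp-index signal;
  the contralateral strike is offset from 50% of the stride by an
  asymmetry term proportional to the Leg severity.
* **Kinematics**: each of the 18 angles follows a fixed low-order Fourier
  template (≤ 4 harmonics, shapes approximating textbook normative gait
  curves; the knee template was fitted to a normative flexion curve with a
  stance flexion wave and a ~60° swing peak). The relevant severity (Leg
  for lower-body angles, Trunk for thorax/spine, Arm for shoulder/elbow)
  shrinks the template amplitude (9% per unit, half effect contralaterally)
  and drifts its offset; the Fluency severity adds a 6th-harmonic wobble
  that shows up strongly in the NAV statistics. Measurement jitter is
  drawn as random low-order harmonics with pointwise standard deviation
  $\sigma_\text{kin}$ (default 1.5°), so traces remain exactly periodic —
  the first and last of the 101 samples always agree.
* **Aids**: cane use is Bernoulli with a logistic mean in the Stability
  severity (slope 3, midpoint 1.6), the orthosis likewise in the Leg
  severity.

Strides per patient are drawn uniformly from 4–12 per side, reproducing the
inhomogeneous pair counts that the training weights correct. A fixed seed
reproduces the cohort bit for bit.

What the generator does **not** emulate: marker-level noise, event-detection
errors, non-stationarity across trials, label noise correlated between
raters, and the tail behaviour of real severity distributions (the severity
prior is a free choice — uniform marginals with moderate cross-subscore
correlation, since a rehabilitation cohort mixes mildly and severely
affected patients and functional domains co-vary). Green tests therefore
demonstrate that the *pipeline* recovers planted structure under realistic
noise, not that the printed clinical accuracies transfer.

## Pipeline decisions

Where the procedure leaves details open, the package fixes them as follows
(all surfaced in the run manifest):

* **NAV scheme** — central differences on the normalized 0–100% grid,
  one-sided at the endpoints: second-order accurate, exact on linear
  traces, and a linear operator.
* **Window boundary** — the sample at foot off belongs to both the stance
  and the swing window (closed windows); simple and symmetric.
* **Limp index** — own-side stance time divided by opposite-side stance
  time (1 = perfectly symmetric). The literature uses several variants;
  this one is isolated in one function.
* **Per-side duplication** — gait speed and cadence are computed per side
  from that side's stride, so the ×2 layout holds even when values nearly
  coincide. Step length is derived as gait speed × step time; single
  support of one side is the opposite side's swing time.
* **Pairing rule** — a stride pair couples an ipsilateral stride with the
  contralateral stride that starts within it; contralateral strides are
  never reused.
* **Split** — patients (never pairs) are partitioned 70/30, stratified by
  SMS with largest-remainder rounding; singleton strata go to training.
* **Weights** — per pair and per target,
  $w_i = (\max_s N_s / N_{s(i)}) / M_{p(i)}$ with $N_s$ the training pairs
  holding label $s$ and $M_p$ the pairs of patient $p$. The balance factor
  equalizes label-class mass exactly; the patient factor equalizes the mass
  of patients within a class (each patient in class $s$ contributes
  $\max_s N_s / N_s$ regardless of how many pairs it has). Note the *total*
  class mass is then $\max_s N_s \cdot P_s / N_s$ ($P_s$ = patients in the
  class), which is equal across classes exactly when pairs-per-patient is
  constant — the tests assert the identities in that form.
* **Representative pair** — per patient, the pair minimizing the Euclidean
  distance, in z-score space over the step-1 features (training
  statistics), to the patient's component-wise median vector; ties go to
  the lowest pair index. A deterministic "most typical stride" criterion.
* **Selection** — Alexander-Govern test on the representative pairs,
  grouped by board level; retention at p < 0.05 with no multiplicity
  correction. Label groups with one representative are dropped; features
  with a zero-variance group are excluded and flagged. Hill's normalizing
  transformation is used for the per-group t statistics.
* **CV** — 10 folds stratified by label at stride-pair level (patients may
  straddle folds, matching the training-at-pair-level design);
  representative pairs assigned to a held-out fold are moved to the
  training side, so they never contribute to a validation score. Fold
  scores are unweighted pair-level R²; fitting uses the weights.
* **DT grid** — max-features ∈ {√n, n, log₂n} (the canonical option triple
  for tree max-features), splitter ∈ {best, random} (random draws one
  uniform threshold per candidate feature and keeps the best candidate),
  minimum child weight fraction ∈ {0.00,…,0.05}, depth ∈ {3,4,5}: 108
  cells. The weight fraction is measured against the total training
  weight, and duplicating a pair is exactly equivalent to doubling its
  weight.
* **MLP** — hidden ReLU stacks {16,8} or {32,16,8}, linear or ReLU output,
  Adam at 1e-3/1e-4/1e-5 with the conditional fine scan
  {7.5e-5,…,2.5e-6} when 1e-5 wins: 12 base cells. Epochs and batch size
  are not part of the tuned grid; the package defaults to 60 epochs at
  batch 32 per fit — enough for the networks to converge on the synthetic
  signal while keeping a full grid search over 10 folds affordable — and
  both are configurable. Inputs are z-scored by training statistics
  (mixed degree/second/unit-free features are otherwise ill-conditioned);
  trees consume raw features. Training is bit-reproducible under a seed.
* **Evaluation** — pair outputs are averaged per patient, cut to [0,3];
  the SMS prediction is the sum of the six range-adjusted subscores
  (hence within [0,18] for arbitrary model outputs); test R² is the
  unweighted patient-level coefficient of determination. ICC(1,1) — the
  one-way random-effects single-rater intraclass correlation — is computed
  per subscore on the patients × 5 rater matrix and on rater-level SMS
  sums for the total.
* **Explanation** — permutation importance on the test set at stride-pair
  level, global (not within-patient) shuffling, 500 repetitions by
  default; tree split-gain importances are normalized error reductions
  summed over splits. Features a tree never uses have exactly zero
  permutation importance and are not resampled.
* **Seeding** — one master seed fans out deterministically: simulation
  uses it directly, the split uses seed + 1, per-target CV seed + 10 ×
  target index, explanation seed + 97.

## Worked scale and numerical choices

The reference conditions used throughout the test suite are 100 patients,
$\sigma_\text{rater} = 0.25$, $\sigma_\text{kin} = 1.5°$, defaults
elsewhere; smaller cohorts (5–50 patients) exercise unit-level behaviour,
and the decision-tree family carries the end-to-end recovery checks with
the MLP exercised on the cheaper Speed target and on toy problems — the
package's choice of problem sizes for a deterministic, quickly reproducible
suite. On the reference cohort the tree models recover the Speed subscore
and the composed SMS with patient-level test R² well above 0.6.

Degenerate inputs are handled explicitly: non-positive stride times,
missing angle traces, and out-of-range stance fractions are errors; a
patient without a valid stride pair is dropped with a warning; zero
observation variance makes R² `NA` with a warning; MLP divergence names
the learning rate. Ties are broken deterministically everywhere (lowest
pair index, earlier grid cell, canonical feature order).

## Limitations

* The synthetic severity prior and coupling coefficients are plausible but
  invented; absolute performance numbers on this cohort say nothing about
  clinical data.
* The representative-pair criterion and the limp-index definition follow
  common practice but other variants exist; both are isolated and
  configurable.
* CV stratifies by label at pair level; patients may straddle folds. A
  patient-grouped CV is a stricter alternative for real data.
* Permutation importance is reported at pair level on the test set;
  within-patient shuffling would answer a subtly different question.
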