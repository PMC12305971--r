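# strideboard

Reconstructing interdisciplinary expert-board **Stroke Mobility Score
(SMS)** assessments from instrumented gait analysis.

After a stroke, mobility is rated by an expert board via six ordinal
subscores — trunk posture, leg movement, arm movement, gait speed, gait
fluency, stability/risk of falling — each 0 (no findings) to 3 (significant
findings), summing to an SMS in 0–18. Each of five raters recommends a
value per subscore; the board value is the mode, with a
compromise-or-weight tiebreaker for the 2-2-1 tied pattern. `strideboard`
rebuilds those assessments from gait data:

* a **synthetic hemiparetic cohort generator**: latent per-subscore
  severities θₖ ∈ [0,3] drive joint-angle kinematics (Fourier templates
  with severity-modulated amplitude), gait events and spatiotemporal
  measurements, walking-aid use (logistic in severity), and five noisy
  rater recommendations `clip(round(θₖ + ε), 0, 3)`;
* the **680-entry stride-pair feature vector**: 30 spatiotemporal gait
  parameters (15 × 2 sides), 648 numerical characterizations of movement —
  min/median/max of each of 18 angles and of its normalized angular
  velocity (NAV, degrees per % cycle) over stance, swing, and full cycle —
  and 2 aid flags;
* **dataset assembly**: stride pairing, a patient-grouped 70/30 split
  stratified by SMS, and bias-correcting weights
  `w = (maxₛ Nₛ / N_s(i)) / M_p(i)` against label imbalance and unequal
  pairs per patient;
* **two-step feature selection**: expert masks per subscore (680 / 356 /
  330 / 32 / 680 / 680 candidates), then an **Alexander-Govern**
  heteroscedastic one-way test on one representative stride pair per
  training patient, retaining features with p < 0.05;
* **models**: weighted CART regression trees and ReLU multilayer
  perceptrons (Adam), grid-searched over the documented hyperparameter
  grids with a 10-fold CV in which representative pairs never enter a
  validation fold;
* **evaluation**: patient-level averaging, range clipping, SMS
  composition, test R², and ICC(1,1) inter-rater reliability;
* **explanation**: split-gain importance and tree export for the trees,
  permutation importance (500 shuffles) for any model, with
  ipsilateral/contralateral share summaries.

## Worked example

```r
library(strideboard)

# the expert board in action: tied panels resolve by compromise or weight
board_subscore(c(1, 1, 2, 3, 3))  # -> 2  (tiebreaker 2 sits between 1 and 3)
board_subscore(c(0, 1, 1, 2, 2))  # -> 1  (tiebreaker 0 weighs toward 1)
board_subscore(c(1, 1, 2, 2, 3))  # -> 2  (tiebreaker 3 weighs toward 2)

# a 30-patient synthetic cohort, decision trees for Speed and Stability
cfg <- pipeline_config(
  sim = sim_config(n_patients = 30, seed = 7),
  families = "dt", targets = c("speed", "stability"),
  perm_reps = 100, seed = 7)
run <- run_pipeline(cfg)
tidy(run$evaluation)
#> # A tibble: 2 × 5
#>   target    family    r2 n_test_patients   icc
#>   <chr>     <chr>  <dbl>           <int> <dbl>
#> 1 speed     dt     0.731               8 0.803
#> 2 stability dt     0.921               8 0.899

head(run$importance$dt_stability$permutation, 3)
#> # A tibble: 3 × 4
#>   feature                    importance      se side
#>   <chr>                           <dbl>   <dbl> <chr>
#> 1 stance_duration_pct_contra     0.442  0.00792 contra
#> 2 swing_start_pct_contra         0.117  0.00377 contra
#> 3 step_width_norm_ipsi           0.0885 0.00214 ipsi
```

Reading the output: `r2` is the unweighted patient-level coefficient of
determination on the held-out test patients (here 8 of 30), comparing each
patient's board value with the mean of their stride-pair predictions cut to
the score range; `icc` is the ICC(1,1) agreement among the five simulated
raters — model performance tracks rater agreement. The importance table
says the Stability tree leans on stance/support timing and step width —
exactly the couplings the generator plants for that subscore; each value is
the mean drop in pair-level test R² over 100 shuffles of that feature's
column.

`autoplot(run$evaluation, target = "speed")` draws the board-versus-
prediction scatter; `export_tree(run$models$dt_speed$fit)` emits the fitted
tree as nested JSON and Graphviz DOT.

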