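# swayclass

Classification of postural sway behaviours from a chest-worn triaxial
accelerometer.

Postural instability is a key clinical sign in degenerative movement
disorders and a predictor of falls, but the reference instruments (force
platforms, vision systems) confine its assessment to structured
environments. A single trunk-mounted accelerometer can monitor sway
continuously — if its raw signal is converted into interpretable sway
quantities and the classification built on them stays reliable under noisy
data. `swayclass` implements that pipeline for four postural classes:
stable standing (**ST**), antero-posterior instability (**AP**),
medio-lateral instability (**ML**) and general multidirectional instability
(**UNST**).

## Method

With the sensor's `y` axis longitudinal, `z` antero-posterior and `x`
medio-lateral, the quasi-static gravity projection gives horizontal node
displacements from the lever-arm geometry

```
D_AP = H1 · Az / sqrt(Ay² + Ax²)        D_ML = H2 · Ax / sqrt(Ay² + Az²)
```

(`H1` = node-to-floor distance, `H2` = node-to-belt-joint distance). The
(D_ML, D_AP) trajectory — the stabilogram — is segmented into 10 s windows
shifted by 1 s, and each window is reduced to four features: the
peak-to-peak ranges `DAPmax` and `DMLmax` (m), the 95 % confidence-ellipse
area `CEA = π·(CSF·σ_AP)·(CSF·σ_ML)` (m², CSF = √χ²₀.₉₅(2) = 2.4477) and
the root-mean-square consecutive-point path displacement `RMS` (m).

Two classifiers consume the features:

* a small **multi-layer perceptron** (hidden layers 8–10–8, rectifier
  activations, softmax output; Adam, batch 32, categorical cross-entropy,
  early stopping), and
* a **threshold-rule baseline** whose per-feature cutoffs are set on the
  training data by ROC analysis (maximum Youden J).

Predictions carry an accuracy index `Q%` (exact-match percentage) and a
ground-truth-free **reliability index** `RI = (P1 − P2)/P1`, the normalised
margin between the two largest class probabilities. A noise-robustness
protocol corrupts features with Gaussian noise scaled as a percentage
(0.1–20 %) of each feature's training-split maximum, optionally retrains on
noise-augmented data, and evaluates the full condition grid
(model × feature subset × training regime × split × noise level).

A synthetic rigid-rig generator emulates the four motion classes at five
sensor heights (100 Hz, ±2 g, 16-bit, records of 60–87 s), so the whole
pipeline runs end-to-end without any measurement campaign. See the methods
vignette (`vignettes/postural-sway-classification.Rmd`) for the model
assumptions, defaults and their rationale.

## Worked example

```r
library(swayclass)

cases   <- default_rig_cases(5)                     # five node heights
records <- simulate_dataset(cases, per_class_records = 1, seed = 42)
dataset <- build_dataset(records, seed = 7)         # features + 75/25 split
nrow(dataset)
#> [1] 1268

mlp <- train_mlp(dataset, seed = 5)
evaluate_model(mlp, dataset, split = "test")
#>   q_pct ri_mean_pct  ri_std_pct   n
#> 1   100    99.99842 0.004113324 316

thr <- fit_thresholds(dataset)
evaluate_model(thr, dataset, split = "test")
#>   q_pct ri_mean_pct ri_std_pct   n
#> 1   100    18.87789   8.101168 316

# inject 15 % feature noise at inference time
evaluate_model(mlp, dataset, split = "test", level = 15, seed = 99)
#>      q_pct ri_mean_pct ri_std_pct   n
#> 1 82.27848    96.07395    13.0889 316
```

The 20 simulated records yield 1268 windowed patterns (316 held out). On
clean data both classifiers separate the four classes perfectly
(`q_pct = 100`), but the MLP is near-certain about every prediction
(`ri_mean_pct ≈ 100`) while the threshold baseline's rule margins leave it
far less confident (`≈ 19 %`). Under 15 % feature noise the MLP's accuracy
drops to ≈ 82 % yet its reliability stays above 96 % — the behaviour the
robustness protocol quantifies across the whole level grid with
`run_condition_grid()`.

A command-line interface wraps the same functions
(`inst/cli/swayclass simulate|extract|train|predict|robustness|report`).

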