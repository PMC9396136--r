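# squatmech

Lower-limb biomechanics of the barbell squat with rearfoot valgus.

`squatmech` is an R implementation of the full musculoskeletal analysis
chain used to compare loaded barbell squats between people with rearfoot
valgus (a standing calcaneus–tibia frontal angle > 5°) and people with
normal foot posture (< 5°): model scaling against a static trial,
marker-driven inverse kinematics on a reduced right-leg linkage,
recursive Newton–Euler inverse dynamics, static-optimization muscle
force estimation, tibiofemoral contact-force decomposition, EMG-based
model validation, squat-cycle segmentation with 101-point time
normalization, and group statistics combining discrete t-tests with
one-dimensional statistical parametric mapping (SPM) over whole cycle
curves. It is aimed at biomechanics researchers who want a tested,
scriptable version of this workflow, and it ships a seeded synthetic
squat-cohort generator (markers, ground reaction forces, EMG, with full
ground truth) so every stage is verifiable by parameter recovery without
any external data.

## The methods in brief

* **Inverse kinematics.** Per frame, joint angles minimize the sum of
  squared distances between experimental and model-predicted markers
  (damped least squares, warm-started), on an 8-DOF chain: hip and knee
  flexion/ab-adduction/rotation, ankle dorsi/plantarflexion, subtalar
  supination/valgus. Signs: flexion (+)/extension (−),
  adduction (+)/abduction (−), dorsiflexion (+)/plantarflexion (−),
  supination (+)/valgus (−).
* **Inverse dynamics.** Bottom-up Newton–Euler recursion foot → shank →
  thigh with the ground reaction at the center of pressure; moments are
  normalized by body + barbell mass (N·m/kg).
* **Static optimization.** Per frame, minimize Σ aⱼ² subject to
  Σ rᵢⱼ·Fmaxⱼ·aⱼ = Mᵢ and 0 ≤ aⱼ ≤ 1 (rigid-tendon muscles,
  F = a·Fmax), solved exactly as a quadratic program; high-cost reserve
  actuators absorb moments no muscle can produce.
* **Knee contact.** Total axial compression (intersegmental force plus
  knee-crossing muscle pull) is split by the frontal-plane static
  balance at contact points ±d from the knee center, d = 25 % of tibial
  plateau width: F_med + F_lat = F_tot, (F_med − F_lat)·d = M_frontal,
  with condylar lift-off clamped and flagged.
* **EMG validation.** Band-pass (100–500 Hz design; high-pass at 100 Hz
  when the upper edge hits Nyquist at a 1,000 Hz rate), moving RMS,
  MVC normalization to a 0–1 activation scale, then per-muscle Pearson
  r / RMSE against the optimized activations on the normalized cycle.
* **Statistics.** Independent two-sample t-tests on peaks/ROM/contact
  forces, and SPM{t} on 101-sample curves with the critical threshold
  from 1-D random-field theory at the residual-estimated FWHM
  smoothness (permutation fallback available), reporting
  suprathreshold clusters as %-cycle intervals, α = 0.05.

## Worked example

```r
library(squatmech)

spec <- cohort_spec(seed = 1)                      # study-default cohort spec
p <- generate_participant("valgus", 42, spec = spec)
model_true <- build_true_model(p)                  # generating model

# scale the generic model against a static trial and check the gates
static <- generate_static_trial(p, model_true, spec, seed = 2)
scaled <- scale_model(build_default_model(p), static)
round(unlist(scaled$report[c("marker_rms_m", "marker_max_m")]), 5)
#> marker_rms_m marker_max_m
#>      0.00057      0.00104

# one 70% 1RM squat trial through the whole chain
trial <- generate_squat_trial(p, load_condition(0.7, p$onerm_kg),
                              model_true, spec, seed = 3)
model <- scaled$model; model$participant <- p
res <- process_trial(model, trial)
round(res$metrics[c("knee_flexion_peak", "ankle_dorsiflexion_peak",
                    "knee_adduction_moment_peak",
                    "total_contact_peak", "medial_contact_peak")], 2)
#>          knee_flexion_peak    ankle_dorsiflexion_peak
#>                     139.81                      42.18
#> knee_adduction_moment_peak         total_contact_peak
#>                       0.42                      25.95
#>        medial_contact_peak
#>                      10.54

res$validation[, c("muscle", "r", "rmse")]
#>              muscle    r  rmse
#> 1    rectus_femoris 0.97 0.024
#> 2    biceps_femoris 0.98 0.070
#> 3 tibialis_anterior 0.99 0.045
#> 4     gastrocnemius 0.95 0.031
```

Reading the numbers: scaling residuals (0.6 mm RMS, 1.0 mm max) clear
the < 0.02 m / < 0.04 m gates; this valgus participant squats to ~140°
knee flexion with a peak external knee adduction moment of
0.42 N·m/kg; total tibiofemoral compression peaks at ~26 N per kg of
body+barbell mass of which ~10.5 N/kg crosses the medial compartment;
and the measured (synthetic) EMG envelopes track the optimized
activations at r ≥ 0.95, the model-validation criterion.

A full cohort analysis — tables of peaks/ROM/moments/contact forces with
significance flags and SPM results per curve family — is one call:

```r
res <- run_pipeline(pipeline_config(spec = cohort_spec(seed = 1), seed = 1))
subset(res$tables, metric == "medial_contact_peak")
```

or from a shell via the thin wrapper
`Rscript inst/scripts/squatmech_run.R --out results --seed 1`.

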