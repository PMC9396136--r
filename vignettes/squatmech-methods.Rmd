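---
title: "Methods: squat biomechanics with rearfoot valgus in squatmech"
author: "squatmech authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: squat biomechanics with rearfoot valgus in squatmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rearfoot valgus (foot pronation) — an everted heel in quiet standing,
here a standing calcaneus–tibia frontal angle strictly greater than 5° —
is suspected to redistribute load at the knee during loaded barbell
squats, pushing compression onto the medial tibiofemoral compartment.
`squatmech` implements the full computation chain needed to test that
hypothesis on motion-capture data: model scaling, marker-driven inverse
kinematics (IK), inverse dynamics (ID), static-optimization muscle force
estimation, tibiofemoral contact-force decomposition, EMG-based model
validation, and group statistics (discrete t-tests plus 1-D statistical
parametric mapping over whole squat-cycle curves), exercised end-to-end
on a synthetic squat cohort with known ground truth.

Two groups are compared (static valgus > 5° vs < 5°, mild valgus capped
at 30°) at three barbell loads — 0, 30 and 70 % of the one-repetition
maximum (1RM) — with three trials per condition.

## The body model

The model is a reduced right-leg rigid-body chain rooted at the planted
foot: foot, shank, thigh, and a pelvis+HAT segment that aggregates
pelvis, trunk, head, arms and the contralateral limb. Segment masses,
lengths, COM offsets and inertias follow de Leva-style anthropometric
fractions of body mass and stature, so total segment mass reproduces the
participant's mass within 1 %. The barbell is a point load on the trunk
axis above the hip (high-bar position). Bilateral symmetry is assumed:
the modeled (force-plate) leg carries its own segments in full plus a
configurable `weight_share` (default 0.5) of the HAT and barbell.

Eight rotational degrees of freedom are modeled: hip
flexion/ab-adduction/rotation, knee flexion/ab-adduction/rotation, ankle
dorsi/plantarflexion, and subtalar supination/valgus. Angles are stored
convention-positive throughout: flexion (+)/extension (−),
adduction (+)/abduction (−), dorsiflexion (+)/plantarflexion (−),
supination (+)/valgus (−).

Three realization choices deserve explanation:

* **Euler order.** Because the chain runs from the planted foot upward
  (child to anatomical parent), each joint composes
  rotation–adduction–flexion — the inverse of the anatomical
  flexion-first sequence. This keeps every flexion axis fixed to the
  anatomically proximal segment and every varus/valgus axis near the
  tibial (or femoral) anterior axis, as in a joint coordinate system.
  A flexion-first composition lets the frontal axis rotate with knee
  flexion and leaks sagittal moment into the ab/adduction channel at
  deep flexion.
* **Subtalar realization.** The subtalar DOF is present and unlocked,
  but it rolls a *calcaneus sub-frame* (carrying the two heel markers)
  about the anterior axis under a planted forefoot, rather than tilting
  the entire shank. Anatomically, rearfoot valgus everts the calcaneus
  under a near-vertical tibia; tilting the whole chain by a 20–30°
  static angle would displace the knee ~15 cm medially and produce
  frontal moments an order of magnitude beyond physiology. IK measures
  the angle from the heel markers exactly as a rearfoot-valgus
  measurement does.
* **Joint moments as generalized forces.** Reported DOF moments are the
  generalized forces conjugate to the joint angles, so extensor demand
  is extension-negative (a squat shows negative knee "flexion" moments),
  matching the convention of the result tables. Three table rows
  conventionally printed positive — the external knee adduction moment,
  ankle "extension" (plantarflexion) and foot valgus moments — are
  extracted as magnitudes of the negated internal curve; the extraction
  mode per row is recorded with the metric definitions.

Muscles are rigid-tendon, activation-proportional actuators
(F = a·Fmax, a ∈ [0, 1]) with explicit signed moment arms — constants or
low-order polynomials in the spanned DOF's angle in degrees — instead of
wrapping-surface geometry. A muscle producing flexion moment has a
positive arm on a flexion DOF, and arms are consistent with
musculotendon length by tendon excursion (dL/dθ = −r, verified to
1e-6 m in the tests). The default set covers the four EMG-monitored
muscles (rectus femoris, biceps femoris, tibialis anterior,
gastrocnemius) plus grouped vasti, gluteals, adductors, soleus, peroneals
and hip rotators.

Two conditioning choices shape the default arms. First, biarticular
couplings are pruned (rectus femoris carries no hip arm, gastrocnemius
no knee flexion arm, soleus and peroneals are pure plantarflexor and
evertor): minimum-norm recruitment is brittle near the zero activation
bound, and antagonist coupling can switch a monitored muscle hard off
for some subjects, which would defeat the EMG-based validation the
workflow depends on. Each monitored muscle therefore has one dominant,
well-conditioned demand channel. Second, the vasti frontal arm
(−0.012 m, abduction-direction) is an *effective lateral-structure* arm
(extensor apparatus plus iliotibial tract): it gives the lateral
compartment its observed dominance in deep flexion when the muscle
moments are carried to the contact balance.

## Scaling and inverse kinematics

Scaling estimates one factor per segment as the mean ratio of
experimental to model inter-marker distances within each rigid
(sub-)frame, then solves the static pose by IK on the time-averaged
marker frame and reports per-marker residuals. The run fails loudly
unless RMS < 0.02 m and the maximum single-marker error < 0.04 m — the
standard scaling quality gates. Under the generator's default 3 mm
marker noise the residuals sit near 0.6–2 mm, comfortably inside the
gates; a single misplaced marker (a constant offset) violates them.

IK minimizes, per frame, the sum of squared distances between
experimental and model-predicted markers over the 8 joint angles, by
damped least squares (Levenberg–Marquardt) with a finite-difference
Jacobian, warm-started from the previous frame for continuity;
tolerance 1e-8 on the relative objective decrease, at most 200
iterations, with an error naming the frame on non-convergence. The
accepted-step sequence makes the objective non-increasing by
construction. Markers are low-pass filtered first (zero-lag Butterworth,
order-2 design run forward and backward, 6 Hz cutoff — standard for slow
squatting movements; the cutoff is configurable).

## Cycle segmentation and time normalization

The squat cycle is segmented on the knee-flexion trace: the deepest
point is the global maximum (earliest frame on ties), and the cycle
starts/ends at the last/first crossing of a 10° upright threshold around
it; a trace that never exceeds the threshold raises "no squat detected".
Descent (start → deepest) is resampled by linear interpolation to
samples 0–50 and ascent to 51–100 of a 101-point 0–100 % cycle, so the
deepest frame lands exactly at 50 % regardless of descent/ascent
duration asymmetry and sampled extrema are preserved exactly. The
101-point grid is the field convention for 1-D curve analysis.

## Inverse dynamics

Net joint moments come from a bottom-up Newton–Euler recursion
(foot → shank → thigh), with the ground reaction force applied at the
center of pressure, segment kinematics differentiated by central
differences (one-sided at the ends) on filtered angles (same 6 Hz
zero-lag filter), gravity 9.81 m/s², and the HAT+barbell entering at the
weight share. Moments and contact forces are normalized by the sum of
body and barbell mass (N·m/kg, N/kg). The recursion is verified against
a hand-derived static pendulum (m·g·d = 4 × 9.81 × 0.2 = 7.848 N·m), a
balanced upright stance (all moments ≈ 0), and an independent
lever-arm oracle at a bent static pose.

## Static optimization

Per frame the net moments are distributed among muscles by minimizing
the sum of squared activations subject to moment balance and activation
bounds:

  minimize Σ aⱼ² subject to Σ rᵢⱼ(pose)·Fmaxⱼ·aⱼ = Mᵢ, 0 ≤ aⱼ ≤ 1.

The box-constrained QP is solved exactly per frame by the
Goldfarb–Idnani dual active-set method (`quadprog::solve.QP`);
determinism is inherited from the exact solver. High-cost reserve
actuators (quadratic weight 1000 per N·m) guarantee feasibility and
absorb moments no muscle can produce; with reserves disabled the
equality-constrained problem is solved exactly and infeasible frames
raise an error naming the DOFs. The closed-form KKT solution of the
single-constraint problem (a = M·c/Σc², c = r·Fmax) and an independent
QP solver serve as oracles in the tests.

One deliberate deviation from the "reserves absorb everything" default:
the knee ab/adduction and int/ext rotation rows are excluded from the
recruitment constraints altogether. The knee frontal moment is carried
by the condylar contact asymmetry — exactly the quantity the
medial/lateral decomposition resolves — so letting muscles or generic
reserves "balance" it would be circular. Reserves remain on all
constrained DOFs and the balance residual is < 1e-6 N·m on every frame.

## Knee contact decomposition

Total tibiofemoral compression is the compressive component of the
intersegmental knee force along the tibial long axis plus the axial pull
of every knee-crossing muscle (per-muscle axial factor, default 0.45,
for line-of-action obliquity). The medial/lateral split places the
contact points at ±d from the knee center with d = 25 % of the tibial
plateau width (default width 0.08 m scaled with stature — not reported
per participant, hence configurable), and solves, per frame,

  F_med + F_lat = F_tot,  (F_med − F_lat)·d = M_frontal,

where M_frontal is the *external* knee ab/adduction moment (the negative
of the internal ID moment) plus the frontal moments of the knee-spanning
muscles, adduction-positive. Taking moments about the lateral contact
point reproduces the familiar lateral-point balance formulation; the
centered 2×2 system is algebraically identical and symmetric to
implement. A negative solution (condylar lift-off) is clamped to zero
with the whole load on the other condyle and a flag raised; conservation
F_med + F_lat = F_tot holds exactly with and without clamping.

## EMG processing and model validation

Raw EMG (1,000 Hz) is band-pass filtered with a zero-phase 4th-order
Butterworth over 100–500 Hz as specified for the recording system. At a
1,000 Hz sampling rate the 500 Hz edge coincides with Nyquist, so the
band-pass is not realizable and the filter degenerates to the 100 Hz
high-pass; a `strict` mode errors instead. Amplitude is extracted as a
moving-window RMS (100 ms window, 50 % overlap, interpolated back to the
sample grid) and normalized by the MVC reference RMS to the 0–1
activation scale ("0" complete inactivation, "1" full activation),
clamped at 1 since test bouts can exceed MVC. Validation correlates the
normalized envelope with the static-optimization activation on the
101-point cycle per muscle (Pearson r and RMSE, pass threshold r ≥ 0.7
by default); constant series are reported as "correlation undefined"
rather than propagating NaN.

## Group statistics

Discrete metrics (peak angles, per-plane ROM, peak moments, peak contact
forces; trial means per participant and load) are compared with
independent two-sample t-tests — pooled variance by default, Welch
selectable — at α = 0.05 per comparison, with no multiplicity correction
across metrics or loads (a caveat worth remembering when reading the
tables). Whole curves are compared with a 1-D SPM two-sample t-test:
the pointwise pooled-t curve is thresholded at the family-wise critical
value from 1-D random-field theory — the expected Euler characteristic
of a t-field at the residual-estimated FWHM smoothness (Kiebel-style
gradient estimator), two-sided at α/2 per tail — and maximal
suprathreshold runs are reported as integer percent-cycle intervals.
A label-permutation threshold on max |t| (default 10,000 permutations,
seeded) is available as a fallback and agrees with the RFT threshold
within 10 % on smooth Gaussian curves at n = 10 per group. Monte-Carlo
calibration over 1,000 seeded null replicates puts the family-wise
false-positive rate near 0.04–0.05 at nominal 0.05.

## The synthetic cohort generator

Because the underlying experiment's raw recordings are not publicly
deposited, every stage is exercised on a seeded synthetic cohort whose
defaults encode the study conditions: 10 participants per group
(valgus angle uniform on (6°, 30°), normal on (0°, 5°); mass and height
around 65.67 kg and 1.72 m; 1RM = 1.2 × body mass), loads 0/30/70 %
1RM, three 4 s trials per condition at 100 Hz markers/GRF and 1,000 Hz
EMG. Hidden per-segment length multipliers (SD 3 %) are the ground truth
the scaling step must recover.

The joint-angle template is a raised-cosine upright→deepest→upright
profile (smooth, zero end velocity) with per-participant peaks drawn
around table-motivated means (knee flexion 134°, hip flexion 92°,
dorsiflexion 34°, knee adduction 3° + a frontal wobble crossing zero)
and valgus-group offsets in the directions of the result tables
(+10° knee flexion, +8° hip flexion, +4° dorsiflexion, +4° knee
adduction, +0.12 N·m/kg external knee adduction moment). Markers are
forward kinematics plus Gaussian noise (SD 3 mm); ground forces are the
routed share of whole-system momentum (so the vertical impulse balances
over a cycle that starts and ends at rest), with noise SD 5 N.

The center of pressure is *prescribed*, not derived from a single-leg
zero-moment point: a one-leg chain carrying a 0.5 share of the trunk has
no dynamically consistent single-plate COP (the unmodeled contralateral
leg balances the rest). Anteriorly the COP rolls from behind the ankle
near upright (recruiting the dorsiflexors) to the forefoot at depth
(recruiting the plantarflexors); laterally it carries the medial shift
that injects the external knee adduction moment. That injection is
closed-loop: one baseline ID pass plus one COP-perturbed pass give the
exact per-frame linear sensitivity of the external frontal moment to the
lateral COP, so the injected moment curve equals its target
(0.21 + 0.12·valgus)·φ N·m/kg exactly; through the contact balance the
same shift produces the medial contact-force excess of roughly
0.12/(2d) ≈ 3 N/kg per unit effect, consistent with the contact-force
table.

Ground-truth torques are computed by running the package's own inverse
dynamics on the true angles and final GRF, and ground-truth activations
by running the package's static optimization on those torques. The
parameter-recovery tests therefore exercise the
marker → IK → differentiation → ID path (not ID self-identity: ID's own
correctness is pinned by the independent hand oracles), and the EMG
channels — band-limited (100–450 Hz) carriers amplitude-modulated by the
true activations over a 0.05 noise floor, with an MVC bout at
modulation 1 — guarantee by construction that the EMG envelope and the
estimated activations should agree (observed r ≈ 0.9–0.99 per muscle on
noisy trials).

What the generator does *not* emulate — and hence what green tests do
not certify about real data: soft-tissue artifact (noise is white, not
correlated with motion), marker occlusion and gap filling, fatigue,
bounce or inter-repetition variability within a set, true wrapping
moment arms, co-contraction beyond minimum-norm recruitment, left-right
asymmetry, and a second force plate. Sagittal moment magnitudes run
somewhat above the printed cohort values (the single-leg share routing
and deterministic COP inflate the knee extensor demand by tens of
percent); group *differences*, which the statistics consume, are
controlled exactly by the injected effects.

## Numerical choices and degenerate inputs

* Derivatives: central differences, one-sided at the series ends; the
  generator uses the same discretization, so recovery tests are not
  confounded by differencing bias.
* Filtering: `signal::filtfilt` with reflective padding (3× the
  rate/cutoff ratio) to suppress end transients.
* Ties for the deepest frame break to the earliest frame.
* Lift-off clamps to the non-negative orthant with conservation kept
  exact; the flag is carried alongside the curves.
* Seeds: every stochastic stage derives child seeds from the user seed
  with a Lehmer-style mixer kept below 2³¹; the same spec yields
  bit-identical cohorts and byte-identical result tables.
* Degenerate inputs error with typed conditions: non-positive masses,
  angles outside [0°, 30°], unknown groups/muscles/DOFs, missing
  markers (named), unscaled models, stream length mismatches, no squat
  detected, infeasible optimization without reserves (DOFs named),
  non-positive MVC, zero pooled variance, groups smaller than 2.

## Problem sizes used by the tests

The shipped test-suite and acceptance runs use desk-scale sizes chosen
to keep the full chain honest while staying fast: single noise-free
trials for parameter recovery (401 frames), 1,000 replicates for the SPM
null calibration, and an n = 10 per group, 70 % 1RM, three-trial cohort
for the effect-direction checks. The `run_pipeline()` defaults process
the full 10+10 × 3 loads × 3 trials cohort in the order of fifteen
minutes on a single core.

## Known limitations

The model is a planar-dominant reduced linkage: no 6-DOF pelvis, no
trunk articulation, no left leg, no ligaments, no elastic foundation
under the condyles, no Hill-type force–length–velocity scaling, and
moment arms are explicit functions rather than geometry. The contact
decomposition assigns all frontal balance to two contact points at
±25 % of tibial width, so its absolute forces inherit every upstream
simplification; its comparative structure (valgus vs normal, load
trends) is the quantity of interest. Statistical tables apply no
multiplicity correction, mirroring per-comparison α = 0.05.
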