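---
title: "Methods: simulating and learning transperineal biopsy sampling strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and learning transperineal biopsy sampling strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind `biopsyplan`, the
assumptions it makes, every tunable that matters, and the choices taken
where the design was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The simulated procedure

Targeted transperineal biopsy samples a suspicious lesion through a
brachytherapy template: a 13×13 lattice of needle holes at 5 mm pitch held
against the perineum, with needles travelling along one image axis. The
simulator works entirely on 3D binary masks of the prostate gland and one
target lesion (a patient with several lesions contributes several cases).
Conventions, fixed once and used everywhere:

* voxel indices are 1-based; world coordinates in mm are voxel centres,
  `world = origin + (index − 1) · spacing`;
* the needle axis is the third array dimension (z); the template plane is
  (x, y);
* grid nodes are `(i, j) ∈ 1..13²` with node (7, 7) at the template centre,
  anchored at the in-plane projection of the *true* gland centroid — the
  physical template is positioned on the patient, so it is not subject to
  the image-registration error that perturbs the observed masks.

## The decision process

The state is `s_t = (P_t, L_t, N_t, N_{t−1}, N_{t−2})`: observed gland and
lesion masks plus the current and two previous needle-trajectory masks; the
two-deep needle history lets a sequential policy react to what has already
been sampled. The action `(δx, δy, δz)` has continuous in-plane components
in (−10, 10), interpreted as *grid steps* (rounded half-away-from-zero,
then clamped to the grid) — a ±10-hole range allows movement across most of
the template in one step, which is the point of making the action
continuous. `δz` (nominally in [−1, 1]) is thresholded three ways: below
−1/3 the needle is not fired; in [−1/3, 1/3) it fires at the apex depth; at
or above 1/3 it fires at the base depth. The printed action tuple has only
two firing depths, while the reward table contains a "not fired" case; the
three-way threshold is the minimal encoding that supports both.

Rewards are the integers +10 (fired, intersects the lesion), −2 (fired,
inside the gland, misses), −1 (not fired), −5 (fired with the trajectory
entirely outside the gland). Precedence for fired needles is outside-gland,
then hit, then miss; "outside the gland" means the trajectory mask shares no
voxel with the gland mask. Episodes are capped at 20 steps and terminate
early at five intersecting needles. Repeat visits to a node are allowed
(nothing in the procedure forbids re-sampling a hole; the coverage metric
penalises redundancy), and repeated hits at one node count toward the five.

### Needle geometry

Needles are straight, axis-aligned cores of configurable length (default
20 mm, a standard biopsy core throw), one voxel thick, centred on the chosen
depth plane and clipped to the image. The apex and base depth planes sit at
25% and 75% of the gland's extent along the needle axis — "near the apex"
and "near the base" without a printed value. A direct consequence worth
knowing: the apex core tip reaches `0.25·extent + 10 mm`, so for glands
longer than ~40 mm a small lesion at the exact gland centre can be
unreachable from either depth. That is a faithful property of two fixed
firing depths, not a bug; study-scale lesions (radius ≥ 6 mm) in typical
glands are reachable.

## Intra-procedure mismatch

Two mechanisms, with deliberately different semantics:

* **Rigid TRE** — isotropic Gaussian translations with per-axis
  σ = level/√3, so the RMS translation magnitude equals the configured level
  (evaluation levels 0/3/6/10 mm). TRE perturbs only what the agent (or the
  expert planner) *observes*; rewards and metrics are computed against the
  unperturbed anatomy. It models a registration error between plan and
  truth. Translations are drawn once per episode (registration error is
  static within one procedure) and independently for gland and lesion by
  default; they are applied with nearest-voxel rounding.
* **Free-form deformation** — displacements at a 10×10×10 equidistant
  control grid spanning the image, smoothed by a separable Gaussian spline
  kernel into a dense field, applied by backward warping with trilinear
  interpolation and a 0.5 threshold. Deformation alters the *true* anatomy
  each step, and the observation shows the deformed anatomy — the deformed
  lesion is the reward target. `rate` is the fraction of control points
  displaced per step (exactly `⌈rate·1000⌉` points); `scale` bounds each
  displacement component, drawn uniformly in [−scale, +scale] ("a range of
  sampled distance", hence uniform rather than Gaussian). Each step's field
  is resampled fresh and applied to the base masks — per-step fields are
  defined "at each time step" without a composition rule, and fresh
  resampling bounds total drift; cumulative composition is available via
  `deform$accumulate = TRUE`.

Kernel width defaults to the control-point spacing (extent/9), the standard
choice giving overlapping basis functions; the kernel is normalised to unit
peak so `scale` remains an interpretable per-point displacement bound (dense
magnitudes can exceed it only by superposition of neighbouring points).

## Expert policies and demonstrations

The **centre** policy fires the five grid nodes nearest the lesion centroid
(voxel-weighted mean of lesion voxel centres), ties broken lexicographically
by (distance, i, j); each needle fires at whichever depth plane is nearer
the centroid's z. The **edge** policy fires the node nearest the centroid,
then the nodes nearest the four boundary points of the lesion's
transverse-plane projection along ±x and ±y through the centroid —
"the edge of the lesion" is not defined operationally anywhere, and the
±axis boundary-extreme rule is this package's documented choice, consistent
with the projected-area convention used by N.Coverage. Duplicate nodes step
outward (away from the centroid along their axis) to the next unused node,
so small lesions still receive five distinct needles. Demonstration order is
centre, +x, −x, +y, −y, fixed for reproducibility.

Plans convert to demonstration actions as relative node displacements plus
the firing depth (`δz` = −2/3 / 0 / 2/3 for no-fire / apex / base);
displacements beyond ten holes split into a no-fire move plus a fire step.
Replaying demo actions in a zero-mismatch environment reproduces the plan
exactly (asserted at construction time). Expert agents used in evaluation
plan from the *observed* lesion on the first step of each episode — so
simulated registration error misleads them exactly as it would mislead a
clinician planning on mis-registered imaging.

## Policy learning

No deep-learning framework exists in this package's dependency set, and the
networks needed here are small, so the policy and value networks are
one-hidden-layer perceptrons (64 tanh units, identical architecture for
both) with exact hand-derived gradients and Adam. Their input is a compact
encoding of the five-channel state: per-channel axis-marginal occupancy
profiles at the configured observation shape (default 64×64×32), per-channel
summaries (centroid relative to the grid centre in pitch units, its
fractional within-cell offset, needle-axis centroid, occupancy), the current
node, step fraction and hit fraction. Marginal profiles keep the in-plane
localisation this task needs — the lesion centroid, which drives both expert
strategies, is a smooth functional of them — at ~2900 parameters per
network.

The actor outputs a diagonal Gaussian: a tanh-bounded mean (δx, δy scaled to
(−10, 10), δz to (−1, 1)) and a state-independent learnable log standard
deviation per component (initial σ = 3, 3, 0.6 — wide in-plane exploration,
and a firing channel that crosses its thresholds often). Exploration noise
itself is unbounded and the environment quantizer clamps; bounding the mean
rather than squashing samples keeps the log-density exact without a
correction term. The critic is a state-value function: although actor–critic
objectives are sometimes written against a state–action Q-value, PPO
conventionally fits V(s), and that is what is implemented.

* **Behavioural cloning** minimises `(1/n) Σ (a_d − a_pred)²` with Adam at
  learning rate 5e-4 (1000-epoch default). On small demo sets, exact
  plan-level reproduction needs roughly 5000 full-batch epochs (~15 s); the
  convergence checks run that length.
* **PPO** maximises the clipped surrogate minus `c1` times the value loss
  plus `c2` times the Gaussian entropy, with γ = 0.99, λ_GAE = 0.95,
  ε = 0.2, c1 = 0.5, c2 = 0.01 — widely used values for the unprinted
  hyperparameters — and learning rate 5e-5 (the lower of the two printed
  rates, which converges more stably). Each episode interacts with a newly
  sampled training case; rollouts of 10 episodes are optimised for 10 epochs
  in minibatches of 64 with per-batch advantage normalisation. Every 100
  episodes the policy is evaluated deterministically on validation cases and
  checkpointed when mean episode reward strictly improves; the saved
  sequence is therefore strictly increasing. Episode terminations (five hits
  or the 20-step cap) are treated as absorbing for bootstrapping. The
  desk-scale training default is 2000 episodes; a full-scale run
  (100,000 episodes) is a configuration choice, not a different code path.

## Metrics

HR = hits/fired (undefined, reported as NaN with a warning, when nothing
was fired). CCL sums per-needle intersection lengths over fired needles.
N.CCL divides by **5 × the lesion's longest needle-axis chord** — the
maximum five ideally placed needles of unlimited core length could attain;
"the maximum possible CCL obtainable within each volume" is ambiguous
between one and five needles, the five-needle reading keeps the metric in
[0, 1] for a five-needle plan, and the single-needle normalisation is
available via `normalization = "single"`. N.Coverage uses **population**
(divide-by-n) standard deviations of the fired needles' world x and y
positions and the lesion's projected area (union of foreground columns ×
in-plane voxel area). The CCL coefficient is a Pearson correlation across
cases (the unqualified "correlation coefficient" default). Aggregates are
mean ± across-case standard deviation; episodes of one case are pooled
before its metrics are computed. Paired comparisons are per-metric paired
t-tests at α = 0.05; identical reports give t = 0, p = 1 by convention
(zero-variance differences).

## Synthetic phantoms

The generator emulates the structural properties the simulator relies on:
one ellipsoidal gland per case (default semi-axes drawn from 20–28 ×
16–22 × 20–28 mm, typical prostate dimensions), one spherical/ellipsoidal
lesion per case fully inside the gland (radii 4–10 mm: diameters of one to
four grid cells), multiple lesions per patient sharing gland geometry, and
patient-level splits. Default volume 96×96×64 at 1 mm isotropic spacing
(room for the 60 mm template around the centroid); tests and the acceptance
script use 64×64×48 for speed. Lesion size distributions are a parameter,
not an assertion — no public distribution exists for the clinical cohorts
this stands in for.

What phantoms do **not** emulate: real gland/lesion shape irregularity,
multi-focality interactions, MR intensities, annotation noise, or any
correlation between lesion size and location. Tests passing on phantoms
therefore validate the *mechanics* (geometry, rewards, learning dynamics,
metric identities) and qualitative trends (hit rate degrading with TRE,
edge spreading more than centre), not clinical performance numbers.

## Numerical choices and degenerate inputs

* Half-away-from-zero rounding for action quantization (sign-symmetric, no
  directional bias), also used for mm→voxel conversions.
* A needle voxel is covered when its centre lies in the half-open core
  interval [c − L/2, c + L/2): a 20 mm core at 1 mm spacing covers exactly
  20 voxels; boundary clipping is by intersection with the image.
* Non-binary mask files are thresholded at 0.5 with a warning.
* Empty lesions/glands, protruding lesions, infeasible ranges, non-finite
  actions or fields, stepping a finished episode, unpaired reports and
  empty splits all raise immediately with descriptive errors.
* Non-finite imitation/PPO losses abort training (PPO returns the last good
  checkpoint with a warning).

## Problem sizes used by the shipped checks

Phantom cohorts of 10–50 cases at 64×64×48 (48×48×36 for plan-only
checks); behavioural cloning on 10 phantoms (≈50 state–action pairs, 5000
epochs); PPO for 2000 episodes on a 64×64×40 toy case whose lesion fills
the gland; TRE trend on 30 phantoms × 4 levels × 2 episodes. These sizes
were chosen to make every check a few seconds to a few minutes on a single
CPU while still exercising full episodes end to end.

## Known limitations

Straight axis-aligned needles only (no bending, no oblique insertion, no
template-hole occlusion or probe collisions); two fixed firing depths;
free-form deformation is geometric, not biomechanical; TRE is a rigid
translation; observations are binary masks, not images; the compact
marginal-profile encoder cannot represent arbitrary 3D shape detail a
convolutional encoder could, which bounds how far learned policies can
specialise to complex lesion geometry.
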