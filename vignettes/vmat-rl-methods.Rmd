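---
title: "Tandem reinforcement learning for VMAT machine parameter optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem RL for VMAT MPO: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the decision process
and reward it optimizes, the dose model behind them, the network and
training machinery, the free design choices we had to make and why, and the
limits of what the synthetic test bed can show.

## The planning problem as a decision process

VMAT machine parameter optimization is cast as a finite Markov decision
process over the arc's control points. A state combines a volumetric view
of the situation (dose so far plus anatomy masks) with the current machine
parameters; an action sets machine parameters; the reward is the change of
a clinical dose objective. Two policies split the work:

* the **MLC policy** steps through the arc CP by CP. Its state is a
  three-channel 3D tensor — the cumulative dose and the PTV and OAR masks,
  all rotated into the beam's-eye view of the current gantry angle — plus a
  53-vector (52 leaf positions + 1 MU) for the CP being revised; its action
  is the 52 leaf positions of that CP. After each action the cumulative
  dose is updated incrementally (subtract the CP's old contribution, add
  the new) and the objective is re-evaluated.
* the **MU policy** refines the whole arc at once: its state is the
  cumulative dose plus full anatomy and the concatenated machine-parameter
  vector of every CP (53 × CPs entries); its action is the complete MU
  vector. Eight such refinement steps form one MU episode — in effect a
  learned segment-weight optimizer.

The split exists because a single network with branching heads must balance
exploration between leaf positions and MUs, and large MU exploration drowns
the dosimetric effect of aperture changes; two tandem networks decouple the
two reward channels.

## Reward: constraint-scaled dose objective

Plan quality is scored after renormalizing the dose grid so that 95% PTV
coverage equals the prescription (scaled to 1.0). On the anchored grid,

$$v = \sum_{i \in S} w_i \, \mathrm{MSE}_i \, f_i^{\,n_i},$$

with per-structure weights and ideal doses (PTV: w = 50, ideal 1.0;
bladder and rectum: w = 20, ideal 0.0), MSE taken per voxel over the
structure, and $n_i$ the number of the structure's dose-volume constraints
strictly satisfied — PTV D2.0 cm³ < 135%, bladder V50% < 40%, rectum
V50% < 50% and V80% < 20%, with factors 0.75 / 0.5 / 0.7. Each newly met
constraint multiplies the whole structure term by its factor, so the step
reward $r_t = v_{t-1} - v_t$ jumps exactly by $w_i\,\mathrm{MSE}_i\,(1-f_i)
f_i^{n_i-1}$ at a crossing; the tests pin these jump ratios exactly.
Femoral heads are evaluated and reported but carry no reward term.

Choices the formulation left open, and how we resolved them:

* *MSE per structure, not per voxel-count weighted*: "(d − o)²" is read as
  the per-voxel mean over the structure so that $w_i$ is independent of
  organ volume.
* *$n$ is per-structure*: each structure's factor counts only its own
  constraints.
* *Strict inequalities*: values exactly at a limit count as unmet; ties in
  deliverability checks, conversely, count as deliverable (a report at the
  limit is still a legal machine state).
* *Reward sign*: old − new, so improvements are positive; episode rewards
  telescope to $v_{\text{initial}} - v_{\text{final}}$ exactly, which the
  suite asserts to 10⁻¹⁰.
* *MU-episode scoring*: the grid is re-anchored at every step before
  scoring, because the objective is only defined on anchored dose; this
  also makes the objective invariant to global MU scale, so only relative
  modulation matters.
* *Degenerate proposals*: an action that zeroes the PTV dose cannot be
  anchored; it is discarded and assigned the episode's worst reward so far,
  keeping training defined without inventing an objective value.

## Dose engine

The engine replaces a Monte Carlo open-field calculator with an analytic
beamlet model chosen to preserve exactly the properties the learner relies
on — linearity in MU, superposition over beamlets, and plausible geometry:

* each beamlet (leaf pair × 5 mm along-travel bin) is a parallel ray with
  exponential depth attenuation $e^{-\mu d}$ (μ = 0.005 mm⁻¹, water-like at
  megavoltage energies) from the phantom surface, and error-function
  box–Gaussian lateral profiles (σ = 3 mm penumbra);
* a single calibration scalar sets 2 Gy per 100 MU at 10 cm depth for an
  open field;
* a control point's dose is MU × Σ (open fraction × beamlet dose), with
  linear partial credit where a leaf bisects a beamlet;
* plan dose is the plain per-angle superposition; an optional
  angular-blending mode spreads each CP over its sector as a linear
  distance-weighted blend of the two nearest precomputed tensors. It is off
  by default because the published description of the field-edge weighting
  is not recoverable in detail; the degenerate (off) case equals per-angle
  summation, which the tests assert.

D95 is the dose of the `ceiling(0.95 n)`-th hottest PTV voxel, by sorting
without interpolation; the anchoring scale is therefore a ratio of two
doses and cancels global MU rescaling bit-for-bit. Gamma comparison is the
global 3%/2 mm criterion with a 10% low-dose threshold, evaluated by
exhaustive voxel-offset search within 3 × the distance criterion, no
sub-voxel interpolation.

## Machine model and deliverability

The modelled delivery hardware: 26 central leaf pairs of 0.71 cm projected
width, leaf speed 6 cm/s, dose rate 425 MU/min, and a configurable per-CP
delivery time (default 0.5 s) from which the inter-CP travel limit
(3 cm) and per-CP MU cap (3.54 MU) derive. The default arc is 2° spacing
with the cryostat gap read conservatively: a CP is removed only when its
whole ±2° sector lies inside 4–23°, excluding {6°, …, 20°} and leaving
exactly 172 CPs; the open-interval convention (171 CPs) is available as a
flag. Deliverability checking is report-only. Sampled actions are repaired
by `project_action_to_bounds()` (clip to the travel range; crossed pairs
close at their midpoint), with log-probabilities evaluated at the
unprojected sample so the policy density stays well-defined. At inference,
`enforce_deliverability()` additionally clamps inter-CP travel sequentially
and caps MU, so every plan the planner emits passes the checker by
construction — the training reward never sees this repair, which only
finalizes deterministic output.

## Networks

Both networks share one topology: a volumetric encoder (3×3×3 convolution,
stride 2, batch-style normalization and ReLU; one residual block of two
convolutions; a second strided convolution; global average pooling), a
vector encoder (tokens projected and given learned positions; multi-head
self-attention with a residual connection and layer normalization; dense
layer), a shared dense trunk, and three heads — means (tanh, scaled to the
leaf travel range, for the MLC role; softplus for MUs), log standard
deviations (linear, clamped to [−5, 2] for numerical safety), and a scalar
value. Tokenization: the MLC state uses one token per leaf pair (its X1/X2
positions) plus an MU token; the MU state uses one token per CP (its 52
leaf positions + MU), each scaled by the travel range or the MU cap.
Normalization statistics are computed per input volume (batches of one).
Filter counts and widths are capacity knobs (toy: 8/16 channels, 8–16-d
attention, 32-d trunk); the topology and head activations are the
contract. All layers are implemented with explicit forward/backward passes
in plain R matrix algebra and verified against finite differences to 10⁻⁴
relative in the test suite; the Adam optimizer applies a global
gradient-norm clip of 1.0.

## Training and inference

Behavioral cloning first: the expert demonstrator is the conformal
projection of the PTV into the isocenter plane at each gantry angle with a
3 mm margin (closed pairs where the target does not project) — it preserves
the imitation-learning mechanism without clinical reference plans. The MLC
mean head is regressed onto the expert apertures (MSE, Adam), and the plans
predicted by the initialized network become the per-patient initial states.

Each RL iteration processes every patient: one MLC episode, one MU episode,
then a PPO update of each network from its own trajectory (never shared).
Advantages use γ = 0.99, λ = 0.95 and are normalized per update batch
(mean 0, sd 1) — the batch here being the episode's steps, the natural unit
at this scale. The PPO objective uses clip ε = 0.15, value coefficient
0.45, entropy bonus 0.005, and its negative is minimized with Adam (4
epochs per episode, minibatch up to 64). A patient's baseline plan is
replaced only when the episode's final plan strictly improves the total
reward, giving a progressively improving baseline; the iteration with the
best mean total plan reward is checkpointed. Training halts with a
diagnostic if the mean objective exceeds 10× its initial value for five
consecutive iterations.

At inference the loop alternates a deterministic (mean-action) MLC pass and
MU refinement using the best-checkpoint weights, finalizes each candidate
with the deliverability projection, accepts it only on strict objective
improvement, and stops otherwise, with a hard cap of 8 outer passes. The
Adam step size is 10⁻⁴ throughout; all regimen constants are plain
`train_config()` fields.

## Synthetic phantoms: what they emulate, what they don't

`generate_phantom()` builds seeded pelvic anatomies: a central ellipsoidal
PTV (prostate + margin), bladder anterior-superior, rectum posterior,
femoral heads lateral, with ±20% half-axis variation and centroid jitter
(±4 mm toy, ±10 mm standard), OARs made disjoint from the PTV so the
per-structure ideal doses are consistent, on 5 mm isotropic grids (16³ toy,
32³ standard). The prescription is 36.25 Gy in 5 fractions. These phantoms
exercise the geometry the planner must reason about — OARs abutting the
target from known directions — but not CT heterogeneity, realistic organ
shapes, or inter-fraction motion; the dose engine is water-box analytic.
Passing the synthetic suites therefore demonstrates the correctness of the
mechanics (reward algebra, GAE/PPO numerics, dose superposition,
deliverability) and the learning dynamics at toy scale, not clinical plan
quality.

A toy-scale caveat worth naming: with a ~30–60-voxel PTV, the D95 anchor is
effectively the near-minimum PTV dose, so a single penumbra-shadowed edge
voxel inflates the renormalized dose and can push the PTV hot-spot metric
over its limit for unlucky anatomies. This is a discretization artifact of
5 mm grids on small targets; clinical-size targets (thousands of voxels)
do not share it.

## Numerical choices and degenerate inputs

* D95/Dx%/Dcc by descending sort, no interpolation; Dcc capped at the
  structure volume.
* Strict (<) constraint comparisons; inclusive (≤) deliverability
  comparisons.
* Dose grids compared for gamma must share geometry exactly; the reference
  maximum defines both the dose criterion and the low-dose threshold.
* An all-zero-MU plan raises an error at evaluation instead of reporting
  zero metrics.
* Plan and network files are JSON at 17 significant digits, making
  write/read round-trips bit-exact; phantom masks are run-length-encoded
  text with a YAML geometry sidecar.
* Rank-sum cohort comparisons use midranks with exact enumeration up to a
  combined n of 10 and the tie-corrected normal approximation beyond; the
  exact branch reproduces textbook two-sided p-values and degenerates to
  p = 1 for a cohort compared with itself.
* All randomness (phantom generation, initialization, action sampling)
  descends from explicit integer seeds; regenerating any artifact with the
  same seed is bit-identical.

## Problem sizes used by the test suite

The suite exercises the full pipeline at deliberately small sizes chosen as
the package's desk-scale defaults: 16³ phantoms, 24-CP arcs, toy networks,
50 imitation epochs and 50 RL iterations over two training phantoms, with
the end-to-end check repeated over three root seeds and decided by
majority, and engine/objective oracles on 4³–12³ hand-built grids. The
clinical-scale template (172 CPs, 48×48×128 states) is constructed and
shape-checked but not trained in the tests.

## Known limitations

* The dose engine is analytic water-box physics: no heterogeneity,
  build-up, scatter kernels, or magnetic-field effects; gamma validation
  against a Monte Carlo reference is out of scope here.
* The expert demonstrator is geometric (conformal projection), not a
  clinical plan; imitation therefore teaches conformality, and all
  OAR-sparing behavior must come from RL.
* Single arc, fixed gantry speed, no dynamic jaw tracking, no multi-arc or
  partial-arc support.
* Desk-scale training budgets demonstrate learning dynamics, not converged
  clinical policies; plan quality on held-out phantoms varies with the
  anatomy draw.
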