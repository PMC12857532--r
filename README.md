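# vmatrl

Tandem reinforcement learning for VMAT machine parameter optimization, at
desk scale.

In volumetric modulated arc therapy (VMAT) a linac delivers radiation
continuously while the gantry rotates; planning means choosing, at every
control point (CP) of the arc, the positions of the multi-leaf collimator
(MLC) leaves that shape the aperture and the monitor units (MU) that set the
output. This package implements a machine-parameter optimizer in which two
cooperating stochastic policies are trained with reinforcement learning to
make those choices directly, without an inverse-planning optimizer:

* an **MLC network** that acts sequentially, one CP at a time, proposing the
  52 leaf positions (26 opposed pairs) from the beam's-eye-view dose and
  anatomy plus the current machine parameters, and
* an **MU network** that acts globally, refining the MU values of all CPs at
  once from the cumulative dose, like a segment weight optimizer (8
  refinement steps per episode).

Both are actor–critic networks (a residual 3D convolution block over the
volumetric state, multi-head self-attention over the machine-parameter
tokens, a shared trunk, and tanh / softplus / linear heads for the action
means, log standard deviations and value). They are trained with proximal
policy optimization (PPO, clip ε = 0.15, c₁ = 0.45, c₂ = 0.005) on
generalized advantage estimates (γ = 0.99, λ = 0.95), after behavioral
cloning of conformal expert apertures initializes the MLC network.

The reward is driven by the dose-volume objective

v = Σᵢ wᵢ · MSEᵢ · fᵢⁿⁱ

where, per structure *i*, MSEᵢ is the mean squared deviation from the ideal
dose (1.0 for the PTV, 0.0 for OARs) on the dose grid renormalized so 95%
PTV coverage equals the prescription, and nᵢ counts the structure's
satisfied dose-volume constraints — PTV D2.0 cm³ < 135% (w 50, f 0.75),
bladder V50% < 40% (w 20, f 0.5), rectum V50% < 50% and V80% < 20% (w 20,
f 0.7). Each newly met constraint multiplies the structure's term by its
factor, so the step reward r = v_old − v_new jumps when a constraint is
crossed. Around the learner the package provides seeded synthetic pelvic
phantoms, a machine/arc model with deliverability checking (leaf bounds,
leaf crossing, 6 cm/s leaf speed, 425 MU/min dose rate), an analytic
beamlet dose engine, DVH metrics, gamma-index comparison, cohort evaluation
with Wilcoxon rank-sum statistics, and a thin command-line interface
(`inst/cli/vmatrl`).

Everything runs from code on synthetic data — no clinical data, TPS or GPU
is involved; the default problem sizes are deliberately small (16³ voxel
phantoms, 24-CP arcs) so the full train/plan/evaluate loop runs on a
laptop. The default clinical-scale arc template (2° spacing with the 4–23°
cryostat gap, 172 CPs) and network state shapes are also available.

## Worked example

```r
library(vmatrl)

machine <- machine_model(field_half_width = 4)   # toy travel range, cm
arc     <- build_arc_template(15, NULL)          # 24 CPs, no gap
envs    <- lapply(1:2, function(s)
             plan_env(generate_phantom(s, "toy"), arc, machine))
demos   <- lapply(envs, function(e)
             generate_expert_demos(e$phantom, arc, machine))

cfg <- train_config(iterations = 50, il_epochs = 50, seed = 1)
tr  <- train(envs, demos, cfg)
print(tr)

# plan a held-out phantom with the trained policies
env9 <- plan_env(generate_phantom(9, "toy"), arc, machine)
res  <- infer(env9, tr$best_mlc_net, tr$best_mu_net, cfg)
rep  <- evaluate_plan(res$plan, env9)
print(rep)
```

A run of the block above prints (abridged to the PTV and the OARs with
reward constraints):

```
Tandem RL training: 50 iterations on 2 patient(s)
  mean objective 2.10866 -> 1.76978 (best reward at iteration 13)
Plan report (phantom-9), deliverable: yes
 structure  metric     value unit
       PTV   Dmean 39.283904   Gy
       PTV     D2% 40.972147   Gy
       PTV    D95% 36.250000   Gy
       PTV    D98% 35.056640   Gy
       PTV D2.0cm3 39.827127   Gy
   bladder   Dmean  2.591854   Gy
   bladder    V50%  0.000000    %
    rectum   Dmean 13.644578   Gy
    rectum    V50% 11.111111    %
    rectum    V80%  0.000000    %
Constraints:
 structure     constraint     value limit  met
       PTV D2.0cm3 < 135%  1.098679  1.35 TRUE
   bladder     V50% < 40%  0.000000 40.00 TRUE
    rectum     V50% < 50% 11.111111 50.00 TRUE
    rectum     V80% < 20%  0.000000 20.00 TRUE
```

The mean objective falls as training accepts strictly improving baselines;
PTV D95% is 36.25 Gy by construction (the grid is renormalized so 95% of
the target receives the prescription, 36.25 Gy in 5 fractions); the
constraint flags report the same dose-volume tests that scale the reward;
and the deliverability line certifies leaf bounds, leaf travel and per-CP
MU limits. `plot_training_log(tr)` and `plot_dvh(dose, phantom)` draw the
reward curve and DVHs.

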