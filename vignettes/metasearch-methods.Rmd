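---
title: "Modeling immersive visual search as a meta-level MDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling immersive visual search as a meta-level MDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasearch)
```

## The model

`metasearch` simulates a searcher looking for a known target object among
dozens of distractors scattered around a 3-D scene, under a deadline. The
searcher cannot perceive object features directly; it must *fixate* objects
to sample noisy measurements of their features, and each fixation costs
time. This is formalized as a meta-level Markov decision process: the states
are beliefs about the scene, the actions are computations (fixations plus a
terminal "report" action), and the reward trades task payoff against
computation cost.

**Latent state.** A scene holds `N_o` objects with a true feature matrix
`A` (`N_o x N_f`). The searcher knows every object's location (a unit
gaze-direction vector on the viewing sphere) and the target's feature vector
`f_target`, but not which object carries it.

**Beliefs.** Beliefs are independent Gaussians per object-feature cell,
summarized by a mean matrix `F` and a precision matrix `J`. Episodes start
from an effectively uninformative prior: `F ~ N(0, 0.01^2)` jitter and
`J = 0.01` (belief variance 100).

**Foveated measurement.** Fixating object `o*` yields a measurement of
every object with precision given by a von Mises-Fisher kernel,
`g_o = scale * exp((x_o' mu - 1) * k)` with `mu` the fixated direction:
full precision (`scale = 3`) at the fovea, exponential decay with angular
misalignment (`k = 200`, so the fovea is sharp: precision halves roughly
every 4-5 degrees). Measurements are `X ~ N(A, 1/g)` elementwise, folded
into the belief by conjugate Gaussian cue combination:
`F <- (F*J + X*J_meas) / (J + J_meas)`, `J <- J + J_meas`.

**Target posterior.** Assuming true feature values are i.i.d. standard
normal, the posterior that object `o` is the target is

```
p_o ∝ exp{ 1/2 * Σ_f [ log(1 + J_of) + J_of/(1+J_of) * F_of^2
                       - J_of * (F_of - f_target_f)^2 ] }
```

computed in log space with max-subtraction. Phantom padding rows (see
below) are zeroed and the rest renormalized. The closed form equals the
ratio of the evidence under "this object's features are `f_target`" to the
marginal under the standard-normal prior; the test suite verifies it
against a numerical-quadrature oracle to 1e-6.

**Reward and stopping.** Each fixation costs `c = 0.01`. The terminal
action reports the posterior argmax and pays 1 if correct. *Fixate-MAP* is
the policy that fixates the posterior argmax and terminates once
`max p_o > theta`.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `prior_mean_sd` | 0.01 | jitter of initial mean beliefs |
| `prior_precision` | 0.01 | initial precision (variance 100) |
| `mask_scale` | 3 | peak measurement precision at the fovea |
| `mask_sharpness` | 200 | angular decay rate of the fovea |
| `cost` | 0.01 | per-fixation computation cost |
| `theta` | none | termination threshold; supply it, use the `THETA_EXPERIMENT = 0.998` preset, or optimize it |
| `fixation_budget` | 22 | fixations allowed before the deadline |

`theta` deliberately has no default: the optimal threshold depends on the
feature representation, so [optimize_threshold()] grid-searches the mean
return over (0.5, 0.999), spaced equally in logit space so the grid is
denser near 1. Common random numbers are replayed across grid points, which
removes simulation noise from the between-threshold comparison.

The fixation budget emulates the task deadline. The default 22 is the 8 s
deadline divided by the seconds-per-fixation constant `tau = 4.55/12.39 ≈
0.367` obtained by [fit_tau()] from the empirical mean reaction time and
the model's mean fixation count. The budget counts *fixations*; the
terminal report is treated as instantaneous (a click at the deadline), so a
policy may still report after its last permitted fixation. An episode whose
policy wants yet another fixation at that point forfeits: termination
reason `"budget"`, no report, reward 0. This is how the model produces
timeout errors analogous to trials where human searchers ran out of time.
The terminal action itself is free by default (`charge_terminate` charges
it like any other computation; Fixate-MAP's fixation ranking is unaffected
either way).

## Synthetic scenes

The generator emulates the statistical structure the belief model assumes,
so that every stage of the package runs without any recorded data:

* object count uniform over 56-113 (one target plus 55-112 distractors);
* true features i.i.d. standard normal, matching the model's prior;
* locations area-uniform in a spherical cap (default half-angle 60
  degrees), a stand-in for a head-fixed field of regard -- the spatial
  distribution of objects within a viewpoint is not otherwise constrained,
  and the cap is configurable for that reason;
* an 8-second deadline;
* optional `distractor_similarity` in [0, 1) that mixes distractor feature
  rows toward the target row (rescaled to keep unit marginal variance),
  making discrimination harder -- similarity 1 (identical identities) is
  excluded by construction.

Scenes of different sizes are padded with *phantom objects* -- zero-feature
rows pinned to the screen-center direction -- to a fixed maximum (113), so
the belief state has a fixed layout. Phantoms carry exactly zero posterior
mass and can be neither fixated nor reported.

What the generator does **not** emulate: room semantics, occlusion,
object-size and visibility constraints, and the correlated feature
structure of real object sets. Tests passing on synthetic scenes therefore
validate the machinery and the model's internal consistency, not claims
about human gaze in real scenes.

## Feature spaces

Real scenes enter the model through object representations:

* **Shape** -- the D2 distribution: the histogram of Euclidean distances
  between 500,000 random point pairs sampled uniformly by area on the
  object's triangle mesh, with 100 bins. The bin range is `[0, mesh
  diameter]` (stored with the histogram, since no binning limit is implied
  by the descriptor itself); the last bin is right-closed. D2 is invariant
  to rigid motions and equivariant to uniform scaling, both verified in the
  tests; on a unit sphere it matches the analytic chord-length density
  `f(d) = d/2`.
* **Color** -- textures resized to 500 x 500 (bilinear), converted from
  sRGB to CIE L\*a\*b\* under the D65 white point, and the flattened a\*
  and b\* channels concatenated (length 500,000). No histogramming, so the
  spatial layout of color is preserved.
* **Embedding** -- a spatial activation tensor (e.g. a 7 x 7 x 512 pooling
  layer of a pretrained CNN) averaged over channels and flattened row-major
  to 49 dimensions. The package consumes such tensors or precomputed
  embedding tables; it does not run a network forward.

Each representation is reduced by centered PCA, retaining the smallest
number of components whose cumulative explained variance reaches a target
(95% convention). Projected scores are standardized to zero mean and unit
variance per component by default: the meta-MDP assumes standard-normal
true features, and standardization is the minimal bridge from arbitrary PCA
scores to that assumption. Raw scores (`standardize = FALSE`) preserve
pairwise distances of the centered data exactly when all components are
kept. A shape+color conjunction is formed by concatenating the two reduced
blocks (k components each), so its effective dimensionality is twice k --
recorded explicitly in ablation output.

## Solving the meta-MDP at reduced scale

[train_agent()] trains an actor-critic agent with a clipped-surrogate
(PPO-style) objective on the meta-MDP, with the belief state encoded as
five tensors (`F`, `J`, `f_target`, 2-D screen coordinates, `p_o`), objects
rank-ordered by posterior so that row 1 / action 1 always refers to the
current MAP object. Each tensor passes through its own dense layer; the
concatenation feeds three dense layers whose width equals the object count,
then an actor softmax (fixations plus terminate) and a critic value head.
Precisions enter the network through `log1p`, a monotone reparameterization
that keeps accumulated precision in a range the tanh units resolve.

Defaults are a reduced scale -- 8 objects, 2 features, tens of thousands of
episodes -- at which training converges on a single CPU in minutes; the
full-scale configuration (113 objects, millions of episodes) is reachable
through the same `training_config()` but is not a test target. Training
hyperparameters (clip 0.2, entropy bonus 0.01, value coefficient 0.5, Adam
with exponential learning-rate decay) were fixed once for stability.
Returns are undiscounted (the episodic horizon is short and no discount is
part of the model); advantages are returns-to-go minus the critic baseline,
normalized per batch. Phantom actions are masked out of the softmax.

A caveat documented here because it is scientifically informative: at the
reduced scale the meta-MDP's optimum is nearly flat between Fixate-MAP and
a "scan the unexplored objects" policy. With only two features a single
fixation rarely settles an object's identity, so systematically sweeping
unexamined objects earns a return statistically indistinguishable from
refixating the posterior leader. Trained agents therefore reliably match
Fixate-MAP's *return*, while their *action agreement* with Fixate-MAP (the
fraction of fixation decisions aimed at the MAP object) depends on which of
the near-equivalent optima the optimizer settles in. With richer features
(more principal components) per-fixation evidence is stronger and the two
policies coincide; this mirrors the finding that the choice of
representation, not the policy family, dominates behavior.

## Threshold optimization and ablation

The ablation harness crosses feature spaces with the number of retained
components. For each cell it builds a scene ensemble from the table's
leading score columns, optimizes `theta`, and simulates independent
Fixate-MAP "agents" (20 by default, one episode per scene each), recording
mean and sd of per-agent return and fixation count. Scene skeletons (which
objects appear, where, and which is the target) are shared across component
counts within a space, so varying the representation is a paired comparison
on identical scenes.

One numerical subtlety: a feature column that is constant across objects is
*not* inert in this model. The posterior's `log(1 + J_of)` term -- the
prior-marginalization penalty -- rewards objects whose value in that
dimension has been confirmed by fixation, so the first appended constant
column changes stopping dynamics (search gets faster) even though it
discriminates nothing. Beyond that first appended component the return is
flat, and an informative component always helps; the acceptance suite
tests exactly these two trends. Constant columns are kept centered at zero
rather than standardized (standardizing a zero-variance column is
undefined).

## Comparing simulated and recorded gaze

Model traces and recorded fixation streams share one code path:

* **Relative looking times** -- per-scene proportions of fixation samples
  per object.
* **Cross-entropy with a lapse rate** -- the model distribution is mixed
  with the uniform distribution, `(1-eps) p + eps/N`, before scoring
  against the empirical distribution; the mixture is the standard
  psychometric lapse convention. `eps` is fitted per participant by 1-D
  minimization ([stats::optimize()], golden section) of the summed
  cross-entropy, checked against the interval endpoints. Scores are
  reported relative to a uniform baseline (higher difference = better
  match), a quantity invariant to object relabeling.
* **Transition structure** -- per-scene matrices of consecutive-fixation
  transition probabilities (self-transitions included by default, a flag
  drops them for dwell-encoded streams), averaged over traces. Two systems
  are compared by a Mantel permutation test on object-by-object distance
  matrices; each object's transition profile is its row concatenated with
  its column (in- and out-transitions; a `row`-only strategy is exposed
  since the profile convention is a free choice). The Mantel `r` is the
  Pearson correlation of the off-diagonal upper triangles and the
  one-sided `p` is `(1 + #[r_perm >= r_obs]) / (n_perm + 1)`, a valid
  (conservative) permutation estimator whose null calibration the
  acceptance suite checks directly.
* **Reaction times** -- a single constant `tau = m/f` (empirical mean RT
  over model mean fixations) maps fixation counts linearly to seconds.
* **Performance breakdown** -- correct / wrong-target / timeout fractions
  per trace set.

## Numerical choices and degenerate inputs

* Posterior computation is in log space with max-subtraction; exact ties in
  the argmax break toward the lowest object index, everywhere, for
  determinism.
* Measurement precisions below `precision_floor = 1e-12` are treated as "no
  sample" (zero precision, ignored by the update) instead of drawing from a
  near-infinite-variance Gaussian; the information content is identical.
* The foveal kernel may underflow to exactly 0 for strongly misaligned
  objects; that is well-defined (it never produces NaN).
* The belief `(F, J)` carries the initialization pseudo-observation
  (`J0 = 0.01`); the posterior uses the maintained `(F, J)` as-is, and the
  quadrature oracle in the tests adopts the same convention. The resulting
  ~0.01-precision distortion relative to a purely data-driven posterior is
  negligible and documented here.
* All-phantom scenes, empty ensembles, empty fixation records, constant
  distance matrices, zero-area meshes, and out-of-range thresholds raise
  descriptive errors rather than propagating NaN.
* Every stochastic stage takes a seed; pipelines derive per-stage child
  seeds deterministically from a global seed, and all seeds stay below
  2^31.

## Problem sizes used by the tests and the acceptance script

The test suite runs everything at sizes a laptop CPU handles in minutes,
chosen once as the package's reduced study conditions: posterior-oracle
checks on 2-3 objects; the open-loop optimality surrogate on 3-object,
1-feature, budget-4 problems (121 enumerated sequences, 10,000 Fixate-MAP
episodes); RL convergence at 8 objects / 2 features / 30,000 episodes;
ablation cells of 16 scenes x 8 objects with 20 agents; Mantel calibration
over 500 replicates of 999 permutations; and a 500,000-pair D2 check. The
acceptance script simulates 60 experiment-scale scenes (56-113 objects, 6
features, threshold 0.998, budget 22) with 20 agents per scene.

## Known limitations

* The synthetic ensemble's independence assumptions match the model's
  prior exactly, so simulated performance is an upper bound on how well the
  machinery could fit data from scenes with correlated features.
* Fixation durations, saccade dynamics, and covert attention are outside
  the model; time enters only through the per-fixation cost and `tau`.
* The exact lapse-fitting and Mantel profile conventions used with the
  original gaze data are not fully determined by the available sources;
  both are exposed as options and the defaults are the field-standard
  choices.
* At the reduced RL scale the optimal-policy basin is nearly degenerate
  (see above); full-scale training would be needed to reproduce the
  distinct convergence to Fixate-MAP.
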