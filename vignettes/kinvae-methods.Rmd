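---
title: "Supervised latent-variable analysis of touchscreen drag kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised latent-variable analysis of touchscreen drag kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinvae)
```

## The problem

Fine-motor control differences between children with Autism Spectrum
Disorder (ASD) and typically developing (TD) children leave measurable
traces in the way a finger drags objects across a touchscreen. `kinvae`
implements a complete analysis chain for such data: it reduces raw
tap-to-lift finger trajectories, sampled at a fixed rate (40 Hz by
default), to a small set of interpretable kinematic features per task,
learns a low-dimensional latent representation of those features with a
variational autoencoder (VAE) that is simultaneously trained to predict
group membership, and then interrogates the latent space to quantify
*which* features drive the separation and *at what values* an individual's
assignment probability tips from one group to the other.

Because clinical touchscreen datasets of this kind are rarely public, the
package ships a synthetic cohort generator that emulates the study design
the method targets — two groups of 30 participants, 25 dragging tasks each
(five difficulty levels, five tasks per level), five trajectories per
task — with controllable between-group effect sizes. The generator is a
first-class, tested component: all simulation results in this package are
produced by it.

## Kinematic features

A *trajectory* is the ordered sequence of (t, x, y) samples from the first
tap to the finger lift. Twelve features summarize each task (the average
of its trajectories):

| Feature | Definition | Units |
|---|---|---|
| MeanSpeed | mean instantaneous speed | units/s |
| MaxSpeed / MinSpeed | mean of local speed maxima / minima | units/s |
| sdSpeed | SD of instantaneous speed | units/s |
| MeanAcceleration | mean signed acceleration | units/s² |
| MaxAcceleration / MinAcceleration | mean of local acceleration maxima / minima | units/s² |
| sdAcceleration | SD of signed acceleration | units/s² |
| STH | straightness: chord length / path length | — (in [0,1]) |
| DC | mean absolute turning angle per unit time | rad/s |
| sdDC | SD of directional change | rad/s |
| MeanLength | mean path length of the task's trajectories | units |

Numerical conventions, chosen where the feature names alone leave room:

* Speeds are forward differences of position at the fixed sampling step;
  no smoothing is applied by default. Acceleration is the signed
  derivative of *scalar* speed, not the vector-acceleration magnitude —
  decelerations must be negative for MinAcceleration to carry
  information.
* "Peaks" (MaxSpeed, MinSpeed, MaxAcceleration, MinAcceleration) are
  interpreted as means of interior local extrema (sign changes of the
  series' first difference), falling back to the global extremum for
  monotone profiles. A `peaks = "global"` switch selects plain extrema
  instead.
* MeanLength is the mean Euclidean path length per task. The count of
  trajectories per task is also recorded (`nTrajectories`) but is not a
  model feature; the two readings of "average amount of trajectories" are
  both available, with mean length as the default.
* Directional change skips zero-length displacements (their direction is
  undefined); a trajectory whose displacements are all zero is degenerate
  and excluded with a warning rather than imputed.
* Tasks flagged as not correctly performed are dropped before
  aggregation, so cognitive errors do not contaminate the motor analysis.

## The model

Each per-task row \(x \in \mathbb{R}^{12}\) (z-scored feature columns) is
mapped by a tanh encoder to the parameters of a diagonal Gaussian over
\(d\) latent variables, \(\mu(x)\) and \(\sigma(x) = \exp(\ell(x)/2)\)
with \(\ell\) a log-variance head, from which a latent sample
\(z = \mu + \sigma \odot \varepsilon\), \(\varepsilon \sim N(0, I)\), is
drawn (the reparameterization trick). A mirrored decoder reconstructs the
features from \(z\) through a linear output layer, and a predictor head —
one tanh layer feeding a two-unit softmax — classifies the row's group
from the same \(z\). The training objective weights its three parts
equally:

\[
\mathcal{L} \;=\;
\underbrace{\tfrac{1}{12}\lVert x - \hat x\rVert^2}_{\text{reconstruction}}
\;+\;
\underbrace{\tfrac12 \textstyle\sum_j
  \bigl(\mu_j^2 + \sigma_j^2 - 1 - \ln\sigma_j^2\bigr)}_{\mathrm{KL}\left(q(z \mid x)\,\Vert\,N(0,I)\right)}
\;+\;
\underbrace{-\bigl[y\log p + (1-y)\log(1-p)\bigr]}_{\text{prediction}}
\]

where \(p\) is the predicted probability of group 1 and \(y\) the label.
The KL term regularizes the latent space toward a standard normal, which
is what later justifies fitting diagonal Gaussians to the two groups'
latent points; the prediction term shapes that same space so the groups
settle into separate regions.

No deep-learning framework is used: the forward pass, backpropagation and
the Adam optimizer are implemented directly in matrix code. This keeps
the model fully inspectable — the test suite verifies the analytic
gradients against finite differences to 1e-4 relative error and the
closed-form KL against numerical quadrature to 1e-6.

Hyperparameters the method itself does not pin down are exposed in
`network_config()` with these defaults: one encoder hidden layer of 32
tanh units (decoder mirrored), a 16-unit predictor hidden layer, Adam at
learning rate 1e-3, batch size 64, 500 epochs, latent dimension 10 for
the selection run and 2 for the final analysis. Predicted probabilities
are clamped to \([10^{-7}, 1-10^{-7}]\) inside the cross-entropy. A
single-sigmoid predictor variant (`predictor_output = "sigmoid"`) is
provided alongside the default two-unit softmax; the two are equivalent
parameterizations of a binary classifier.

## Evaluation and latent-dimension selection

`kfold_cv()` estimates test accuracy with stratified k-fold
cross-validation (k = 10 by default): standardization statistics are
computed on the training folds only and applied to the held-out fold, and
test rows are classified by arg-max of the predictor output evaluated at
the encoder mean. Row-level stratified splitting matches per-observation
evaluation, but note that it lets a participant's remaining tasks inform
the fold they are tested in; `by_participant = TRUE` gives
participant-disjoint folds for a leakage-free (and typically slightly
lower) estimate. Both are provided because either can be the protocol of
record in a given study.

The working latent dimensionality is chosen by training once with a
generous dimension (10), projecting every participant to the mean of
their tasks' encoder means, and running a PCA on those points
(`pca_explained_variance()`): the selected dimension is the smallest
number of components whose cumulative explained variance reaches 95%.
The pipeline then retrains at that dimension (floored at 2, since the
downstream density maps are two-dimensional).

## Latent-space analysis

All analysis uses encoder means; sampling noise is never injected after
training. `fit_class_gaussian()` fits each group's participant points
with a diagonal Gaussian (maximum-likelihood, variance floored at 1e-6),
mirroring the structure the KL term imposes.
`assignment_posterior()` converts the two densities at a latent point
into assignment probabilities with equal priors, computed in log-density
space. Using the fitted distributions instead of the predictor head makes
assignments conservative for points that fall outside the charted region
of the latent space.

`perturb_feature()` implements the Monte-Carlo sensitivity analysis: one
feature of one participant is resampled 100 times from a normal with that
feature's empirical mean and SD while the others stay fixed; each draw is
written into all of the participant's task rows, re-standardized, and
encoded, giving a trace of 100 latent positions and posteriors. Features
whose traces sweep across the class boundary are the ones that matter for
classification; `perturbation_ranking()` summarizes this as the mean
latent displacement per feature. The moment scope of the resampling
distribution is selectable (`dataset`, `group`, or `participant`);
whole-dataset moments are the default so that every participant's
perturbation explores the same, interpretable feature range.

`feature_response_curve()` produces the assignment-probability curves: a
grid of values spanning the feature's mean ± 3 SD (50 points) is imposed
on all participants, and the mean ± SD of the posterior across
participants is reported per grid point. Posterior curves (which cross
near 0.5) are the default reading; the raw class log-densities can be
recovered from the fitted Gaussians if preferred.

Because a VAE's latent space is identified only up to rotation (and
reflection), `latent_alignment()` solves the orthogonal Procrustes
problem between matched participant configurations from two training
runs; the relative residual after alignment is the package's measure of
cross-seed consistency.

## The synthetic cohort generator

Two generation paths are provided, and they play different roles:

* **Trajectory mode** (`generate_cohort()`) synthesizes raw 40 Hz paths:
  a minimum-jerk position profile along the start→target chord (the
  standard model of point-to-point human reaching), with class-dependent
  irregularity entering as multiplicative smooth jitter on the tangential
  speed profile and additive lateral tremor pinned to zero at the
  endpoints. Start points lie near the bottom and targets near the top of
  a 1280 × 800 canvas. Group-1 participants shift two knobs — log
  movement duration and log jitter amplitude — through a calibrated gain
  matrix so that the extracted MaxSpeed and MaxAcceleration effect sizes
  match the configured targets in expectation; higher jitter then also
  raises sdAcceleration and lowers MinAcceleration, reproducing the
  qualitative effect pattern. The configured sdSpeed effect is *not*
  realized in this mode: slowing the movement shrinks the speed scale by
  roughly as much as the jitter widens it, and the two cancel. This mode
  exists to exercise the extractor end to end with physically plausible
  inputs.
* **Feature mode** (`sample_feature_table()`) draws per-task rows
  directly from a group-conditional multivariate normal whose
  standardized mean differences equal the configured effect sizes
  *exactly* by construction, with 30% of within-group variance as a
  participant random effect and 70% as row noise. It is the canonical
  input for model validation, because its statistical structure is
  controlled in closed form. With `latent_rank = r`, all structured
  variation is confined to an r-dimensional subspace of feature space
  (first direction aligned with the effect contrast) plus 5% isotropic
  noise — the construction used to validate latent-dimension selection.

Default effect sizes follow the ASD-like pattern described in the
motor-phenotyping literature: +1.5 SD on
sdSpeed, MaxAcceleration and sdAcceleration, −1.5 SD on MaxSpeed and
MinAcceleration, 0 elsewhere. Raw feature scales (e.g. speeds of hundreds
of screen units/s, STH near 0.92) are fixed constants chosen to resemble
real drags across such a canvas, making the standardization step
non-trivial.

What the generator does *not* emulate: cognitive task content (which card
goes where — correctness is an i.i.d. flag), touch pressure, multi-finger
contact, device physics, heavy-tailed or skewed feature distributions,
and any drift or learning across the session. Passing tests on this
cohort therefore demonstrate that the machinery recovers planted,
Gaussian-shaped structure at realistic sample sizes — not that the
clinical effect itself is re-established.

All randomness flows from one master seed through named, counter-based
substreams (per participant, task, trajectory, fold, perturbation), so
any stage can be regenerated in isolation and identical configurations
give bit-identical outputs.

## Problem sizes and numerical choices

Simulation-backed checks in the test suite and acceptance script use the
study-scale design throughout: 60 participants × 25 tasks = 1,500 rows,
10-fold cross-validation, 100 Monte-Carlo draws per feature, and three
independent training runs wherever run-to-run variability matters.
Generator calibration checks use larger cohorts (200–500 per group) where
standard errors, not runtime, set the requirement.

Other numerical decisions: latent SDs are parameterized as
\(\exp(\ell/2)\) with \(\ell\) clamped to ±15 (inactive in normal
training, it only guards against overflow on pathological inputs);
z-scoring refuses zero-variance columns by error rather than silently
dividing by zero; Gaussian fits floor variances at 1e-6; posteriors are
computed via log-sum-exp; PCA ratios come from `stats::prcomp`;
Procrustes rotations from the SVD solution (cross-checked against
`vegan::procrustes` in the tests).

## Known limitations

* The generator's realism in trajectory space is unverifiable against the
  original clinical recordings (not deposited); it is calibrated only to
  the qualitative feature-effect pattern. Quantitative claims should rely
  on feature mode.
* Row-level cross-validation folds share participants between training
  and test sets; use `by_participant = TRUE` when participant-level
  generalization is the question.
* Acceleration statistics are derivatives of scalar speed; curvature
  accelerations at constant speed register in DC, not in the
  acceleration features.
* The predictor head sees single tasks; participant-level classification
  is obtained post hoc by averaging latent positions, not by a pooled
  likelihood.

## A minimal run

```{r example, eval = FALSE}
library(kinvae)

report <- run_pipeline(run_config(
  cohort = cohort_config(seed = 7),
  network = network_config(),
  out_dir = "kinvae-run", seed = 7))
report
report$ranking

# plot the latent map and one response curve (requires ggplot2)
plot_latent(report$projection)
plot_response_curve(report$curves$MaxAcceleration)
```
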