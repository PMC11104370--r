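---
title: "Modeling autism-like developmental learning with S-CTRNNPB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling autism-like developmental learning with S-CTRNNPB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The package implements a stochastic continuous-time recurrent neural network
with parametric bias (S-CTRNNPB): a three-level predictive-coding network
that learns to predict the next frame of a multivariate sequence together
with the precision of that prediction.  Neurons fall into five contiguous
groups — external input $I_I$, parametric bias $I_P$ (the higher level),
lower-level recurrent units $I_L$, and output units predicting the mean
$I_M$ and variance $I_V$ of the next input.  The internal state of a
lower-level neuron evolves by leaky integration,

$$u_{t,i} = \frac{1}{\tau}\Big(\sum_{j \in I_I} w_{ij} x_{t,j}
 + \sum_{j \in I_L} w_{ij}\, l_{t-1,j}
 + \sum_{j \in I_P} w_{ij}\, p_{t,j} + a_i\Big)
 + \Big(1 - \frac{1}{\tau}\Big) u_{t-1,i},$$

with activity $l = \tanh(u)$.  The PB internal state does not change within
a sequence — the higher level is a static code whose value must explain the
whole trajectory.  Output units read the lower level linearly; the predicted
mean is squashed by $\tanh$ and the predicted variance is
$v = \exp(u) + \epsilon$ with floor $\epsilon = 10^{-6}$.  Training
minimizes, per step and dimension, the Gaussian negative log-likelihood

$$L_{t,i} = \tfrac{1}{2}\ln(2\pi v_{t,i}) +
 \frac{(\hat y_{t,i} - y_{t,i})^2}{2 v_{t,i}},$$

a precision-weighted prediction error: the network is rewarded for being
accurate where it claims to be precise and forgiven where it predicts high
variance.  "Stochastic" refers to this Gaussian output model; the dynamics
themselves are deterministic given parameters.  Gradients are exact
backpropagation through time, implemented in compiled code and verified
against central finite differences at relative tolerance $10^{-4}$.

## The two experimental parameters

**Connection proportion (FC).**  Inter-level weight blocks are masked by
binary matrices with an exact ones-count:
`round(proportion/100 * rows * cols)` connections drawn uniformly without
replacement.  The PB→lower block carries the *higher-level* proportion; the
input→lower, lower→mean and lower→variance blocks each carry the
*lower-level* proportion.  The same lower-level proportion is applied
independently to each of those three blocks — the design treats them as one
"lower-level connectivity" factor without specifying per-block differences,
so uniform treatment is the neutral choice.  Within-level topology is fixed
across all conditions: full recurrence among lower-level neurons, no PB–PB
connections.

**Excitability homogeneity (K).**  Lower-level activity thresholds are
drawn once per network from $N(0, K)$ and never updated by learning.
$K \in \{0.1, 1, 10\}$ names the highly homogeneous, modestly homogeneous
and heterogeneous conditions.  Small $K$ means all neurons share nearly the
same operating point; large $K$ spreads them across the saturating
nonlinearity, giving the population a diverse basis of responses.

## Protocol

Developmental training optimizes the masked weights, output biases, and one
PB internal-state vector per training sequence (initialized at zero) by
full-batch adaptive-moment gradient descent (learning rate $10^{-3}$,
moment decays 0.9/0.999).  No emotion labels are used.  Recognition (the
test phase) freezes the structure — verified bit-exact in the tests — and
optimizes only a fresh PB vector for each held-out sequence.
Cross-validation blocks by identity: each fold holds out all emotions of a
group of identities, so generalization is always across individuals.  One
mask/threshold/weight draw is made per replicate seed and shared across
folds; folds differ only in the data split, which isolates the data-split
effect from the draw of the network topology.  Re-drawing masks per fold is
a defensible alternative; sharing them is this package's convention.

Recognition must be run to convergence: the held-out PB starts at the
origin, which typically lies inside the self-organized cluster region, so a
truncated PB optimization leaves test PBs artificially close to the
training clusters and *inflates* the recognition index — most strongly for
overfitted networks, whose test PBs belong far outside the clusters.  The
default is therefore 2000 recognition epochs (the inferred PBs and the
index are unchanged when extended to 5000 at desk scale), against 3000
developmental epochs.

Performance is summarized by the cross-validated test MSE (generalization)
and by the *emotion recognition index*: the average silhouette width of
held-out PB activities against the training PB clusters grouped by true
emotion.  Test points are scored against training clusters only — that
operationalizes "similarity of the test PB to the training clusters of the
same emotion" most directly; a variant that also scores the training points
against each other is exposed via `include_train = TRUE`.

## Mechanism analyses

Three probes explain *why* conditions differ.  *Tolerance*: from each
trained PB, generate closed-loop (feeding the predicted mean back as input,
initial frame taken from each target) and count the training sequences
reproduced below an MSE threshold (default 0.005; 0.01 is the other
conventional choice and is available).  *Sensory-driven generation*:
open-loop prediction with random PBs drawn uniformly on activity scale —
networks whose predictions survive a meaningless PB are bottom-up
dependent.  Random activities are mapped to internal states by inverse
tanh.  *Top-down-only generation*: infer the PB, then generate closed-loop
— networks that reproduce sequences this way carry their information
top-down.

## Synthetic data

The sequence generator stands in for feature series extracted from facial
expression videos: 6 emotions × 16 identities, 9 features.  Each emotion is
a deterministic smooth prototype (per-feature sinusoid plus ramp with
emotion-specific frequency, phase, amplitude); identities add a smooth
low-frequency perturbation (scale 0.1) and i.i.d. observation noise (scale
0.02), clipped to $[-0.9, 0.9]$ so targets stay inside the invertible
region of the tanh output.  Sequence length defaults to 60 steps, a
desk-scale choice with no empirical anchor.  What the generator does *not* emulate: the spectral content,
cross-feature correlations and non-stationarity of real facial-expression
features.  Passing tests therefore demonstrate properties of the method
under emotion-separable smooth dynamics, not performance on real videos.

The cohort generator emulates, at parameter level only, a resting-state
fMRI cohort of 849 subjects (≈48% affected): two correlated
connectivity values on correlation scale (latent correlation 0.2 — a
modest positive dependence between neighbouring connections that also keeps
all 75 subgroups occupied at this sample size), a lognormal regional
homogeneity (so the Box-Cox step is non-trivial), covariates, a logistic
diagnosis model with planted ReHo main effect and ReHo×FC interaction, and
ADI-R-style symptom scores for affected subjects tied to the diagnostic
linear predictor.  It makes no claim of reproducing real BOLD-derived
distributions; association analyses on it test *statistical recovery of
planted structure*, not any real cohort's effect sizes or p-values.

## Simulation-to-cohort mapping

Connectivity values are Fisher r-to-z transformed, ReHo is Box-Cox
transformed (profile-likelihood $\lambda$ on the grid $[-3, 3]$, step
0.01), and both are residualized on age, sex, FIQ, mean framewise
displacement and site.  Subjects are then ranked into quintiles (each FC)
and tertiles (ReHo) — contiguous groups of near-equal size, ties broken by
stable subject order — and each rank triple maps to a condition: FC rank 1
↔ 20% … rank 5 ↔ 100%; ReHo rank 1 ↔ heterogeneous ($K=10$), rank 3 ↔
highly homogeneous ($K=0.1$), following the reading of ReHo as local
synchronization and hence excitability homogeneity.  The logistic
association model reports single main-effect and interaction terms, so the
two FC measures enter as one combined term (mean of the two standardized
adjusted values) by default, with a both-terms variant available
(`separate_fc = TRUE`).  The three-group analysis clusters subjects in the
(test error, recognition index) plane by k-means with three centres and a
fixed seed — an explicit, reproducible rule for a grouping that is visually
apparent in the plane.  No multiple-testing correction is applied; the
analyses are reported as single pre-specified tests.

## Numerical choices and degenerate inputs

* Variance pre-activation capped at +10 before exponentiation; the cap
  blocks the gradient when active and is not reached in normal runs.
* Lower-level internal state starts at zero; the first prediction is made
  for step 2 from the input at step 1.
* `tau_lower = 2`, a moderate leak giving the lower level short-term
  memory; PB has an effectively infinite time constant by construction.
* Weight initialization: $N(0, 1/\text{fan-in})$; PB internal states start
  at 0, placing every sequence at the PB-space origin before learning.
* `round()` ties in mask counts and rank boundaries are broken upward
  (half-up), documented because R's own `round()` is half-even.
* Non-finite losses abort training with the epoch index; nonpositive
  variances and out-of-range correlations are rejected with errors.
* Silhouette width is defined as 0 when both cluster distances are 0.

## Problem sizes

Routine runs in this package use desk-scale settings chosen for convergence
of the optimizer on a single CPU core: the learning-property
demonstrations use 6 emotions × 8 identities (T = 40, 4-fold, 2000 epochs);
the multi-seed overfitting/recognition contrasts use a 2-emotion smoke
variant (8 identities, T = 24, 2-fold, 3000 developmental epochs,
recognition to convergence, 5 replicate seeds, medians reported); and the
processing-mode dissociation uses 6 emotions × 6 identities (T = 40,
2000 epochs, networks trained on all 36 sequences — the mechanism probes
need trained networks, not held-out data).  The two scales are deliberate:
with a two-dimensional PB and this epoch budget, recognition clusters
organize cleanly only for few emotions, whereas the sensory-vs-top-down
contrast emerges only with the full emotion diversity and sequence length —
with few or short sequences a fully connected network is accurate enough
that even a random PB leaves its open-loop error below that of a
low-capacity sparse network.  The condition contrasts are sign patterns
over medians; the error-based overfitting signature and the tolerance and
top-down contrasts are stable across seed sets at these scales, while the
within-homogeneous-network recognition reversal and the sensory-driven
contrast have seed-to-seed spreads comparable to their median differences —
they carry less evidential weight at desk scale.  Absolute error
magnitudes do not transfer across scales.  Replicate seeds (default 5) are
layered on top of the condition grid so that every contrast is a median
over independent initializations.  The standalone reproduction script under
`scripts/` runs the learning demonstration and the dissociation at 1500
developmental epochs so that a full recomputation stays under twenty
minutes on one CPU core.

## Known limitations

* The optimizer (adaptive moments), the output activation maps and the
  initialization scheme are this package's own choices, made from the
  standard stochastic-CTRNN toolbox; other reasonable choices exist and
  may shift absolute error levels.
* Low-connectivity (20%) conditions have genuinely lower capacity and
  converge more slowly; at desk scale their absolute training error remains
  above the full-connectivity conditions'.
* The cohort pipeline validates statistical machinery on synthetic data;
  real-data effect sizes and p-values are out of scope by design.
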