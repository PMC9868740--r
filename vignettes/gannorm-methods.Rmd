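---
title: "Adversarial normative modeling of functional connectivity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial normative modeling of functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gannorm)
```

## The modeling problem

Resting-state functional connectivity (FC) summarizes the coupling between
brain regions as a symmetric ROI-by-ROI matrix of Pearson correlations
between BOLD time courses. Normative modeling asks a one-class question:
learn the distribution of FC in a reference (neurotypical) population, so
that individuals who deviate from it stand out — without ever training on
the atypical group.

`gannorm` implements this with generative adversarial networks. A generator
learns to produce synthetic neurotypical feature vectors; a discriminator
learns to tell them from real ones. After training, the discriminator's
sigmoid output on a subject's FC features is read as a *neurotypicality
score* in (0, 1). Because only neurotypical data enter training, a low
score marks a connectivity pattern the model never learned to accept.

One model is trained per resting-state brain functional network (RSBFN) —
Default, DorsalAttn, VentralAttn, FrontoParietal, CO+SN — on that network's
intra-network connections only. Per-network models are then combined into
ensembles, and ensemble decisions (mean score or majority vote against a
0.5 threshold) classify subjects as neurotypical or neuroatypical.

## Feature pipeline

1. **Fisher transform.** Each off-diagonal correlation r becomes
   z = atanh(r); self-connections are excluded throughout.
2. **Vectorization.** The strict upper triangle in row-major (i < j) order;
   a 333-parcel atlas gives 55,278 features. The ordering is a package-wide
   contract: network subsetting, explanation weights and centrality maps
   all index into it.
3. **Per-network subsetting.** Only features whose *both* ROIs belong to the
   network (k ROIs give k(k-1)/2 features).
4. **Clip and scale.** z values are clipped at ±2 and mapped by the fixed
   affine map x/2 onto [-1, 1], the input range tanh-generated samples can
   reach. The map is deterministic and identical for training and
   evaluation data; per-feature min-max scaling would leak evaluation
   statistics. Note the map is intentionally *not* idempotent — it is a
   fixed rescaling, so it must be applied exactly once after the Fisher
   transform. Re-cleaning cleaned data clips nothing (modified fraction 0).
5. **Exclusion rule.** A subject whose fraction of clipped cells exceeds
   0.15 *strictly* is dropped from that network's dataset (a subject at
   exactly 15% is retained). Exclusion is per network: the same subject can
   be dropped from one network and kept in another; at ensemble time the
   union of the member networks' exclusions is removed from the eligible
   set.

## Splits

Only neurotypical subjects are trained on. The cross-validation pool is the
largest multiple of 5 *strictly below* 80% of the retained typicals,
computed in exact integer arithmetic (366 retained typicals give 290, hence
five folds of 58 and 76 evaluation typicals; 124 retained atypicals then
leave 48 for validation after 76 are sampled into the balanced evaluation
set). Membership is drawn by seeded shuffle; the original randomization
scheme is not recorded, so a uniform shuffle is the neutral choice. The
pipeline derives one consistent partition from the subjects retained in
every modeled network, which keeps folds comparable across networks; the
harmonization step still guards ensembles whose membership differs.

## The adversarial pair

- **Generator:** a 100-length standard-normal latent vector, dense hidden
  layers with batch normalization then LeakyReLU (slope 0.2), and a tanh
  output layer in feature space.
- **Discriminator:** dense hidden layers with LeakyReLU, each followed by
  dropout (rates 0.40-0.70 are the evaluated range), and a single sigmoid
  output node — the neurotypicality score.
- The reference architecture is a single 200-node generator hidden layer,
  50% dropout, and 75-50-25 discriminator hidden layers.

Each training epoch performs one discriminator step — a mini-batch of 32
real samples labeled 1 plus 32 generated samples labeled 0, binary
cross-entropy, Adam (learning rate 0.0002, beta1 = 0.5 as is standard for
adversarial training) — and one generator step through the composite
network with the discriminator frozen and the generated batch labeled 1.
After every epoch the full training fold is scored in inference mode
(dropout off, batch normalization on moving statistics) and the fraction of
scores above 0.5 is recorded. Training halts when the standard deviation of
that fraction over a moving window (15,000 epochs at full scale; 500 in
the desk profile) falls below 0.01 — the score distribution has stopped
moving, which also guards against overfitting. A constant metric stream
therefore stops training exactly at the window length.

### Numerical choices

- **Generator output initialization.** Cleaned FC features occupy a narrow
  band inside [-1, 1] (with the default synthetic regime, roughly ±0.3). A
  freshly initialized tanh output layer at full Glorot scale fills most of
  [-1, 1], so the discriminator initially separates real from generated
  data on amplitude alone, its training metric saturates at once, and the
  stop criterion fires at the window minimum before the game carries any
  information. The output layer therefore starts at a tenth of Glorot
  scale: generated samples begin near the center of the feature range and
  the two subnetworks stay in genuine competition. Empirically this is the
  difference between a discriminator that scores everything near its
  equilibrium and one whose scores straddle 0.5 informatively.
- Batch normalization uses momentum 0.99 and epsilon 1e-3 on the running
  statistics; biased batch variance in the training pass.
- Binary cross-entropy probabilities are clamped at 1e-12 before the log.
- All randomness — weight initialization, mini-batch sampling, dropout
  masks, latent draws — flows through one seeded RNG scope per fit, so a
  fit is bit-reproducible from its seed and the caller's RNG state is
  untouched.
- Optional input-layer dropout (`gan_architecture(input_dropout = TRUE)`)
  feeds each step a random feature subset. It spreads the score's reliance
  across connections but measurably degrades the absolute calibration of
  scores around 0.5 in our synthetic regime, so it is off by default.

## Selection and ensembles

For each architecture, five fold models are trained; the representative
fold is the one with the best fold-out performance (percentage of scores
above 0.5, or mean score), with ties broken by the other metric and then
the lowest fold index. Ensembles take 0 or 1 representative per network —
candidate counts (2, 2, 2, 3, 4) give exactly 539 non-empty combinations.
Each ensemble is ranked by the fraction of validation subjects (an
all-atypical set) it flags as atypical; ties are broken by the mean
fold-out neurotypicality score of its members (higher first — an ensemble
that also keeps typicals high is preferred), then lexicographically by
member signature so the ranking is deterministic. The validation set
contains only atypicals, so detection rate is the only computable
performance measure on it.

Decision rules at threshold 0.5 (both strict): *mean* — neurotypical iff
the mean member score exceeds 0.5; *vote* — each member votes neurotypical
iff its score exceeds 0.5, majority decides, and an exact tie is resolved
as neuroatypical (the cautious direction for a detection task).

## Evaluation

The positive class is neuroatypical: sensitivity is the fraction of
atypicals detected, specificity the fraction of typicals kept, balanced
accuracy their mean. Metrics whose defining margin is empty are reported as
missing rather than 0. The permutation test shuffles the true labels
(without replacement by default, preserving class counts; a
with-replacement bootstrap variant is available behind a flag) and uses the
add-one estimator p = (1 + #{permuted BA >= observed}) / (n + 1), which
cannot return 0. On small discrete evaluation sets the tie mass between
permuted and observed balanced accuracies makes this estimator
conservative (mean null p slightly above 0.5); calibration checks use
evaluation sets of the size the pipeline actually produces (about 90-100
subjects).

## Explanations and centrality

Local surrogate (LIME-style) explanations probe a trained discriminator
around one subject's features: Gaussian perturbations with per-feature
standard deviation equal to the training data's feature standard deviation
(the tabular-LIME convention), an exponential proximity kernel with width
0.75 * sqrt(d), and a weighted ridge regression (penalty 1) of scores on
features. The k largest-|coefficient| features (default 20) form the
explanation. Per group, feature weights are averaged across subjects
(absent features count 0), reshaped onto the ROI grid, and summarized as
ROI centrality — the mean importance of a ROI's connections. Positive
centrality marks ROIs whose connections raised the neurotypicality score;
groups are mapped separately so group differences do not confound the
maps. The explained model per network is the one with the highest
individual (single-model) accuracy on the evaluation set.

The original work fixes none of LIME's hyperparameters; the values above
are conventions and all are arguments.

## The synthetic cohort

The simulator generates the statistical structure the pipeline consumes and
nothing more: a block-structured population correlation matrix (within_r
inside each network, between_r elsewhere), Gaussian multivariate time
series per subject, and empirical Pearson correlations. The atypical
group's population matrix shifts every within-network correlation involving
the first ceil(hub_fraction * n) ROIs of each network by
perturbation_delta, then re-projects to the nearest positive-definite
correlation matrix (eigenvalue floor 1e-6, renormalized to unit diagonal)
if needed — these hub ROIs are the ground truth the explanation stage
should recover. Defaults emulate the published cohort's scale: 377/126
subjects, 180 timepoints, five networks whose smallest has 24 ROIs (276
features).

The simulator deliberately omits temporal autocorrelation, motion and
scanner/site effects, global signal structure, and heavy-tailed noise: the
pipeline only consumes correlation matrices, so those features would not
change its contracts. Passing tests on this cohort therefore demonstrate
that the machinery recovers planted structure under its own assumptions —
not that comparable accuracy is attainable on real developmental cohorts,
where the published balanced accuracies were in the 0.51-0.61 range.

## Problem sizes used in the shipped studies

`desk_profile()` is the package's reduced-scale study and the configuration
exercised by the acceptance suite: five 16-ROI networks (120 features
each), 200 typical / 80 atypical subjects at 400 timepoints, within_r
0.35, between_r 0.10, hub fraction 0.2, perturbation -0.4, the reference
architecture per network, stop window 500 with a 6,000-epoch ceiling, vote
strategy, 500 permutations, 30 explained subjects per group per network
with 800 perturbations each. At these sizes a full pipeline run takes a
few minutes on one CPU. The hub-recovery summary counts the fraction of
ground-truth hubs whose atypical-group |centrality| lands in the top
quartile of their network; a majority recovered (>= 0.5, against a chance
level of 0.25) is the pass mark used in the tests. `full_profile()`
reproduces the published operating point (candidate counts 2/2/2/3/4,
stop window 15,000) and is provided for completeness; it takes hours.

## Known limitations

- GAN training is stochastic by design; performance is seed-dependent, and
  the package surfaces that (seed sweeps, per-seed reports) rather than
  hiding it.
- The discriminator explains *its own* decision function, not the data:
  centrality maps reflect the connections the model relies on, which under-
  or over-weight planted hubs when the model can separate groups using a
  feature subset.
- Scores are calibrated only relative to the 0.5 threshold convention; they
  are not probabilities of group membership.
- The fixed clip/scale map assumes Fisher-z inputs; applying it twice
  rescales values and is the caller's responsibility to avoid (the state
  marker on `connectivity_matrix` is there to help).
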