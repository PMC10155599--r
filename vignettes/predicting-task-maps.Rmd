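---
title: "Predicting individual task contrast maps from resting-state connectomes on the sphere"
author: "surftask"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Predicting individual task contrast maps from resting-state connectomes on the sphere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Task fMRI contrast maps localize brain function at the level of the
individual, but task protocols are expensive and fragile; resting-state
fMRI is cheap and robust but does not directly localize task responses.
`surftask` implements a surface-based predictive model that maps a
subject's resting-state functional connectome to that subject's task
contrast maps, together with the references any such model must be judged
against: the group-average contrast, an ensembled parcel-wise linear
regression, and the test-retest repeat scan.

All computation lives on icospheres — recursively subdivided icosahedra —
because the exact nesting of subdivision levels gives provably invertible
pooling between resolutions. Real cortical template meshes (e.g. a 32k
surface, which is not an exact icosphere) enter through a nearest-neighbor
resampling adapter (`resampleNearest`).

# The model

## Input: vertex-to-ROI connectomes

For vertex $i$ and ROI $j$, the input feature is the Pearson correlation
$r_{ij} = \mathrm{corr}(\mathbf{t}_i, \bar{\mathbf{t}}_j)$ between the
vertex's resting timeseries and the ROI's mean timeseries. ROIs come from
winner-take-all assignment on component z-score maps (`winnerTakeAll`;
ties to the lowest component index, assignment even when all z-scores are
negative, optional z-floor off by default). A V-vertex surface with M ROIs
yields a V × M multi-channel field; concatenating hemispheres doubles the
channels (`concatHemispheres`). Degenerate constant series produce a
correlation of 0 (with a warning) rather than NaN, so downstream tensors
stay finite.

Runs are augmented by contiguous segmentation (`splitSegments`): the two
halves of each run at training time, all segments averaged at test time
(`ensemblePredict`). Input channels are z-scored with statistics computed
on the training connectomes only and frozen into the model
(`normalizeChannels`; the model applies them automatically at prediction).
Per-channel z-scoring is this package's default and is configurable;
no particular input scaling is canonical for this class of model.

## Spherical convolution

Convolution on the sphere uses parameterized differential operators: each
output channel is a learned mixture of a feature's value, its two
tangential derivatives (east–west and north–south), and its Laplacian:

$$\mathrm{out}_c = \sum_k w_{ck0} f_k + w_{ck1}\, D_{ew} f_k +
  w_{ck2}\, D_{ns} f_k + w_{ck3}\, \Delta f_k + b_c.$$

The derivative operators are assembled per vertex by a least-squares fit
of a linear function over the one-ring in the local tangent frame
(`assembleDiffOps`); the Laplacian is the uniform normalized graph
Laplacian by default (a cotangent variant is available; on the
near-regular icosphere the difference is small and the uniform version is
exactly reproducible). All three operators annihilate constants by
construction. At the two possible pole vertices where the tangent frame
degenerates, the frame of the nearest non-degenerate neighbor is reused.

## The U-Net

`buildModel` assembles an encoder of conv–pool stages, a bottleneck, and a
decoder of unpool–conv stages with skip connections that concatenate
encoder features into the decoder, followed by a per-vertex linear head
projecting to one channel per task contrast. Pooling restricts to the
coarse index prefix; unpooling copies coarse values and averages the two
edge parents at each midpoint. Multi-contrast prediction shares all
backbone weights across contrasts; the head is the only contrast-specific
part, which is what makes head surgery (`replaceHead`) and backbone-only
finetuning (`setTrainable`) meaningful.

The method fixes the topology, not sizes or layer types. Defaults here: instance normalization, leaky-ReLU (slope 0.01), widths
doubling from 64 — all configurable in `modelSpec`. The scaled experiments
in this package use widths 32/48/64 at depth 2 on a level-3 sphere (642
vertices), a size chosen so a full two-phase training run takes about a
minute on one CPU core. Forward and backward passes are written directly
against the sparse operators (no external deep-learning runtime), and the
analytic gradients are verified against central differences to 1e-4
relative error in the test suite.

## Reconstructive–contrastive loss

With batch predictions $\hat{x}_i$ and targets $x_i$,

$$L_R = \tfrac1N \sum_i d(\hat{x}_i, x_i), \qquad
  L_{RC} = [L_R - \alpha]_+ + [L_R - L_C + \gamma]_+ ,$$

where $d$ is the mean squared difference over unmasked vertices ×
unmasked channels (mean, not sum, so margins are resolution-independent)
and $L_C$ averages the cross divergence $d(\hat{x}_i, x_j)$, $i \ne j$.
Formulations of this loss sometimes normalize by the $(N^2-N)/2$
unordered pairs while summing ordered pairs; this package averages over
ordered pairs (equivalently: the mean over unordered pairs of the
symmetrized cross term), which matches the stated pair count and gives
every prediction in the batch a contrastive gradient. With batch size 2 —
the default — there is exactly one cross pair.

Training (`trainModel`) runs in two phases: plain MSE, then the R-C
objective with margins initialized from the converged phase-1 model
(`initMargins`: $\alpha_0 = \bar{L}_R$; $\gamma_0$ is by default the gap
$\bar{L}_C - \bar{L}_R$, with $\gamma_0 = \bar{L}_C$ selectable — both
conventions are defensible) and rescheduled every 20 epochs
($\alpha$ halved, $\gamma$ doubled; `marginSchedule`). A single-subject
batch has no contrastive term and falls back to the hinge on $L_R$.

One structural property of this objective is worth knowing: at the
phase-1 optimum, both hinges start exactly at their boundaries
($L_R = \alpha_0$ and the gap equals $\gamma_0$), so $L_{RC} = 0$ at
phase-2 initialization. Stochastic minibatch hinge activations — with
batch size 2 the contrastive term is a single cross-pair divergence and
highly variable — then produce a drift equilibrium in which the training
$L_R$ settles some 10% above $\alpha_0$ while the contrast gap grows.
The effect is insensitive to the phase-2 learning rate and batch size
(measured across 3e-3 to 1e-4 and batches of 2 to 8). The intended effect
of the margin initialization — keeping reconstruction near its converged
level while the model individualizes — is realized; a strict
$L_R \le \alpha$ at convergence is not, and the acceptance suite reports
that comparison honestly rather than relaxing it.

## Transfer learning

`finetuneModel` implements three modes: `denovo` (ignore pretrained
weights), `full_with_new_head` (re-initialize the head, finetune
everything — for a new task battery), and `backbone_only` (freeze the
head, finetune the backbone with the loss restricted to unmasked
channels — leave-one-task-out domain adaptation; held-out channels
contribute exactly zero gradient, asserted in the tests). Finetuning uses
the MSE objective; the contrastive term is disabled by default on small
datasets.

# Evaluation

`topFracSet` takes the $k = \max(1, \mathrm{round}(x V))$ most activated
(largest signed value) unmasked vertices, round-half-even, ties to the
lower vertex index; absolute-value and most-deactivated modes exist.
`diceAUC` integrates the Dice overlap of the top-$x$ sets over
$x \in \{0.05, \dots, 0.50\}$ with the composite trapezoidal rule on the
*fraction* axis, so perfect agreement scores 0.45. The fraction (rather
than percent) axis is an interpretation choice, documented here, that
keeps reported AUCs on a unit scale (0 to 0.45).
`identificationMatrix` scores subject identifiability: entry $(i,j)$ is
the Dice AUC of prediction $j$ against target $i$, and a subject counts
as identified only when its diagonal entry is the *strict* column
maximum. `reliabilityScreen` flags a contrast as individual-level
reliable when the mean target-vs-repeat AUC exceeds the mean
target-vs-group-average AUC. `wholeBrainR2` is the standard
$1 - SS_{res}/SS_{tot}$ per contrast over masked vertices.

# The synthetic cohort

`makeCohort` generates the test harness: a cohort in which a
low-dimensional subject fingerprint $z_i \sim N(0, \beta^2 I_K)$ drives
both rest and task data, so ground truth is known exactly.

- **Parcellation**: M seed vertices by farthest-point sampling, labels by
  nearest seed, and synthetic z-maps as distance-decay bumps, so
  winner-take-all provably recovers the labels.
- **Rest**: per run, latent ROI signals are unit-variance AR(1) series;
  vertex timeseries are subject loadings times signals plus noise, where
  the loadings are a smooth base topography plus $\sum_k z_{ik} B_k$ with
  fixed smooth basis fields. Optionally a global nuisance series is added
  to every vertex (site-like contamination).
- **Task**: per visit, a smooth unit-sd group template plus a
  fingerprint-coupled deviation plus spatially smoothed scan noise;
  visits share the signal and differ only in noise. Under
  `link = "nonlinear"` half of the deviation energy enters through
  normalized quadratic and interaction features of $z$ — the regime in
  which a per-parcel linear readout is misspecified and the network
  should win over the linear readout while both beat the naive group
  reference.

Default conditions (chosen once as a realistic desk-scale emulation, and
used by the scaled experiments): 4 resting runs of 1200 timepoints split
into 600-point halves (the run structure typical of large public rest/task datasets);
K = 3 latent dimensions, so the nonlinear coupling has 9 features and is
identifiable from a 40-subject training set; deviation scale 0.6 and
smoothed scan noise 0.25 against a unit-sd template, which yields repeat
reliability AUC ≈ 0.43 versus a group-average AUC ≈ 0.33 — i.e., clearly
individual-level-reliable contrasts with headroom between the naive
reference and the generative ceiling (`oraclePredictor`).

The transfer domain (`runTransferExperiment`) keeps the task battery
(templates and coupling fields) and shifts the domain: templates move by
0.3 sd along a field that is 80% shared across contrasts, the base
connectivity topography shifts (loading shift 0.6), and acquisition
changes (2 × 600 timepoints, higher noise, slower autocorrelation, global
signal). The shift is deliberately dominated by shared, input-side
structure: that is what makes leave-one-task-out backbone finetuning able
to improve a contrast it never trained on, as in real multi-site
transfer. An output-side shift drawn independently per contrast would be
unlearnable for the held-out task by construction.

What the generator does *not* emulate: hemodynamics, motion or
physiological artifacts, spatially heterogeneous noise, inter-subject
misregistration, and task-design idiosyncrasies. Passing tests on this
cohort demonstrate that the machinery — connectome construction, the
spherical network, losses, references, metrics — behaves as specified
under a controlled generative model; they do not certify performance on
real cortical data.

# Numerical choices and degenerate inputs

- Minimum-norm pseudoinverse with relative singular-value cutoff 1e-10
  for the parcel-wise baseline (systems can be under-determined when a
  parcel has fewer vertices than features); no intercept by default, with
  an optional flag.
- The linear-baseline features are the same vertex-to-ROI correlations as
  the network input; the per-subject mean connectome across segments is
  used for fitting and prediction.
- Zero-variance timeseries → correlation 0 with a warning; zero-variance
  targets → R² reported as NA; zero-sd channels left unscaled with a
  warning; empty parcels error at the consuming operation, naming the
  parcel.
- Adam (lr 3e-3 for the MSE phase, 1e-3 for the R-C phase in the scaled
  experiments; both configurable per phase), batch size 2, one connectome
  sampled per subject per epoch; every random draw (initialization,
  shuffling, sampling, cohort generation) flows from explicit seeds, and
  fixed seeds give bit-identical parameters and history on one thread.
- Vertex indices are 1-based in memory; GIFTI/CIFTI adapters convert to
  the formats' 0-based conventions at the boundary. Files are written
  with 64-bit floats so round trips are bit-lossless; 32-bit files are
  accepted on read.
- Mesh levels are memoised in-session; a rebuild from scratch is
  bit-identical, which the tests assert, so no on-disk cache is needed.

# Known limitations

- No GPU or multi-device path; the network is sized for hundreds-to-
  thousands of vertices, not the 32k full-resolution mesh.
- Only single-surface CIFTI brain models are written (one hemisphere per
  file); multi-structure files are out of scope.
- The R-C phase's ~10% L_R drift above the initial margin discussed above.
- Subcortical/volumetric prediction and group-level inference across real
  subjects are explicitly out of scope.
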