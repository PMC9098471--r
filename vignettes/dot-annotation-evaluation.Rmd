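---
title: "Evaluating and simulating dot-annotation cell competitions"
author: "dotmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and simulating dot-annotation cell competitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotmatch)
```

# The problem

Crowdsourced annotation of Ki67-stained breast-cancer tiles asks
participants to click one dot per cell and assign one of four classes —
positive tumour (PT), negative tumour (NT), positive non-tumour (PNT),
negative non-tumour (NNT); "positive" nuclei express Ki67 and stain brown
with DAB, negative nuclei counterstain blue with haematoxylin. Tiles are
512 × 512 px at 40X (0.25 µm/px) with annotation confined to the central
256 × 256 px square so that every annotated cell has visual context.
Submissions are scored against expert ground truth. This vignette explains
the models and procedures the package implements, the defaults it chooses
where the problem statement is silent, and what its synthetic data can and
cannot show.

# The matching model

A submitted dot annotates a ground-truth cell correctly when it lies
within a Euclidean radius of 14 px (3.5 µm) of it. Scoring requires a
one-to-one pairing: without it, clicking many dots on one obvious cell
would buy extra credit. The rule only fixes the radius, not which of
several feasible pairings to take, so `matchPoints()` uses the standard
detection-evaluation formalisation: among all one-to-one assignments
restricted to radius-feasible edges, maximise the number of pairs, then
break ties by minimum total paired distance. This is a min-cost
maximum-cardinality bipartite assignment. Greedy nearest-first pairing is
*not* equivalent (two mutually nearby cells can strand a dot that the
optimal assignment places), which is why the solver exists.

Implementation: the radius-feasibility graph is decomposed into connected
components — dots in different components can never compete — and each
component is solved by successive shortest augmenting paths (Bellman–Ford
on the residual graph, augmenting along the cheapest path whenever any
augmenting path exists). With the default cell separation (see below)
components hold a handful of dots, so the exact solver is fast even
though the worst case is cubic. An exhaustive oracle,
`bruteForceMatch()`, enumerates all assignments for up to 8 dots per side;
the test suite checks solver/oracle agreement on hundreds of random
instances, including a crowded preset that forces large components.

Numerical choices: distances are Euclidean in pixel units (the µm radius
is derived display information); comparisons use an absolute tolerance of
1e-9 so that floating-point ties cannot flip the assignment; iteration
order is fixed, making the result deterministic for a fixed input.

With `classAware = TRUE` (the default) matching runs independently within
each class, because a correct annotation means a correct *identification*:
per-class F1 presupposes it. The class-agnostic mode exists for the
confusion matrix and for profile recovery, where cross-class pairs are the
object of interest. Whether a live competition scorer counted
class-agnostic hits is a configuration question, so it is an explicit
flag, not a hidden assumption.

# Metrics

Per class: TP = matched pairs, FN = unmatched ground-truth dots,
FP = unmatched submitted dots, summed over images before deriving
TPR = TP/(TP+FN), PPV = TP/(TP+FP), F1 = 2·TPR·PPV/(TPR+PPV)
(micro-averaging; `aggregateMetrics()` pools raw counts the same way).
Competition accuracy is 100 × correct/total, which under class-aware
matching equals 100 × pooled TPR. Zero-denominator rates are reported as
`NA` ("undefined") and excluded from averages with their count reported —
silently scoring an absent class as 0 would distort small fixtures and
cohort summaries alike. The confusion matrix cross-tabulates true against
recorded class over class-agnostic pairs; missed cells fall in the `NONE`
column, spurious dots in the `NONE` row, so its margins reconcile exactly
with the per-class counts.

# Competition structure

The two packaged editions live in versioned JSON under
`inst/extdata/config/` and are loaded by `defaultCompetition()`. The main
edition has four levels (Mild, Hot, Spicy, Supercharger) with 20/40/60/80
images and 1/2/3/4 classes, introduced in the order PT, NT, PNT, NNT —
easiest to hardest — plus two 5-image practice levels ({PT}, {PT, NT}).
The pilot edition has three levels (20/30/50 images) with all four classes
throughout. Both gate at 50% accuracy with an inclusive bound ("at least
half"), so exactly 50.0 passes. Leaderboards keep each annotator's best
score per level (repeated attempts were allowed), rank by accuracy and
break ties by earlier timestamp when available, else lexicographically —
a documented, deterministic rule. Funnel percentages are rounded half-up
to integers for parity with printed competition reports; a level with no
entrants reports an undefined percentage rather than zero. Where printed
counts and a printed percentage disagree (e.g. 22 of 28 quoted as 81%),
the package computes from counts (79%).

The Supercharger class mix is 21% PT, 60% NT — 81% tumour cells — with
the remaining 19% split 12% PNT / 7% NNT as a package default (the split
within non-tumour is not printed anywhere; PNT is set above NNT to match
the qualitative prevalence of positive non-tumour errors). Lower-level
mixes (Hot 35/65, Spicy 25/62/13, pilot levels Supercharger-like) are
likewise declared defaults, not inferences.

# The synthetic annotator and layout model

`generateLayout()` rejection-samples cell centres uniformly in the
evaluation region subject to a minimum separation, drawing per-image cell
counts uniformly from a range and classes independently from the level
mix. Defaults: 8–40 cells per tile and 30 px minimum separation, chosen
so that the 14 px radius makes matching unambiguous (separation more than
twice the radius); a crowded preset (10 px) deliberately removes that
guarantee to stress the solver. Placement failing after 400 attempts per
cell raises an "infeasible density" error instead of looping. Real tiles
have clustered, anisotropic cell layouts and variable density; uniform
placement is a deliberate simplification — tests passing on it demonstrate
the correctness of scoring machinery, not robustness to real morphology.

`simulateAnnotator()` applies an `annotatorProfile()` generatively: each
cell is detected with a per-class probability; detected dots get isotropic
Gaussian jitter (clamped to the image) and are relabelled by a
row-stochastic confusion matrix; a Poisson number of spurious dots per
image lands uniformly in the evaluation region (modelling artefacts
mis-read as cells — as a spatial process only, with no artefact texture).
All generators are pure functions of their seed.

## Parameter recovery

`recoverProfile()` inverts the model by moments: class-agnostic matching
gives per-class recall (detection probability), the paired-distance mean
gives the jitter scale (isotropic Gaussian jitter makes paired distance
Rayleigh, so σ̂ = mean distance / √(π/2)), row-normalised pair
cross-tabulation gives the confusion rows, and unmatched submitted dots
per image give the spurious rate. Two corrections matter:

* **Radius truncation.** Jittered dots beyond 14 px are lost, so σ̂ is
  biased low as σ approaches the radius; the test suite pins the
  direction of this bias at σ = 10. Below σ ≈ 4 (radius/3.5) the
  truncated mass is under 0.3% and the estimator is effectively unbiased.
* **Chance coincidence.** A spurious dot landing within the radius of a
  missed cell is absorbed into a pair, deflating the spurious-rate
  estimate and inflating recall. The expected absorption probability is
  (missed cells per image) × (matching-disc area / region area); the
  estimator solves the resulting two-equation system by fixed-point
  iteration and redistributes the absorbed count across classes in
  proportion to observed misses. Contamination of confusion rows and σ̂
  by absorbed pairs is second order (< 1% under realistic profiles) and
  left uncorrected.

Fewer than 10 matched pairs flag σ̂ unreliable. The recovery tests use
5,000-cell studies with profiles designed for identifiability: spurious
rates of at least 2 per image (≥ 500 Poisson events) and confusion mass of
at least 0.25 on classes with enough detected cells, so that a 10%
relative-error check sits at ≥ 2 standard errors rather than inside
sampling noise.

# The tile renderer

`renderImage()` is a stylised blob renderer, not a histology simulator:
nuclei are soft-edged ellipses centred exactly on the annotation
coordinate, brown-dominant for Ki67-positive classes and blue-dominant for
negative ones, with tumour nuclei drawn from a larger and more eccentric
radius range (7–11 px vs 4–7 px) on a pale, lightly noised background. It
exists to exercise image I/O and give the patch classifier a learnable
signal whose generative truth is known. It reproduces none of the texture,
chromatin structure, stain variation or artefacts of real IHC, so
classifier results on rendered tiles are statements about the training
mechanics, not about real-world performance.

# Frozen features versus end-to-end training

The package reproduces the *mechanism* of comparing transfer learning
against training from scratch on a practice-sized dataset (~15 tiles,
a few hundred dot-centred patches): real pretrained backbones and real
competition data are out of scope, so the comparison is a mechanism study;
what is reproducible is the design contrast, not any particular score.

* `frozen_features`: a seed-fixed random convolutional feature map over
  the **luminance** channel (6 filters of 5 × 5, ReLU, 2 × 2 average
  pooling), with only a multinomial logistic head trained on top
  (`nnet::multinom`). Freezing is verifiable — the report carries a
  checksum of the filter bank before and after training. The extractor is
  deliberately colour-blind: the defining weakness of a frozen backbone
  trained for another domain is that its features are not adapted to the
  discriminative signal of the target task, which here is stain
  colourimetry. Random RGB convolutions would pass colour straight
  through and make the "transfer" arm nearly as strong as end-to-end
  training, erasing the contrast under study. A `featureFun` hook accepts
  genuinely pretrained extractors.
* `end_to_end`: a single-hidden-layer softmax network (`nnet::nnet`,
  12 hidden units) on raw pixels downsampled to 12 × 12 × 3, every
  parameter trained from seed-fixed random initialisation. A
  hand-written convolutional network with backpropagation was rejected:
  the established small-network fitter preserves the frozen-vs-trained
  contrast exactly while keeping training on one CPU to seconds.

Patches (default side 32 px) are cut centred on each dot with reflective
border padding; the train/holdout split holds out whole tiles so that test
patches never share a tile with training ones, and dihedral augmentation
(the 8 symmetries of the square — flips and 90° rotations) is available
for the training split. `compareStrategies()` trains both arms over paired
seeds (identical splits within a pair) and summarises per-class and macro
F1, computed through the same count-based derivation as the spatial
metrics. On the rendered fixture the end-to-end arm wins, the direction such
comparisons show when frozen features are mismatched to the target
domain.

# Problem sizes and determinism

Test and acceptance studies use sizes chosen to keep the full suite
comfortably reproducible on a single CPU while leaving the statistical
checks well-powered: 500 random solver/oracle instances of up to 6 + 6
dots; 10,000-cell class-mix checks; 5,000-cell recovery studies
(250 tiles × 20 cells) over 5 profiles × 3 seeds; an 8-annotator cohort
on 500 cells for the per-class F1 ordering; and 5 paired seeds for the
strategy comparison on a ~200-patch dataset. Every stochastic step takes
an explicit integer seed, and multi-step commands derive child seeds from
one root seed, so identical invocations produce identical files
(byte-identical CSV and PNG).

# Known limitations

* Uniform spatial layouts and the blob renderer do not emulate real tissue;
  conclusions about real annotator or model performance require real data.
* Recovery assumes the submission was generated by the package's own
  annotator model; human error structure (systematic border effects,
  fatigue drift, correlated misses in crowded regions) is richer.
* The confusion-row and σ estimators ignore the second-order
  contamination from absorbed spurious pairs.
* One-to-one matching is a design decision; a live scorer using
  many-to-one matching would score duplicate clicks more leniently.
* The classifier stage is a mechanism study on synthetic patches; it makes
  no claim about AlexNet/VGG16-scale architectures or ImageNet features.
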