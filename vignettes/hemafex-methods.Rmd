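---
title: "Joint autoencoder feature extraction for hematopoietic cancer subtypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint autoencoder feature extraction for hematopoietic cancer subtypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hematopoietic cancers (leukemias, lymphomas, myelomas) are classified into
subtypes by cell lineage rather than anatomical site, and bulk RNA-seq gives a
single FPKM expression profile per patient over tens of thousands of genes.
Two features of such cohorts make subtype classification awkward for standard
methods: dimensionality (far more genes than patients) and severe class
imbalance — a typical five-subtype cohort has class sizes on the order of
550 / 818 / 104 / 113 / 860 (lymphoid leukemia, myeloid leukemia, leukemia
not otherwise specified, mature B-cell leukemia, plasma cell neoplasm).
`hemafex` implements a pipeline for this setting: supervised low-dimensional
feature extraction with a jointly trained deep autoencoder, minority
oversampling, a grid of downstream classifiers, imbalance-aware evaluation,
and Shapley-value biomarker ranking.

## The model

The feature extractor is a fully connected autoencoder whose code layer also
feeds a classifier head, trained on the **sum** of two losses:

$$L(\mathrm{input}, \mathrm{output}) = L_{\mathrm{DAE}} + L_{\mathrm{NN}}$$

* $L_{\mathrm{DAE}}$ is the reconstruction mean squared error between the
  input batch and the decoder output. For the variational variant it
  additionally contains the Gaussian KL regularizer
  $\tfrac12\sum_d(\mu^2 + e^{\log\sigma^2} - 1 - \log\sigma^2)$.
* $L_{\mathrm{NN}}$ is a classification loss on the code: either
  cross-entropy $-\log p_t$ or focal loss $-(1-p_t)^\gamma \log p_t$, whose
  modulating factor $(1-p_t)^\gamma$ down-weights easy samples and thereby
  counters class imbalance.

The grid shorthand follows the loss-column taxonomy: CE and FL are the
classification losses alone, RE is reconstruction alone, TOC = CE + RE,
TOF = FL + RE.

Reference architecture: encoder input → 2000 → 500 → 100 (ReLU throughout,
the last width is the code dimension), decoder 100 → 500 → 2000 → input with
a sigmoid output layer, classifier head 100 → 100 (ReLU) → softmax.
Optimization is Adam at learning rate 1e-4, batch size 128, up to 3000
epochs with early stopping. The whole forward/backward machinery is
implemented in vectorized R on BLAS; its gradients are verified against
central finite differences in the test suite, which is the contract that
matters for a hand-built network.

### Design choices where the design was open

* **Decoder widths.** Only "two hidden layers" is fixed; we mirror the
  encoder (500, 2000). A symmetric autoencoder is the conventional default.
* **Activation placement.** ReLU on all hidden layers; sigmoid on the
  reconstruction output (inputs are scaled to [0, 1], so the decoder must be
  bounded); softmax on the head so CE/FL act on probabilities.
* **Joint from scratch.** Encoder, decoder and head are trained
  simultaneously on the summed objective — a single objective implies joint
  training; no autoencoder pre-training phase.
* **Focal $\gamma$.** Default 2.0, the standard value in the focal-loss
  literature; exposed in `loss_config()`.  No class-weighting $\alpha$ term.
* **Early stopping.** Patience 50 epochs on validation total loss, minimum
  delta 1e-6, best-weights restore, 10% validation carve-out. The carve-out
  is stratified by class when a classification loss is enabled; with
  reconstruction-only loss it is a simple random carve-out, so that
  label-free training provably never reads the labels (a property the test
  suite checks by scrambling labels).
* **VAE details.** Reparameterized sampling during training only; the
  posterior mean is the deterministic feature at extraction time; the KL
  term carries unit weight and is bundled with the reconstruction component.
* **Numerical guards.** Probabilities are clipped at 1e-12 before logs; the
  $(1-p_t)^{\gamma-1}$ factor in the focal gradient is likewise clipped so
  $\gamma < 1$ stays finite; a non-finite loss aborts training with the
  epoch and component named.
* **Determinism.** Every stochastic element (initialization, shuffling,
  carve-out, reparameterization noise, SMOTE, classifier backends) is driven
  by explicit seeds; the same configuration and seed reproduce results
  bit-identically, including through a model checkpoint round trip.

## Preprocessing

FPKM values are transformed by $\log_2(x+1)$ followed by per-gene min–max
scaling to [0, 1], with statistics fit on the training split only and reused
for test data (`preprocess_for_ae()`). Bounded inputs are required by the
sigmoid decoder; the log stabilizes the heavy-tailed FPKM scale. Values of
new data outside the training range are clipped to [0, 1], the bounded
completion of the transform. Genes constant on the training data map to
zero. Samples with missing or negative entries are dropped at read time
(`read_expression()`), never imputed.

The stratified 80/20 split takes $\lfloor 0.8\, n_c \rfloor$ training
samples per class — the rounding that reproduces the reference cohort's
train/test table exactly (e.g. 104 → 83/21, 113 → 90/23).

## SMOTE

`smote_oversample()` brings every class up to the majority count by
interpolating $x + u\,(x_{nn} - x)$, $u \sim U(0,1)$, toward one of the
$k=5$ nearest same-class neighbors. It is applied to the **extracted
training features only**: resampling happens between feature extraction and
classification, and touching test data would leak. Raw-space application
remains possible by passing the raw matrix. Originals pass through
unchanged; a singleton class is an error rather than a silent degenerate
interpolation.

## Evaluation

All metrics derive from the one-vs-rest reduction of the multi-class
confusion matrix: precision, recall (sensitivity), specificity, F1,
G-mean $\sqrt{\mathrm{Rec}\cdot\mathrm{Spe}}$, and the index of balanced
accuracy $\{1+\alpha(\mathrm{Rec}-\mathrm{Spe})\}\cdot \mathrm{GM}$ with
$\alpha = 0.1$. Two deliberate choices:

* Recall is $TP/(TP+FN)$ — sensitivity. (Printed formulations of this
  metric sometimes garble it as $TN/(TN+FN)$; the text definition
  "recall = sensitivity" is authoritative.)
* The IBA uses GM as its base, matching the form printed alongside the
  metric suite we mirror; `iba_squared = TRUE` switches to the
  GM² form of the original IBA literature.

Reported summary values are the **unweighted macro averages** over classes
(accuracy remains global). Micro or weighted averaging cannot be ruled out
for every published table of this kind, so per-class values are always
reported alongside. Zero-denominator ratios are reported as 0 and flagged so
macro averages stay defined. Average precision is the step-wise integral
$\sum_i (R_i - R_{i-1}) P_i$ over distinct score thresholds.

## Shapley attribution

`shapley_attribution()` is a model-agnostic Monte-Carlo permutation
estimator: for each sampled feature ordering, features switch one at a time
from a random background row to the explained sample, and the marginal
output change is credited to the switched feature. The estimator is unbiased
for the exact Shapley value, and each per-sample estimate satisfies the
efficiency axiom exactly against the sampled background mean (a telescoping
identity the tests assert to 1e-10). The explained quantity is the
predicted-class probability of the end-to-end encoder + head in **gene
space**, since biomarkers are genes; explaining a feature-space classifier
works the same way by passing its predictor. The default background is a
stratified subsample of training data. Ranking is by mean absolute
attribution, ties broken lexicographically by gene ID.

## The synthetic data generator

`generate_synthetic()` emulates the statistical structure the method
assumes: non-negative FPKM-scale values, heavy right tail, many
uninformative genes, a small block of class-discriminative genes, and
imbalanced classes. Log-expression is Normal(`base_log_mean` = 1,
`noise_sd` = 1), exponentiated; each class's `n_signal_genes_per_class`
(default 10) designated genes get an additive log-mean shift of
`signal_effect` (default 2). Default class sizes are the reference cohort's
550/818/104/113/860. A log-normal with additive log-shifts is the simplest
generator with the right support and a single tunable separability knob.

What it does **not** emulate: gene–gene correlation, library-size and
batch effects, dropout, multi-modal subtype substructure, and the realistic
ratio of 60k genes to 2.5k samples. Passing tests therefore demonstrate
correctness of the machinery and recoverability of planted structure — not
expected performance on real TCGA-scale data, whose headline accuracies
depend on the unreleased cohort assembly.

## Problem sizes used in the shipped tests

The validation suite runs a scaled-down study chosen to exercise every
moving part at desk scale: 5 classes of 110/164/21/23/172 samples, 500 genes
with 10 planted signal genes per class at effect 3, encoder 500/100/32,
TOC loss, at most 300 epochs, SMOTE, and an RBF SVM. Under these conditions
the pipeline reaches macro F1 ≥ 0.90 on the held-out 20% and ranks planted
signal genes at the top of the biomarker list; the grid test runs one
classifier's full 24-cell grid (PCA, NMF, AE × 5 losses, VAE × 5 losses,
× 2 samplings) at a smaller size still. `scripts/acceptance.R` re-runs the
flagship cell from scratch and writes the measured metrics as JSON.

## Known limitations

* No GPU path and no minibatch parallelism; training the reference
  2000/500/100 architecture on tens of thousands of genes is feasible but
  slow in pure R.
* NMF uses multiplicative updates with a fixed iteration budget; it is a
  baseline, not an optimized factorization.
* KNN class scores are neighbor-vote fractions; with small k the PR curves
  for KNN are coarse.
* The permutation Shapley estimator costs one model evaluation per feature
  per permutation; for very wide matrices use modest permutation counts or
  explain a feature-space classifier instead.
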