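---
title: "Methods: generative models for perturbation signatures"
author: "perturbDGM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generative models for perturbation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the numerical choices, and the design
decisions behind `perturbDGM`, and states what the bundled synthetic data
can and cannot show about real perturbation compendia.

## Data model

The central container, `PerturbationExperiment`, extends
`SummarizedExperiment`: a `zscore` assay with genes in rows and samples in
columns, and per-sample metadata (`perturbagen_id`, `pert_type`,
`cell_line`, optional `pcl_label` and `target_gene`). Profiles are moderated
z-scores; values are expected within a fixed range (default [-10, 10]) and
construction fails on out-of-range values unless `permissive = TRUE`, so a
mis-scaled input is caught at the door. GCT #1.2 and delimited tables are
supported; because GCT 1.2 carries no sample annotations, metadata travel in
a sidecar table keyed by `sample_id`.

Dataset assembly follows fixed filtering rules. A cell line is *major* when
it contributes strictly more than `majorCellLineMin` samples of the relevant
perturbation type (the strict reading of "over N samples"); a class is
*major* when at least `majorPclMin` samples carry it (inclusive reading of
"at least N"). Merged small-molecule/knockdown datasets exclude named
outlier perturbagens (defaults: the proteasome inhibitors bortezomib and
MG-132, which form an outlier cloud in principal-component space). Major
cell lines are always determined on the per-type subsets *before*
perturbagen exclusion, which makes exclusion and cell-line filtering
commute — a property the test suite checks. Vehicle controls are dropped by
the type filter; `keepControls = TRUE` retains them, since it is genuinely
open whether controls belong in a generative training set (we default to
excluding them: the models target perturbation responses).

## The VAE

Architecture: tanh hidden layers (`layerSizes`, last entry = top hidden
layer = latent dimension), affine heads for the posterior mean and
log-variance, a mirrored decoder, and a final `outputScale * tanh(.)`
output so reconstructions always lie inside the z-score range. The tanh
choice preserves sign information (up- vs down-regulation); the Gaussian
heads are deliberately *not* tanh-squashed, because the latent must be
unbounded to match the N(0, I) prior — we read "tanh on all hidden layers"
as applying to the hidden stacks only. The encoder emits log-variance and
exponentiates, which guarantees positive posterior variances; log-variances
are clamped to [-15, 15] purely as an overflow guard (the clamp is never
active in a healthy fit).

The loss is elementwise mean-squared reconstruction error plus the
closed-form diagonal-Gaussian KL divergence, summed over latent dimensions
and averaged over the batch. The KL is never estimated by sampling; a test
checks the closed form against a 10^5-draw Monte-Carlo estimate. Training
uses Adam (moment decay 0.9/0.999) over shuffled minibatches, with a seeded
random 90/10 train/validation split (unstratified — nothing suggests the
original splits were stratified). All forward/backward passes are
hand-derived base-R matrix code; gradient correctness is enforced by
finite-difference tests rather than trusted.

Defaults are desk-scale (hidden 64-64-16, 100 epochs, batch 64, learning
rate 1e-3); `vaeConfig(preset = "paper")` switches to the full-scale L1000
setting (978-1000-1000-100, 300 epochs, batch 512).

Downstream representation extraction uses the deterministic posterior mean
at the top layer, not a sampled z: reproducibility matters more than
stochastic faithfulness for representation analyses (sampling remains
available through `sampleLatent()`). Decoder-layer representations are the
post-activation hidden values obtained by decoding mu(x).

## The S-VQ-VAE

The supervised vector-quantized VAE adds a label-indexed codebook
E (one row per class). Training replaces the encoding with the *own-class*
code e_y (a label lookup, not a nearest-neighbour lookup — a regression
test guards this distinction); testing replaces it with the Euclidean
nearest code, ties broken by lowest index. The objective combines
reconstruction, the VQ dictionary loss, a beta-weighted commitment loss,
and two subtracted terms gated by I(k != y) that push encodings and the
nearest wrong-class code apart; gamma scales only the commitment-like part
of the subtracted group, exactly as the objective is written (the
subtracted dictionary part is unscaled). The quantization step has no
gradient; the reconstruction gradient at the decoder input is copied
verbatim onto z_e (straight-through estimator). Stop-gradients are placed
exactly as written: the codebook receives gradient only from the dictionary
and mis-class dictionary terms, the encoder from the straight-through copy
plus the commitment and divergence terms, the decoder only from
reconstruction. Finite-difference tests pin each of these routes.

Codebook initialisation is small uniform random values by default, with a
`"classmean"` option that starts each code at the class mean of the initial
encodings. The validation split is stratified by class so every code is
evaluated. The per-class variance used for class-conditional generation is
the diagonal sample variance of the final training encodings of that class
("estimated from the training data" pins no particular estimator; the
diagonal choice scales to large embedding dimensions).

Two empirical lessons from the recovery experiments, both visible in the
test suite:

* With random codebook initialisation the codes and encodings can settle
  into an entangled geometry where nearest-code accuracy plateaus;
  class-mean initialisation removes this failure mode, so the recovery
  experiments use it.
* Because reconstruction is always computed from e_y, nothing in the
  default objective limits the *within-class spread* of encodings except
  the commitment term. At beta = 0.25 the encoding clusters are wide and
  anisotropic, which leaves nearest-code classification intact but makes
  ancestral sampling z ~ N(e_y, sigma^2) decode off-manifold. The stated
  robustness of the model over beta, gamma in [0, 1] holds for
  classification; for generation experiments we use beta = 1 (still inside
  that range), which tightens encodings around their codes and makes
  class-conditional generation land near real same-class samples. Package
  defaults remain beta = 0.25, gamma = 0.1.

## Signature nodes

Top-layer units split into a small high-activation group and a large
near-zero group (the KL term shrinks any dimension not driven by data).
`findSignatureNodes()` computes each node's mean absolute activation and
splits nodes by 1-dimensional 2-means implemented as an exact search over
sorted split points — deterministic and free of local optima, unlike
restarted Lloyd iterations. Mean |activation| is the clustering statistic;
per-node variance is attached for reporting, since high mean and high
variance coincide in practice. If the two group means differ by less than a
factor of 2 the split is flagged as degenerate (warning) but still
returned. The signature count is data-driven, not hard-coded: how many
nodes stay active depends on data complexity relative to the bottleneck.

Per-class signature patterns are means over the class's samples at the
signature nodes; pattern-conditioned generation fixes signature positions
to the pattern and draws the remaining positions from N(0, 1), then
decodes. Generated profiles are evaluated by exhaustive Euclidean
nearest-real-neighbour search with per-class composition summaries. On the
synthetic benchmark most classes place well over half of their generated
samples next to real same-class profiles; classes whose patterns nearly
coincide absorb each other's samples, which mirrors what happens to
mechanistically adjacent drug classes on real data. Replacing pattern
values by sign(pattern) times a constant preserves class assignment only up
to the resolution of the sign patterns — with few signature nodes, 2^nodes
can be smaller than the number of classes, so the sign-only probe is judged
against the set of classes sharing a sign pattern.

## Evaluation machinery

*Mixing score.* For two categories spread over k clusters,
MS_k = sum_i max(p_i, q_i) / N, in [0.5, 1]. The implementation is compared
against brute-force majority counting on hundreds of random instances. The
real-vs-generated protocol hierarchically clusters the union of generated
and real samples with distance 1 - Pearson correlation, average linkage
(the linkage is not pinned by the protocol's description; average linkage
is the conventional choice with correlation distances and is recorded in
the output), cuts at k clusters and repeats with fresh draws; the CI is the
2.5/97.5 percentile range over repeats.

*PCL graph.* Each class row is connected from its maximally correlated
partner (edge direction source -> target = "source is nearest to target"),
weight = correlation. Louvain community detection runs on the undirected
collapse of the graph (parallel edges merged, stronger weight kept) with
weights shifted to be positive, resolution 1 and a fixed seed; a restart
count allows best-of-several-modularity runs. Modularity is verified
against the standard formula in a test.

*Classification harness.* Stratified 10-fold cross-validation of
multinomial logistic regression (`nnet::multinom`) and a linear-kernel SVM
(`e1071::svm`) per representation type, reporting mean fold accuracy and
Cohen's kappa from pooled out-of-fold predictions, plus the random-guess
baseline sum_c (n_c/N)^2 for uneven class distributions.

*Drug-target retrieval.* Pearson correlations between each drug-treated
sample's representation and every knockdown sample's representation; a
gene's score is its best-correlated knockdown sample (so a gene is judged
by its closest signature), genes are ranked by decreasing score with ties
broken lexically by symbol for determinism; per drug, the best and mean
over samples of the top known target's rank are reported, plus recall@n and
hit@n aggregates. Mean rank averages over samples (not drug/cell-line
combinations). Raw latent vectors enter the correlation unstandardised —
Pearson is location/scale invariant, so standardisation would be a no-op.

## Synthetic data

The generator plants: a random linear decoder W (genes x latent), one
latent centroid per class (sd `centroidScale` = 2), within-class latent
scatter and gene-level noise (both sd `noiseSd` = 0.3), and an affine tanh
squash into the z-score range (divisor `squashScale` = 3), so values
approach but never pile up at the boundaries — mimicking the moderated
z-score range without boundary atoms. A single noise knob means `noiseSd =
0` yields exactly repeated within-class profiles and perfectly correlated
drug/knockdown twins, which the tests exploit as closed-form cases. Twin
knockdown classes (for the retrieval benchmark) share the drug centroid up
to a shift of sd `noiseSd`/2; unlinked knockdown classes act as
distractors. Class priors are uniform by default with a `"skewed"` option
(sizes proportional to 1/rank) to mimic unevenly distributed classes.
`simulateDataset()` emits the drug classes; the twin machinery lives in
`simulateDrugTargetBenchmark()`.

Defaults — 100 genes, 10 true latent dimensions, 8 classes, 50 (or 250)
samples per class — are desk-scale stand-ins for compendium-scale data.
The generator emulates the *shape* of the data (range, low-dimensional
class structure, drug/knockdown correspondence) but not L1000 specifics:
no gene-gene correlation beyond the planted low-rank structure, no
cell-line heterogeneity, no batch effects, no heavy-tailed noise. Passing
tests therefore demonstrate algorithmic correctness and recoverability
under the planted model, not performance on LINCS-scale data.

## Problem sizes and reproducibility

The recovery experiments use 2,000 samples / 200 epochs for the VAE and
400 samples / 800 epochs for the S-VQ-VAE — sizes at which every experiment
in the test suite and the acceptance script completes in about a minute
each on a single CPU while leaving comfortable statistical margins. Every
stochastic step (initialisation, splits, minibatch order, sampling,
Louvain) is governed by explicit integer seeds; reruns with the same root
seed are bit-identical, including through the command-line interface.

## Known limitations

* Pure-R training is fine at desk scale but slow at the full 978-gene,
  10^5-sample scale; the `"paper"` presets are provided for completeness,
  not speed.
* The S-VQ-VAE's generative mode inherits the decoder's narrow training
  support (it only ever decodes the Y code points during training);
  generation quality is sensitive to the commitment strength, as discussed
  above.
* GCTX/HDF5 binary inputs, probe re-annotation and gene-alias resolution
  are out of scope; genes are matched by exact symbol.
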