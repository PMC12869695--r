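---
title: "Models and methods behind combisyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind combisyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

combisyn is a desk-scale toolkit for drug-combination synergy analysis: it
scores dose-response checkerboards under four reference (null) models of
non-interaction, engineers multimodal features for drugs and cancer samples,
trains an attention-fusion neural classifier of synergy, evaluates it under
leakage-free cross-validation splits, and runs the downstream
patient-stratification and interactome analyses. This vignette explains the
models, their assumptions, the tunable parameters, and the choices made where
the design was genuinely open.

## Synergy scores from dose-response checkerboards

A measurement unit is a `dose_block`: a complete matrix of % inhibition over
two increasing concentration series whose first element is 0, so the first
row and column are the monotherapy margins. All four scores are the **mean
excess of observed over expected inhibition across the interior wells**
(mean, not sum, so scores do not grow with grid size):

* **Bliss** independence expects `yA + yB - yA*yB/100`, treating the drugs as
  independent probabilistic inhibitors. Computed directly from the observed
  margins; exact closed form.
* **HSA** expects the better single agent, `max(yA, yB)`.
* **Loewe** additivity treats doses as interchangeable through the two
  monotherapy curves: the expected response `y*` of the well `(d1, d2)`
  solves `d1/DA(y*) + d2/DB(y*) = 1`, where `DA`, `DB` invert fitted
  four-parameter Hill curves (`e_max` bounded in [0, 120] %, `ec50 > 0`,
  slope in (0.1, 10]). The root is found by bisection on
  `(0, min(e_maxA, e_maxB))` with tolerance 1e-6 and at most 100 iterations;
  wells where the equation has no root in range (combinations beyond both
  plateaus) fall back to the HSA expectation, and an inert partner reduces
  the expectation to the active drug's curve.
* **ZIP**-style delta compares conditional potency shifts: for every
  interior well we fit a conditional Hill curve along its row and its column
  (baseline pinned to the fitted monotherapy of the co-drug) and compare the
  mean conditional fit against the Bliss surface of the fitted monotherapies.
  This is a documented simplification of the full published ZIP formulation
  (flagged `zip_method: conditional` on every record): it keeps the
  delta-vs-fitted-potency idea while reusing the package's single Hill
  fitter.

Hill fits use Levenberg-Marquardt least squares with bounded parameters; a
fit that fails, or whose curve does not positively track the data (e.g.
inverted, decreasing responses), is replaced by a median-interpolation
fallback with `converged = FALSE` rather than an error, so one pathological
margin never aborts a screen-sized batch.

Records are canonicalized (lexicographic drug order; all scores are invariant
under transposing the block), duplicates are collapsed by arithmetic mean,
and the binary label is `score_loewe > 0` — an exact zero is labeled
non-synergistic, reading "threshold at 0" as strict exceedance. Inputs on a
viability scale must be converted (`100 - response`; `--viability` in the
CLI), because the Bliss/HSA formulas above assume inhibition.

## The synthetic world

Because the package must be testable without external screens, a generative
model emulates every input. Genes are partitioned into pathways (default 12
pathways of 20 genes); the PPI is sampled edgewise with probability 0.3
within a pathway and 0.01 across (STRING-like scores in (0,1], higher within
pathways); each of 30 drugs targets 3 genes of one pathway; each of 40
samples carries an independent Bernoulli(0.5) activity state per pathway;
expression is `5 + 2*activity + N(0, 0.5)` on the log2(TPM+1) scale; the
mutation matrix is independent Bernoulli(0.05) noise by default (an optional
sentinel flag copies each pathway's activity into its first gene, making the
mutation modality informative on demand).

**The planted rule**: a triplet (drug a, drug b, sample) is synergistic —
with latent strength 25% inhibition — exactly when the drugs target
*different* pathways that are *both* active in the sample. The signal
depends jointly on both drugs and the sample, so withholding whole drugs at
evaluation time is a genuine generalization test.

Dose-response blocks use a 6x6 design (0 plus five half-log steps,
0.1-10 uM). Monotherapy follows each drug's Hill curve (`E_max` in
[80, 100] %, slope in [1, 2]); the EC50 is divided by 3 when the drug's
pathway is active (active pathway = more potent drug). Combination wells are
the Bliss expectation of the margins plus `truth * k(d1, d2)` plus N(0, 3)
noise, clipped to [0, 100], where the kernel `k` is a product of linear hats
equal to 1 at the central well and 0 on the dose-0 margins. EC50s are drawn
log-uniformly over the **upper** interior of the grid (from 3x the central
dose to the top dose): with draws across the whole grid, both-active pairs
saturate the response ceiling at the central well and the clip would swallow
the planted bump — this placement keeps the identifiability property exact
(with zero noise, thresholding the central-well Bliss excess at half the
bump recovers the planted labels perfectly).

What the generator deliberately does **not** emulate: realistic chemistry
(the deterministic fragment SMILES need only parse and be mutually
distinct — and they are uninformative about the planted rule on purpose, so
the chemical-ablation variant should cost little), tumor heterogeneity
beyond binary pathway activity, correlated mutation processes, or survival
models beyond the exponential. Passing tests therefore demonstrate that the
machinery recovers a known signal under its stated assumptions, not that it
will attain any particular performance on real screens.

### A known limitation: Loewe labels on Bliss-generated nulls

Null blocks are generated *at* the Bliss expectation, but Bliss and Loewe
are different null models: their expected surfaces differ by a few percent
inhibition for ordinary Hill curves. A null block's Loewe excess is
therefore a small random quantity centered near zero, and the strict
`> 0` labeling rule turns roughly half the null blocks into false positives
even though the *score* separates planted from null blocks almost perfectly
(the rank AUROC of the Loewe score against planted truth is ~1). The
per-block recovery rule that is exact by construction is the central-well
Bliss-excess threshold at half the bump; the acceptance script reports the
agreement of both rules side by side. On real screens this manifests as
instability of near-zero labels, which is why duplicate averaging before
binarization matters.

## Features

* **Chemistry** — Morgan (circular-substructure) fingerprints, radius 2,
  hashed to 2,048 bits. SMILES parsing is delegated to ChemmineR/OpenBabel;
  the neighborhood hashing is implemented in the package (no installed R
  package exposes Morgan fingerprints) from order-invariant atom invariants,
  so different notations of one molecule give identical bits. Tanimoto
  similarity is |intersection|/|union| of set bits (1 for two empty
  fingerprints). Drug harmonization merges ids only at similarity exactly
  1.0 — synonyms, not analogs; near matches (>= 0.95) are reported for
  review. Molecular graphs (atoms x features, adjacency) are provided with a
  deliberately minimal aromaticity perception (alternating Kekule rings).
* **Targets** — a binary drug x gene matrix propagated over the PPI by
  random walk with restart, `F <- alpha*F0 + (1-alpha)*F*S` iterated to a
  1e-6 sup-norm tolerance with `S = D^{-1/2} A D^{-1/2}`; restart
  probability alpha defaults to 0.5 (the propagation-vs-restart balance is
  not dictated by theory; 0.5 treats them evenly). Isolated nodes keep their
  restart mass (self-loop convention), so an edgeless network returns the
  input at every alpha. Variants: removing the top-5%-degree hubs before
  normalization, and additionally down-weighting edges by
  `1/sqrt(deg_i*deg_j)`.
* **Samples** — marker genes are the union of a landmark list, the top 15%
  most-variable genes (variance stands in for differential expression, which
  has no defined contrast groups here), the top-1000 hubs of the
  high-confidence PPI (score > 0.7), and the drug-target universe, each gene
  tagged with its provenance. Expression over the markers is compressed by a
  symmetric autoencoder (hidden widths scaled from the classic
  G -> 1024 -> 256 geometry proportionally to the gene count; input dropout
  0.2; Adam step 1e-3; 100 epochs with a 10% held-out split and best-epoch
  selection). Inputs are used on the log2(TPM+1) scale and standardized per
  gene with training-fold statistics only, to keep fold evaluation
  leakage-free. The binary mutation profile admits the five nonsynonymous
  classes (missense, nonsense, frameshift insertion/deletion, splice site).

## The fusion model

Five branch embeddings of a common width d — chemistry of drug a and b
(2-layer MLP on the fingerprint), propagated targets of a and b (1-D
convolution, kernel 8 / stride 4 / 8 channels, flattened through a
500-wide "target embedding" layer), and the sample (the pre-trained
expression encoder plus a projection; fine-tuned by default, freezable) —
enter one scaled dot-product attention layer,
`A = softmax(QX (KX)^T / sqrt(d_k))`, one updated token per input token with
a linear map back to width d. The printed form of this attention is
normalized to the standard scaled dot-product; a `mask_self` flag restricts
attention to the other modalities for users who prefer the strictly
cross-modal reading. The fused tokens are flattened (5d) into a rectifier
MLP head (512, 128, 1) ending in a sigmoid; the output layer is
zero-initialized so an untrained model predicts exactly 0.5.

Training minimizes binary cross-entropy (predictions clipped to
[1e-7, 1-1e-7]) by mini-batch Adam (step 1e-3, batch 64); every triplet is
seen in both drug orders (augmentation), validation AUROC is evaluated each
epoch and the best-validation weights are returned; inference averages both
drug orders, so predictions are exactly symmetric. Probability > 0.5 is
classified synergistic. Variants: a mutation-input model (same architecture,
binary mutation profile into the sample branch), a chemistry-ablated model
(3 tokens), and a mean-probability ensemble. The whole network is base-R
matrix code with hand-derived gradients, checked against finite differences
to 1e-4 relative in the test suite.

Desk-scale geometry: the configuration defaults to d = 256 (the width used
at real-data scale), but all synthetic experiments in the tests and the
acceptance script use d = 32, hidden widths 64-128, 20 epochs, and ~4,000
triplets — sizes chosen so a full cross-validated run completes in minutes
on one CPU while leaving the planted signal comfortably recoverable.

## Evaluation

Three split strategies, each with the structural guarantee asserted on every
plan: **leave-combo-out** partitions canonical drug pairs into five folds
(pairs never span folds); **leave-drug-out** clusters drugs by Tanimoto
distance (agglomerative, average linkage, cut at k) and keeps only triplets
whose two drugs share a cluster — cross-cluster triplets are dropped, the
only choice that keeps the no-shared-drug guarantee exact (a fold whose
cluster yields no within-cluster pairs reports NA and is excluded from
aggregates); **leave-sample-out** clusters samples by affinity propagation
(damping 0.9, preference = median similarity, 1000 iterations, k-medoids
k = 4 fallback) on the top-1000 most-variable genes and trains on the
largest cluster. A random 10% of each nominal training set is carved out
for epoch selection. Metrics are AUROC (normalized Mann-Whitney U, ties
half), AUPRC (step integration), and Spearman correlation of predicted
probability against the continuous synergy score; cross-validation reports
per-fold values and mean +/- sd across folds.

## Downstream analyses

* `predict_matrix()` fills a patients x partner-combinations matrix of
  predicted probabilities (anchor drug + each partner); "effective" means
  probability > 0.5, and partners rank by column mean.
* `stratify_patients()` cuts average-linkage hierarchical clustering of the
  matrix rows (Euclidean distance; the distance/linkage pair is a recorded
  convention) at two groups and labels the higher-grand-mean cluster
  responsive. `logrank_compare()` tests the survival split (two-group
  log-rank via the survival package).
* `fit_lps()` implements the classic linear-predictor-score construction:
  per-gene two-sample Welch t-statistics on a training portion, the 50
  largest |t| as weights, `LPS(x) = sum t_j x_j`, and a two-Gaussian Bayes
  posterior with empirical priors. The posterior cutoff is 0.5 with ties
  broken toward the first group level; a confidence band (classifying only
  beyond 0.9) is available as an option.
* `lcc_permutation_test()` measures the largest connected component induced
  by a gene set in the PPI against `n_perm` uniform same-size node sets,
  with the +1-corrected p-value (never exactly 0); tiny graphs can be
  enumerated exhaustively, and a degree-matched null is offered as an
  option without any claim that it matches the uniform-sampling convention.

## Numerical conventions and degenerate inputs

Every stochastic stage is a pure function of its seed (child seeds are
derived by hashing stream labels, so stages are independently reproducible).
Degenerate inputs prefer informative errors over silent misbehavior:
all-identical drug structures make leave-drug-out advise leave-combo-out;
all-identical samples make leave-sample-out refuse (nothing to hold out);
an all-identical prediction matrix refuses to stratify; one-class labels
refuse training and metrics; groups without events refuse the log-rank test.
Loewe bisection tolerance is 1e-6 with HSA fallback for rootless wells;
propagation caps at 10,000 iterations and reports its residual on failure.
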