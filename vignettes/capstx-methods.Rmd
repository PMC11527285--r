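---
title: "Methods: capsule encoding, attention classification and transfer for expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capsule encoding, attention classification and transfer for expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`capstx` classifies case/control status from log-scale gene-expression
profiles with a two-stage network whose intermediate representation is a set
of vector-valued *capsules*: units whose norm encodes how strongly a learned
gene program is active in a sample and whose direction encodes the program's
state.

**Capsule encoder.** A profile $x \in \mathbb{R}^{n}$ is projected by $P = 8$
linear maps into primary capsules $u_i = W_i x$, $W_i \in
\mathbb{R}^{d_p \times n}$. Prediction vectors $\hat u_{j|i} = w_{ij} u_i$
connect every primary capsule to each of $J = 20$ output capsules of
dimension $d_c = 16$. Dynamic routing-by-agreement then mixes them: with
logits $b_{ij}$ initialized to zero, each of $T = 3$ iterations computes
coupling coefficients $c_{ij} = e^{b_{ij}} / \sum_i e^{b_{ij}}$, sums
$s_j = \sum_i c_{ij} \hat u_{j|i}$, squashes
$v_j = \frac{\lVert s_j\rVert^2}{1 + \lVert s_j\rVert^2}
\frac{s_j}{\lVert s_j\rVert}$ (norm in $[0,1)$, direction preserved), and
updates $b_{ij} \leftarrow b_{ij} + \hat u_{j|i} \cdot v_j$. Coupling
coefficients are recomputed on every forward pass and are not trainable
parameters; the weights $W_i$ and $w_{ij}$ are learned by backpropagation.

**Attention classifier.** The capsule matrix $V'$ (capsules as rows) is
decoded by multi-head scaled dot-product self-attention,
$\mathrm{attention}(Q, K, V) = \mathrm{softmax}(QK^\top/\sqrt{d_k})V$ with
$Q = W_q V'$, $K = W_k V'$, $V = W_v V'$ per head and $d_k = 16$. Head
outputs are concatenated and flattened, then a dense layer of 150 neurons
(sigmoid activation by default) and a logistic output unit produce the case
probability.

**Training.** Binary cross-entropy, Adam (lr $10^{-3}$, $\beta = (0.9,
0.999)$, $\epsilon = 10^{-8}$), mini-batches of 32, up to 50 epochs with
early stopping (patience 5 on validation loss, best weights restored), and a
random 80/10/10 cell-level train/validation/test split. Gradients are
computed by a hand-derived reverse pass that is exact through the unrolled
routing loop, including the softmax dependence of the coupling coefficients
on earlier iterations; tests verify it against central finite differences at
$10^{-4}$ relative tolerance.

**Transfer to bulk cohorts.** The single-cell pretrained model is moved to a
bulk cohort by re-initializing the dense head, training only the head with
all capsule and attention tensors frozen (their change is exactly zero, an
asserted contract), and then fine-tuning the whole network at a smaller
learning rate (defaults: 10 epochs at $10^{-3}$, then 10 at $10^{-4}$; a
stratified 30% of the cohort is used for tuning). The rotated test fine-tunes
on each cohort in turn and evaluates on every other cohort.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_primary` ($P$) | 8 | primary capsules |
| `n_capsules` ($J$) | 20 | output capsules |
| `d_c` | 16 | capsule dimension (also $d_k$) |
| `d_p` | 16 | primary capsule dimension |
| `n_heads` | 4 | attention heads |
| `hidden_units` | 150 | dense-head width |
| `routing_iterations` | 3 | routing passes |
| `activation` | sigmoid | dense-head activation (relu/tanh available) |
| `batch_size` / `epochs` | 32 / 50 | optimization schedule |

$d_p$ and `n_heads` are not pinned by the reference architecture; the
defaults ($d_p = d_c = 16$, 4 heads) keep tensor shapes uniform and can be
swept with `crossvalidate()`, which reproduces the hyperparameter protocol
(5-fold stratified CV over capsule count, neuron count, routing iterations
and activation) at synthetic scale.

## Design choices where the architecture is open

* **Routing softmax axis.** The printed coupling definition normalizes over
  the *input* capsules ($\sum_i c_{ij} = 1$), whereas the original
  routing-by-agreement convention normalizes over outputs. The default
  follows the printed form (`softmax_axis = "input_capsules"`) and the
  alternative is a configuration switch.
* **Head layout.** "A dense layer with 150 neurons and a sigmoid" is read as
  a 150-unit hidden layer plus a separate logistic output unit.
* **Full-width heads.** Each head projects $d_c \to d_c$ rather than
  splitting $d_c$ across heads, matching the printed $Q = W_q V'$ form.
* **No biases** in $W_i$, $w_{ij}$ or the attention projections: the maps
  are written as pure linear transforms.
* **Zero-vector squash.** The squash is undefined at $s = 0$; the norm
  denominator is guarded with $\max(\lVert s\rVert, 10^{-8})$, which leaves
  all non-degenerate values exact and maps zero to zero.
* **Probability clamps.** Loss probabilities are clamped at $10^{-7}$ (the
  loss diverges at 0/1) and emitted probabilities at $10^{-12}$, so the
  "strictly inside $(0,1)$" contract survives saturating logits in floating
  point.
* **Filtering order.** Samples recording under 20% of genes are removed
  first (against the full gene set), then genes recorded in under 20% of the
  retained samples. One caveat: with adversarial sparsity a second
  application can remove further samples, because the surviving gene set has
  changed; the operation is idempotent in the generic case but not
  universally.
* **Split rounding.** Validation and test sizes are floored; the remainder
  goes to training. Gene order after `intersect_genes()` is lexicographic
  (C locale); checkpoints carry their gene list, so order is
  self-describing.
* **Interpretation scores.** Occlusion sets one gene to a baseline (log-scale
  zero by default, optionally the reference mean) and records the mean change
  of each capsule norm, so a positive score means the gene activates the
  capsule; single-gene enumeration covers all genes. Primary-capsule gene
  weights aggregate the columns of $W_i$ by L2 norm by default (the reduction
  behind one-number-per-gene heatmaps is not pinned; `signed_mean` and
  `mean_abs` are available), and the important-gene threshold is strict:
  $|w| > 0.06$.

## The synthetic test bed

`synthetic_spec()` plants known structure so that every stage of the
pipeline can be validated without any external download: 600 genes, 3 cell
types, six disjoint 30-gene modules — three cell-type markers (shift +1.5 in
their type) and three disease modules (shift $\delta = 1$ in case subjects,
affecting all types / type 1 / types 2–3) — over a log-scale Gaussian
baseline $\mathcal{N}(1, 0.5)$ clipped at zero, with 40 case and 40 control
subjects contributing 50 cells each and 30% dropout in single-cell output.

Two features keep the planted task in the performance regime reported for
real sepsis cohorts (AUROC ≈ 0.93–0.99) instead of a saturated toy:

* a per-subject latent severity factor ($\mathcal{N}(0, 0.35)$, shared
  across disease modules, present in cases and controls) — between-subject
  heterogeneity of inflammation state, which bounds attainable AUROC away
  from 1;
* bulk cohorts draw each subject's cell-type composition from a symmetric
  Dirichlet ($\alpha = 2$) and apply a cohort-specific platform map
  $a_g x + b_g + \varepsilon$ with per-gene lognormal scales and Gaussian
  offsets, modelling probe-level heterogeneity between platforms, plus
  measurement noise. Bulk profiles average each subject's pre-dropout cells
  (dropout is a single-cell measurement artifact).

What the generator does **not** emulate: count-level sampling noise
(negative binomial / UMI models), library-size variation, doublets, batch
chemistry effects, correlated module overlap, or nonlinear probe response.
Passing tests therefore show that the implementation learns, transfers and
attributes correctly under a clean planted-factor model — not that the
architecture outperforms alternatives on real data.

A consequence worth stating explicitly: because AUROC is invariant to
cohort-constant monotone transformations, the gene-wise affine platform maps
above barely disturb the *ranking* a pretrained model induces within a
cohort, even though they wreck its calibration. In this test bed zero-shot
transfer therefore already ranks near the attainable ceiling, and two-phase
fine-tuning restores calibration and matches — but cannot appreciably
exceed — zero-shot AUROC. The transfer tests assert the freeze contract, the
rotated design and non-inferiority of fine-tuning; a large fine-tuning AUROC
*gain* should not be expected from monotone platform shifts combined with a
low-rank disease signal.

## Evaluation

AUROC is computed from average ranks (the Mann–Whitney statistic, ties
half-weighted), which equals trapezoidal integration of the all-thresholds
ROC; positives are predicted at score $\ge$ threshold. AUPRC uses step-wise
interpolation (average precision) rather than linear interpolation between
PR points, which would over-estimate the area. Enrichment of capsule gene
sets uses the upper-tail hypergeometric test with Benjamini–Hochberg
correction across the collection.

## Problem sizes used by the tests and the acceptance script

Pretraining runs use the default 4,000-cell study with 15 epochs for the
headline model and 4–5 epochs for multi-seed replicates and null controls;
transfer runs fine-tune on stratified 30% splits of 80-subject cohorts;
attribution uses 40 reference cells with full 600-gene enumeration. These
sizes are the package's chosen desk-scale operating point for a complete
train–transfer–interpret cycle.

## Known limitations

* The exact early-stopping rule, Adam hyperparameters, weight
  initialization, $d_p$ and the number of attention heads of the reference
  setup are unreported; the defaults documented above are conventional
  choices, not assertions about the original training runs.
* Splits are by cell, not subject, by default (matching the reference
  protocol); `subject_id` is carried through the containers so a
  subject-aware splitter can be applied externally by filtering samples.
* Reproducing the reference count of 2,869 intersected genes requires the
  external cohort accessions and is out of scope; `intersect_genes()`
  implements the operation generically.
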