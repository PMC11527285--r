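# capstx

Capsule-network encoding with a self-attention classifier for
expression-based case/control prediction, with single-cell → bulk transfer
learning and capsule-level interpretability.

## The problem

Classifiers trained on single-cell RNA-seq of patient blood can separate
disease from control cells, but two things usually get in the way of using
them: clinical data arrives as *bulk* profiles (RNA-seq or microarray, on a
different measurement scale), and black-box scores give no handle on *which
gene programs* drive a prediction. `capstx` addresses both with one
architecture:

* a **capsule encoder** groups genes into vector-valued capsules by dynamic
  routing-by-agreement — the norm of capsule *j* measures how active its
  learned gene program is in a sample;
* a **multi-head self-attention classifier** reads the capsule set and
  outputs a case probability;
* a **transfer protocol** (head re-initialization → frozen-body head
  training → full fine-tuning) carries a single-cell pretrained model onto
  bulk cohorts, with a rotated cross-cohort test;
* an **interpretability suite** extracts per-gene capsule weights,
  occlusion-based capsule attributions, hypergeometric gene-set enrichment
  and a capsule–pathway network.

## The model

With expression vector $x \in \mathbb{R}^n$:

```
u_i   = W_i x                          i = 1..8 primary capsules
û_j|i = w_ij u_i                       prediction vectors
c_ij  = exp(b_ij) / Σ_i exp(b_ij)      coupling (b starts at 0)
s_j   = Σ_i c_ij û_j|i
v_j   = (‖s_j‖² / (1+‖s_j‖²)) s_j/‖s_j‖     squash, 3 routing iterations
                                            b_ij ← b_ij + û_j|i · v_j
Z_h   = softmax(Q K'/√d_k) V           per attention head, Q = W_q V' etc.
p     = σ( w₂' · act(W₁ [Z_1 … Z_H] + b₁) + b₂ )
```

Defaults: 8 primary capsules, 20 output capsules of 16 dimensions, 3
routing iterations, d_k = 16, 4 heads, a 150-neuron sigmoid dense layer,
binary cross-entropy with Adam (batch 32, up to 50 epochs, early stopping).
Gradients are computed by an exact hand-derived backward pass through the
unrolled routing loop (verified against finite differences in the tests).

## Worked example

Everything below runs on synthetic data with planted gene modules (no
downloads). The generator plants cell-type marker modules and disease
modules whose activity shifts in case subjects; the model must find them.

```r
library(capstx)

spec <- synthetic_spec(n_genes = 200, module_size = 15,
                       n_subjects_case = 12, n_subjects_control = 12,
                       cells_per_subject = 25, seed = 42)
sc <- generate_single_cell(spec)
sc$dataset
#> <labelled_dataset> 200 genes x 600 samples (300 case / 300 control)

splits <- split_cells(sc$dataset, c(0.8, 0.1, 0.1), seed = 42)
model <- train_capsnet(splits$train, splits$val,
                       train_config(epochs = 15, seed = 42))
model
#> <caps_model> 200 genes -> 8 primary capsules (d_p=16) -> 20 capsules (d_c=16)
#>   -> 4-head attention -> dense(150) -> sigmoid
#>   trained 9 epochs; final val loss 0.6289

p <- predict(model, splits$test$matrix)
round(auroc(p, splits$test$labels), 3)
#> [1] 0.866
round(auprc(p, splits$test$labels), 3)
#> [1] 0.905
```

The held-out AUROC of 0.87 is against a synthetic cohort with deliberate
between-subject severity heterogeneity, so chance is 0.5 and perfect
separation is unattainable. Now ask *which genes* drive the most active
capsule, by occluding one gene at a time and measuring the change in each
capsule's norm:

```r
scores <- capsule_activation_test(model, splits$test$matrix)
j <- which.max(colSums(abs(scores)))
top15 <- rownames(scores)[order(abs(scores[, j]), decreasing = TRUE)][1:15]
enr <- hypergeometric_enrichment(top15, module_collection(spec), model$gene_ids)
head(enr[, c("set_name", "overlap", "set_size", "p_value", "adjusted_p")], 3)
#>       set_name overlap set_size     p_value  adjusted_p
#> 4    disease_1       6       15 0.000209826 0.001258956
#> 6    disease_3       4       15 0.017280920 0.051842759
#> 1 marker_type1       1       15 0.703070448 0.843684538
```

The capsule's top genes are significantly enriched (BH-adjusted p = 0.0013)
for the planted disease module — the capsule recovered a gene program that
was never labelled, only implied by the classification task.

Transfer to bulk cohorts works the same way: `generate_bulk()` produces
platform-shifted cohorts, `reinit_head()` + `fine_tune()` apply the
two-phase protocol, and `rotated_test()` fills the tune-on-A/test-on-B
matrix.

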