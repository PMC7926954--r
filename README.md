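# hemafex

Joint autoencoder feature extraction and imbalance-aware classification of
hematopoietic cancer subtypes from bulk RNA-seq FPKM expression matrices.

## The problem

Hematopoietic cancer cohorts pair very high-dimensional expression profiles
(tens of thousands of genes per patient, FPKM scale) with severely
imbalanced subtype labels — e.g. five subtypes of sizes 550 / 818 / 104 /
113 / 860 (lymphoid leukemia, myeloid leukemia, leukemia NOS, mature B-cell
leukemia, plasma cell neoplasm). Ordinary classifiers overfit the gene
space and ignore the minority subtypes. `hemafex` addresses both ends:

* **Feature extraction.** A deep autoencoder whose low-dimensional code
  also feeds a classifier head, trained on the *sum* of a reconstruction
  loss and a classification loss,

  L(input, output) = L_DAE + L_NN,

  where L_DAE is the reconstruction MSE (plus the Gaussian KL term for the
  variational variant) and L_NN is cross-entropy (CE), −log p_t, or focal
  loss (FL), −(1 − p_t)^γ log p_t, whose modulating factor down-weights easy
  samples to counter class imbalance. Grid shorthand: RE (reconstruction
  only), CE, FL, TOC = CE + RE, TOF = FL + RE. PCA and NMF are provided as
  baseline extractors.
* **Imbalance handling.** SMOTE oversampling of the extracted training
  features to a uniform class histogram, plus the focal loss above.
* **Evaluation.** One-vs-rest confusion-matrix metrics: precision, recall,
  specificity, F1, G-mean = sqrt(Rec·Spe), and the index of balanced
  accuracy IBA = {1 + α(Rec − Spe)}·GM (α = 0.1), with macro averages,
  PR curves, and a five-classifier comparison grid (LR, RF, KNN, ANN, SVM).
* **Interpretation.** A sampling-based Shapley-value estimator attributes
  the trained model's predicted-class probability to individual genes and
  ranks top-k biomarkers.
* **Synthetic data.** A seeded generator of FPKM-like matrices with planted
  class-discriminative genes, so the whole pipeline is testable end to end.

The neural network (forward, backprop, Adam) is implemented in vectorized R
on BLAS and verified against finite-difference gradients in the test suite.

## Worked example

```r
library(hemafex)

spec <- synthetic_spec(class_sizes = c(110, 164, 21, 23, 172), n_genes = 300,
                       n_signal_genes_per_class = 10, signal_effect = 1.5,
                       noise_sd = 1, seed = 42)
ds <- generate_synthetic(spec)
split <- stratified_split(ds, train_fraction = 0.8, seed = 1)
prep <- preprocess_for_ae(split$train)                     # log2 + min-max, fit on train
test <- preprocess_for_ae(split$test, scaler = prep$scaler)

arch <- architecture_config(input_dim = n_genes(ds), n_classes = 5,
                            encoder_dims = c(256, 64, 32),
                            decoder_dims = c(64, 256), head_hidden_dim = 32)
model <- build_model(arch, loss_config("FL", use_reconstruction = TRUE), seed = 1)  # TOF
fit <- train_joint(model, prep$dataset,
                   train_config(max_epochs = 200, learning_rate = 1e-3,
                                early_stopping_patience = 30, seed = 1))

f_train <- extract_features(fit$model, prep$dataset)       # 32-d codes
f_test  <- extract_features(fit$model, test$dataset)
bal <- smote_oversample(f_train, label_factor(split$train), k_neighbors = 5, seed = 1)
pred <- fit_predict(classifier_spec("SVM", seed = 1), bal$features, bal$labels, f_test)
report <- compute_metrics(confusion(label_factor(split$test), pred$labels))
print(report)
```

```
accuracy: 0.9700
macro:   precision=0.9795  recall=0.9482  specificity=0.9914  f1=0.9616  gmean=0.9687  iba=0.9648
  class precision recall specificity     f1  gmean    iba flagged
1    LL    0.9565 1.0000      0.9872 0.9778 0.9936 0.9948   FALSE
2    ML    0.9697 0.9697      0.9851 0.9697 0.9774 0.9759   FALSE
3    NO    1.0000 0.8000      1.0000 0.8889 0.8944 0.8765   FALSE
4    MB    1.0000 1.0000      1.0000 1.0000 1.0000 1.0000   FALSE
5    PC    0.9714 0.9714      0.9846 0.9714 0.9780 0.9767   FALSE
```

97% of held-out samples are classified correctly; the macro rows show the
minority class (NO, 5 test samples) is the hard one — exactly what the
imbalance-aware metrics are there to surface. Biomarker ranking of the
trained model in gene space:

```r
bg <- prep$dataset$matrix[unlist(lapply(1:5, function(c)
        head(which(split$train$labels == c), 8))), ]
sh <- shapley_attribution(function(x) predict_proba(fit$model, x),
                          bg, test$dataset$matrix[seq(1, 100, by = 10), ],
                          n_permutations = 10, seed = 1)
top_k_biomarkers(sh, 5)
```

```
            gene_id mean_abs_attribution rank
1 ENSG00000000015.1           0.04319105    1
2 ENSG00000000004.1           0.03828011    2
3 ENSG00000000046.1           0.03472576    3
4 ENSG00000000001.1           0.03383701    4
5 ENSG00000000047.1           0.03028706    5
```

All five are planted signal genes (the generator plants genes 1–50 as
class-discriminative). The full experiment grid — extractors × losses ×
sampling × classifiers — runs via `run_grid()` / `rank_results()`, and a
thin CLI over these functions lives at `inst/cli/hemafex.R`.

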