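# mognn: multi-omics integration with graph neural networks

`mognn` implements a complete multi-omics classification pipeline for
molecular tumour typing and similar sample-classification problems:
statistical feature selection per omics layer, inner-join integration
across layers, two graph constructions, and three graph neural network
classifiers trained under stratified cross-validation, with a signed-rank
comparison of multi- versus single-omics models. A seeded synthetic
multi-omics generator makes every stage testable without any external
download.

It is aimed at computational biologists who want a transparent,
dependency-light R implementation of this class of pipeline — every
statistical and numerical component is implemented in the package and
validated against independent oracles (`limma`, `glmnet`, `MASS`, dense
matrix algebra) in the test suite.

## The pipeline

**Feature selection.** mRNA counts are screened by a per-gene negative
binomial GLM (log link, two-group contrast, median-of-ratios library-size
offsets, method-of-moments dispersion) with a Wald test at p < 0.001.
Methylation features are screened by an empirical-Bayes moderated t-test
(per-feature variances shrunk toward a scaled inverse-chi-square prior
fitted across features) at p < 0.05. Each screened layer is then refined
by L1-penalised regression,

    min_beta  (1/2n) * sum_i (y_i - x_i' beta)^2 + lambda * sum_j |beta_j|

solved by cyclic coordinate descent with soft-thresholding; the final set
is the union over one-vs-rest class responses of features with nonzero
coefficients at a cross-validated lambda.

**Graphs.** Two structures are supported. The *sample-correlation graph*
connects samples i, j when the Pearson correlation of their integrated
feature profiles reaches a threshold (default 0.9); classification is
transductive node labelling. The *protein-interaction feature graph* uses
gene/protein nodes with a curated edge list; each sample carries a node ×
channel feature matrix (one channel per omics layer, gene-level means) on
the shared topology, and classification is per-sample graph labelling with
a global mean-pool readout.

**Models.** Three message-passing architectures, each with its reference
configuration:

| architecture | layers | propagation rule |
| --- | --- | --- |
| GCN | 3 x 1024, ReLU, dropout 0.5, linear head | `H' = relu(D^-1/2 (A+I) D^-1/2 H W)` |
| GAT | 1024/8, 512/4, 256/2, 32/1 (width/heads), BN + LeakyReLU + dropout, linear head | `h_i' = sum_j alpha_ij W h_j`, `alpha = softmax_j LeakyReLU(a'[Wh_i || Wh_j])` |
| GTN | 2 transformer layers (1024, then n_classes) | `softmax(Q K' / sqrt(d_k)) V` over each node's neighbourhood |

Training uses Adam (initial learning rate 0.001), cross-entropy on the
training mask, dropout 0.5, 100 epochs, and a reduce-on-plateau schedule
on validation accuracy, under stratified 5-fold cross-validation with an
80/20 train/validation split inside each fold. The layers and their
gradients are implemented on a small reverse-mode autodiff tape; every
sparse forward pass is tested against a dense masked-matrix oracle and
every gradient against central finite differences.

## Worked example

```r
library(mognn)

# synthetic multi-omics data: 4 classes, complementary signal per layer
cfg <- sim_config(n_samples_per_class = 30, n_classes = 4,
                  n_features = c(mrna = 200, mirna = 60, meth = 200),
                  frac_informative = 0.2, effect_size = 2,
                  signal_mode = "complementary", seed = 1)
ds <- simulate_multiomics(cfg)

# screen + lasso per layer, integrate, build the sample graph
sel <- select_features(ds, seed = 1)
omics <- mapply(function(m, keep) m[, intersect(colnames(m), keep), drop = FALSE],
                ds$omics, sel$selected, SIMPLIFY = FALSE)
integ <- integrate_omics(omics, ds$labels)
g <- build_sample_graph(integ, threshold = 0.5)
#> Warning: 43 isolated node(s) in the sample graph (no correlation >= 0.5)
print(g)
#> Sample-correlation graph: 89 nodes, 69 edges (density 0.018, 43 isolated), threshold r >= 0.50

# train a GCN on one fold and evaluate the held-out samples
folds <- make_folds(integ$labels, k = 5, seed = 1)
spec <- model_spec("gcn", in_dim = ncol(integ$X),
                   n_classes = nlevels(integ$labels), hidden = c(32, 32, 32))
fit <- train_model(build_model(spec, seed = 1), g, folds[[1]],
                   train_config(epochs = 100, seed = 1))
round(unlist(evaluate(fit, folds[[1]]$test)$metrics), 3)
#> accuracy precision    recall        f1   roc_auc      aupr
#>    0.750     0.583     0.700     0.632     0.964     0.940
```

On this single fold the integrated GCN assigns 75% of held-out samples to
the right class with near-complete separation by score (ROC-AUC 0.96);
across the full 5-fold suite the three-layer combination averages about
0.90 accuracy for the GCN while single layers top out near 0.50 on the
same data, because each layer carries only part of the class structure
(see the vignette). The isolated-node warning is a diagnostic: synthetic
profiles correlate more weakly than real tumour profiles, which is why
this example thresholds at 0.5 rather than the 0.9 default.

The full experiment grid — every architecture × omics combination over 5
folds, with the Wilcoxon multi- vs single-omics comparison — is one call:

```r
suite <- run_comparison_suite(ds, "correlation", select = TRUE,
                              hidden = list(gcn = c(32, 32, 32),
                                            gat = c(32, 16, 8, 8), gtn = 32),
                              heads = list(gat = c(4, 2, 2, 1)),
                              correlation_threshold = 0.5, seed = 1)
print(suite)
write_suite_results(suite, "results/")
```

A command-line wrapper with `simulate / select / integrate / build-graph /
train / evaluate / compare` subcommands is installed at
`system.file("cli", "mognn", package = "mognn")`.

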