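# enose

Classification of electronic-nose (e-nose) gas-sensor array recordings, built
around the pipeline used to detect fungal infection in apples from their
volatile fingerprint: signal preprocessing, transient-response feature
extraction, outlier removal, dimensionality reduction, and a back-propagation
neural network (BPNN) whose hidden-layer sizes are tuned by the sparrow search
algorithm (SSA), with particle swarm (PSO) and grey wolf (GWO) comparators.
Everything is exercisable end-to-end on a seeded synthetic curve generator, so
the full chain is testable without any instrument or download.

## Who this is for

Researchers working with multi-channel gas-sensor transients (machine
olfaction, food quality control) who want a reproducible, scripted version of
the standard e-nose analysis chain, and methods researchers who want a clean
reference implementation of SSA/PSO/GWO architecture search over a from-scratch
BPNN.

## The pipeline

An acquisition is a set of per-channel response curves `c(t)` (concentration in
mg/L, 1 s sampling, 350 s duration). The stages are:

1. **k-point linear smoothing** — each point replaced by the unweighted mean of
   the k values centred on it (k = 7 by default; shrunken symmetric windows at
   the edges).
2. **Dead-channel exclusion** — channels whose reading never leaves the
   detection floor are dropped (two of the eight default channels).
3. **Duplicated-sensor consistency rule** — the array carries two identical
   sensors; a record is discarded when
   `max_{t in [150,300]} |c_a(t) - c_b(t)| > 1.2 mg/L`.
4. **Six descriptors per channel** over the 30–300 s window: trapezoidal
   integral, population variance, mean slope `(v_m - v_1)/((m-1)Δt)`, maximum
   one-step gradient, plateau mean (final half of the window), and energy
   `Σ v_i² Δt` — 48 features for 8 channels, 36 after exclusion.
5. **Mahalanobis outlier removal** — per-class distances
   `d_i = sqrt((x_i - μ)' S⁻¹ (x_i - μ))` with a diagonal-shrunk covariance and
   a chi-square cutoff `sqrt(χ²_{1-α}(d))`, α = 0.025.
6. **Reduction** — LDA (Fisher's generalized eigenproblem `S_B w = λ S_W w`,
   at most 3 discriminants for 4 classes), PCA, or principal-factor FA.
7. **Classifier** — a from-scratch BPNN (sigmoid hidden layers, softmax
   cross-entropy head, full-batch gradient descent) or KNN / SVM / random
   forest baselines.
8. **Architecture search** — SSA/PSO/GWO minimise the negative inner-3-fold
   validation accuracy over integer hidden-layer sizes (population 15, 100
   iterations by default).
9. **Evaluation** — stratified 10-fold cross-validation reporting mean/sd
   accuracy, macro true-positive rate, macro F1 and the pooled confusion
   matrix.

## Worked example

```r
library(enose)

ds  <- generate_dataset(generator_config(seed = 1))   # 160 samples, 4 classes
ds  <- smooth_dataset(ds, k = 7)
ds  <- drop_dead_channels(ds)$dataset                 # 8 -> 6 channels
ds  <- apply_pair_rule(ds)$dataset
ft  <- extract_features(ds)                           # 160 x 36
report <- cross_validate(ft, "bpnn",
                         classifier_params = list(hidden_sizes = c(8, 8)),
                         reduction = "lda", outlier_alpha = 0.025,
                         k = 10, seed = 1)
print(report)
#> <cv_report> bpnn: accuracy 0.8250 +/- 0.1243 over 10 folds; macro TPR 0.8250,
#> macro F1 0.8207, train time 2.87 s
```

The printed numbers are the 10-fold cross-validated mean accuracy and its
standard deviation across folds, the macro-averaged per-class recall (TPR) and
F1 of the pooled confusion matrix, and the total classifier training time.
Tuning the hidden layers with the sparrow search (population 8, 15 iterations)
raises the mean accuracy on this seed from 0.825 to 0.856:

```r
red <- fit_lda(ft$X, ft$labels)
sw  <- swarm_config(bounds = rbind(c(2, 2), c(64, 64)), population = 8,
                    iterations = 15, integer_dims = c(TRUE, TRUE), seed = 1)
tuned <- optimize_bpnn_architecture(predict(red, ft$X), ft$labels,
                                    algorithm = "ssa", swarm = sw,
                                    node_bounds = rbind(c(2, 2), c(64, 64)),
                                    base_config = bpnn_config(3, n_classes = 4))
tuned$hidden_sizes
#> [1]  7 27
```

An end-to-end run (`run_pipeline(pipeline_config())`) chains every stage and
writes the feature table, outlier report, optimizer history and fold-level
report as CSV. A thin subcommand CLI wrapping the same functions ships at
`inst/cli/enose.R` (`simulate`, `preprocess`, `extract`, `reduce`, `tune`,
`evaluate`, `run`).

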