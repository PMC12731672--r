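# fedecg

Explainable federated-learning simulation for multi-class heart-condition
classification from ECG fiducial features, in R.

Hospitals cannot pool raw ECGs, yet single-site classifiers generalize
poorly. `fedecg` simulates the standard answer end to end on one machine:
ten virtual institutions hold private tables of nine per-beat fiducial
features — HR, R-wave height (R-H), P-wave height (P-H), PR interval
(PRQ), QT, corrected QT (QTC), RR interval (RR-I), QRS duration, and
ST-segment level — labelled arrhythmic / healthy / ischemic. Each client
trains a local stacked LSTM (64→32→16 units, dropout 0.2, softmax-3;
32,499 trainable parameters) on its shard; a server aggregates with
federated averaging

    θ_g = (1/N) Σᵢ θᵢ        (optionally size-weighted: Σᵢ |Dᵢ|/|D| · θᵢ)

for R communication rounds, minimizing the federated objective
min_θ Σᵢ (|Dᵢ|/|D|) Lᵢ(θ) with sparse categorical cross-entropy, batch 32,
15 local epochs, Adam at 0.001. The final global model is explained post
hoc with **exact Shapley values** (all 2⁹ = 512 feature coalitions, the
interventional value function, factorial weights — no sampling) and
**LIME** kernel-weighted sparse linear surrogates.

Everything around that core is first-class and tested: a seeded synthetic
cohort generator with class-conditional physiology (depressed ST and
prolonged QTc for ischemia; dispersion-coded rhythm irregularity and
reduced P-waves for arrhythmia), Dirichlet non-IID sharding (label skew
and size skew), per-client SMOTE rebalancing, subject-level train/test
splitting, a confusion-matrix metric suite with one-vs-rest ROC/AUC, and
federated k-fold cross-validation. The LSTM forward/backward pass and
training loop are compiled (RcppArmadillo) and fully deterministic under a
seed.

## Worked example

```r
library(fedecg)

cohort <- generate_cohort(cohort_spec(n_per_class = c(1500, 1500, 1500), seed = 0))
split  <- split_train_test(cohort, train_frac = 0.67, seed = 0)
shards <- shard_non_iid(split$train, n_clients = 10, label_skew = 0.5, seed = 0)
fit <- run_rounds(shards, network_spec(), training_config(),
                  federation_config(rounds = 15, seed = 0),
                  split$test, verbose = TRUE)
#> round  1 | accuracy 0.5000 | loss 0.9296
#> round  5 | accuracy 0.8899 | loss 0.3284
#> round 10 | accuracy 0.9047 | loss 0.3248
#> round 15 | accuracy 0.9074 | loss 0.3606
tail(as.data.frame(fit$history), 1)
#>    round accuracy     f1     fnr    fpr   loss mc_rate precision recall
#> 15    15   0.9074 0.9098 0.09027 0.0457 0.3606 0.09257    0.9122 0.9074

roc_auc_ovr(split$test$labels, predict_proba(fit$model, split$test))$per_class
#> arrhythmic    healthy   ischemic
#>     0.9823     0.9761     0.9834
```

Accuracy climbs from 0.50 at round 1 to 0.91 at round 15 while the test
loss falls — the federation converges despite every client seeing a
different, skewed slice of the classes. The misclassification rate is
exactly `1 - accuracy`, and (support-weighted) recall equals accuracy by
algebraic identity, so those columns cross-check the table. One-vs-rest
AUC near 0.98 per class says the three conditions are almost fully
separable by the learned scores.

Explaining the trained model:

```r
bg <- sample_background(split$train, 100, seed = 1)
shap_summary(fit$model, split$test[1:20], bg, target_class = "ischemic")
#> # A tibble: 9 x 4   (ST and QTC dominate, as ischemia physiology dictates)
lime_explain(fit$model, split$test$values[1, ], target_class = "ischemic",
             seed = 1)
```

A YAML-configurable command-line front end covers the same flows:

```sh
Rscript inst/cli/fedecg.R simulate --out runs/demo --seed 1
Rscript inst/cli/fedecg.R train    --out runs/fit  --seed 1
Rscript inst/cli/fedecg.R crossval --out runs/cv --k 10
Rscript inst/cli/fedecg.R explain  --checkpoint runs/fit/checkpoint.json \
        --data runs/demo/test.csv --out runs/explain
```

## Package layout

- `R/feature-matrix.R` — canonical feature registry, CSV I/O, validation,
  standardization
- `R/cohort.R` — synthetic cohort generator, subject-level split,
  Dirichlet non-IID sharding
- `R/smote.R` — SMOTE oversampling
- `R/network.R`, `src/lstm.cpp` — LSTM spec, parameter registry,
  prediction, local training (compiled BPTT + Adam/SGD)
- `R/federation.R` — FedAvg, communication rounds, federated k-fold CV
- `R/metrics.R` — confusion-matrix suite, one-vs-rest ROC/AUC
- `R/explain.R` — exact Shapley enumeration, LIME surrogates
- `R/cli.R`, `inst/cli/fedecg.R` — experiment commands and YAML config
- `vignettes/fedecg-methods.Rmd` — model, generator design, and the
  reasoning behind every open design choice
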