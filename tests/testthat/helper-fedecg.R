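# Shared fixture builders for the test suite. Everything is generated in
# code, seeded, and small.

# A random valid feature matrix (positive intervals, plausible magnitudes).
make_fm <- function(n, seed = 1, labels = NULL, subject_ids = NULL) {
  withr::with_seed(seed, {
    vals <- cbind(
      HR = runif(n, 50, 110),
      `R-H` = runif(n, 0.4, 1.8),
      `P-H` = runif(n, 0.02, 0.3),
      PRQ = runif(n, 110, 220),
      QT = runif(n, 300, 470),
      QTC = runif(n, 360, 510),
      `RR-I` = runif(n, 500, 1200),
      QRS = runif(n, 60, 140),
      ST = runif(n, -0.3, 0.3)
    )
    if (is.null(labels)) labels <- sample(0:2, n, replace = TRUE)
    feature_matrix(vals, labels, subject_ids = subject_ids)
  })
}

# A small architecture that trains in well under a second.
tiny_spec <- function(dropout = 0.2) {
  network_spec(lstm_units = c(6, 4), dropout_rate = dropout, n_classes = 3)
}

# Linear test double on the raw 9-feature space: f(X) = X w + b.
linear_double <- function(w, b = 0) {
  force(w); force(b)
  function(x) as.numeric(as.matrix(x) %*% w + b)
}

# A linearly separable labeled fixture: class = argmax of three fixed
# linear scores plus small noise, so cross-entropy is easy to reduce.
separable_fm <- function(n = 300, seed = 4) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n * 9), n, 9,
                   dimnames = list(NULL, fiducial_features()))
    scores <- cbind(vals[, "ST"], vals[, "P-H"], -vals[, "QTC"])
    labels <- max.col(scores) - 1L
    feature_matrix(vals, labels)
  })
}

# Default-scale cohort pipeline used by the end-to-end checks: ~3000
# training / ~1500 test records, 10 non-IID clients.
reference_pipeline <- function(seed = 0) {
  spec <- cohort_spec(n_per_class = c(1500, 1500, 1500), seed = seed)
  cohort <- generate_cohort(spec)
  sp <- split_train_test(cohort, train_frac = 0.67, seed = seed)
  shards <- shard_non_iid(sp$train, n_clients = 10, label_skew = 0.5,
                          size_skew = 1000, seed = seed)
  list(train = sp$train, test = sp$test, shards = shards)
}

# Independent pairwise-concordance AUC oracle (ties count one half).
auc_bruteforce <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}
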