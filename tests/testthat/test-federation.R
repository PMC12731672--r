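test_that("FedAvg algebra: idempotence, means, weights, symmetry, invariance", {
  spec <- tiny_spec()
  p <- init_parameters(spec, seed = 1)
  q <- init_parameters(spec, seed = 2)

  # all clients identical -> global equals the common parameters, both modes
  same <- aggregate_fedavg(list(p, p, p))
  expect_equal(same, p)
  expect_equal(aggregate_fedavg(list(p, p), sizes = c(7, 3)), p)

  # scalar check: parameters 2 and 4 -> uniform 3; sizes (1, 3) -> 3.5
  two <- unflatten_parameters(p, rep(2, length(flatten_parameters(p))))
  four <- unflatten_parameters(p, rep(4, length(flatten_parameters(p))))
  expect_equal(flatten_parameters(aggregate_fedavg(list(two, four))),
               rep(3, length(flatten_parameters(p))))
  expect_equal(flatten_parameters(aggregate_fedavg(list(two, four),
                                                   sizes = c(1, 3))),
               rep(3.5, length(flatten_parameters(p))))

  # +theta / -theta pairs cancel exactly
  neg <- unflatten_parameters(p, -flatten_parameters(p))
  zero <- aggregate_fedavg(list(p, neg, p, neg))
  expect_true(all(flatten_parameters(zero) == 0))

  # permutation invariance (uniform) and equal sizes reduce to uniform
  perm <- aggregate_fedavg(list(q, p))
  expect_equal(perm, aggregate_fedavg(list(p, q)))
  expect_equal(aggregate_fedavg(list(p, q), sizes = c(5, 5)),
               aggregate_fedavg(list(p, q)))

  expect_error(aggregate_fedavg(list()), "non-empty")
  other <- init_parameters(network_spec(lstm_units = c(3, 2)), seed = 1)
  expect_error(aggregate_fedavg(list(p, other)), "registries")
  expect_error(aggregate_fedavg(list(p, q), sizes = c(1, 0)), "positive")
})

test_that("zero rounds is a no-op federation and one client reduces to local training", {
  fm <- make_fm(80, seed = 3, subject_ids = sprintf("s%02d", rep(1:20, 4)))
  test_fm <- make_fm(30, seed = 4, subject_ids = sprintf("t%02d", 1:30))
  shards <- shard_non_iid(fm, n_clients = 2, seed = 1)
  spec <- tiny_spec()
  fed0 <- federation_config(n_clients = 2, rounds = 0, seed = 5)
  fit0 <- run_rounds(shards, spec, training_config(local_epochs = 1),
                     fed0, test_fm, smote = FALSE)
  expect_equal(nrow(fit0$history), 0)
  expect_identical(fit0$model$params, init_parameters(spec, seed = 5))

  # single client, uniform aggregation: global model equals that client's
  # local_train result from the same initialization
  one <- shard_non_iid(fm, n_clients = 1, seed = 1)
  fed1 <- federation_config(n_clients = 1, rounds = 1, seed = 5)
  cfg <- training_config(local_epochs = 2, seed = 5)
  fit1 <- run_rounds(one, spec, cfg, fed1, test_fm, smote = FALSE)
  scaler <- standardize_features(one[[1]]$data)$scaler
  local_data <- apply_scaler(scaler, one[[1]]$data)
  cfg_expected <- cfg
  cfg_expected$seed <- fed1$seed + 997L + 1L  # round-1, client-1 derived seed
  manual <- local_train(
    structure(list(spec = spec, params = init_parameters(spec, seed = 5),
                   scaler = NULL), class = "fed_model"),
    local_data, cfg_expected)
  expect_identical(flatten_parameters(fit1$model$params),
                   flatten_parameters(manual$params))
})

test_that("round records satisfy the accounting identities and the leakage check fires", {
  sid <- sprintf("s%03d", rep(1:25, each = 4))
  fm <- make_fm(100, seed = 6, subject_ids = sid)
  test_fm <- make_fm(40, seed = 7, subject_ids = sprintf("t%02d", 1:40))
  shards <- shard_non_iid(fm, n_clients = 3, seed = 2)
  fit <- run_rounds(shards, tiny_spec(), training_config(local_epochs = 1),
                    federation_config(n_clients = 3, rounds = 2, seed = 1,
                                      include_round0 = TRUE),
                    test_fm, smote = FALSE)
  h <- fit$history
  expect_equal(nrow(h), 3)  # round 0 + 2 rounds
  expect_equal(h$round, 0:2)
  expect_identical(h$mc_rate, 1 - h$accuracy)
  expect_equal(h$recall, h$accuracy, tolerance = 1e-12)
  expect_true(all(h$loss >= 0))
  rate_cols <- c("accuracy", "f1", "fnr", "fpr", "mc_rate", "precision",
                 "recall")
  expect_true(all(as.matrix(h[rate_cols]) >= 0 &
                    as.matrix(h[rate_cols]) <= 1))

  # deterministic reruns
  fit2 <- run_rounds(shards, tiny_spec(), training_config(local_epochs = 1),
                     federation_config(n_clients = 3, rounds = 2, seed = 1,
                                       include_round0 = TRUE),
                     test_fm, smote = FALSE)
  expect_identical(fit$history, fit2$history)

  leaky_test <- make_fm(10, seed = 8, subject_ids = c("s001", sprintf("t%02d", 2:10)))
  expect_error(
    run_rounds(shards, tiny_spec(), training_config(local_epochs = 1),
               federation_config(n_clients = 3, rounds = 1), leaky_test),
    "leakage")
})

test_that("federated k-fold partitions records by subject and summarizes folds", {
  cohort <- generate_cohort(cohort_spec(n_per_class = c(40, 40, 40),
                                        records_per_subject = 5, seed = 9))
  cv <- federated_kfold(
    cohort, k = 3, net_spec = tiny_spec(),
    train_config = training_config(local_epochs = 1, seed = 1),
    fed_config = federation_config(n_clients = 2, rounds = 1, seed = 1),
    smote = FALSE, seed = 3)
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(sum(cv$per_fold$n_test), n_records(cohort))
  # every record lands in exactly one test fold, whole subjects at a time
  expect_length(cv$folds, n_records(cohort))
  expect_setequal(unique(cv$folds), 1:3)
  split_subj <- split(cohort$subject_ids, cv$folds)
  expect_length(Reduce(intersect, split_subj), 0)
  # summary is the mean/sd of the fold columns
  acc_row <- cv$summary[cv$summary$metric == "accuracy", ]
  expect_equal(acc_row$mean, mean(cv$per_fold$accuracy))
  expect_equal(acc_row$sd, sd(cv$per_fold$accuracy))

  expect_error(federated_kfold(cohort, k = 1), ">= 2")
  expect_error(make_subject_folds(cohort, k = 1000), "subjects")
})
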