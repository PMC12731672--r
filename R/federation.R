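#' Federation (server-side) configuration
#'
#' @param n_clients Number of participating clients N (default 10; all
#'   clients participate in every communication round).
#' @param rounds Number of communication rounds R (default 15; 0 is a
#'   no-op federation).
#' @param aggregation `"uniform"` (unweighted FedAvg mean, the default) or
#'   `"size_weighted"` (clients weighted by their dataset sizes, matching
#'   the size-weighted federated objective).
#' @param seed Integer base seed; per-client, per-round training seeds are
#'   derived from it.
#' @param include_round0 Also record the untrained initial global model's
#'   test metrics as round 0 (off by default).
#' @return An object of class `federation_config`.
#' @export
federation_config <- function(n_clients = 10, rounds = 15,
                              aggregation = c("uniform", "size_weighted"),
                              seed = 1L, include_round0 = FALSE) {
  aggregation <- match.arg(aggregation)
  if (n_clients < 1) stop("n_clients must be >= 1", call. = FALSE)
  if (rounds < 0) stop("rounds must be >= 0", call. = FALSE)
  structure(
    list(n_clients = as.integer(n_clients), rounds = as.integer(rounds),
         aggregation = aggregation, seed = as.integer(seed),
         include_round0 = isTRUE(include_round0)),
    class = "federation_config"
  )
}

#' Federated averaging of client model parameters
#'
#' Uniform mode returns the elementwise mean `(1/N) * sum(theta_i)`;
#' size-weighted mode returns `sum(|D_i| / |D| * theta_i)`, the weights of
#' the size-weighted federated objective. All registries must agree in
#' tensor names, order and shapes.
#'
#' @param params_list Non-empty list of `model_parameters`.
#' @param sizes Optional positive client dataset sizes `|D_i|`; when
#'   supplied, aggregation is size-weighted, otherwise uniform.
#' @return The aggregated `model_parameters` (the global model theta_g).
#' @export
aggregate_fedavg <- function(params_list, sizes = NULL) {
  if (length(params_list) == 0) {
    stop("params_list must be non-empty", call. = FALSE)
  }
  ref <- params_list[[1]]
  stopifnot(inherits(ref, "model_parameters"))
  for (p in params_list[-1]) {
    if (!identical(names(p), names(ref)) ||
        !identical(lapply(p, dim), lapply(ref, dim))) {
      stop("mismatched parameter registries: tensor names/shapes differ",
           call. = FALSE)
    }
  }
  if (is.null(sizes)) {
    w <- rep(1 / length(params_list), length(params_list))
  } else {
    if (length(sizes) != length(params_list) || any(sizes <= 0)) {
      stop("sizes must be positive and match params_list in length",
           call. = FALSE)
    }
    w <- sizes / sum(sizes)
  }
  out <- lapply(names(ref), function(nm) {
    acc <- ref[[nm]] * w[1]
    for (i in seq_along(params_list)[-1]) {
      acc <- acc + params_list[[i]][[nm]] * w[i]
    }
    acc
  })
  names(out) <- names(ref)
  structure(out, class = "model_parameters")
}

# FedAvg for the per-client feature scalers: the centers and scales are
# averaged with the same weights as the model parameters.
aggregate_scalers <- function(scalers, sizes = NULL) {
  w <- if (is.null(sizes)) rep(1 / length(scalers), length(scalers))
       else sizes / sum(sizes)
  center <- Reduce(`+`, Map(function(s, wi) s$center * wi, scalers, w))
  scale <- Reduce(`+`, Map(function(s, wi) s$scale * wi, scalers, w))
  structure(list(center = center, scale = scale), class = "fiducial_scaler")
}

# Fit one client's private scaler (only these per-feature moments ever
# leave the client).
client_scaler <- function(shard) {
  standardize_features(shard$data)$scaler
}

# Standardize one client's shard with the agreed federation scaler and
# optionally SMOTE-rebalance it in that standardized space.
prepare_client <- function(shard, scaler, smote = TRUE, smote_k = 5,
                           seed = 1L) {
  local <- apply_scaler(scaler, shard$data)
  if (smote) {
    local <- smote_oversample(local, k_neighbors = smote_k,
                              target = "balance", seed = seed,
                              on_singleton = "skip")
  }
  list(data = local, size = n_records(local))
}

evaluate_round <- function(round, spec, params, scaler, test_x, test_labels) {
  model <- structure(list(spec = spec, params = params, scaler = NULL),
                     class = "fed_model")
  probs <- predict_proba(model, test_x)
  y_pred <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion_matrix(test_labels, y_pred, spec$n_classes)
  m <- classification_metrics(cm, losses = cross_entropy(probs, test_labels))
  tibble::tibble(
    round = round, accuracy = m$accuracy, f1 = m$f1, fnr = m$fnr,
    fpr = m$fpr, loss = m$loss, mc_rate = m$mc_rate,
    precision = m$precision, recall = m$recall
  )
}

#' Run the federated communication-round loop
#'
#' Each round broadcasts the global parameters, trains every client locally
#' from that starting point on its private (standardized and, by default,
#' SMOTE-rebalanced) shard, aggregates the returned parameters with FedAvg,
#' and evaluates the new global model on the held-out test set, appending
#' one history row per round. Only model parameters and per-feature scaler
#' summaries cross the client boundary — never records. The test set must
#' be disjoint from every shard (checked via subject ids when present).
#'
#' @param shards List of `client_shard` objects from [shard_non_iid()].
#' @param net_spec A [network_spec()].
#' @param train_config A [training_config()].
#' @param fed_config A [federation_config()].
#' @param test_set A [feature_matrix()] held out from all shards.
#' @param smote Apply per-client SMOTE rebalancing to each local training
#'   shard (default TRUE).
#' @param smote_k SMOTE neighbour count.
#' @param verbose Print per-round metrics.
#' @return List with `model` (the final global `fed_model`, carrying the
#'   aggregated scaler) and `history` (tibble of per-round test metrics:
#'   round, accuracy, f1, fnr, fpr, loss, mc_rate, precision, recall).
#' @export
run_rounds <- function(shards, net_spec = network_spec(),
                       train_config = training_config(),
                       fed_config = federation_config(),
                       test_set, smote = TRUE, smote_k = 5,
                       verbose = FALSE) {
  stopifnot(length(shards) >= 1, inherits(test_set, "feature_matrix"))
  test_subjects <- test_set$subject_ids
  if (!is.null(test_subjects)) {
    for (sh in shards) {
      overlap <- intersect(sh$data$subject_ids, test_subjects)
      if (length(overlap) > 0) {
        stop("data leakage: subject(s) ",
             paste(utils::head(overlap, 3), collapse = ", "),
             " appear in both client ", sh$client_id,
             " and the test set", call. = FALSE)
      }
    }
  }
  # scaler federation round: clients share only per-feature moments; the
  # FedAvg-aggregated scaler becomes the federation's common input space
  shard_sizes <- vapply(shards, `[[`, numeric(1), "size")
  agg_sizes0 <- if (fed_config$aggregation == "size_weighted") shard_sizes
                else NULL
  global_scaler <- aggregate_scalers(lapply(shards, client_scaler),
                                     agg_sizes0)
  clients <- lapply(seq_along(shards), function(i) {
    prepare_client(shards[[i]], global_scaler, smote = smote,
                   smote_k = smote_k, seed = fed_config$seed + i)
  })
  sizes <- vapply(clients, `[[`, numeric(1), "size")
  agg_sizes <- if (fed_config$aggregation == "size_weighted") sizes else NULL
  global_params <- init_parameters(net_spec, seed = fed_config$seed)
  test_x <- sweep(sweep(test_set$values, 2, global_scaler$center, "-"),
                  2, global_scaler$scale, "/")

  history <- list()
  if (fed_config$include_round0) {
    history[["0"]] <- evaluate_round(0L, net_spec, global_params,
                                     global_scaler, test_x, test_set$labels)
  }
  for (r in seq_len(fed_config$rounds)) {
    updates <- vector("list", length(clients))
    for (i in seq_along(clients)) {
      cfg <- train_config
      cfg$seed <- fed_config$seed + 997L * r + i
      local_model <- structure(
        list(spec = net_spec, params = global_params, scaler = NULL),
        class = "fed_model")
      updates[[i]] <- local_train(local_model, clients[[i]]$data, cfg)$params
    }
    global_params <- aggregate_fedavg(updates, agg_sizes)
    rec <- evaluate_round(r, net_spec, global_params, global_scaler,
                          test_x, test_set$labels)
    history[[as.character(r)]] <- rec
    if (verbose) {
      message(sprintf("round %2d | accuracy %.4f | loss %.4f",
                      r, rec$accuracy, rec$loss))
    }
  }
  history <- if (length(history) > 0) {
    do.call(rbind, history)
  } else {
    tibble::tibble(round = integer(0), accuracy = numeric(0),
                   f1 = numeric(0), fnr = numeric(0), fpr = numeric(0),
                   loss = numeric(0), mc_rate = numeric(0),
                   precision = numeric(0), recall = numeric(0))
  }
  model <- structure(
    list(spec = net_spec, params = global_params, scaler = global_scaler),
    class = "fed_model")
  list(model = model, history = history)
}

# Subject-grouped fold assignment: a subject never straddles folds; folds
# are balanced greedily by record count.
make_subject_folds <- function(data, k, seed = 1L) {
  sid <- data$subject_ids
  if (is.null(sid)) sid <- as.character(seq_len(n_records(data)))
  subjects <- unique(sid)
  if (k > length(subjects)) {
    stop("k (", k, ") exceeds the number of subjects (", length(subjects),
         ")", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    subjects <- sample(subjects)
  })
  sizes <- table(sid)[subjects]
  fold_of_subject <- integer(length(subjects))
  fold_counts <- numeric(k)
  # seed each fold with one subject, then greedily balance
  fold_of_subject[seq_len(k)] <- seq_len(k)
  fold_counts[seq_len(k)] <- sizes[seq_len(k)]
  if (length(subjects) > k) {
    for (i in (k + 1):length(subjects)) {
      f <- which.min(fold_counts)
      fold_of_subject[i] <- f
      fold_counts[f] <- fold_counts[f] + sizes[i]
    }
  }
  fold_of_subject[match(sid, subjects)]
}

#' Federated k-fold cross-validation
#'
#' Partitions the data into k subject-grouped folds; for each fold, the
#' remaining data is sharded non-IID across the configured clients,
#' federated training runs for the configured rounds, and the held-out
#' fold is scored with the full metric suite. Fold-level results are
#' summarized as mean and standard deviation per metric.
#'
#' @param data A [feature_matrix()] with `n_records(data) >= k`.
#' @param k Number of folds (default 10, `>= 2`; must not exceed the
#'   number of subjects).
#' @param net_spec,train_config,fed_config Model and training settings as
#'   in [run_rounds()].
#' @param label_skew,size_skew Non-IID sharding parameters per
#'   [shard_non_iid()].
#' @param smote,smote_k Per-client SMOTE settings per [run_rounds()].
#' @param seed Integer seed for fold assignment and sharding.
#' @return List with `per_fold` (tibble: fold, n_test, and the final-round
#'   metric columns) and `summary` (tibble: metric, mean, sd).
#' @export
federated_kfold <- function(data, k = 10, net_spec = network_spec(),
                            train_config = training_config(),
                            fed_config = federation_config(),
                            label_skew = 0.5, size_skew = 1000,
                            smote = TRUE, smote_k = 5, seed = 1L) {
  stopifnot(inherits(data, "feature_matrix"))
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n_records(data) < k) stop("fewer records than folds", call. = FALSE)
  folds <- make_subject_folds(data, k, seed = seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_fold <- data[folds == f]
    train_fold <- data[folds != f]
    fc <- fed_config
    fc$seed <- fed_config$seed + 13L * f
    shards <- shard_non_iid(train_fold, fc$n_clients,
                            label_skew = label_skew, size_skew = size_skew,
                            seed = seed + 101L * f)
    fit <- run_rounds(shards, net_spec, train_config, fc, test_fold,
                      smote = smote, smote_k = smote_k)
    final <- fit$history[nrow(fit$history), ]
    final$round <- NULL
    rows[[f]] <- cbind(tibble::tibble(fold = f,
                                      n_test = n_records(test_fold)),
                       final)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), c("fold", "n_test"))
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = unname(vapply(metric_cols, function(mc) mean(per_fold[[mc]]),
                         numeric(1))),
    sd = unname(vapply(metric_cols, function(mc) stats::sd(per_fold[[mc]]),
                       numeric(1)))
  )
  list(per_fold = per_fold, summary = summary, folds = folds)
}
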