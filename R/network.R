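#' Specify the client-side stacked LSTM classifier
#'
#' The default architecture feeds each record's nine fiducial features, in
#' canonical order, as a length-9 sequence of scalars through three stacked
#' LSTM layers of 64, 32 and 16 units. The first two layers return their
#' full output sequence, the third returns only its final step; a ReLU is
#' applied to each layer's emitted output (the cells themselves use the
#' standard sigmoid/tanh gates) and a dropout layer with rate 0.2 follows
#' every LSTM layer. A dense softmax head with `n_classes` units produces
#' the class probabilities.
#'
#' @param input_len Sequence length (number of features fed step-wise; 9).
#' @param lstm_units Ordered positive unit counts per layer
#'   (default `c(64, 32, 16)`).
#' @param dropout_rate Dropout fraction in `[0, 1)` after each LSTM layer.
#' @param n_classes Number of output classes (`>= 2`).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_len = 9, lstm_units = c(64, 32, 16),
                         dropout_rate = 0.2, n_classes = 3) {
  lstm_units <- as.integer(lstm_units)
  if (length(lstm_units) == 0 || any(lstm_units <= 0)) {
    stop("lstm_units must be a non-empty vector of positive counts",
         call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  structure(
    list(input_len = as.integer(input_len), lstm_units = lstm_units,
         dropout_rate = dropout_rate, n_classes = as.integer(n_classes)),
    class = "network_spec"
  )
}

#' Training hyperparameters for local client optimization
#'
#' Defaults follow the federated experimental protocol: mini-batch size 32,
#' 15 local epochs, learning rate 0.001, the Adam optimizer, and sparse
#' categorical cross-entropy loss. `optimizer = "sgd"` gives the plain
#' gradient step `theta <- theta - eta * grad`.
#'
#' @param batch_size Mini-batch size B (`>= 1`).
#' @param local_epochs Local epochs E per call (`>= 0`; 0 is a no-op).
#' @param learning_rate Step size eta (`> 0`).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed Integer seed driving batch shuffling and dropout masks.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 32, local_epochs = 15,
                            learning_rate = 0.001,
                            optimizer = c("adam", "sgd"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (local_epochs < 0) stop("local_epochs must be >= 0", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(
    list(batch_size = as.integer(batch_size),
         local_epochs = as.integer(local_epochs),
         learning_rate = learning_rate, optimizer = optimizer,
         seed = as.integer(seed)),
    class = "training_config"
  )
}

# Tensor registry for a network spec: names, shapes, and order are a pure
# function of the spec. Gate rows within each 4h-row LSTM block are stacked
# input/forget/candidate/output.
parameter_shapes <- function(spec) {
  shapes <- list()
  input_dim <- 1L
  for (l in seq_along(spec$lstm_units)) {
    h <- spec$lstm_units[l]
    shapes[[sprintf("lstm%d.W", l)]] <- c(4L * h, input_dim)
    shapes[[sprintf("lstm%d.U", l)]] <- c(4L * h, h)
    shapes[[sprintf("lstm%d.b", l)]] <- c(4L * h, 1L)
    input_dim <- h
  }
  h_last <- spec$lstm_units[length(spec$lstm_units)]
  shapes[["dense.W"]] <- c(spec$n_classes, h_last)
  shapes[["dense.b"]] <- c(spec$n_classes, 1L)
  shapes
}

#' Initialize the model parameter registry
#'
#' Glorot-uniform initialization for the input and recurrent kernels and
#' the dense head; biases start at zero except the forget-gate block,
#' which starts at one (the usual LSTM forget-bias trick). Deterministic
#' under `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return An object of class `model_parameters`: an ordered named list of
#'   numeric matrices whose order and shapes depend only on `spec`.
#' @export
init_parameters <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  shapes <- parameter_shapes(spec)
  withr::with_seed(as.integer(seed), {
    params <- lapply(names(shapes), function(nm) {
      dm <- shapes[[nm]]
      if (endsWith(nm, ".b")) {
        b <- matrix(0, dm[1], dm[2])
        if (startsWith(nm, "lstm")) {
          h <- dm[1] %/% 4L
          b[(h + 1L):(2L * h), 1] <- 1  # forget gate bias
        }
        return(b)
      }
      limit <- sqrt(6 / (dm[1] + dm[2]))
      matrix(stats::runif(prod(dm), -limit, limit), dm[1], dm[2])
    })
    names(params) <- names(shapes)
    structure(params, class = "model_parameters")
  })
}

#' Flatten a parameter registry to a single numeric vector
#'
#' Concatenates every tensor (column-major) in registry order.
#' `unflatten_parameters(template, flatten_parameters(p))` reproduces `p`
#' bit-exactly.
#'
#' @param params A `model_parameters` object.
#' @return Numeric vector of all trainable scalars.
#' @export
flatten_parameters <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  unlist(lapply(params, as.numeric), use.names = FALSE)
}

#' Rebuild a parameter registry from a flat vector
#'
#' @param template A `model_parameters` object supplying names and shapes.
#' @param x Numeric vector with exactly as many entries as the template.
#' @return A `model_parameters` object.
#' @export
unflatten_parameters <- function(template, x) {
  stopifnot(inherits(template, "model_parameters"))
  sizes <- vapply(template, length, integer(1))
  if (length(x) != sum(sizes)) {
    stop("flat vector has length ", length(x), ", expected ", sum(sizes),
         call. = FALSE)
  }
  off <- 0L
  out <- lapply(template, function(t) {
    n <- length(t)
    m <- matrix(x[(off + 1L):(off + n)], nrow(t), ncol(t))
    off <<- off + n
    m
  })
  structure(out, class = "model_parameters")
}

#' Build a client network
#'
#' Instantiates the architecture of a [network_spec()] with seeded
#' deterministic initialization.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for initialization.
#' @param scaler Optional `fiducial_scaler` attached to the model; when
#'   present, [predict_proba()] standardizes inputs automatically.
#' @return An object of class `fed_model` with fields `spec`, `params`,
#'   and `scaler`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L, scaler = NULL) {
  structure(
    list(spec = spec, params = init_parameters(spec, seed), scaler = scaler),
    class = "fed_model"
  )
}

#' @export
print.fed_model <- function(x, ...) {
  cat("<fed_model> LSTM(", paste(x$spec$lstm_units, collapse = "-"),
      ") dropout=", x$spec$dropout_rate, " -> softmax-", x$spec$n_classes,
      "; ", count_trainable_parameters(x), " trainable parameters\n",
      sep = "")
  invisible(x)
}

#' Count trainable scalar parameters
#'
#' Exact count of trainable scalars under the single-bias LSTM
#' parameterization: each layer contributes `4 * (h * (h + in) + h)` and
#' the dense head `h_last * n_classes + n_classes`. Equals
#' `length(flatten_parameters(params))` by construction.
#'
#' @param x A `fed_model`, `model_parameters`, or `network_spec`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(x) {
  if (inherits(x, "fed_model")) x <- x$params
  if (inherits(x, "network_spec")) {
    return(as.integer(sum(vapply(parameter_shapes(x), prod, numeric(1)))))
  }
  stopifnot(inherits(x, "model_parameters"))
  as.integer(sum(vapply(x, length, integer(1))))
}

# Resolve a feature_matrix or plain matrix to the (optionally standardized)
# n x 9 numeric input the compiled forward pass expects.
model_input <- function(model, data) {
  if (inherits(data, "feature_matrix")) {
    if (!is.null(model$scaler)) data <- apply_scaler(model$scaler, data)
    return(data$values)
  }
  x <- as.matrix(data)
  if (ncol(x) != model$spec$input_len) {
    stop("input has ", ncol(x), " columns, expected ",
         model$spec$input_len, call. = FALSE)
  }
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), fiducial_features())) {
    stop("feature-order mismatch: columns must follow the canonical ",
         "registry ", paste(fiducial_features(), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(model$scaler)) {
    x <- sweep(sweep(x, 2, model$scaler$center, "-"),
               2, model$scaler$scale, "/")
  }
  x
}

#' Predict class probabilities
#'
#' Runs the forward pass (dropout disabled) on each record reshaped to the
#' length-9 scalar sequence in canonical feature order. Every returned row
#' sums to one. If the model carries a scaler, raw-feature inputs are
#' standardized automatically; otherwise inputs must already be in the
#' model's training space.
#'
#' @param model A `fed_model`.
#' @param data A [feature_matrix()] or numeric matrix with 9 columns in
#'   canonical order.
#' @param chunk_size Rows per compiled-forward batch (memory bound only).
#' @return Numeric `n x n_classes` matrix of class probabilities, columns
#'   named by [class_labels()].
#' @export
predict_proba <- function(model, data, chunk_size = 4096L) {
  stopifnot(inherits(model, "fed_model"))
  x <- model_input(model, data)
  n <- nrow(x)
  k <- model$spec$n_classes
  out <- matrix(NA_real_, n, k)
  if (k == 3) colnames(out) <- class_labels()
  if (n == 0) return(out)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n)
    out[s:e, ] <- lstm_predict_cpp(model$params, x[s:e, , drop = FALSE], k)
  }
  out
}

#' Predict hard class labels
#'
#' Argmax of [predict_proba()], with exact probability ties broken toward
#' the lowest class code.
#'
#' @inheritParams predict_proba
#' @return Integer vector of class codes.
#' @export
predict_classes <- function(model, data) {
  probs <- predict_proba(model, data)
  if (nrow(probs) == 0) return(integer(0))
  max.col(probs, ties.method = "first") - 1L
}

#' Mean sparse categorical cross-entropy of a model on labeled data
#' @inheritParams predict_proba
#' @return Mean per-record cross-entropy (natural log).
#' @export
evaluate_loss <- function(model, data) {
  stopifnot(inherits(data, "feature_matrix"))
  probs <- predict_proba(model, data)
  mean(cross_entropy(probs, data$labels))
}

#' Local client training (one federated participant's update)
#'
#' Runs `local_epochs` epochs of mini-batch optimization of the sparse
#' categorical cross-entropy on the client's private data, with dropout
#' active during training and fresh optimizer state per call (as in a
#' federated round, where the optimizer is re-created after each broadcast).
#' All randomness (batch shuffling, dropout masks) is drawn from R's RNG
#' seeded with `config$seed`, so identical inputs give identical outputs.
#'
#' @param model A `fed_model` holding the starting parameters (typically
#'   the broadcast global model).
#' @param shard A `client_shard` or `feature_matrix` of training records,
#'   already expressed in the model's input space.
#' @param config A [training_config()].
#' @return List with `params` (updated `model_parameters`) and `loss`
#'   (mean training loss over the final epoch; for `local_epochs = 0` the
#'   parameters are returned unchanged and `loss` is the current loss).
#' @export
local_train <- function(model, shard, config = training_config()) {
  stopifnot(inherits(model, "fed_model"),
            inherits(config, "training_config"))
  data <- if (inherits(shard, "client_shard")) shard$data else shard
  stopifnot(inherits(data, "feature_matrix"))
  if (n_records(data) < 1) stop("empty shard: nothing to train on",
                                call. = FALSE)
  if (config$local_epochs == 0) {
    return(list(params = model$params, loss = evaluate_loss(model, data)))
  }
  x <- data$values
  withr::with_seed(config$seed, {
    res <- lstm_train_cpp(model$params, x, data$labels,
                          config$local_epochs, config$batch_size,
                          config$learning_rate, config$optimizer,
                          model$spec$dropout_rate, model$spec$n_classes)
  })
  params <- res$params
  names(params) <- names(model$params)
  list(params = structure(params, class = "model_parameters"),
       loss = res$final_loss)
}

# per-record sparse categorical cross-entropy with clamped probabilities
cross_entropy <- function(probs, labels) {
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  -log(pmax(p, 1e-12))
}
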