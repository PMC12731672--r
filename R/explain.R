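# Resolve `model` (a fed_model or a plain function of an n x 9 matrix) and
# a target class to a scalar-output prediction function on raw inputs.
as_predict_fun <- function(model, target_class = 0L) {
  if (is.function(model)) {
    return(function(x) as.numeric(model(x)))
  }
  stopifnot(inherits(model, "fed_model"))
  target_class <- resolve_class(target_class)
  function(x) {
    colnames(x) <- fiducial_features()
    predict_proba(model, x)[, target_class + 1L]
  }
}

resolve_class <- function(target_class) {
  if (is.character(target_class)) {
    code <- match(tolower(target_class), class_labels()) - 1L
    if (is.na(code)) stop("unknown class: ", target_class, call. = FALSE)
    return(code)
  }
  as.integer(target_class)
}

background_matrix <- function(background) {
  bg <- if (inherits(background, "feature_matrix")) background$values
        else as.matrix(background)
  if (nrow(bg) == 0) stop("background must be non-empty", call. = FALSE)
  bg
}

#' Sample a seeded background reference set
#'
#' Convenience sampler for the interventional Shapley value function:
#' draws `n` rows (without replacement when possible) from a reference
#' dataset, typically the training data.
#'
#' @param data A [feature_matrix()].
#' @param n Number of background rows (default 100).
#' @param seed Integer seed.
#' @return A `feature_matrix` of `min(n, n_records(data))` rows.
#' @export
sample_background <- function(data, n = 100, seed = 1L) {
  stopifnot(inherits(data, "feature_matrix"))
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(n_records(data), min(n, n_records(data)))
  })
  data[idx]
}

#' Exact Shapley feature attribution by coalition enumeration
#'
#' Computes, for one instance, the exact Shapley value of each of the nine
#' features under the interventional value function: for a coalition S,
#' `f_S(x_S)` is the mean model output over the background rows with the
#' features in S replaced by the instance's values. All `2^9 = 512`
#' coalitions are enumerated and marginal contributions are combined with
#' the factorial weights `|S|! (|F|-|S|-1)! / |F|!`. The model output
#' explained is the target-class softmax probability; positive values push
#' that probability up. The efficiency axiom
#' `sum(phi) = f(x) - base_value` holds to numerical precision by
#' construction.
#'
#' @param model A `fed_model`, or any function mapping an `n x 9` matrix
#'   to a numeric vector of outputs (useful for test doubles).
#' @param x Numeric length-9 instance in canonical feature order (raw
#'   feature space; a model scaler, if any, is applied internally).
#' @param background Non-empty `feature_matrix` or matrix of reference
#'   rows (see [sample_background()]).
#' @param target_class Class code or name whose probability is explained
#'   (ignored for function models).
#' @return An object of class `shap_attribution`: list with `phi` (named
#'   9-vector), `base_value` (mean output over the background), `fx`
#'   (output at `x`), `x`, and `target_class`.
#' @export
exact_shapley <- function(model, x, background, target_class = 0L) {
  f <- as_predict_fun(model, target_class)
  x <- as.numeric(x)
  d <- length(x)
  stopifnot(d == 9)
  bg <- background_matrix(background)
  stopifnot(ncol(bg) == d)
  b <- nrow(bg)
  n_masks <- 2L^d

  # membership[s, i]: does coalition s-1 contain feature i?
  membership <- matrix(FALSE, n_masks, d)
  for (i in seq_len(d)) {
    membership[, i] <- bitwAnd(seq_len(n_masks) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  }

  # big stacked input: for each coalition, the background with in-coalition
  # features overwritten by x
  big <- bg[rep(seq_len(b), times = n_masks), , drop = FALSE]
  rows_of_mask <- rep(seq_len(n_masks), each = b)
  for (i in seq_len(d)) {
    sel <- membership[rows_of_mask, i]
    big[sel, i] <- x[i]
  }
  preds <- f(big)
  v <- unname(rowsum(preds, rows_of_mask)[, 1]) / b  # coalition values

  sizes <- rowSums(membership)
  # weight of a coalition of size s (excluding feature i): s!(d-s-1)!/d!
  wt <- exp(lfactorial(0:(d - 1)) + lfactorial(d - 1 - (0:(d - 1))) -
              lfactorial(d))
  phi <- numeric(d)
  masks0 <- seq_len(n_masks) - 1L
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(!membership[, i])
    with_i <- masks0[without] + bit + 1L
    phi[i] <- sum(wt[sizes[without] + 1L] * (v[with_i] - v[without]))
  }
  names(phi) <- fiducial_features()
  structure(
    list(x = stats::setNames(x, fiducial_features()),
         target_class = if (is.function(model)) NA_integer_
                        else resolve_class(target_class),
         phi = phi, base_value = v[1], fx = v[n_masks],
         n_background = b),
    class = "shap_attribution"
  )
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat("<shap_attribution> base", sprintf("%.4f", x$base_value),
      "-> f(x)", sprintf("%.4f", x$fx), "\n")
  print(round(sort(x$phi, decreasing = TRUE), 4))
  invisible(x)
}

#' Global Shapley summary over a dataset
#'
#' Aggregates [exact_shapley()] attributions over the rows of `X` into the
#' per-feature mean signed value and mean absolute value, ranked by the
#' latter (both are reported because signed means and absolute-magnitude
#' rankings answer different questions).
#'
#' @param model A `fed_model` or prediction function.
#' @param X A non-empty [feature_matrix()] of instances to explain.
#' @param background Reference rows for the value function.
#' @param target_class Class code or name to explain.
#' @return Tibble with columns `feature`, `mean_phi`, `mean_abs_phi`,
#'   `rank`, sorted by decreasing `mean_abs_phi`.
#' @export
shap_summary <- function(model, X, background, target_class = 0L) {
  stopifnot(inherits(X, "feature_matrix"), n_records(X) > 0)
  phis <- vapply(seq_len(n_records(X)), function(i) {
    exact_shapley(model, X$values[i, ], background, target_class)$phi
  }, numeric(9))
  out <- tibble::tibble(
    feature = fiducial_features(),
    mean_phi = rowMeans(phis),
    mean_abs_phi = rowMeans(abs(phis))
  )
  out <- out[order(-out$mean_abs_phi), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' LIME local surrogate explanation
#'
#' Fits a kernel-weighted sparse linear surrogate to the model around one
#' instance: perturbations `Z` are drawn by Gaussian jitter of `x` in
#' standardized feature space, each weighted by the locality kernel
#' `pi_x(z) = exp(-d(x, z)^2 / kernel_width^2)` (Euclidean distance), and
#' a weighted least-squares linear model of the target-class probability
#' is fitted. Complexity is capped by keeping only the `sparsity_cap`
#' largest-magnitude coefficients and refitting. Local fidelity is the
#' kernel-weighted R-squared of the surrogate against the model on `Z`.
#'
#' @param model A `fed_model` or prediction function.
#' @param x Numeric length-9 instance in canonical order (raw space).
#' @param target_class Class code or name to explain.
#' @param n_samples Number of perturbations (`>= 10 * sparsity_cap`).
#' @param kernel_width Positive kernel width in standardized units
#'   (default `0.75 * sqrt(9)`, the usual heuristic for 9 features).
#' @param sparsity_cap Maximum number of nonzero coefficients (default 9,
#'   i.e. no sparsification).
#' @param seed Optional integer seed.
#' @param perturb_sd Per-feature perturbation standard deviations in raw
#'   units; defaults to the model scaler's scales (so perturbations are
#'   unit-variance in standardized space) or to 1 for scaler-free models.
#'   Must be strictly positive.
#' @return An object of class `lime_explanation`: coefficients (named
#'   9-vector in standardized per-feature units, zeros outside the
#'   selected support), intercept, kernel width, perturbation count,
#'   weighted-R-squared `fidelity`, and the sparsity cap.
#' @export
lime_explain <- function(model, x, target_class = 0L, n_samples = 1000,
                         kernel_width = 0.75 * sqrt(9), sparsity_cap = 9,
                         seed = NULL, perturb_sd = NULL) {
  if (n_samples < 10 * sparsity_cap) {
    stop("n_samples must be at least 10 * sparsity_cap", call. = FALSE)
  }
  if (kernel_width <= 0) stop("kernel_width must be > 0", call. = FALSE)
  f <- as_predict_fun(model, target_class)
  x <- as.numeric(x)
  d <- length(x)
  sparsity_cap <- min(sparsity_cap, d)
  if (is.null(perturb_sd)) {
    perturb_sd <- if (!is.function(model) && !is.null(model$scaler)) {
      as.numeric(model$scaler$scale)
    } else rep(1, d)
  }
  if (any(perturb_sd <= 0)) {
    stop("degenerate perturbations: perturb_sd must be > 0", call. = FALSE)
  }
  run <- function() {
    noise <- matrix(stats::rnorm(n_samples * d), n_samples, d)
    z_raw <- sweep(sweep(noise, 2, perturb_sd, "*"), 2, x, "+")
    y <- f(z_raw)
    # regression in standardized coordinates: distance and coefficients
    # are per-SD of the perturbation law
    z_std <- sweep(z_raw, 2, perturb_sd, "/")
    x_std <- x / perturb_sd
    d2 <- rowSums(sweep(z_std, 2, x_std, "-")^2)
    w <- exp(-d2 / kernel_width^2)
    fit_wls <- function(cols) {
      design <- cbind(Intercept = 1, z_std[, cols, drop = FALSE])
      fit <- stats::lm.wfit(design, y, w)
      fit$coefficients
    }
    coef_full <- fit_wls(seq_len(d))
    keep <- order(abs(coef_full[-1]), decreasing = TRUE)[seq_len(sparsity_cap)]
    keep <- sort(keep)
    coef_sel <- fit_wls(keep)
    coefficients <- stats::setNames(numeric(d), fiducial_features())
    coefficients[keep] <- coef_sel[-1]
    intercept <- unname(coef_sel[1])
    y_hat <- intercept + z_std %*% coefficients
    y_bar <- sum(w * y) / sum(w)
    ss_res <- sum(w * (y - y_hat)^2)
    ss_tot <- sum(w * (y - y_bar)^2)
    fidelity <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    structure(
      list(x = stats::setNames(x, fiducial_features()),
           target_class = if (is.function(model)) NA_integer_
                          else resolve_class(target_class),
           coefficients = coefficients, intercept = intercept,
           kernel_width = kernel_width, n_samples = n_samples,
           fidelity = fidelity, sparsity_cap = sparsity_cap),
      class = "lime_explanation"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' @export
print.lime_explanation <- function(x, ...) {
  cat("<lime_explanation> fidelity", sprintf("%.4f", x$fidelity),
      "| nonzero", sum(x$coefficients != 0), "\n")
  nz <- x$coefficients[x$coefficients != 0]
  print(round(nz[order(-abs(nz))], 4))
  invisible(x)
}
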