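test_that("Shapley axioms hold for constant, linear, dummy and symmetric games", {
  bg <- make_fm(40, seed = 1)
  x <- make_fm(1, seed = 2)$values[1, ]

  # null game: a constant model attributes nothing
  const <- exact_shapley(function(m) rep(0.7, nrow(m)), x, bg)
  expect_true(all(const$phi == 0))
  expect_equal(const$base_value, 0.7)
  expect_equal(const$fx, 0.7)

  # linear game closed form: phi_i = w_i * (x_i - mean(bg_i))
  w <- c(0.3, -1.2, 0, 2, 0.05, 0, -0.4, 1, 0.7)
  lin <- exact_shapley(linear_double(w, b = 5), x, bg)
  expect_equal(unname(lin$phi), unname(w * (x - colMeans(bg$values))),
               tolerance = 1e-9)
  # dummy features (zero weight) get exactly zero
  expect_identical(unname(lin$phi[w == 0]), c(0, 0))
  # efficiency
  expect_lt(abs(sum(lin$phi) - (lin$fx - lin$base_value)), 1e-9)

  # symmetry: exchangeable features get equal attributions
  sym_bg <- bg
  sym_bg$values[, 2] <- sym_bg$values[, 1]
  x_sym <- x
  x_sym[2] <- x_sym[1]
  sym <- exact_shapley(function(m) m[, 1] * m[, 2], x_sym, sym_bg)
  expect_lt(abs(sym$phi[1] - sym$phi[2]), 1e-9)
})

test_that("coalition enumeration matches a permutation-average oracle on 4-feature games", {
  # a nonlinear game touching only the first four features
  f <- function(m) m[, 1] * m[, 2] + exp(m[, 3] / 4) - 2 * m[, 4] * m[, 1]
  bg <- make_fm(15, seed = 3)
  x <- make_fm(1, seed = 4)$values[1, ]

  # independent oracle: average marginal contribution over all 4! orders of
  # the active features, same interventional value function
  v_of <- function(S) {
    m <- bg$values
    for (i in S) m[, i] <- x[i]
    mean(f(m))
  }
  orders <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  orders <- orders[apply(orders, 1, function(r) length(unique(r)) == 4), ]
  phi_oracle <- numeric(4)
  for (r in seq_len(nrow(orders))) {
    ord <- as.integer(orders[r, ])
    S <- integer(0)
    for (i in ord) {
      phi_oracle[i] <- phi_oracle[i] + (v_of(c(S, i)) - v_of(S))
      S <- c(S, i)
    }
  }
  phi_oracle <- phi_oracle / nrow(orders)

  res <- exact_shapley(f, x, bg)
  expect_equal(unname(res$phi[1:4]), phi_oracle, tolerance = 1e-9)
  expect_true(all(res$phi[5:9] == 0))  # untouched features are dummies
})

test_that("Shapley attributions on the trained network satisfy efficiency", {
  model <- build_network(tiny_spec(), seed = 6)
  bg <- make_fm(25, seed = 7)
  for (i in 1:3) {
    x <- make_fm(5, seed = 8)$values[i, ]
    att <- exact_shapley(model, x, bg, target_class = i - 1)
    expect_lt(abs(sum(att$phi) - (att$fx - att$base_value)), 1e-6)
    expect_equal(att$fx,
                 unname(predict_proba(model, matrix(x, 1))[1, i]),
                 tolerance = 1e-9)
  }
})

test_that("Shapley summary aggregates, ranks, and respects duplication", {
  bg <- make_fm(20, seed = 9)
  X <- make_fm(4, seed = 10)
  w <- c(0, 0, 0, 0, 0, 0, 0, 0, 1)  # only ST matters
  f <- linear_double(w)
  s1 <- shap_summary(f, X[1], bg)
  att <- exact_shapley(f, X$values[1, ], bg)
  expect_equal(unname(s1$mean_phi[match(fiducial_features(), s1$feature)]),
               unname(att$phi), tolerance = 1e-12)

  s4 <- shap_summary(f, X, bg)
  expect_identical(s4$feature[1], "ST")
  expect_true(all(s4$mean_abs_phi[-1] < 1e-12))

  dup <- shap_summary(f, X[c(1:4, 1:4)], bg)
  expect_equal(dup$mean_phi, s4$mean_phi, tolerance = 1e-12)
})

test_that("LIME recovers linear models and respects the sparsity cap", {
  w <- c(1.5, -2, 0.3, 0, 0.8, -0.1, 2.2, 0.05, -1)
  f <- linear_double(w, b = 0.25)
  x <- rep(0.5, 9)
  ex <- lime_explain(f, x, n_samples = 2000, kernel_width = 20, seed = 3)
  expect_true(all(abs(ex$coefficients - w) <= 0.05 * pmax(abs(w), 0.1)))
  expect_gte(ex$fidelity, 0.99)

  const <- lime_explain(function(m) rep(0.4, nrow(m)), x, seed = 4)
  expect_true(all(abs(const$coefficients) < 1e-9))
  expect_equal(const$intercept, 0.4, tolerance = 1e-9)
  expect_equal(const$fidelity, 1)  # flat function is fitted exactly

  sparse <- lime_explain(f, x, sparsity_cap = 2, n_samples = 500, seed = 5)
  expect_lte(sum(sparse$coefficients != 0), 2)
  # the two largest true weights survive the cap
  expect_setequal(names(which(sparse$coefficients != 0)),
                  fiducial_features()[order(-abs(w))][1:2])

  expect_error(lime_explain(f, x, n_samples = 20), "10")
  expect_error(lime_explain(f, x, perturb_sd = rep(0, 9)), "degenerate")
})

test_that("shrinking the kernel width localizes the surrogate gradient", {
  # curved game with asymmetric curvature: f(z) = z1^3; the local gradient
  # at x1 = 1 is 3, while a wide-kernel linear fit inflates the slope by
  # about three times the effective sampling variance
  f <- function(m) m[, 1]^3
  x <- c(1, rep(0, 8))
  wide <- lime_explain(f, x, n_samples = 4000, kernel_width = 6, seed = 6)
  narrow <- lime_explain(f, x, n_samples = 4000, kernel_width = 0.4, seed = 6)
  expect_lt(abs(narrow$coefficients[1] - 3), abs(wide$coefficients[1] - 3))
  expect_lt(abs(narrow$coefficients[1] - 3), 0.5)
})

test_that("explanations work on fed_model objects with a scaler attached", {
  model <- build_network(tiny_spec(), seed = 11)
  train <- make_fm(60, seed = 12)
  model$scaler <- standardize_features(train)$scaler
  bg <- sample_background(train, 15, seed = 2)
  x <- train$values[1, ]
  att <- exact_shapley(model, x, bg, target_class = "ischemic")
  expect_lt(abs(sum(att$phi) - (att$fx - att$base_value)), 1e-6)
  ex <- lime_explain(model, x, target_class = 2, n_samples = 400, seed = 1)
  expect_true(is.finite(ex$fidelity))
})
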