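test_that("cohort generation is seeded, typed, and honors empty specs", {
  empty <- generate_cohort(cohort_spec(n_per_class = c(0, 0, 0)))
  expect_equal(n_records(empty), 0)

  spec <- cohort_spec(n_per_class = c(40, 50, 60), seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$values, b$values)
  expect_identical(a$labels, b$labels)
  expect_identical(a$subject_ids, b$subject_ids)
  expect_identical(unname(class_counts(a)), c(40L, 50L, 60L))

  # every generated record satisfies the record invariants
  out <- validate_records(a)
  expect_equal(sum(out$report), 0)
})

test_that("default cohort encodes the class physiology with clear margins", {
  cohort <- generate_cohort(cohort_spec(n_per_class = c(1000, 1000, 1000),
                                        seed = 42))
  v <- cohort$values
  cl <- cohort$labels
  se2 <- function(x, y) 2 * sqrt(var(x) / length(x) + var(y) / length(y))
  st_h <- v[cl == 1, "ST"]; st_i <- v[cl == 2, "ST"]
  expect_gt(mean(st_h) - mean(st_i), se2(st_h, st_i))
  qtc_h <- v[cl == 1, "QTC"]; qtc_i <- v[cl == 2, "QTC"]
  expect_gt(mean(qtc_i) - mean(qtc_h), se2(qtc_h, qtc_i))
  ph_h <- v[cl == 1, "P-H"]; ph_a <- v[cl == 0, "P-H"]
  expect_gt(mean(ph_h) - mean(ph_a), se2(ph_h, ph_a))
  expect_gt(sd(v[cl == 0, "RR-I"]), 2 * sd(v[cl == 1, "RR-I"]))
})

test_that("class-wise sample means recover the spec locations", {
  spec <- cohort_spec(n_per_class = c(4000, 4000, 4000), seed = 7)
  cohort <- generate_cohort(spec)
  for (code in 0:2) {
    cl <- class_labels()[code + 1]
    p <- spec$class_params[[cl]]
    v <- cohort$values[cohort$labels == code, ]
    # tolerance: 5 standard errors of the per-feature mean, plus the
    # subject random effect on HR/RR-I
    sd_eff <- p$sd
    if (cl == "arrhythmic") sd_eff[["RR-I"]] <- sd_eff[["RR-I"]] * spec$rr_jitter_arrhythmic
    sd_eff[["HR"]] <- sqrt(sd_eff[["HR"]]^2 + spec$subject_effect_sd[["HR"]]^2)
    sd_eff[["RR-I"]] <- sqrt(sd_eff[["RR-I"]]^2 + spec$subject_effect_sd[["RR-I"]]^2)
    tol <- 5 * sd_eff / sqrt(nrow(v))
    # subject effects are shared within blocks, widening the effective SE
    tol[c("HR", "RR-I")] <- tol[c("HR", "RR-I")] * sqrt(spec$records_per_subject)
    expect_true(all(abs(colMeans(v) - p$mean) < tol),
                info = paste("class", cl))
  }
})

test_that("subject-level split keeps subjects intact near the target fraction", {
  cohort <- generate_cohort(cohort_spec(n_per_class = c(300, 300, 300),
                                        seed = 3))
  sp <- split_train_test(cohort, train_frac = 0.67, seed = 1)
  expect_equal(n_records(sp$train) + n_records(sp$test), n_records(cohort))
  expect_length(intersect(sp$train$subject_ids, sp$test$subject_ids), 0)
  frac <- n_records(sp$train) / n_records(cohort)
  expect_gt(frac, 0.62)
  expect_lt(frac, 0.72)
})

test_that("non-IID sharding is an exact partition with non-empty shards", {
  fm <- make_fm(200, seed = 11, subject_ids = sprintf("s%03d", 1:200))
  shards <- shard_non_iid(fm, n_clients = 7, label_skew = 0.4, seed = 2)
  expect_length(shards, 7)
  sizes <- vapply(shards, `[[`, numeric(1), "size")
  expect_true(all(sizes > 0))
  expect_equal(sum(sizes), n_records(fm))
  all_subj <- unlist(lapply(shards, function(s) s$data$subject_ids))
  expect_identical(sort(all_subj), sort(fm$subject_ids))

  # determinism
  shards2 <- shard_non_iid(fm, n_clients = 7, label_skew = 0.4, seed = 2)
  expect_identical(lapply(shards, `[[`, "data"),
                   lapply(shards2, `[[`, "data"))

  # degenerate partition
  one <- shard_non_iid(fm, n_clients = 1, seed = 9)
  expect_identical(one[[1]]$data$values, fm$values)
  expect_error(shard_non_iid(make_fm(3, seed = 1), n_clients = 5),
               "exceeds")
})

test_that("label_skew controls heterogeneity: IID limit and dominant-class shards", {
  cohort <- generate_cohort(cohort_spec(n_per_class = c(1000, 1000, 1000),
                                        seed = 13))
  global <- class_counts(cohort) / n_records(cohort)
  for (seed in 1:20) {
    iid <- shard_non_iid(cohort, n_clients = 10, label_skew = 1e6,
                         size_skew = 1000, seed = seed)
    for (sh in iid) {
      expect_true(all(abs(sh$class_proportions - global) <= 0.05),
                  info = paste("seed", seed))
    }
    skewed <- shard_non_iid(cohort, n_clients = 10, label_skew = 0.3,
                            size_skew = 1000, seed = seed)
    max_prop <- vapply(skewed, function(s) max(s$class_proportions),
                       numeric(1))
    expect_gt(max(max_prop), 0.5)
  }
})
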