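test_that("kernel specifications validate and print their parameters", {
  q <- kernel_spec("quadratic", degree = 5)   # family pins the degree
  expect_equal(q$degree, 2L)
  expect_error(kernel_spec("polynomial", degree = 1), "degree")
  expect_error(kernel_spec("rbf", gamma = -1), "gamma")
  expect_error(kernel_spec("rbf", cost = 0), "cost")
  expect_output(print(kernel_spec("rbf", gamma = 0.5)), "rbf")
})

test_that("kernel_eval matches the closed-form kernels", {
  u <- c(1, 2, 3); v <- c(0.5, -1, 2)
  expect_equal(kernel_eval(kernel_spec("rbf", gamma = 0.7), u, u), 1)
  expect_equal(kernel_eval(kernel_spec("rbf", gamma = 0.7), u, v),
               exp(-0.7 * sum((u - v)^2)))
  expect_equal(kernel_eval(kernel_spec("polynomial", degree = 3, gamma = 0.2,
                                       coef0 = 1.5), u, v),
               (0.2 * sum(u * v) + 1.5)^3)
  # quadratic is the polynomial family at degree 2
  expect_equal(kernel_eval(kernel_spec("quadratic", gamma = 0.2, coef0 = 1.5), u, v),
               kernel_eval(kernel_spec("polynomial", degree = 2, gamma = 0.2,
                                       coef0 = 1.5), u, v))
  expect_error(kernel_eval(kernel_spec("rbf"), u, c(1, 2)), "dimension mismatch")
})

test_that("kernel matrices are symmetric positive semidefinite", {
  set.seed(33)
  x <- matrix(rnorm(10 * 3), 10)
  specs <- list(kernel_spec("quadratic", gamma = 0.5, coef0 = 1),
                kernel_spec("polynomial", degree = 4, gamma = 0.3, coef0 = 0.5),
                kernel_spec("rbf", gamma = 1.2))
  for (spec in specs) {
    K <- outer(seq_len(10), seq_len(10),
               Vectorize(function(i, j) kernel_eval(spec, x[i, ], x[j, ])))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
})

test_that("one-vs-all training builds one oriented machine per class", {
  df <- blob_dataset(k = 6, n_per_class = 10, seed = 2)
  for (fam in c("quadratic", "polynomial", "rbf")) {
    spec <- if (fam == "rbf") kernel_spec(fam, gamma = 0.5)
            else kernel_spec(fam, gamma = 0.5, coef0 = 1)
    fit <- train_ova(df, spec = spec)
    expect_length(fit$machines, 6L)
    expect_identical(fit$class_labels, levels(df$label))
    # separable clusters: perfect training accuracy for every family
    expect_equal(multiclass_rate(fit, df), 100)
    expect_true(all(fit$sv_count_per_class >= 1))
    expect_true(all(fit$sv_count_per_class <= nrow(df)))
  }
  expect_error(train_ova(df[df$label == "HC", , drop = FALSE],
                         spec = kernel_spec("rbf")), "2 distinct classes")
})

test_that("prediction picks the largest decision value with a stable tie-break", {
  df <- blob_dataset(k = 3, n_per_class = 15, seed = 4)
  fit <- train_ova(df, spec = kernel_spec("rbf", gamma = 0.3))
  # points deep inside a cluster keep their cluster's label
  pred <- predict(fit, df)
  expect_equal(as.character(pred), as.character(df$label))
  # predictions are invariant to test-set order
  set.seed(11)
  perm <- sample(nrow(df))
  expect_identical(as.character(predict(fit, df[perm, ])),
                   as.character(pred)[perm])
  expect_error(predict(fit, df[, 1, drop = FALSE]), "dimension mismatch")
})

test_that("retraining on duplicated data leaves decision values unchanged", {
  df <- blob_dataset(k = 3, n_per_class = 12, sep = 12, seed = 6)
  spec <- kernel_spec("rbf", gamma = 0.4, cost = 10)
  # tight dual tolerance so solver slack does not mask the identity
  fit1 <- train_ova(df, spec = spec, tolerance = 1e-8)
  fit2 <- train_ova(rbind(df, df), spec = spec, tolerance = 1e-8)
  d1 <- gesturekit:::decision_matrix(fit1, df)
  d2 <- gesturekit:::decision_matrix(fit2, df)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("training is deterministic for a fixed input order", {
  df <- small_semg_dataset(seed = 3, reps = 2)
  spec <- kernel_spec("quadratic", coef0 = 1)
  f1 <- train_ova(df, spec = spec)
  f2 <- train_ova(df, spec = spec)
  expect_identical(gesturekit:::decision_matrix(f1, df),
                   gesturekit:::decision_matrix(f2, df))
  expect_identical(f1$sv_count_per_class, f2$sv_count_per_class)
})

test_that("per-class binary rates behave like one-vs-rest accuracies", {
  df <- blob_dataset(k = 4, n_per_class = 10, seed = 8)
  fit <- train_ova(df, spec = kernel_spec("rbf", gamma = 0.3))
  rates <- per_class_binary_rate(fit, df)
  expect_length(rates, 4L)
  expect_true(all(rates >= 0 & rates <= 100))
  expect_equal(unname(rates), rep(100, 4))   # separable clusters

  # a machine that never fires scores exactly the negative prevalence
  dull <- fit
  dull$machines <- lapply(dull$machines, function(m) { m$sign <- 0; m })
  r0 <- per_class_binary_rate(dull, df)
  prevalence <- as.numeric(table(df$label)[fit$class_labels]) / nrow(df)
  expect_equal(unname(r0), 100 * (1 - prevalence))

  expect_error(per_class_binary_rate(fit, df[0, , drop = FALSE]), "empty")
})

test_that("support-vector accounting sums and averages per class", {
  df <- blob_dataset(k = 6, n_per_class = 8, seed = 10)
  fit <- train_ova(df, spec = kernel_spec("rbf", gamma = 0.3))
  expect_equal(total_sv_count(fit), sum(fit$sv_count_per_class))
  expect_equal(mean_sv_per_class(fit), total_sv_count(fit) / 6)

  fake <- fit
  fake$sv_count_per_class <- c(3, 4, 5, 6, 7, 5)
  expect_equal(mean_sv_per_class(fake), 5)

  # hard-margin limit on separable data needs fewer SVs than a tiny C
  # (kernel wide enough that the margin is carried by a few points)
  hard <- train_ova(df, spec = kernel_spec("rbf", gamma = 0.02, cost = 1e4))
  soft <- train_ova(df, spec = kernel_spec("rbf", gamma = 0.02, cost = 1e-3))
  expect_lt(total_sv_count(hard), total_sv_count(soft))
})

test_that("a fitted normalizer travels with the model", {
  df <- small_semg_dataset(seed = 12, reps = 2)
  norm <- fit_normalizer(df)
  fit <- train_ova(df, spec = kernel_spec("rbf", gamma = 1), normalizer = norm)
  expect_equal(multiclass_rate(fit, df), 100, tolerance = 2)
})
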