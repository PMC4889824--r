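#' Benchmark experiment configuration
#'
#' Fixes the feature combinations, kernel families, splitting and
#' cross-validation settings of the benchmark grid. The default feature
#' sets are the four combinations classically benchmarked for SEMG
#' time-domain classification: MAV alone, WL alone, MAV+WL+WAMP and
#' MAV+WL+SSC.
#'
#' @param feature_sets Named list of feature subsets (see [feature_config()]).
#' @param kernels Character vector of baseline kernel families.
#' @param test_fraction Fraction of samples held out for testing, in (0, 1);
#'   default 0.5.
#' @param n_repeats Number of repeated random splits; default 10.
#' @param cv_folds Folds of the cross-validation fitness; default 10.
#' @param rng_seed Integer base seed; repeat r uses `rng_seed + r`.
#' @param rate_type How per-gesture table entries are computed:
#'   `"ova_binary"` (default) scores each class's own one-vs-rest binary
#'   machine; `"multiclass_recall"` scores per-class recall of the
#'   aggregated multiclass prediction.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(feature_sets = list(
                                "MAV" = "MAV",
                                "WL" = "WL",
                                "MAV+WL+WAMP" = c("MAV", "WL", "WAMP"),
                                "MAV+WL+SSC" = c("MAV", "WL", "SSC")),
                              kernels = c("quadratic", "polynomial", "rbf"),
                              test_fraction = 0.5, n_repeats = 10L,
                              cv_folds = 10L, rng_seed = 1L,
                              rate_type = c("ova_binary", "multiclass_recall")) {
  stopifnot(is.list(feature_sets), length(feature_sets) >= 1L)
  if (is.null(names(feature_sets)) || anyDuplicated(names(feature_sets))) {
    stop("feature_sets must be uniquely named")
  }
  stopifnot(all(kernels %in% c("quadratic", "polynomial", "rbf")),
            test_fraction > 0, test_fraction < 1,
            n_repeats >= 1L, cv_folds >= 2L)
  structure(
    list(feature_sets = feature_sets, kernels = kernels,
         test_fraction = test_fraction, n_repeats = as.integer(n_repeats),
         cv_folds = as.integer(cv_folds), rng_seed = as.integer(rng_seed),
         rate_type = match.arg(rate_type)),
    class = "experiment_config"
  )
}

#' Stratified train/test split
#'
#' Randomly assigns `round(n_k * test_fraction)` samples of each class k to
#' the test side, preserving class proportions within one sample.
#'
#' @param data Labelled feature data frame (column `label`).
#' @param test_fraction Fraction in (0, 1).
#' @return List with data frames `train` and `test`. Uses (and advances)
#'   R's global RNG stream; seed beforehand for reproducibility.
#' @export
split_train_test <- function(data, test_fraction) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  y <- as.factor(data$label)
  test_idx <- integer(0)
  for (lab in levels(y)) {
    idx <- which(y == lab)
    n_test <- round(length(idx) * test_fraction)
    if (n_test < 1L || n_test >= length(idx)) {
      stop("class ", lab, " has too few samples (", length(idx),
           ") for a ", test_fraction, " split")
    }
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = data[-test_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE])
}

# Stratified fold assignment: per class, folds sized within one sample.
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  folds <- integer(length(y))
  for (lab in levels(y)) {
    idx <- which(y == lab)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Cross-validated classification rate of one kernel setting
#'
#' Stratified k-fold cross-validation of the one-vs-all SVM: per fold, train
#' on the remaining folds and score multiclass accuracy on the held-out
#' fold; the rate is the mean of the fold rates. The support-vector count
#' comes from a final fit on the full training material. Fold assignments
#' are redrawn from the current RNG stream on every call, so when used as an
#' optimisation fitness the objective is mildly stochastic — matching an
#' experimental procedure that redraws the inner split per evaluation.
#'
#' @param data Labelled feature data frame (training side).
#' @param spec A [kernel_spec()].
#' @param folds Number of folds (default 10). Classes smaller than `folds`
#'   degrade gracefully (some folds simply lack the class).
#' @param class_weights Passed to [train_ova()].
#' @return List with `rate` (mean fold accuracy, percent), `sv_total` and
#'   `sv_per_class` from the final full fit.
#' @export
cv_rate <- function(data, spec, folds = 10L, class_weights = FALSE) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  n <- nrow(data)
  if (folds > n) stop("folds (", folds, ") exceeds sample count (", n, ")")
  fold_id <- stratified_folds(data$label, folds)
  rates <- numeric(0)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    if (!any(hold)) next
    fit <- train_ova(data[!hold, , drop = FALSE], spec = spec,
                     class_weights = class_weights)
    rates <- c(rates, multiclass_rate(fit, data[hold, , drop = FALSE]))
  }
  final <- train_ova(data, spec = spec, class_weights = class_weights)
  list(rate = mean(rates), sv_total = total_sv_count(final),
       sv_per_class = mean_sv_per_class(final))
}

#' Default search space for SVM kernel selection
#'
#' Kernel family index 0/1/2 (quadratic / polynomial / rbf) and polynomial
#' degree 2..5 as integers; `gamma` in `[2^-15, 2^3]` and cost `C` in
#' `[2^-5, 2^15]` on log10 scale; `coef0` in `[0, 10]` linear.
#'
#' @return A [search_space()].
#' @export
kernel_search_space <- function() {
  search_space(
    integer_dims = list(
      list(name = "kernel", low = 0, high = 2),
      list(name = "degree", low = 2, high = 5)
    ),
    real_dims = list(
      list(name = "gamma", low = 2^-15, high = 2^3, scale = "log10"),
      list(name = "coef0", low = 0, high = 10, scale = "linear"),
      list(name = "cost", low = 2^-5, high = 2^15, scale = "log10")
    )
  )
}

#' Decode optimizer parameters into a kernel specification
#'
#' @param params Named list with `kernel` (0 = quadratic, 1 = polynomial,
#'   2 = rbf), `degree`, `gamma`, `coef0`, `cost`, as produced by
#'   [decode_position()] over [kernel_search_space()].
#' @return A [kernel_spec()].
#' @export
params_to_kernel_spec <- function(params) {
  family <- c("quadratic", "polynomial", "rbf")[params$kernel + 1L]
  kernel_spec(family, degree = params$degree, gamma = params$gamma,
              coef0 = params$coef0, cost = params$cost)
}

# Default baseline spec per family: library-convention gamma (1/d), zero
# offset, unit cost, cubic polynomial.
default_kernel_spec <- function(family) {
  switch(family,
         quadratic = kernel_spec("quadratic", gamma = NULL, coef0 = 1, cost = 1),
         polynomial = kernel_spec("polynomial", degree = 3L, gamma = NULL,
                                  coef0 = 1, cost = 1),
         rbf = kernel_spec("rbf", gamma = NULL, cost = 1))
}

# Per-gesture rates for one fitted model under the configured convention.
gesture_rates <- function(model, test, rate_type) {
  if (rate_type == "ova_binary") {
    per_class_binary_rate(model, test)
  } else {
    pred <- predict(model, test)
    y <- as.character(test$label)
    vapply(model$class_labels, function(lab) {
      100 * mean(as.character(pred)[y == lab] == lab)
    }, numeric(1))
  }
}

# One repeated-split evaluation of a fixed kernel spec on a feature frame.
evaluate_kernel <- function(data, spec, cfg) {
  per_rep <- lapply(seq_len(cfg$n_repeats), function(r) {
    set.seed(cfg$rng_seed + r)
    sp <- split_train_test(data, cfg$test_fraction)
    fit <- train_ova(sp$train, spec = spec)
    rates <- gesture_rates(fit, sp$test, cfg$rate_type)
    list(rates = rates, mean_rate = mean(rates),
         multiclass = multiclass_rate(fit, sp$test),
         sv_per_class = mean_sv_per_class(fit))
  })
  summarise_reps(per_rep)
}

summarise_reps <- function(per_rep) {
  rate_mat <- do.call(rbind, lapply(per_rep, `[[`, "rates"))
  mean_rates <- colMeans(rate_mat)
  rep_means <- vapply(per_rep, `[[`, numeric(1), "mean_rate")
  list(
    gesture_rates = mean_rates,
    mean_rate = mean(mean_rates),
    sd_rate = if (length(rep_means) > 1L) stats::sd(rep_means) else 0,
    multiclass_rate = mean(vapply(per_rep, `[[`, numeric(1), "multiclass")),
    mean_sv_per_class = mean(vapply(per_rep, `[[`, numeric(1), "sv_per_class"))
  )
}

#' Baseline kernel benchmark grid
#'
#' For every configured feature set and kernel family: repeat `n_repeats`
#' times — fresh stratified split, train the one-vs-all SVM with the
#' family's default parameters on the training side, score per-gesture and
#' multiclass rates on the test side — then average. This reproduces the
#' layout of a fixed-kernel SEMG benchmark table: one row per feature set,
#' per-gesture columns, their mean, the SD of the repeat means, and the mean
#' support-vector count per class.
#'
#' @param segments Segment list from [sliding_segments()] (REST segments are
#'   excluded), or a named list of pre-extracted labelled feature data
#'   frames, one per feature set.
#' @param cfg An [experiment_config()].
#' @return `data.frame` with columns `feature_set`, `kernel`, one column per
#'   gesture, `mean_rate`, `sd_rate`, `multiclass_rate`,
#'   `mean_sv_per_class`.
#' @export
run_baseline_grid <- function(segments, cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  datasets <- feature_frames(segments, cfg)
  rows <- list()
  for (fs in names(datasets)) {
    for (kern in cfg$kernels) {
      res <- evaluate_kernel(datasets[[fs]], default_kernel_spec(kern), cfg)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(feature_set = fs, kernel = kern, stringsAsFactors = FALSE),
        as.data.frame(as.list(res$gesture_rates)),
        data.frame(mean_rate = res$mean_rate, sd_rate = res$sd_rate,
                   multiclass_rate = res$multiclass_rate,
                   mean_sv_per_class = res$mean_sv_per_class)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Build one labelled feature frame per configured feature set.
feature_frames <- function(segments, cfg) {
  if (is.data.frame(segments)) {
    stop("pass a segment list or a named list of feature data frames")
  }
  if (length(segments) > 0L && is.data.frame(segments[[1L]])) {
    missing <- setdiff(names(cfg$feature_sets), names(segments))
    if (length(missing) > 0L) {
      stop("no feature frame supplied for feature set(s): ",
           paste(missing, collapse = ", "))
    }
    return(segments[names(cfg$feature_sets)])
  }
  out <- lapply(cfg$feature_sets, function(feats) {
    extract_dataset(segments, feature_config(feats), drop_rest = TRUE)
  })
  names(out) <- names(cfg$feature_sets)
  out
}

#' Cuckoo-Search-optimised SVM experiment
#'
#' The full optimisation procedure, repeated over `cfg$n_repeats` fresh
#' stratified splits: on each training side, run [cs_optimize()] with the
#' k-fold cross-validated multiclass rate as primary fitness and the total
#' support-vector count as the tie-breaking secondary objective; retrain the
#' winning kernel specification on the full training side; score the test
#' side. Splits are drawn from the same per-repeat seeds as
#' [run_baseline_grid()], so baseline and optimised rows are paired run for
#' run.
#'
#' @param data Labelled feature data frame (one feature set, e.g. MAV).
#' @param cfg An [experiment_config()].
#' @param cs_cfg A [cs_config()]; its `rng_seed` is ignored (each repeat is
#'   seeded from `cfg$rng_seed`).
#' @param space Search space over kernel parameters; default
#'   [kernel_search_space()].
#' @return List with the summary fields of [run_baseline_grid()] plus
#'   `best_specs` (per-repeat winning [kernel_spec()]s), `best_cv_rates`
#'   and `row` (a one-row data frame in the grid layout, kernel `"CS"`).
#' @export
run_cs_experiment <- function(data, cfg = experiment_config(),
                              cs_cfg = cs_config(), space = kernel_search_space()) {
  stopifnot(is.data.frame(data), "label" %in% names(data),
            inherits(cfg, "experiment_config"), inherits(cs_cfg, "cs_config"))
  cs_cfg$rng_seed <- NULL   # per-repeat seeding below governs the stream
  per_rep <- vector("list", cfg$n_repeats)
  best_specs <- vector("list", cfg$n_repeats)
  best_cv <- numeric(cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    set.seed(cfg$rng_seed + r)
    sp <- split_train_test(data, cfg$test_fraction)
    fitness <- function(params) {
      res <- cv_rate(sp$train, params_to_kernel_spec(params), folds = cfg$cv_folds)
      c(res$rate, res$sv_total)
    }
    opt <- cs_optimize(fitness, space, cs_cfg)
    spec <- params_to_kernel_spec(opt$best$params)
    fit <- train_ova(sp$train, spec = spec)
    rates <- gesture_rates(fit, sp$test, cfg$rate_type)
    per_rep[[r]] <- list(rates = rates, mean_rate = mean(rates),
                         multiclass = multiclass_rate(fit, sp$test),
                         sv_per_class = mean_sv_per_class(fit))
    best_specs[[r]] <- spec
    best_cv[r] <- opt$best$primary
  }
  res <- summarise_reps(per_rep)
  res$best_specs <- best_specs
  res$best_cv_rates <- best_cv
  res$row <- cbind(
    data.frame(feature_set = "optimised", kernel = "CS", stringsAsFactors = FALSE),
    as.data.frame(as.list(res$gesture_rates)),
    data.frame(mean_rate = res$mean_rate, sd_rate = res$sd_rate,
               multiclass_rate = res$multiclass_rate,
               mean_sv_per_class = res$mean_sv_per_class)
  )
  res
}
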