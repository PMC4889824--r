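#' Kernel specification for the soft-margin SVM
#'
#' The three kernel families the classifier supports:
#'
#' * `quadratic`: `(gamma * <u, v> + coef0)^2` — the polynomial family fixed
#'   at degree 2;
#' * `polynomial`: `(gamma * <u, v> + coef0)^degree`;
#' * `rbf`: `exp(-gamma * ||u - v||^2)` (degree and coef0 unused).
#'
#' @param family One of `"quadratic"`, `"polynomial"`, `"rbf"`.
#' @param degree Integer degree >= 2 (polynomial family; forced to 2 for
#'   quadratic).
#' @param gamma Positive kernel scale, or `NULL` to use `1/d` (d = feature
#'   dimension) at training time.
#' @param coef0 Offset of the polynomial families (default 0).
#' @param cost Positive soft-margin box constraint C (default 1).
#' @return Object of class `kernel_spec`.
#' @examples
#' kernel_spec("rbf", gamma = 0.5)
#' kernel_spec("quadratic", coef0 = 1)
#' @export
kernel_spec <- function(family = c("quadratic", "polynomial", "rbf"),
                        degree = 3L, gamma = NULL, coef0 = 0, cost = 1) {
  family <- match.arg(family)
  if (family == "quadratic") degree <- 2L
  degree <- as.integer(degree)
  if (family == "polynomial" && (is.na(degree) || degree < 2L)) {
    stop("polynomial degree must be an integer >= 2")
  }
  if (!is.null(gamma)) {
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
      stop("`gamma` must be a single positive number (or NULL for 1/d)")
    }
  }
  if (!is.numeric(coef0) || length(coef0) != 1L || !is.finite(coef0)) {
    stop("`coef0` must be a single finite number")
  }
  if (!is.numeric(cost) || length(cost) != 1L || !is.finite(cost) || cost <= 0) {
    stop("`cost` must be a single positive number")
  }
  structure(
    list(family = family, degree = degree, gamma = gamma,
         coef0 = as.numeric(coef0), cost = as.numeric(cost)),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  g <- if (is.null(x$gamma)) "1/d" else format(x$gamma)
  extra <- switch(x$family,
                  rbf = sprintf("gamma=%s", g),
                  sprintf("degree=%d, gamma=%s, coef0=%g", x$degree, g, x$coef0))
  cat(sprintf("kernel_spec: %s (%s), C=%g\n", x$family, extra, x$cost))
  invisible(x)
}

#' Evaluate a kernel function on a pair of vectors
#'
#' @param spec A [kernel_spec()].
#' @param u,v Numeric vectors of equal length.
#' @return Scalar kernel value.
#' @examples
#' kernel_eval(kernel_spec("rbf", gamma = 1), c(1, 2), c(1, 2))  # exactly 1
#' @export
kernel_eval <- function(spec, u, v) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(u) != length(v)) {
    stop("dimension mismatch: length(u) = ", length(u), ", length(v) = ", length(v))
  }
  g <- if (is.null(spec$gamma)) 1 / length(u) else spec$gamma
  switch(spec$family,
         quadratic = (g * sum(u * v) + spec$coef0)^2,
         polynomial = (g * sum(u * v) + spec$coef0)^spec$degree,
         rbf = exp(-g * sum((u - v)^2)))
}

# Map a kernel_spec to e1071::svm() arguments.
svm_args <- function(spec, d) {
  g <- if (is.null(spec$gamma)) 1 / d else spec$gamma
  switch(spec$family,
         quadratic = list(kernel = "polynomial", degree = 2L, gamma = g,
                          coef0 = spec$coef0, cost = spec$cost),
         polynomial = list(kernel = "polynomial", degree = spec$degree, gamma = g,
                           coef0 = spec$coef0, cost = spec$cost),
         rbf = list(kernel = "radial", gamma = g, cost = spec$cost))
}

#' Train a one-against-all multiclass kernel SVM
#'
#' Trains one binary soft-margin SVM per class (that class versus all
#' others) and aggregates them by the largest real-valued decision score at
#' prediction time. The underlying binary solver is the libsvm dual solver
#' from \pkg{e1071}; the support-vector count per class is the number of
#' training points with nonzero dual coefficient in that class's binary
#' machine.
#'
#' @param x Numeric feature matrix or a feature data frame with a `label`
#'   column (as produced by [extract_dataset()]).
#' @param y Factor (or character) of class labels; may be omitted when `x`
#'   carries a `label` column.
#' @param spec A [kernel_spec()].
#' @param class_weights If `TRUE`, weight the binary problems by inverse
#'   class prevalence to counter the 1:(K-1) imbalance of the one-vs-all
#'   relabeling. Default `FALSE`.
#' @param normalizer Optional fitted [fit_normalizer()] applied to `x` now
#'   and to new data at prediction time.
#' @param ... Further arguments for the underlying [e1071::svm()] solver
#'   (e.g. `tolerance` for a tighter dual solve).
#' @return Object of class `ova_svm` with elements `class_labels`,
#'   `machines`, `sv_count_per_class`, `kernel` (gamma resolved), and
#'   `normalizer`.
#' @export
train_ova <- function(x, y = NULL, spec = kernel_spec("rbf"),
                      class_weights = FALSE, normalizer = NULL, ...) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (is.null(y)) {
    if (!is.data.frame(x) || !"label" %in% names(x)) {
      stop("`y` missing and `x` has no label column")
    }
    y <- x$label
  }
  m <- feature_matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(m) != length(y)) stop("x and y sizes disagree")
  if (!all(is.finite(m))) stop("non-finite feature values")
  labs <- levels(y)
  if (length(labs) < 2L) stop("need at least 2 distinct classes, got ", length(labs))
  if (!is.null(normalizer)) m <- apply_normalizer(normalizer, m)
  args <- svm_args(spec, ncol(m))
  machines <- vector("list", length(labs))
  names(machines) <- labs
  sv_counts <- integer(length(labs))
  for (k in seq_along(labs)) {
    yk <- factor(ifelse(y == labs[k], "pos", "neg"), levels = c("pos", "neg"))
    wts <- if (class_weights) {
      tab <- table(yk)
      stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
    } else NULL
    fit <- do.call(e1071::svm, c(
      list(x = m, y = yk, type = "C-classification", scale = FALSE,
           class.weights = wts, fitted = FALSE),
      args, list(...)
    ))
    # libsvm orients the decision value toward whichever level it saw first;
    # record the sign that makes positive mean "this class".
    dv_name <- colnames(attr(
      stats::predict(fit, m[1L, , drop = FALSE], decision.values = TRUE),
      "decision.values"))
    machines[[k]] <- list(fit = fit,
                          sign = if (identical(dv_name, "neg/pos")) -1 else 1)
    sv_counts[k] <- fit$tot.nSV
  }
  structure(
    list(class_labels = labs, machines = machines,
         sv_count_per_class = stats::setNames(sv_counts, labs),
         kernel = within_spec_gamma(spec, ncol(m)),
         normalizer = normalizer, n_features = ncol(m),
         feature_names = colnames(m), n_train = nrow(m)),
    class = "ova_svm"
  )
}

within_spec_gamma <- function(spec, d) {
  if (is.null(spec$gamma)) spec$gamma <- 1 / d
  spec
}

#' @export
print.ova_svm <- function(x, ...) {
  cat(sprintf("ova_svm: %d classes (%s), %d features, kernel %s, %d SVs total\n",
              length(x$class_labels), paste(x$class_labels, collapse = ", "),
              x$n_features, x$kernel$family, sum(x$sv_count_per_class)))
  invisible(x)
}

# n x K matrix of decision values, oriented so larger means "more that class".
decision_matrix <- function(model, newx) {
  m <- feature_matrix(newx)
  if (ncol(m) != model$n_features) {
    stop("dimension mismatch: model expects ", model$n_features,
         " features, got ", ncol(m))
  }
  if (!is.null(model$normalizer)) m <- apply_normalizer(model$normalizer, m)
  dv <- vapply(model$machines, function(mk) {
    raw <- attr(stats::predict(mk$fit, m, decision.values = TRUE), "decision.values")
    mk$sign * as.numeric(raw[, 1L])
  }, numeric(nrow(m)))
  dv <- matrix(dv, nrow = nrow(m), dimnames = list(NULL, model$class_labels))
  dv
}

#' Predict gesture labels with a one-vs-all model
#'
#' Each test point receives the label of the binary machine with the largest
#' decision value; exact ties go to the earlier label in `class_labels`.
#'
#' @param object A trained [train_ova()] model.
#' @param newdata Feature matrix or data frame (a `label` column is ignored).
#' @param ... Unused.
#' @return Factor of predicted labels with levels `class_labels`.
#' @export
predict.ova_svm <- function(object, newdata, ...) {
  dv <- decision_matrix(object, newdata)
  idx <- apply(dv, 1L, which.max)   # which.max takes the first maximum: tie contract
  factor(object$class_labels[idx], levels = object$class_labels)
}

#' Per-class one-vs-rest binary classification rates
#'
#' For each class k, the percentage of test samples that the k-th binary
#' machine classifies correctly in its own k-versus-rest problem. These are
#' the per-gesture entries of the benchmark tables.
#'
#' @param model A trained [train_ova()] model.
#' @param newdata Labelled feature data frame, or a feature matrix when `y`
#'   is given.
#' @param y True labels (optional when `newdata` has a `label` column).
#' @return Named numeric vector of rates in `[0, 100]`, one per class.
#' @export
per_class_binary_rate <- function(model, newdata, y = NULL) {
  if (is.null(y)) {
    if (!is.data.frame(newdata) || !"label" %in% names(newdata)) {
      stop("`y` missing and `newdata` has no label column")
    }
    y <- newdata$label
  }
  y <- as.character(y)
  if (length(y) == 0L) stop("empty test set")
  dv <- decision_matrix(model, newdata)
  rates <- vapply(seq_along(model$class_labels), function(k) {
    lab <- model$class_labels[k]
    predicted_pos <- dv[, k] > 0
    truly_pos <- y == lab
    100 * mean(predicted_pos == truly_pos)
  }, numeric(1))
  stats::setNames(rates, model$class_labels)
}

#' Multiclass classification rate
#'
#' Percentage of test samples whose aggregated one-vs-all prediction equals
#' the true label.
#'
#' @inheritParams per_class_binary_rate
#' @return Scalar rate in `[0, 100]`.
#' @export
multiclass_rate <- function(model, newdata, y = NULL) {
  if (is.null(y)) {
    if (!is.data.frame(newdata) || !"label" %in% names(newdata)) {
      stop("`y` missing and `newdata` has no label column")
    }
    y <- newdata$label
  }
  if (length(y) == 0L) stop("empty test set")
  pred <- predict(model, newdata)
  100 * mean(as.character(pred) == as.character(y))
}

#' Support-vector counts of a trained model
#'
#' @param model A trained [train_ova()] model.
#' @return `total_sv_count()`: sum of the per-class binary machines'
#'   support-vector counts; `mean_sv_per_class()`: that total divided by the
#'   number of classes.
#' @export
total_sv_count <- function(model) {
  stopifnot(inherits(model, "ova_svm"))
  sum(model$sv_count_per_class)
}

#' @rdname total_sv_count
#' @export
mean_sv_per_class <- function(model) {
  stopifnot(inherits(model, "ova_svm"))
  mean(model$sv_count_per_class)
}
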