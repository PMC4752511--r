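#' Classification evaluation configuration
#'
#' Protocol settings shared by the binary and multiclass evaluators: an
#' outer stratified shuffle-split loop (default 200 repeats holding out 20%
#' for testing), an inner 10-fold stratified cross-validation on each
#' training split that selects the L2 regularization strength from a fixed
#' logarithmic grid, and the random-forest size for multiclass staging.
#'
#' @param n_repeats outer shuffle-split repeats.
#' @param test_frac held-out fraction per repeat.
#' @param inner_folds folds of the inner stratified CV.
#' @param lambda_grid decreasing grid of L2 penalties (13 log-spaced values
#'   spanning 1e-3 to 1e3 by default).
#' @param n_trees random-forest size for multiclass evaluation.
#' @param seed integer seed; fixes every split and fit.
#' @return an object of class `classify_config`.
#' @export
classify_config <- function(n_repeats = 200, test_frac = 0.2,
                            inner_folds = 10,
                            lambda_grid = 10^seq(3, -3, length.out = 13),
                            n_trees = 500, seed = 1) {
  stopifnot(n_repeats >= 1, test_frac > 0, test_frac < 1)
  structure(list(n_repeats = n_repeats, test_frac = test_frac,
                 inner_folds = inner_folds,
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 n_trees = n_trees, seed = as.integer(seed)),
            class = "classify_config")
}

# Rank-based (Mann-Whitney) AUC; `labels` coerced so the second factor level
# is the positive class.
auc_score <- function(labels, scores) {
  y <- as.integer(as.factor(labels)) - 1L
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified assignment of indices to k folds.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified shuffle split: per class, a random `frac` share goes to test
# (at least one observation per class on each side).
stratified_split <- function(y, frac) {
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- max(1L, min(length(idx) - 1L, round(frac * length(idx))))
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

# z-score using training statistics only (leakage guard); constant columns
# pass through centred.
zscore_train_test <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sd, "/"))
}

# glmnet needs >= 2 columns; a zero column is inert under an L2 penalty.
pad_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) >= 2) x else cbind(x, .pad = 0)
}

# Inner loop: stratified k-fold CV over the lambda grid on the training
# split; returns the lambda with the highest mean validation AUC (ties break
# towards the stronger penalty).
select_lambda <- function(x, y, config) {
  k <- min(config$inner_folds, min(table(y)))
  if (k < 2) return(config$lambda_grid[length(config$lambda_grid)])
  fold <- stratified_folds(y, k)
  aucs <- matrix(NA_real_, nrow = k, ncol = length(config$lambda_grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
    fit <- glmnet::glmnet(pad_matrix(x[tr, , drop = FALSE]), y[tr],
                          family = "binomial", alpha = 0,
                          lambda = config$lambda_grid, standardize = FALSE)
    pred <- stats::predict(fit, pad_matrix(x[!tr, , drop = FALSE]),
                           s = config$lambda_grid)
    aucs[f, ] <- apply(pred, 2, function(s) auc_score(y[!tr], s))
  }
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  config$lambda_grid[which.max(mean_auc)]
}

#' Evaluate a binary classifier on a feature set
#'
#' L2-regularized logistic regression evaluated by repeated stratified
#' shuffle-split: on each of `n_repeats` outer splits, features are z-scored
#' with training statistics, the penalty strength is chosen by inner
#' stratified cross-validation, the selected model is refit on the full
#' training split, and its AUC is measured on the held-out subjects. The
#' mean and SD of the held-out AUC over repeats summarize discriminability.
#'
#' @param x data frame or matrix of per-subject features (no missing
#'   values).
#' @param y binary labels (two-level factor or coercible); fewer than 20
#'   subjects in a class triggers a warning.
#' @param config a [classify_config()].
#' @param splits optional list of precomputed test-index vectors (used by
#'   [compare_feature_sets()] to share splits across feature sets).
#' @return an object of class `classifier_report`: `mean_auc`, `sd_auc`,
#'   per-repeat `aucs`, `n_repeats`, `seed`.
#' @export
evaluate_binary <- function(x, y, config = classify_config(),
                            splits = NULL) {
  x <- as.matrix(as.data.frame(x))
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2, nrow(x) == length(y), !anyNA(x))
  if (min(table(y)) < 20)
    warning("fewer than 20 subjects in a class; AUC estimates will be noisy",
            call. = FALSE)
  if (is.null(splits)) splits <- make_splits(y, config)
  aucs <- with_seed(config$seed + 1L, vapply(splits, function(test) {
    tr_x <- x[-test, , drop = FALSE]; te_x <- x[test, , drop = FALSE]
    z <- zscore_train_test(tr_x, te_x)
    lam <- select_lambda(z$train, y[-test], config)
    fit <- glmnet::glmnet(pad_matrix(z$train), y[-test],
                          family = "binomial", alpha = 0,
                          lambda = config$lambda_grid, standardize = FALSE)
    auc_score(y[test], stats::predict(fit, pad_matrix(z$test), s = lam))
  }, numeric(1)))
  structure(list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
                 aucs = aucs, n_repeats = config$n_repeats,
                 seed = config$seed, type = "binary"),
            class = "classifier_report")
}

make_splits <- function(y, config) {
  with_seed(config$seed,
            lapply(seq_len(config$n_repeats),
                   function(i) stratified_split(y, config$test_frac)))
}

#' Evaluate a multiclass classifier on a feature set
#'
#' Random forest evaluated under the same outer shuffle-split protocol as
#' [evaluate_binary()]: per repeat the forest is trained on 80% of subjects
#' and its accuracy measured on the held-out 20%; predictions are pooled
#' into a single true-by-predicted confusion matrix across repeats.
#'
#' @inheritParams evaluate_binary
#' @param y class labels with at least 3 levels.
#' @return an object of class `classifier_report`: `mean_accuracy`,
#'   `sd_accuracy`, per-repeat `accuracies`, pooled `confusion`.
#' @export
evaluate_multiclass <- function(x, y, config = classify_config(),
                                splits = NULL) {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) >= 3, nrow(x) == length(y), !anyNA(x))
  if (is.null(splits)) splits <- make_splits(y, config)
  conf <- matrix(0L, nlevels(y), nlevels(y),
                 dimnames = list(true = levels(y), predicted = levels(y)))
  accs <- with_seed(config$seed + 1L, vapply(splits, function(test) {
    fit <- randomForest::randomForest(x[-test, , drop = FALSE], y[-test],
                                      ntree = config$n_trees)
    pred <- stats::predict(fit, x[test, , drop = FALSE])
    conf <<- conf + unclass(table(y[test], pred))
    mean(pred == y[test])
  }, numeric(1)))
  structure(list(mean_accuracy = mean(accs), sd_accuracy = stats::sd(accs),
                 accuracies = accs, confusion = conf,
                 n_repeats = config$n_repeats, seed = config$seed,
                 type = "multiclass"),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  if (x$type == "binary") {
    cat(sprintf("Binary classifier: mean AUC = %.3f (SD %.3f) over %d repeats\n",
                x$mean_auc, x$sd_auc, x$n_repeats))
  } else {
    cat(sprintf("Multiclass classifier: mean accuracy = %.3f (SD %.3f) over %d repeats\n",
                x$mean_accuracy, x$sd_accuracy, x$n_repeats))
    print(x$confusion)
  }
  invisible(x)
}

#' Compare feature sets on identical outer splits
#'
#' Evaluates several feature sets for the same subjects and labels on a
#' shared sequence of outer splits (common random numbers), so per-split AUC
#' differences are paired. Reports the per-set AUC summary and a matrix of
#' paired two-sided t-test p-values for all set pairs.
#'
#' @param sets named list of feature tables, all with the same rows
#'   (subjects) in the same order.
#' @param y binary labels shared by all sets.
#' @param config a [classify_config()].
#' @return an object of class `feature_comparison`: `$summary` (one row per
#'   set: `mean_auc`, `sd_auc`), `$aucs` (repeats x sets), `$p_values`
#'   (pairwise paired t tests).
#' @export
compare_feature_sets <- function(sets, y, config = classify_config()) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  n <- unique(vapply(sets, function(s) nrow(as.data.frame(s)), integer(1)))
  if (length(n) != 1 || n != length(y))
    stop("all feature sets must cover the same subjects as the labels",
         call. = FALSE)
  y <- droplevels(as.factor(y))
  splits <- make_splits(y, config)
  aucs <- sapply(sets, function(s)
    evaluate_binary(s, y, config, splits = splits)$aucs)
  nm <- names(sets)
  p <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i == j) { p[i, j] <- 1; next }
    d <- aucs[, i] - aucs[, j]
    p[i, j] <- if (stats::sd(d) == 0) 1
               else stats::t.test(d)$p.value
  }
  structure(list(
    summary = data.frame(feature_set = nm,
                         mean_auc = colMeans(aucs),
                         sd_auc = apply(aucs, 2, stats::sd),
                         row.names = NULL),
    aucs = aucs, p_values = p, n_repeats = config$n_repeats,
    seed = config$seed), class = "feature_comparison")
}

#' @export
print.feature_comparison <- function(x, ...) {
  cat(sprintf("Feature-set comparison on %d shared splits\n", x$n_repeats))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
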