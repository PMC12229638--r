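# Repeated stratified train/test evaluation of random-forest and ridge
# logistic-regression classifiers on small cohort feature tables.

#' Evaluation configuration for repeated splits
#'
#' Defaults mirror the small-cohort protocol: 14 training and 6 test
#' samples drawn stratified from a 10 + 10 cohort, 200 trials, 500-tree
#' random forest or L2 (ridge) logistic regression with unit
#' regularization.
#'
#' @param model `"rf"` or `"lr"`.
#' @param n_trials Number of repeated splits.
#' @param n_train,n_test Split sizes; their sum must not exceed the cohort.
#' @param stratified Keep class proportions in each split (default TRUE).
#' @param seed Integer seed; the whole evaluation is a pure function of
#'   (data, config, seed).
#' @param rf_trees Trees per forest.
#' @param lr_lambda Ridge penalty for the logistic model.
#' @return An `eval_config` list.
#' @export
eval_config <- function(model = c("rf", "lr"), n_trials = 200L,
                        n_train = 14L, n_test = 6L, stratified = TRUE,
                        seed = 1L, rf_trees = 500L, lr_lambda = 1) {
  model <- match.arg(model)
  stopifnot(n_trials >= 1, n_train >= 2, n_test >= 1, rf_trees >= 1,
            lr_lambda > 0)
  structure(list(model = model, n_trials = as.integer(n_trials),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 stratified = isTRUE(stratified), seed = as.integer(seed),
                 rf_trees = as.integer(rf_trees), lr_lambda = lr_lambda),
            class = "eval_config")
}

# Stratified split of indices: n_train per-class counts proportional to
# class sizes (largest-remainder rounding), test drawn from the remainder.
.stratified_split <- function(groups, n_train, n_test) {
  lev <- unique(groups)
  n <- length(groups)
  prop <- vapply(lev, function(l) sum(groups == l), numeric(1)) / n
  tr_n <- floor(prop * n_train)
  rem <- n_train - sum(tr_n)
  if (rem > 0) {
    o <- order(prop * n_train - tr_n, decreasing = TRUE)
    tr_n[o[seq_len(rem)]] <- tr_n[o[seq_len(rem)]] + 1L
  }
  te_n <- floor(prop * n_test)
  rem <- n_test - sum(te_n)
  if (rem > 0) {
    o <- order(prop * n_test - te_n, decreasing = TRUE)
    te_n[o[seq_len(rem)]] <- te_n[o[seq_len(rem)]] + 1L
  }
  train <- integer(0); test <- integer(0)
  for (i in seq_along(lev)) {
    idx <- which(groups == lev[i])
    idx <- sample(idx)
    train <- c(train, idx[seq_len(tr_n[i])])
    test <- c(test, idx[tr_n[i] + seq_len(te_n[i])])
  }
  list(train = train, test = test)
}

.fit_predict <- function(xtr, ytr, xte, config) {
  # standardize on the training fold only (no leakage)
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xtr <- scale(xtr, mu, sdv)
  xte <- scale(xte, mu, sdv)
  if (config$model == "rf") {
    fit <- randomForest::randomForest(x = xtr, y = factor(ytr),
                                      ntree = config$rf_trees)
    as.character(stats::predict(fit, xte))
  } else {
    # glmnet warns about classes under 8 observations; 7-per-class training
    # folds are the design here, so the warning is expected and muted
    fit <- suppressWarnings(
      glmnet::glmnet(xtr, factor(ytr), family = "binomial",
                     alpha = 0, lambda = config$lr_lambda,
                     standardize = FALSE))
    as.character(stats::predict(fit, xte, type = "class",
                                s = config$lr_lambda))
  }
}

#' Repeated stratified train/test evaluation
#'
#' For each trial: a seeded stratified split, standardization fitted on the
#' training fold only, model fit, test accuracy. Reports per-trial
#' accuracies, their mean and SD (percent), and full-data feature
#' importances. Identical (data, config, seed) give identical reports.
#'
#' @param table Cohort data.frame: `sample_id`, `group`, optional `matrix`,
#'   then numeric feature columns.
#' @param config An [eval_config()].
#' @return A `thiol_eval` object with `print()` method; fields
#'   `per_trial_accuracy` (fractions), `mean_accuracy` / `sd_accuracy`
#'   (percent), `feature_importance` (sorted, sums to 1), `confusion`
#'   (summed test-fold confusion counts).
#' @export
repeated_eval <- function(table, config = eval_config()) {
  .check_cohort(table)
  feats <- .cohort_features(table)
  x <- as.matrix(table[, feats, drop = FALSE])
  if (!all(is.finite(x))) stop("features must be numeric and finite", call. = FALSE)
  groups <- table$group
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two classes required", call. = FALSE)
  if (any(table(groups) < 2L)) stop(">= 2 samples per class required", call. = FALSE)
  if (config$n_train + config$n_test > nrow(x))
    stop("n_train + n_test exceeds the number of samples", call. = FALSE)
  # verify the requested sizes keep both classes in every training fold
  chk <- .stratified_split(groups, config$n_train, config$n_test)
  if (length(unique(groups[chk$train])) < 2L)
    stop("requested split sizes leave a class out of the training set",
         call. = FALSE)
  set.seed(config$seed)
  acc <- numeric(config$n_trials)
  conf <- matrix(0L, 2L, 2L, dimnames = list(truth = lev, predicted = lev))
  for (k in seq_len(config$n_trials)) {
    sp <- if (config$stratified)
      .stratified_split(groups, config$n_train, config$n_test)
    else {
      idx <- sample(nrow(x), config$n_train + config$n_test)
      list(train = idx[seq_len(config$n_train)],
           test = idx[config$n_train + seq_len(config$n_test)])
    }
    pred <- .fit_predict(x[sp$train, , drop = FALSE], groups[sp$train],
                         x[sp$test, , drop = FALSE], config)
    truth <- groups[sp$test]
    acc[k] <- mean(pred == truth)
    for (i in seq_along(truth)) conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
  }
  imp <- feature_importance(table, config)
  structure(list(per_trial_accuracy = acc,
                 mean_accuracy = 100 * mean(acc),
                 sd_accuracy = 100 * stats::sd(acc),
                 feature_importance = imp,
                 confusion = conf,
                 config = config),
            class = "thiol_eval")
}

#' @export
print.thiol_eval <- function(x, ...) {
  cat(sprintf("<thiol_eval> %s, %d trials (train %d / test %d, seed %d)\n",
              x$config$model, x$config$n_trials, x$config$n_train,
              x$config$n_test, x$config$seed))
  cat(sprintf("  accuracy %.2f%% (SD %.2f%%)\n", x$mean_accuracy, x$sd_accuracy))
  cat("  top features:",
      paste(utils::head(names(x$feature_importance), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Normalized feature importance on the full cohort
#'
#' Random forest: mean decrease in node impurity (Gini) averaged over
#' trees. Logistic regression: absolute ridge coefficient on standardized
#' features. Both normalized to sum to 1 and sorted descending; constant
#' features get importance 0.
#'
#' @inheritParams repeated_eval
#' @return Named numeric vector, descending.
#' @export
feature_importance <- function(table, config = eval_config()) {
  .check_cohort(table)
  feats <- .cohort_features(table)
  x <- as.matrix(table[, feats, drop = FALSE])
  mu <- colMeans(x); sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
  xs <- scale(x, mu, sdv)
  y <- factor(table$group)
  set.seed(config$seed)
  if (config$model == "rf") {
    fit <- randomForest::randomForest(x = xs, y = y, ntree = config$rf_trees,
                                      importance = FALSE)
    imp <- fit$importance[, "MeanDecreaseGini"]
  } else {
    fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                          lambda = config$lr_lambda, standardize = FALSE)
    co <- as.matrix(stats::coef(fit, s = config$lr_lambda))[-1L, 1L]
    imp <- abs(co)
  }
  imp <- stats::setNames(as.numeric(imp), feats)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  sort(imp, decreasing = TRUE)
}
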