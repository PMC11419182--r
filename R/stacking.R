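# Stacking ensemble: base learners -> repeated stratified k-fold bagging with
# out-of-fold (OOF) predictions -> one stacking layer whose inputs are the
# base OOF columns concatenated with the original features (skip features) ->
# greedy ensemble selection over the stack models. Two levels only: stacking
# deeper mostly buys overfitting on cohort-sized tables.

#' Stacking-ensemble configuration
#'
#' @param base_learners Learner names for the base layer (default the five
#'   families: logistic/linear model, k-NN, random forest, boosted trees,
#'   MLP).
#' @param stack_learners Learner names for the (single) stacking layer.
#' @param bag_folds Folds per bagging round (default 5).
#' @param bag_repeats Bagging repeats whose OOF predictions are averaged
#'   (default 2).
#' @param selection_iters Greedy ensemble-selection steps (default 25).
#' @param seed Integer seed.
#' @return A `stack_config`.
#' @export
stack_config <- function(base_learners = c("logistic", "knn", "rf", "gbt", "mlp"),
                         stack_learners = c("logistic", "gbt"),
                         bag_folds = 5L, bag_repeats = 2L,
                         selection_iters = 25L, seed = 1L) {
  structure(
    list(base_learners = base_learners, stack_learners = stack_learners,
         bag_folds = check_count(bag_folds, "bag_folds", 2L),
         bag_repeats = check_count(bag_repeats, "bag_repeats", 1L),
         selection_iters = check_count(selection_iters, "selection_iters", 1L),
         stack_levels = 2L, seed = as.integer(seed)),
    class = "stack_config"
  )
}

#' Out-of-fold predictions under repeated stratified k-fold bagging
#'
#' Each repeat splits the rows into `k` folds (stratified by label for
#' classification); every row's prediction comes from the model trained on
#' the other `k - 1` folds, so no model ever predicts a sample it saw.
#' Repeats are averaged.
#'
#' @param learner Learner name or object.
#' @param X Numeric feature matrix / data frame.
#' @param y Labels.
#' @param weights Optional per-sample weights, threaded into every fold fit.
#' @param k,repeats Folds and repeats.
#' @param task `"classification"` or `"regression"`.
#' @param seed Integer seed (distinct fold assignments per repeat).
#' @param ... Learner hyper-parameters.
#' @return A list: `oof` (averaged predictions, one per row), `per_repeat`
#'   (n x repeats matrix), `folds` (n x repeats fold assignments).
#' @export
oof_predictions <- function(learner, X, y, weights = NULL, k = 5L,
                            repeats = 1L, task = NULL, seed = 1L, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- check_count(k, "k", 2L)
  if (n < k) abort("fewer rows than folds.")
  if (is.null(task)) task <- if (all(y %in% c(0, 1))) "classification" else "regression"
  if (task == "classification") {
    cls <- table(y)
    if (any(cls < k)) {
      abort(sprintf("class with %d members cannot be stratified into %d folds; use smaller k.",
                    min(cls), k))
    }
  }
  if (is.null(weights)) weights <- rep(1 / n, n)
  lrn <- get_learner(learner, ...)
  strata <- if (task == "classification") as.character(y) else
    as.character(cut(rank(y), k))
  per_repeat <- matrix(NA_real_, n, repeats)
  fold_rec <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(strata, k, seed = child_seed(seed, r))
    fold_rec[, r] <- folds
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- lrn$fit(X[tr, , drop = FALSE], y[tr], weights = weights[tr],
                       task = task, seed = child_seed(seed, r * 100L + f))
      per_repeat[folds == f, r] <- lrn$predict(model, X[folds == f, , drop = FALSE])
    }
  }
  list(oof = rowMeans(per_repeat), per_repeat = per_repeat, folds = fold_rec)
}

#' Greedy ensemble selection
#'
#' Forward selection with replacement: at every step, the candidate whose
#' inclusion (one more unit vote) minimizes the validation loss of the
#' averaged blend is added. Because the current blend is always a candidate
#' extension of itself, the selected blend's validation loss never exceeds
#' the best single model's.
#'
#' @param candidate_preds Numeric matrix, one column of validation
#'   predictions per candidate model.
#' @param labels Validation labels.
#' @param iters Greedy steps (default 25).
#' @param loss `"logloss"` (default for 0/1 labels) or `"squared"`.
#' @return Normalized weight vector over candidates (sums to 1).
#' @export
ensemble_selection <- function(candidate_preds, labels, iters = 25L,
                               loss = NULL) {
  P <- as.matrix(candidate_preds)
  if (!ncol(P)) abort("empty candidate list.")
  if (any(!is.finite(P))) abort("non-finite candidate predictions.")
  if (is.null(loss)) loss <- if (all(labels %in% c(0, 1))) "logloss" else "squared"
  loss_fn <- if (loss == "logloss") {
    function(p) -mean(labels * log(pmax(p, 1e-12)) +
                        (1 - labels) * log(pmax(1 - p, 1e-12)))
  } else {
    function(p) mean((p - labels)^2)
  }
  counts <- rep(0L, ncol(P))
  blend <- rep(0, nrow(P))
  for (it in seq_len(check_count(iters, "iters", 1L))) {
    cand_loss <- vapply(seq_len(ncol(P)), function(j) {
      loss_fn((blend * sum(counts) + P[, j]) / (sum(counts) + 1L))
    }, numeric(1))
    j <- which.min(cand_loss)
    counts[j] <- counts[j] + 1L
    blend <- (blend * (sum(counts) - 1L) + P[, j]) / sum(counts)
  }
  counts / sum(counts)
}

#' Fit the stacking layer on base OOF predictions plus skip features
#'
#' Trains the second-layer learners on the base learners' out-of-fold
#' prediction columns concatenated with the original features (skip
#' connections), computes the stack models' own OOF predictions, and runs
#' greedy [ensemble_selection()] over them. This is the single stacking level
#' above the base layer; [fit_ensemble()] wraps it together with the base
#' layer.
#'
#' @param base_oof Matrix of base-learner OOF predictions, one column per
#'   base model, rows aligned with `X`.
#' @param X Original feature matrix (already preprocessed), row-aligned with
#'   `base_oof`.
#' @param y Labels.
#' @param weights Optional per-sample weights.
#' @param config A [stack_config()].
#' @param task `"classification"` or `"regression"`.
#' @return A `stack_fit` list: `stack_names`, `stack_models`, `stack_oof`,
#'   `selection_weights`. Predict by building the same
#'   `cbind(base_preds, features)` design and calling each stack model (done
#'   for you by `predict.ensemble_fit`).
#' @export
fit_stack <- function(base_oof, X, y, weights = NULL, config = stack_config(),
                      task = NULL) {
  base_oof <- as.matrix(base_oof)
  X <- as.matrix(X)
  n <- nrow(X)
  if (nrow(base_oof) != n) abort("`base_oof` and `X` must be row-aligned.")
  if (length(y) != n) abort("`y` must be row-aligned with `X`.")
  if (is.null(task)) task <- if (all(y %in% c(0, 1))) "classification" else "regression"
  if (is.null(weights)) weights <- rep(1 / n, n)
  Z <- cbind(base_oof, X)
  stack_names <- config$stack_learners
  if (task == "regression") stack_names[stack_names == "logistic"] <- "linear"
  stack_oof <- matrix(NA_real_, n, length(stack_names),
                      dimnames = list(NULL, stack_names))
  stack_models <- vector("list", length(stack_names))
  for (j in seq_along(stack_names)) {
    sj <- child_seed(config$seed, 1000L + j)
    oof <- oof_predictions(stack_names[j], Z, y, weights = weights,
                           k = config$bag_folds, repeats = 1L,
                           task = task, seed = sj)
    stack_oof[, j] <- oof$oof
    lrn <- get_learner(stack_names[j])
    stack_models[[j]] <- list(
      learner = lrn,
      model = lrn$fit(Z, y, weights = weights, task = task, seed = sj)
    )
  }
  sel <- ensemble_selection(stack_oof, y, iters = config$selection_iters)
  structure(list(stack_names = stack_names, stack_models = stack_models,
                 stack_oof = stack_oof, selection_weights = sel, task = task),
            class = "stack_fit")
}

#' Fit the two-level stacking ensemble
#'
#' Base learners produce repeated k-fold OOF prediction columns; the stacking
#' layer trains on those columns concatenated with the original features; the
#' stack models' own OOF predictions feed greedy ensemble selection. All
#' sample weights (e.g. from the alpha-weighted objective) are threaded to
#' every fit.
#'
#' @param X Numeric feature matrix / data frame (already preprocessed).
#' @param y Labels.
#' @param weights Optional per-sample weights.
#' @param config A [stack_config()].
#' @param task `"classification"` or `"regression"`.
#' @param ... Unused.
#' @return An `ensemble_fit` supporting `predict()` and [glance()].
#' @export
fit_ensemble <- function(X, y, weights = NULL, config = stack_config(),
                         task = NULL, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(task)) task <- if (all(y %in% c(0, 1))) "classification" else "regression"
  if (is.null(weights)) weights <- rep(1 / n, n)
  base_names <- config$base_learners
  if (task == "regression") base_names[base_names == "logistic"] <- "linear"

  base_oof <- matrix(NA_real_, n, length(base_names),
                     dimnames = list(NULL, base_names))
  base_models <- vector("list", length(base_names))
  for (j in seq_along(base_names)) {
    sj <- child_seed(config$seed, j)
    oof <- oof_predictions(base_names[j], X, y, weights = weights,
                           k = config$bag_folds, repeats = config$bag_repeats,
                           task = task, seed = sj)
    base_oof[, j] <- oof$oof
    lrn <- get_learner(base_names[j])
    base_models[[j]] <- list(
      learner = lrn,
      model = lrn$fit(X, y, weights = weights, task = task, seed = sj)
    )
  }

  stk <- fit_stack(base_oof, X, y, weights = weights, config = config,
                   task = task)
  structure(
    list(base_names = base_names, base_models = base_models,
         stack_names = stk$stack_names, stack_models = stk$stack_models,
         selection_weights = stk$selection_weights, base_oof = base_oof,
         stack_oof = stk$stack_oof,
         task = task, config = config, feature_cols = colnames(X)),
    class = "ensemble_fit"
  )
}

#' @export
predict.ensemble_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  base_pred <- vapply(object$base_models, function(bm) {
    bm$learner$predict(bm$model, X)
  }, numeric(nrow(X)))
  if (is.null(dim(base_pred))) base_pred <- matrix(base_pred, nrow = nrow(X))
  colnames(base_pred) <- object$base_names
  Z <- cbind(base_pred, X)
  stack_pred <- vapply(object$stack_models, function(sm) {
    sm$learner$predict(sm$model, Z)
  }, numeric(nrow(X)))
  if (is.null(dim(stack_pred))) stack_pred <- matrix(stack_pred, nrow = nrow(X))
  drop(stack_pred %*% object$selection_weights)
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("<ensemble_fit>", length(x$base_names), "base learners ->",
      length(x$stack_names), "stack learners\n")
  cat("  selection weights:",
      paste(sprintf("%s=%.2f", x$stack_names, x$selection_weights),
            collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.ensemble_fit <- function(x, ...) {
  tibble(base_learners = paste(x$base_names, collapse = "+"),
         stack_learners = paste(x$stack_names, collapse = "+"),
         bag_folds = x$config$bag_folds, bag_repeats = x$config$bag_repeats,
         task = x$task)
}

#' Wrap the stacking ensemble as a weight-accepting learner
#'
#' Lets [fit_weighted()] and [adapt()] train the full ensemble under the
#' alpha-weighted objective.
#'
#' @param config A [stack_config()].
#' @return A learner object implementing the `fit`/`predict` contract.
#' @export
ensemble_learner <- function(config = stack_config()) {
  list(
    name = "ensemble",
    fit = function(X, y, weights = NULL, task = "classification", seed = 1L) {
      cfg <- config
      cfg$seed <- seed
      fit_ensemble(X, y, weights = weights, config = cfg, task = task)
    },
    predict = function(model, X) predict(model, X)
  )
}
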