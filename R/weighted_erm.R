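# The core method: the alpha-weighted empirical-risk objective that mixes m
# source samples and n target samples,
#   -(1 - alpha)/m * sum_source log p(y|x) - alpha/n * sum_target log p(y|x),
# realized as normalized per-sample weights so any weight-accepting learner
# plugs in, plus the k/(k+1) candidate grid and nested-CV selection of alpha.

#' Candidate grid for the source/target mixing weight
#'
#' Returns \eqn{\alpha = k/(k+1)} for \eqn{k = 1, \dots, k_{max}}:
#' 1/2, 2/3, 3/4, ... The grid gets finer as \eqn{\alpha} approaches 1,
#' which is where the interesting regime lies when target samples are scarce
#' but informative.
#'
#' @param k_max Largest `k` (default 10, giving a top value of 10/11).
#' @return Strictly increasing numeric vector in (0, 1).
#' @export
alpha_grid <- function(k_max = 10L) {
  k_max <- check_count(k_max, "k_max")
  k <- seq_len(k_max)
  k / (k + 1)
}

#' Per-sample weights realizing the alpha-weighted objective
#'
#' Source samples receive weight \eqn{(1-\alpha)/m}, target samples
#' \eqn{\alpha/n}; the weights always sum to 1 when both sides are non-empty.
#' At \eqn{\alpha = n/(m+n)} every sample has weight \eqn{1/(m+n)}: the
#' weighted objective coincides with pooled unweighted training.
#'
#' @param m,n Source and target sample counts.
#' @param alpha Mixing weight in \[0, 1\].
#' @return Numeric vector of length `m + n` (source weights first).
#' @export
erm_weights <- function(m, n, alpha) {
  check_scalar_number(alpha, "alpha", 0, 1)
  m <- check_count(m, "m", lower = 0L)
  n <- check_count(n, "n", lower = 0L)
  if (alpha > 0 && n == 0L) abort("target samples required when alpha > 0.")
  if (alpha < 1 && m == 0L) abort("source samples required when alpha < 1.")
  c(if (m > 0) rep((1 - alpha) / m, m),
    if (n > 0) rep(alpha / n, n))
}

#' Alpha-weighted negative log-likelihood
#'
#' Evaluates
#' \deqn{-\frac{1-\alpha}{m}\sum_{source} \log p_\theta(y_i|x_i)
#'       - \frac{\alpha}{n}\sum_{target} \log p_\theta(y_i|x_i).}
#' The objective is affine in \eqn{\alpha}:
#' \eqn{(1-\alpha)\hat R_s + \alpha \hat R_t}, with the two empirical risks
#' being the mean per-group NLLs. Probabilities are clipped at `clip` before
#' the log so degenerate learners keep the objective finite.
#'
#' @param source_prob,target_prob Predicted probability of the observed label
#'   for each sample, i.e. \eqn{p_\theta(y_i | x_i)} (pass
#'   `prob_of_label()` output for binary models).
#' @param alpha Mixing weight in \[0, 1\].
#' @param clip Lower clip for probabilities (default 1e-12).
#' @return The scalar weighted NLL.
#' @export
weighted_nll <- function(source_prob, target_prob, alpha, clip = 1e-12) {
  check_scalar_number(alpha, "alpha", 0, 1)
  m <- length(source_prob)
  n <- length(target_prob)
  if (alpha > 0 && n == 0L) abort("target samples required when alpha > 0.")
  if (alpha < 1 && m == 0L) abort("source samples required when alpha < 1.")
  nll <- function(p) -log(pmax(p, clip))
  s_term <- if (m > 0) (1 - alpha) * mean(nll(source_prob)) else 0
  t_term <- if (n > 0) alpha * mean(nll(target_prob)) else 0
  s_term + t_term
}

#' Probability assigned to the observed binary label
#'
#' @param prob Predicted probability of class 1.
#' @param y Observed 0/1 labels.
#' @return `prob` where `y == 1`, `1 - prob` where `y == 0`.
#' @export
prob_of_label <- function(prob, y) ifelse(y == 1, prob, 1 - prob)

#' Configuration for a source-to-target adaptation fit
#'
#' @param alpha Fixed mixing weight in \[0, 1\], or `NULL` to select by
#'   nested cross-validation over `grid`.
#' @param grid Candidate values, strictly increasing, all in (0, 1\]
#'   (default [alpha_grid()]).
#' @param target_fraction Fraction of target data available for training: a
#'   number in \[0, 1\] or one of `"0%"`, `"10%"`, `"all"`. At 0 the model is
#'   source-only and `alpha` is forced to 0.
#' @param regularization_strength Ridge penalty passed to learners that
#'   support one (default 0).
#' @param folds Inner cross-validation folds for alpha selection (default 5).
#' @param seed Integer seed used for every internal randomization.
#' @return An `adaptation_config`.
#' @export
adaptation_config <- function(alpha = NULL,
                              grid = alpha_grid(),
                              target_fraction = "10%",
                              regularization_strength = 0,
                              folds = 5L,
                              seed = 1L) {
  if (is.character(target_fraction)) {
    target_fraction <- switch(target_fraction,
      "0%" = 0, "10%" = 0.1, "all" = 1,
      abort('`target_fraction` must be a number or one of "0%", "10%", "all".')
    )
  }
  check_scalar_number(target_fraction, "target_fraction", 0, 1)
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid > 1)) {
    abort("`grid` must be strictly increasing with values in (0, 1].")
  }
  if (target_fraction == 0) alpha <- 0
  if (!is.null(alpha)) check_scalar_number(alpha, "alpha", 0, 1)
  check_scalar_number(regularization_strength, "regularization_strength", 0)
  structure(
    list(alpha = alpha, grid = grid, target_fraction = target_fraction,
         regularization_strength = regularization_strength,
         folds = check_count(folds, "folds", 2L),
         seed = as.integer(seed)),
    class = "adaptation_config"
  )
}

#' Fit a learner under the alpha-weighted objective
#'
#' Trains any registered learner on the union of source and target rows with
#' per-sample weights \eqn{(1-\alpha)/m} and \eqn{\alpha/n}. For convex
#' learners this is exactly the weighted maximum-likelihood solution; for the
#' others the weights enter their native weighting interfaces.
#'
#' @param source,target Data frames of already-preprocessed numeric features
#'   plus a label column. `target` may be `NULL`/empty when `alpha = 0`.
#' @param learner Learner name (see [learner_names()]) or object.
#' @param alpha Mixing weight in \[0, 1\].
#' @param label_col Name of the label column (default `"label"`).
#' @param task `"classification"` or `"regression"`; default guessed from the
#'   label.
#' @param seed Integer seed.
#' @param ... Learner hyper-parameters, passed to [get_learner()].
#' @return An `erm_fit`: the trained model with its alpha, sample counts and
#'   training-objective value. Supports `predict()`, [tidy()] and
#'   [glance()].
#' @export
fit_weighted <- function(source, target, learner = "logistic", alpha,
                         label_col = "label", task = NULL, seed = 1L, ...) {
  check_scalar_number(alpha, "alpha", 0, 1)
  feat <- function(d) as.matrix(d[, setdiff(names(d), label_col), drop = FALSE])
  m <- if (is.null(source)) 0L else nrow(source)
  n <- if (is.null(target)) 0L else nrow(target)
  if (alpha > 0 && n == 0L) abort("target samples required when alpha > 0.")
  if (alpha < 1 && m == 0L) abort("source samples required when alpha < 1.")
  Xs <- if (m > 0) feat(source) else NULL
  Xt <- if (n > 0) feat(target) else NULL
  X <- rbind(Xs, Xt)
  y <- c(if (m > 0) source[[label_col]], if (n > 0) target[[label_col]])
  if (is.null(task)) {
    task <- if (all(y %in% c(0, 1))) "classification" else "regression"
  }
  w <- erm_weights(m, n, alpha)
  # rows with zero weight contribute nothing; drop them so boundary alphas
  # are literally source-only / target-only fits
  keep <- w > 0
  lrn <- get_learner(learner, ...)
  model <- lrn$fit(X[keep, , drop = FALSE], y[keep], weights = w[keep],
                   task = task, seed = seed)
  pr <- lrn$predict(model, X)
  obj <- if (task == "classification") {
    weighted_nll(
      source_prob = if (m > 0) prob_of_label(pr[seq_len(m)], y[seq_len(m)]),
      target_prob = if (n > 0) prob_of_label(pr[m + seq_len(n)], y[m + seq_len(n)]),
      alpha = alpha
    )
  } else {
    r2 <- (pr - y)^2
    s <- if (m > 0) (1 - alpha) * mean(r2[seq_len(m)]) else 0
    s + if (n > 0) alpha * mean(r2[m + seq_len(n)]) else 0
  }
  structure(
    list(model = model, learner = lrn, learner_name = lrn$name %||% "custom",
         alpha = alpha, m = m, n = n, task = task,
         feature_cols = colnames(X), label_col = label_col,
         objective = obj, seed = seed),
    class = "erm_fit"
  )
}

#' @export
predict.erm_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  object$learner$predict(object$model, X)
}

#' @export
print.erm_fit <- function(x, ...) {
  cat(sprintf("<erm_fit> %s, alpha = %.4g (m = %d source, n = %d target)\n",
              x$learner_name, x$alpha, x$m, x$n))
  cat(sprintf("  task: %s; training objective: %.6g\n", x$task, x$objective))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.erm_fit <- function(x, ...) {
  if (x$learner_name %in% c("logistic", "linear") &&
      identical(x$model$kind, "glm")) {
    cf <- coef(x$model$model)
    return(tibble(term = names(cf), estimate = unname(cf)))
  }
  tibble(term = character(), estimate = numeric())
}

#' @exportS3Method generics::glance
glance.erm_fit <- function(x, ...) {
  tibble(learner = x$learner_name, alpha = x$alpha, m = x$m, n = x$n,
         task = x$task, objective = x$objective)
}

#' Select the mixing weight by inner cross-validation
#'
#' Splits the training pool (all source rows plus the available target rows)
#' into `folds` parts, stratified by label and with the target rows spread
#' evenly across folds. For every candidate alpha, a weighted fit on each
#' fold-complement predicts its validation fold; the per-alpha score is the
#' metric (AUC for classification, negative MAE for regression) on the
#' pooled out-of-fold predictions of the *target-role* validation rows —
#' the quantity adaptation actually cares about. When the pooled target rows
#' are degenerate (single class), all validation rows are scored instead.
#' Ties are broken toward the smallest alpha (prefer more source data).
#' An `alpha = 0` row is always evaluated and reported as the explicit
#' source-only baseline, but it is only selectable when no target data is
#' available.
#'
#' @inheritParams fit_weighted
#' @param grid Candidate alphas (default [alpha_grid()]).
#' @param folds Number of inner folds (default 5); every fold needs at least
#'   one target row.
#' @param metric `"auc"`, `"neg_mae"`, or `NULL` to match the task.
#' @return A list with `alpha` (the selected value) and `cv_table` (one row
#'   per candidate with its pooled target metric and mean over scorable
#'   folds).
#' @export
select_alpha <- function(source, target, learner = "logistic",
                         grid = alpha_grid(), folds = 5L,
                         label_col = "label", task = NULL,
                         metric = NULL, seed = 1L, ...) {
  folds <- check_count(folds, "folds", 2L)
  if (nrow(target) < folds) {
    abort(sprintf(
      "only %d target rows for %d folds; reduce `folds` so each inner fold has a target row.",
      nrow(target), folds))
  }
  y_all <- c(source[[label_col]], target[[label_col]])
  if (is.null(task)) {
    task <- if (all(y_all %in% c(0, 1))) "classification" else "regression"
  }
  if (is.null(metric)) metric <- if (task == "classification") "auc" else "neg_mae"
  score <- function(pred, y) {
    if (metric == "auc") {
      if (length(unique(y)) < 2L) return(NA_real_)
      auc(pred, y)
    } else {
      -mae(pred, y)
    }
  }
  # fold assignment: stratify source and target separately so every fold has
  # its share of target rows (and of each label within each role)
  strat <- function(d) {
    if (task == "classification") as.character(d[[label_col]]) else
      as.character(cut(rank(d[[label_col]]), folds))
  }
  fs <- stratified_folds(strat(source), folds, seed = child_seed(seed, 1L))
  ft <- stratified_folds(strat(target), folds, seed = child_seed(seed, 2L))
  candidates <- c(0, grid)
  rows <- lapply(candidates, function(a) {
    fold_scores <- rep(NA_real_, folds)
    pool_pred <- numeric(0); pool_y <- numeric(0)
    pool_pred_all <- numeric(0); pool_y_all <- numeric(0)
    for (f in seq_len(folds)) {
      src_tr <- source[fs != f, , drop = FALSE]
      tgt_tr <- target[ft != f, , drop = FALSE]
      src_va <- source[fs == f, , drop = FALSE]
      tgt_va <- target[ft == f, , drop = FALSE]
      fit <- fit_weighted(src_tr, tgt_tr, learner = learner, alpha = a,
                          label_col = label_col, task = task,
                          seed = child_seed(seed, 100L + f), ...)
      va <- bind_rows(src_va, tgt_va)
      pred <- predict(fit, va)
      n_t <- nrow(tgt_va)
      if (n_t > 0) {
        pred_t <- pred[nrow(src_va) + seq_len(n_t)]
        pool_pred <- c(pool_pred, pred_t)
        pool_y <- c(pool_y, tgt_va[[label_col]])
        fold_scores[f] <- score(pred_t, tgt_va[[label_col]])
      }
      pool_pred_all <- c(pool_pred_all, pred)
      pool_y_all <- c(pool_y_all, va[[label_col]])
    }
    pooled <- score(pool_pred, pool_y)
    if (is.na(pooled)) pooled <- score(pool_pred_all, pool_y_all)
    tibble(alpha = a, pooled_metric = pooled,
           mean_fold_metric = mean(fold_scores, na.rm = TRUE),
           scorable_folds = sum(!is.na(fold_scores)))
  })
  cv_table <- bind_rows(rows)
  selectable <- cv_table$alpha > 0
  best <- max(cv_table$pooled_metric[selectable])
  # tie rule: smallest alpha among (near-)ties — prefer more source data
  chosen <- min(cv_table$alpha[selectable & cv_table$pooled_metric >= best - 1e-12])
  list(alpha = chosen, cv_table = cv_table, metric = metric)
}

#' Adapt a model from a source group to a target group
#'
#' One-call front end: selects alpha on the training pool by
#' [select_alpha()] (unless the config fixes it), then fits the final
#' weighted model on all training rows.
#'
#' @inheritParams select_alpha
#' @param config An [adaptation_config()].
#' @return An `erm_fit` whose `cv_table` attribute records the selection.
#' @export
adapt <- function(source, target, learner = "logistic",
                  config = adaptation_config(), label_col = "label",
                  task = NULL, ...) {
  if (config$target_fraction == 0 || is.null(target) || nrow(target) == 0L) {
    fit <- fit_weighted(source, NULL, learner = learner, alpha = 0,
                        label_col = label_col, task = task,
                        seed = config$seed, ...)
    attr(fit, "cv_table") <- NULL
    return(fit)
  }
  if (!is.null(config$alpha)) {
    return(fit_weighted(source, target, learner = learner,
                        alpha = config$alpha, label_col = label_col,
                        task = task, seed = config$seed, ...))
  }
  sel <- select_alpha(source, target, learner = learner, grid = config$grid,
                      folds = config$folds, label_col = label_col,
                      task = task, seed = config$seed, ...)
  fit <- fit_weighted(source, target, learner = learner, alpha = sel$alpha,
                      label_col = label_col, task = task,
                      seed = config$seed, ...)
  attr(fit, "cv_table") <- sel$cv_table
  fit
}
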