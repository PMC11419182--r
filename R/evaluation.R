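# Evaluation protocol: outer five-fold split geometry for the 0% / 10% / all
# target-data settings, AUC / MAE with fold-wise mean +/- sd, paired
# significance comparison between configurations, and the fairness audit.

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half (rank / Mann-Whitney form).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("`scores`/`labels` length mismatch.")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) abort("`labels` must be 0/1.")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) abort("both classes must be present for AUC.")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean absolute error
#'
#' @param predicted,actual Equal-length numeric vectors (e.g. predicted and
#'   chronological age, in years).
#' @return Mean of `|predicted - actual|`.
#' @export
mae <- function(predicted, actual) {
  if (length(predicted) != length(actual)) abort("length mismatch.")
  if (!length(predicted)) abort("empty input.")
  mean(abs(predicted - actual))
}

#' Fairness audit: demographic parity and equalized odds differences
#'
#' Thresholds the scores at `threshold` and reports
#' \itemize{
#'   \item DPD: max over sensitive groups of the positive-prediction rate
#'     minus the min;
#'   \item EOD: the larger, over the two label strata, of the max-min gap of
#'     \eqn{P(\hat y = 1 | Y = y)} across groups (i.e. the worse of the
#'     true-positive-rate and false-positive-rate gaps).
#' }
#' Both lie in \[0, 1\]; 0 indicates a fair model under these metrics. A
#' label stratum where some group has no members is skipped with a warning.
#'
#' @param scores Numeric scores or already-thresholded 0/1 predictions.
#' @param labels Binary 0/1 outcomes.
#' @param group Sensitive-attribute value per subject (>= 2 groups).
#' @param threshold Classification threshold on `scores` (default 0.5).
#' @return A tibble with columns `dpd` and `eod`.
#' @export
fairness_audit <- function(scores, labels, group, threshold = 0.5) {
  group <- as.character(group)
  gs <- unique(group)
  if (length(gs) < 2L) abort("need at least 2 sensitive groups.")
  yhat <- as.numeric(scores >= threshold)
  rate <- vapply(gs, function(g) mean(yhat[group == g]), numeric(1))
  dpd <- max(rate) - min(rate)
  strata_gap <- vapply(c(0, 1), function(yv) {
    counts <- vapply(gs, function(g) sum(group == g & labels == yv), numeric(1))
    if (any(counts == 0)) {
      warn(sprintf("label stratum Y=%d empty for some group; skipped in EOD.", yv))
      return(NA_real_)
    }
    r <- vapply(gs, function(g) mean(yhat[group == g & labels == yv]), numeric(1))
    max(r) - min(r)
  }, numeric(1))
  eod <- if (all(is.na(strata_gap))) NA_real_ else max(strata_gap, na.rm = TRUE)
  tibble(dpd = dpd, eod = eod)
}

#' Outer split plans for source-to-target evaluation
#'
#' Builds the five outer train/test plans of the evaluation protocol. The
#' target group is split into five equal folds stratified by label; then per
#' setting:
#' \describe{
#'   \item{`"0%"`}{one plan: train on all source rows, evaluate on the entire
#'     target group (no test folds).}
#'   \item{`"10%"`}{per outer fold `f`: train on all source rows plus
#'     `floor(0.1 n)` target rows drawn (stratified) from fold `f`; test on
#'     all target rows outside fold `f` (80% when 5 divides `n`); the rest of
#'     fold `f` stays unused — bookkeeping kept deliberately simple.}
#'   \item{`"all"`}{per outer fold `f`: train on all source rows plus the
#'     target rows outside fold `f` (80%); test on fold `f` (20%).}
#' }
#' Train and test never overlap, and test rows are always target-group only.
#'
#' @param cohort A `grouped_cohort` or data frame with a `group` column.
#' @param source_group,target_group Group identifiers.
#' @param setting `"0%"`, `"10%"` or `"all"`.
#' @param seed Integer seed (fold assignment and the 10% subsample).
#' @param label_col Label column name.
#' @return A `split_plan` list: one element per outer fold, each holding
#'   integer row indices `train_source`, `train_target`, `test`, `unused`.
#' @export
make_split_plan <- function(cohort, source_group, target_group,
                            setting = c("10%", "0%", "all"),
                            seed = 1L, label_col = "label") {
  setting <- match.arg(setting)
  src_idx <- which(cohort$group == source_group)
  tgt_idx <- which(cohort$group == target_group)
  if (!length(src_idx)) abort(sprintf("no rows in source group `%s`.", source_group))
  if (!length(tgt_idx)) abort(sprintf("no rows in target group `%s`.", target_group))
  y <- cohort[[label_col]][tgt_idx]
  classification <- all(y %in% c(0, 1))
  if (setting == "0%") {
    plans <- list(list(fold = 0L, train_source = src_idx,
                       train_target = integer(), test = tgt_idx,
                       unused = integer()))
    return(structure(plans, class = "split_plan", setting = setting,
                     seed = seed, source_group = source_group,
                     target_group = target_group))
  }
  if (classification) {
    cls_counts <- table(y)
    if (any(cls_counts < 5L)) {
      abort(paste0("stratification infeasible: target class counts ",
                   paste(sprintf("%s=%d", names(cls_counts), cls_counts),
                         collapse = ", "),
                   " (need >= 5 per class)."))
    }
  }
  strata <- if (classification) as.character(y) else as.character(cut(rank(y), 5L))
  folds <- stratified_folds(strata, 5L, seed = child_seed(seed, 1L))
  n <- length(tgt_idx)
  plans <- lapply(seq_len(5L), function(f) {
    in_fold <- tgt_idx[folds == f]
    out_fold <- tgt_idx[folds != f]
    if (setting == "all") {
      return(list(fold = f, train_source = src_idx, train_target = out_fold,
                  test = in_fold, unused = integer()))
    }
    n_train <- floor(0.1 * n)
    if (n_train < 1L) abort("target group too small for the 10% setting.")
    # stratified draw of the 10% training subset from fold f
    sub_strata <- strata[folds == f]
    pick <- integer()
    with_seed(child_seed(seed, 10L + f), {
      per_stratum <- table(sub_strata)
      quota <- round(n_train * per_stratum / sum(per_stratum))
      # fix rounding so exactly n_train rows are drawn
      while (sum(quota) > n_train) quota[which.max(quota)] <- quota[which.max(quota)] - 1L
      while (sum(quota) < n_train) quota[which.min(quota)] <- quota[which.min(quota)] + 1L
      for (s in names(per_stratum)) {
        ids <- in_fold[sub_strata == s]
        pick <- c(pick, sample(ids, min(quota[[s]], length(ids))))
      }
    })
    list(fold = f, train_source = src_idx, train_target = sort(pick),
         test = out_fold, unused = setdiff(in_fold, pick))
  })
  structure(plans, class = "split_plan", setting = setting, seed = seed,
            source_group = source_group, target_group = target_group)
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> setting %s: %d plan(s), source `%s` -> target `%s`\n",
              attr(x, "setting"), length(x), attr(x, "source_group"),
              attr(x, "target_group")))
  for (p in x) {
    cat(sprintf("  fold %d: %d source-train, %d target-train, %d test, %d unused\n",
                p$fold, length(p$train_source), length(p$train_target),
                length(p$test), length(p$unused)))
  }
  invisible(x)
}

#' Run the source-to-target evaluation protocol
#'
#' For each outer plan: fits the preprocessor on the training rows only,
#' selects alpha by inner cross-validation (when target training rows exist
#' and no fixed alpha is configured), fits both the weighted model and the
#' source-only baseline, and scores them on the target test rows. Reports
#' fold-wise metrics; the summary `sd` is the standard deviation of the five
#' fold metrics.
#'
#' @inheritParams make_split_plan
#' @param learner Learner name or object.
#' @param config An [adaptation_config()].
#' @param sensitive_col Optional column name for a fairness audit of the test
#'   predictions (classification only).
#' @param outer_folds `NULL` (default) to run every outer plan, or an integer
#'   count / vector of fold numbers to evaluate a subset (useful in
#'   replicated experiments where each replicate affords one fold).
#' @param ... Learner hyper-parameters.
#' @return An `eval_report` tibble: one row per (fold, model) with the
#'   metric, chosen alpha, and optional `dpd`/`eod` columns.
#' @export
evaluate_adaptation <- function(cohort, source_group, target_group,
                                setting = "10%", learner = "logistic",
                                config = adaptation_config(target_fraction = setting),
                                sensitive_col = NULL, outer_folds = NULL,
                                label_col = "label", seed = config$seed, ...) {
  plans <- make_split_plan(cohort, source_group, target_group,
                           setting = setting, seed = seed,
                           label_col = label_col)
  if (!is.null(outer_folds)) {
    keep <- if (length(outer_folds) == 1L && outer_folds[1L] <= length(plans)) {
      seq_len(outer_folds[1L])
    } else {
      intersect(as.integer(outer_folds), seq_along(plans))
    }
    if (!length(keep)) abort("`outer_folds` selects no plan.")
    plans <- structure(plans[keep], class = "split_plan",
                       setting = setting, seed = seed,
                       source_group = source_group,
                       target_group = target_group)
  }
  task <- attr(cohort, "task") %||%
    if (all(cohort[[label_col]] %in% c(0, 1))) "classification" else "regression"
  metric_name <- if (task == "classification") "auc" else "mae"
  num_cols <- numeric_features(cohort) %||%
    names(cohort)[vapply(cohort, is.numeric, TRUE) &
                    !names(cohort) %in% c(".id", label_col)]
  cat_cols <- categorical_features(cohort)

  rows <- list()
  for (p in plans) {
    train_idx <- c(p$train_source, p$train_target)
    prep <- fit_preprocessor(cohort[train_idx, , drop = FALSE],
                             numeric_cols = num_cols,
                             categorical_cols = cat_cols)
    design <- function(idx) {
      d <- apply_preprocessor(prep, cohort[idx, , drop = FALSE])
      d[[label_col]] <- cohort[[label_col]][idx]
      d
    }
    src <- design(p$train_source)
    tgt <- if (length(p$train_target)) design(p$train_target) else NULL
    tst <- design(p$test)
    y_test <- tst[[label_col]]
    score <- function(pred) {
      if (task == "classification") auc(pred, y_test) else mae(pred, y_test)
    }
    fold_seed <- child_seed(seed, 1000L + p$fold)

    base_fit <- fit_weighted(src, NULL, learner = learner, alpha = 0,
                             label_col = label_col, task = task,
                             seed = fold_seed, ...)
    base_pred <- predict(base_fit, tst)
    out <- tibble(fold = p$fold, model = "source_only", alpha = 0,
                  metric = metric_name, value = score(base_pred))
    if (!is.null(tgt)) {
      fit <- adapt(src, tgt, learner = learner,
                   config = modify_config(config, seed = fold_seed),
                   label_col = label_col, task = task, ...)
      pred <- predict(fit, tst)
      out <- bind_rows(out, tibble(fold = p$fold, model = "weighted",
                                   alpha = fit$alpha, metric = metric_name,
                                   value = score(pred)))
    }
    if (!is.null(sensitive_col) && task == "classification") {
      grp <- cohort[[sensitive_col]][p$test]
      fa_base <- fairness_audit(base_pred, y_test, grp)
      out$dpd <- NA_real_; out$eod <- NA_real_
      out$dpd[out$model == "source_only"] <- fa_base$dpd
      out$eod[out$model == "source_only"] <- fa_base$eod
      if (!is.null(tgt)) {
        fa_w <- fairness_audit(pred, y_test, grp)
        out$dpd[out$model == "weighted"] <- fa_w$dpd
        out$eod[out$model == "weighted"] <- fa_w$eod
      }
    }
    rows[[length(rows) + 1L]] <- out
  }
  report <- bind_rows(rows)
  structure(report, class = c("eval_report", class(report)),
            setting = setting, source_group = source_group,
            target_group = target_group, metric = metric_name, seed = seed)
}

modify_config <- function(config, ...) {
  upd <- list(...)
  for (nm in names(upd)) config[[nm]] <- upd[[nm]]
  config
}

#' Summarise an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One row per model: fold-wise mean and sd of the metric (the sd of
#'   the five fold values, not a pooled recomputation).
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$model) |>
    summarise(metric = .data$metric[1L],
              mean = mean(.data$value),
              sd = if (dplyr::n() > 1L) sd(.data$value) else NA_real_,
              folds = dplyr::n(),
              mean_alpha = mean(.data$alpha),
              .groups = "drop")
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) as_tibble(x)

#' Paired significance comparison between two evaluated configurations
#'
#' Two-sided paired t-test on the per-fold metrics of two models from the
#' same split plans.
#'
#' @param report An `eval_report` (or tibble with `fold`, `model`, `value`).
#' @param model1,model2 Model names to compare.
#' @return A tibble with the mean difference (`model1 - model2`) and the
#'   two-sided p-value.
#' @export
compare_models <- function(report, model1 = "weighted", model2 = "source_only") {
  a <- report$value[report$model == model1][order(report$fold[report$model == model1])]
  b <- report$value[report$model == model2][order(report$fold[report$model == model2])]
  if (length(a) != length(b) || length(a) < 2L) {
    abort("need matched fold metrics for both models (>= 2 folds).")
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(model1 = model1, model2 = model2,
         mean_diff = mean(a - b), p_value = tt$p.value)
}

#' @describeIn evaluate_adaptation Dot-and-line plot of fold metrics per
#'   model.
#' @param object An `eval_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$model, .data$value, group = .data$fold)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)), size = 2) +
    ggplot2::labs(y = attr(object, "metric"), x = NULL, colour = "fold",
                  title = sprintf("%s → %s (%s target data)",
                                  attr(object, "source_group"),
                                  attr(object, "target_group"),
                                  attr(object, "setting"))) +
    ggplot2::theme_minimal()
}
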