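test_that("AUC matches the worked example and the exhaustive oracle", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75,
               tolerance = 1e-12)
  for (r in 1:30) {
    withr::with_seed(700L + r, {
      n <- sample(4:50, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1] <- 1 - labels[1]
    })
    expect_equal(auc(scores, labels), auc_naive(scores, labels),
                 tolerance = 1e-12)
  }
  # flipping the scores reflects the AUC
  withr::with_seed(1L, {
    s <- runif(40); y <- rbinom(40, 1, 0.5); y[1] <- 1; y[2] <- 0
  })
  expect_equal(auc(-s, y), 1 - auc(s, y), tolerance = 1e-12)
  expect_error(auc(s, rep(1, 40)), "both classes")
})

test_that("MAE is the plain mean absolute error", {
  expect_equal(mae(c(70, 80), c(72, 77)), 2.5)
  expect_equal(mae(1:5, 1:5), 0)
  expect_error(mae(1:3, 1:2), "length")
})

test_that("fairness audit reproduces the constructed DPD and EOD examples", {
  # identical rates across groups: DPD = 0
  yhat <- rep(c(1, 0), 10)
  grp <- rep(c("a", "b"), each = 10)
  y <- rep(c(1, 0), 10)
  fa <- fairness_audit(yhat, y, grp)
  expect_equal(fa$dpd, 0)
  expect_equal(fa$eod, 0)
  # disjoint rates: one group always flagged, the other never
  fa2 <- fairness_audit(c(rep(1, 10), rep(0, 10)), y, grp)
  expect_equal(fa2$dpd, 1)
  # TPRs 0.9 / 0.6 and FPRs 0.2 / 0.2 -> EOD = 0.3
  ya <- c(rep(1, 10), rep(0, 10))
  pa <- c(rep(1, 9), 0, rep(1, 2), rep(0, 8))
  yb <- c(rep(1, 10), rep(0, 10))
  pb <- c(rep(1, 6), rep(0, 4), rep(1, 2), rep(0, 8))
  fa3 <- fairness_audit(c(pa, pb), c(ya, yb),
                        rep(c("a", "b"), each = 20))
  expect_equal(fa3$eod, 0.3, tolerance = 1e-12)
  # empty strata (one per label value here): warned and skipped
  w <- capture_warnings(
    fa4 <- fairness_audit(c(1, 0, 1), c(1, 1, 0), c("a", "a", "b"))
  )
  expect_true(all(grepl("skipped", w)))
  expect_length(w, 2L)
  expect_false(is.na(fa4$dpd))
  expect_true(is.na(fa4$eod))
})

test_that("split plans are sound in every setting", {
  spec <- cohort_spec(n_per_group = c(S = 300, T = 100), class_balance = 0.5,
                      seed = 81L)
  ch <- generate_cohort(spec)
  tgt_rows <- which(ch$group == "T")

  for (setting in c("10%", "all")) {
    plan <- make_split_plan(ch, "S", "T", setting = setting, seed = 2L)
    expect_length(plan, 5L)
    test_union <- integer()
    for (p in plan) {
      train <- c(p$train_source, p$train_target)
      expect_length(intersect(train, p$test), 0L)
      expect_true(all(p$test %in% tgt_rows))
      test_union <- union(test_union, p$test)
    }
    expect_setequal(test_union, tgt_rows)
  }

  plan10 <- make_split_plan(ch, "S", "T", setting = "10%", seed = 2L)
  for (p in plan10) {
    expect_length(p$train_target, floor(0.1 * 100))
    expect_length(p$test, floor(0.8 * 100))
    expect_length(p$unused, 100 - 10 - 80)
    expect_length(intersect(p$train_target, p$unused), 0L)
  }

  plan_all <- make_split_plan(ch, "S", "T", setting = "all", seed = 2L)
  for (p in plan_all) {
    expect_length(p$train_target, 80L)
    expect_length(p$test, 20L)
    expect_length(p$unused, 0L)
  }

  plan0 <- make_split_plan(ch, "S", "T", setting = "0%", seed = 2L)
  expect_length(plan0, 1L)
  expect_length(plan0[[1]]$train_target, 0L)
  expect_setequal(plan0[[1]]$test, tgt_rows)

  expect_identical(make_split_plan(ch, "S", "T", setting = "10%", seed = 2L),
                   plan10)
  expect_error(make_split_plan(ch, "S", "nope"), "target")
})

test_that("infeasible stratification is rejected with class counts", {
  spec <- cohort_spec(n_per_group = c(S = 100, T = 30), seed = 82L)
  ch <- generate_cohort(spec)
  ch$label[ch$group == "T"] <- c(rep(0, 27), rep(1, 3))
  expect_error(make_split_plan(ch, "S", "T", setting = "all"), ">= 5")
})

test_that("the protocol evaluates both models and summarises fold statistics", {
  cohort <- generate_cohort(example_adaptation_spec(m = 300, n = 100, seed = 83L))
  rep1 <- evaluate_adaptation(cohort, "S", "T", setting = "10%",
                              seed = 3L, outer_folds = 2L)
  expect_s3_class(rep1, "eval_report")
  expect_setequal(unique(rep1$model), c("source_only", "weighted"))
  expect_equal(nrow(rep1), 4L)
  expect_true(all(rep1$metric == "auc"))
  expect_true(all(rep1$alpha[rep1$model == "weighted"] %in% alpha_grid()))
  gl <- glance(rep1)
  w <- rep1$value[rep1$model == "weighted"]
  expect_equal(gl$sd[gl$model == "weighted"], sd(w), tolerance = 1e-12)
  expect_equal(gl$mean[gl$model == "weighted"], mean(w), tolerance = 1e-12)
  # paired comparison runs on the fold metrics
  cmp <- compare_models(rep1)
  expect_equal(cmp$mean_diff,
               mean(w - rep1$value[rep1$model == "source_only"]),
               tolerance = 1e-12)
})

test_that("the 0% setting yields a source-only report", {
  cohort <- generate_cohort(example_adaptation_spec(m = 200, n = 60, seed = 84L))
  rep0 <- evaluate_adaptation(cohort, "S", "T", setting = "0%", seed = 1L)
  expect_equal(unique(rep0$model), "source_only")
  expect_equal(nrow(rep0), 1L)
})

test_that("fold-wise preprocessing never touches test rows (mutation test)", {
  cohort <- generate_cohort(example_adaptation_spec(m = 200, n = 100, seed = 85L))
  plan <- make_split_plan(cohort, "S", "T", setting = "10%", seed = 4L)
  p <- plan[[1]]
  train_idx <- c(p$train_source, p$train_target)
  mutated <- cohort
  mutated$x1[p$test] <- 1e6
  mutated$x2[p$test] <- -1e6
  prep_clean <- fit_preprocessor(cohort[train_idx, ])
  prep_mut <- fit_preprocessor(mutated[train_idx, ])
  expect_identical(prep_clean, prep_mut)
  # and the full protocol gives identical training-side state: the metric on
  # the mutated cohort differs only because the test features themselves moved
  r1 <- evaluate_adaptation(cohort, "S", "T", setting = "10%", seed = 4L,
                            outer_folds = 1L)
  r2 <- evaluate_adaptation(cohort, "S", "T", setting = "10%", seed = 4L,
                            outer_folds = 1L)
  expect_identical(r1, r2)
})

test_that("a sensitive column adds a fairness audit to the report", {
  cohort <- generate_cohort(example_adaptation_spec(m = 200, n = 100, seed = 86L))
  rep1 <- evaluate_adaptation(cohort, "S", "T", setting = "10%",
                              sensitive_col = "sex", seed = 5L,
                              outer_folds = 1L)
  expect_true(all(c("dpd", "eod") %in% names(rep1)))
  expect_true(all(rep1$dpd >= 0 & rep1$dpd <= 1))
})

test_that("regression cohorts are scored with MAE", {
  spec <- cohort_spec(n_per_group = c(S = 150, T = 60), task = "regression",
                      seed = 87L)
  ch <- generate_cohort(spec)
  rep1 <- evaluate_adaptation(ch, "S", "T", setting = "all",
                              learner = "linear", seed = 6L, outer_folds = 1L)
  expect_true(all(rep1$metric == "mae"))
  expect_true(all(rep1$value >= 0))
})
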