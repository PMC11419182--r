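test_that("equal priors and symmetric classes put the LDA boundary at the midpoint", {
  # exactly equal class sizes and exactly symmetric values around each mean
  probs <- c(0.2 - 0.05, 0.2 + 0.05, 0.2 - 0.1, 0.2 + 0.1,
             0.8 - 0.05, 0.8 + 0.05, 0.8 - 0.1, 0.8 + 0.1)
  cls <- rep(c("sMCI", "pMCI"), each = 4)
  res <- lda_progression(probs, cls, pairs = list(c("pMCI", "sMCI")),
                         folds = 2L, seed = 1L)
  fit <- attr(res, "lda")[["pMCI_vs_sMCI"]]
  expect_equal(fit$boundary, 0.5, tolerance = 1e-12)
  expect_equal(fit$priors, c(0.5, 0.5))
})

test_that("tied scores leave the progression AUC at chance", {
  probs <- rep(0.4, 40)
  cls <- rep(c("pMCI", "sMCI"), 20)
  expect_warning(res <- lda_progression(probs, cls, folds = 5L, seed = 2L),
                 "missing class|skipped")
  row <- res[res$negative == "sMCI", ]
  expect_equal(row$auc_mean, 0.5, tolerance = 1e-12)
})

test_that("the LDA pipeline recovers the Gaussian closed-form AUC", {
  dmu <- 1
  sigma <- 0.8
  withr::with_seed(3L, {
    x <- c(rnorm(2000, 0, sigma), rnorm(2000, dmu, sigma))
  })
  cls <- rep(c("sMCI", "pMCI"), each = 2000)
  res <- lda_progression(x, cls, pairs = list(c("pMCI", "sMCI")),
                         folds = 5L, seed = 4L)
  expect_equal(res$auc_mean, pnorm(dmu / (sigma * sqrt(2))), tolerance = 0.03)
  expect_equal(res$folds_used, 5L)
})

test_that("a diagnosis model's probabilities separate pMCI from nMCI best", {
  spec <- cohort_spec(n_per_group = c(A = 800), seed = 91L)
  ch <- generate_cohort(spec)
  coef <- c(rep(1, 5), rep(0, 15))
  ch <- make_progression_labels(ch, coef, strength = 2, seed = 5L)
  prep <- fit_preprocessor(ch)
  df <- apply_preprocessor(prep, ch)
  df$label <- ch$label
  fit <- fit_weighted(df, NULL, alpha = 0)
  probs <- predict(fit, df)
  res <- lda_progression(probs, ch$progression, folds = 5L, seed = 6L)
  expect_gt(res$auc_mean[res$negative == "nMCI"], 0.5)
  expect_gt(res$auc_mean[res$negative == "nMCI"],
            res$auc_mean[res$negative == "sMCI"] - 0.05)
})

test_that("brain-age residuals are definitional and report dropped rows", {
  bt <- brain_age_residuals(c(72, 66, 80), c(70, 68, 80))
  expect_equal(bt$bar, c(2, -2, 0))
  expect_equal(attr(bt, "n_dropped"), 0L)
  bt2 <- brain_age_residuals(c(72, 66), c(70, NA))
  expect_equal(nrow(bt2), 1L)
  expect_equal(attr(bt2, "n_dropped"), 1L)
  expect_error(brain_age_residuals(c(70, 71), c(70, -3)), "positive")
  expect_error(brain_age_residuals(1:3, 1:2), "mismatch|length")
  # a constant offset moves every residual by that offset
  bt3 <- brain_age_residuals(c(72, 66, 80) + 5, c(70, 68, 80))
  expect_equal(bt3$bar, bt$bar + 5)
})

test_that("BAR correlations match cor.test and honor duplication invariance", {
  bt <- brain_age_residuals(c(71, 69, 75), c(70, 70, 70))
  vars <- data.frame(mmse = c(30, 29, 26))
  res <- bar_correlations(bt, vars)
  ref <- cor.test(bt$bar, vars$mmse)
  expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # perfectly anti-correlated example
  bt2 <- brain_age_residuals(c(69, 70, 71), c(70, 70, 70))
  res2 <- bar_correlations(bt2, data.frame(v = c(30, 29, 28)))
  expect_equal(res2$r, -1, tolerance = 1e-12)
  # duplicating the rows leaves r unchanged
  bt3 <- brain_age_residuals(rep(c(71, 69, 75), 2), rep(70, 6))
  res3 <- bar_correlations(bt3, data.frame(mmse = rep(vars$mmse, 2)))
  expect_equal(res3$r, res$r, tolerance = 1e-12)
  # degenerate inputs are reported, not errored
  res4 <- bar_correlations(bt, data.frame(flat = c(1, 1, 1)))
  expect_true(is.na(res4$r))
  expect_match(res4$reason, "constant")
  res5 <- bar_correlations(bt, data.frame(sparse = c(1, NA, NA)))
  expect_match(res5$reason, "fewer than 3")
})

test_that("correlation significance is calibrated at the 1% level under the null", {
  rej <- vapply(1:2000, function(r) {
    withr::with_seed(5000L + r, {
      bar <- rnorm(40)
      v <- rnorm(40)
    })
    bt <- brain_age_residuals(bar + 70, rep(70, 40))
    bar_correlations(bt, data.frame(v = v))$significant
  }, logical(1))
  lo <- qbinom(0.005, 2000, 0.01) / 2000
  hi <- qbinom(0.995, 2000, 0.01) / 2000
  expect_gte(mean(rej), lo)
  expect_lte(mean(rej), hi)
})

test_that("synthetic MMSE-like and TMT-like variables recover the expected signs", {
  withr::with_seed(6L, {
    aging <- rnorm(300)
    bar <- aging + rnorm(300, sd = 0.8)
    mmse <- 28 - 2 * aging + rnorm(300, sd = 1)   # declines with aging
    tmt <- 60 + 15 * aging + rnorm(300, sd = 8)   # slows (increases) with aging
  })
  bt <- brain_age_residuals(70 + bar, rep(70, 300))
  res <- bar_correlations(bt, data.frame(mmse = mmse, tmt = tmt))
  expect_lt(res$r[res$variable == "mmse"], 0)
  expect_gt(res$r[res$variable == "tmt"], 0)
  expect_true(all(res$significant))
  expect_true(all(res$p_value < 0.01))
})

test_that("adapting the diagnosis model does not degrade progression AUC on average", {
  deltas <- vapply(1:20, function(r) {
    cohort <- generate_cohort(example_adaptation_spec(m = 400, n = 150,
                                                      seed = 600L + r))
    # progression severity follows the target group's own disease direction
    # (the benchmark spec flips the sign of the first two coefficients)
    beta_target <- c(-1, -1, rep(1, 3), rep(0, 15))
    cohort <- make_progression_labels(
      cohort, beta_target,
      flagged = cohort$group == "T", strength = 2, seed = r
    )
    prep <- fit_preprocessor(cohort)
    df <- apply_preprocessor(prep, cohort)
    df$label <- cohort$label
    src <- df[cohort$group == "S", ]
    tgt_all <- which(cohort$group == "T")
    tr <- tgt_all[seq_len(30L)]
    te <- setdiff(tgt_all, tr)
    f0 <- fit_weighted(src, NULL, alpha = 0, seed = r)
    f1 <- fit_weighted(src, df[tr, ], alpha = 0.8, seed = r)
    p0 <- predict(f0, df[te, ])
    p1 <- predict(f1, df[te, ])
    prog <- cohort$progression[te]
    a0 <- lda_progression(p0, prog, pairs = list(c("pMCI", "nMCI")),
                          seed = r)$auc_mean
    a1 <- lda_progression(p1, prog, pairs = list(c("pMCI", "nMCI")),
                          seed = r)$auc_mean
    a1 - a0
  }, numeric(1))
  expect_gte(mean(deltas), -0.02)
})
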