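test_that("the alpha grid is k/(k+1) for k = 1..10", {
  g <- alpha_grid()
  expect_equal(g, (1:10) / (2:11), tolerance = 1e-15)
  expect_true(all(g > 0 & g < 1))
  expect_true(all(diff(g) > 0))
})

test_that("per-sample weights realize the two-term objective and sum to 1", {
  w <- erm_weights(4L, 2L, 0.25)
  expect_equal(w, c(rep(0.75 / 4, 4), rep(0.25 / 2, 2)), tolerance = 1e-15)
  expect_equal(sum(erm_weights(7L, 3L, 0.6)), 1, tolerance = 1e-12)
  expect_error(erm_weights(0L, 3L, 0.5), "source|m")
  expect_error(erm_weights(3L, 0L, 0.5), "target|n")
})

test_that("weighted_nll matches hand arithmetic and is affine in alpha", {
  # source likelihood exp(-1), target exp(-3), alpha 1/4: 0.75*1 + 0.25*3
  expect_equal(weighted_nll(exp(-1), exp(-3), 0.25), 1.5, tolerance = 1e-12)
  withr::with_seed(1L, {
    ps <- runif(20, 0.05, 0.95)
    pt <- runif(7, 0.05, 0.95)
  })
  rs <- mean(-log(ps))
  rt <- mean(-log(pt))
  for (a in c(0, 0.3, 0.5, 0.9, 1)) {
    expect_equal(weighted_nll(ps, pt, a), (1 - a) * rs + a * rt,
                 tolerance = 1e-12)
  }
})

test_that("boundary alphas reduce to source-only and target-only fits", {
  src <- make_xy(80, seed = 2L)
  tgt <- make_xy(30, beta = c(-1, 1, 1), seed = 3L)
  probe <- make_xy(50, seed = 4L)[, 1:3]

  f0 <- fit_weighted(src, tgt, alpha = 0)
  f_src <- fit_weighted(src, NULL, alpha = 0)
  expect_equal(predict(f0, probe), predict(f_src, probe), tolerance = 1e-9)

  f1 <- fit_weighted(src, tgt, alpha = 1)
  f_tgt <- fit_weighted(NULL, tgt, alpha = 1)
  expect_equal(predict(f1, probe), predict(f_tgt, probe), tolerance = 1e-9)

  expect_error(fit_weighted(src, NULL, alpha = 0.5), "target")
  expect_error(fit_weighted(NULL, tgt, alpha = 0.5), "source")
})

test_that("alpha = n/(m+n) is exactly the pooled unweighted fit", {
  src <- make_xy(60, seed = 5L)
  tgt <- make_xy(20, seed = 6L)
  probe <- make_xy(40, seed = 7L)[, 1:3]
  pooled <- rbind(src, tgt)
  f_mix <- fit_weighted(src, tgt, alpha = nrow(tgt) / nrow(pooled))
  f_pool <- fit_weighted(pooled, NULL, alpha = 0)
  expect_equal(predict(f_mix, probe), predict(f_pool, probe), tolerance = 1e-8)
})

test_that("weighted logistic fits match the replicated-dataset oracle", {
  # alpha = 0.5, m = 40, n = 10: target weight is 4x the source weight, so
  # duplicating every target row 4 times and fitting unweighted is identical
  src <- make_xy(40, seed = 8L)
  tgt <- make_xy(10, beta = c(2, -1, 0), seed = 9L)
  probe <- make_xy(30, seed = 10L)[, 1:3]
  f_w <- fit_weighted(src, tgt, alpha = 0.5)
  replicated <- rbind(src, tgt[rep(seq_len(nrow(tgt)), each = 4L), ])
  f_rep <- fit_weighted(replicated, NULL, alpha = 0)
  expect_equal(predict(f_w, probe), predict(f_rep, probe), tolerance = 1e-6)
})

test_that("the recorded objective equals the weighted NLL of the fit", {
  src <- make_xy(50, seed = 11L)
  tgt <- make_xy(25, seed = 12L)
  f <- fit_weighted(src, tgt, alpha = 0.75)
  ps <- prob_of_label(predict(f, src[, 1:3]), src$label)
  pt <- prob_of_label(predict(f, tgt[, 1:3]), tgt$label)
  expect_equal(f$objective, weighted_nll(ps, pt, 0.75), tolerance = 1e-10)
})

test_that("cross-validated selection breaks exact ties toward alpha = 1/2", {
  src <- make_xy(40, seed = 13L)
  tgt <- make_xy(20, seed = 14L)
  sel <- select_alpha(src, tgt, learner = constant_learner(), seed = 1L)
  expect_equal(sel$alpha, 0.5)
  expect_true(all(abs(sel$cv_table$pooled_metric - 0.5) < 1e-12))
})

test_that("selection is deterministic, stays on the grid, and never returns 0", {
  src <- make_xy(80, seed = 15L)
  tgt <- make_xy(30, beta = c(-1, -1, 1), seed = 16L)
  s1 <- select_alpha(src, tgt, seed = 4L)
  s2 <- select_alpha(src, tgt, seed = 4L)
  expect_identical(s1, s2)
  expect_true(s1$alpha %in% alpha_grid())
  expect_equal(nrow(s1$cv_table), 11L)  # alpha = 0 reported but not selectable
  expect_gt(s1$alpha, 0)
  expect_error(select_alpha(src, tgt[1:3, ], folds = 5L), "folds")
})

test_that("with no shift, selection does not over-commit to scarce target data", {
  alphas <- vapply(1:12, function(r) {
    src <- make_xy(300, seed = 400L + r)
    tgt <- make_xy(40, seed = 900L + r)
    select_alpha(src, tgt, seed = r)$alpha
  }, numeric(1))
  expect_lte(median(alphas), 2 / 3)
})

test_that("adaptation_config enforces the 0% rule and validates the grid", {
  cfg <- adaptation_config(target_fraction = "0%")
  expect_equal(cfg$alpha, 0)
  expect_error(adaptation_config(grid = c(0.5, 0.5)), "increasing")
  expect_error(adaptation_config(grid = c(0, 0.5)), "increasing|\\(0, 1\\]")
  expect_error(adaptation_config(target_fraction = "42%"), "target_fraction")
})

test_that("adapt() front end honors a fixed alpha and records the CV table", {
  src <- make_xy(60, seed = 17L)
  tgt <- make_xy(25, seed = 18L)
  fixed <- adapt(src, tgt, config = adaptation_config(alpha = 0.8))
  expect_equal(fixed$alpha, 0.8)
  expect_null(attr(fixed, "cv_table"))
  searched <- adapt(src, tgt, config = adaptation_config(folds = 5L, seed = 2L))
  expect_true(searched$alpha %in% alpha_grid())
  expect_s3_class(attr(searched, "cv_table"), "tbl_df")
  none <- adapt(src, tgt, config = adaptation_config(target_fraction = "0%"))
  expect_equal(none$alpha, 0)
  expect_equal(none$n, 0L)
})

test_that("tidy and glance expose the fit summary", {
  src <- make_xy(50, seed = 19L)
  tgt <- make_xy(20, seed = 20L)
  f <- fit_weighted(src, tgt, alpha = 0.75)
  td <- tidy(f)
  gl <- glance(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(gl$alpha, 0.75)
  expect_equal(gl$m, 50L)
  expect_equal(gl$n, 20L)
})
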