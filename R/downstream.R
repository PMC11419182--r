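# Downstream clinical analyses built on trained diagnostic / age models:
# (a) linear discriminant analysis on the disease-probability output to
#     separate progressive / stable / reverting MCI at baseline;
# (b) brain-age residuals and their Pearson correlations with clinical
#     variables.

# One-dimensional two-class LDA with pooled variance and empirical priors.
lda_1d <- function(x, class) {
  lev <- sort(unique(class))
  if (length(lev) != 2L) abort("lda_1d needs exactly 2 classes.")
  x1 <- x[class == lev[1L]]; x2 <- x[class == lev[2L]]
  mu <- c(mean(x1), mean(x2))
  n <- length(x)
  s2 <- (sum((x1 - mu[1L])^2) + sum((x2 - mu[2L])^2)) / (n - 2L)
  if (s2 <= 0) s2 <- .Machine$double.eps
  priors <- c(length(x1), length(x2)) / n
  # decision boundary: equal discriminants of the two classes
  boundary <- if (mu[1L] != mu[2L]) {
    (mu[1L] + mu[2L]) / 2 + s2 * log(priors[1L] / priors[2L]) / (mu[2L] - mu[1L])
  } else {
    NA_real_
  }
  list(levels = lev, means = mu, pooled_var = s2, priors = priors,
       boundary = boundary)
}

lda_1d_posterior <- function(fit, x) {
  # posterior probability of the second (higher-sorted) class
  a <- (fit$means[2L] - fit$means[1L]) / fit$pooled_var
  b <- (fit$means[1L]^2 - fit$means[2L]^2) / (2 * fit$pooled_var) +
    log(fit$priors[2L] / fit$priors[1L])
  plogis(a * x + b)
}

#' MCI progression analysis from disease-probability scores
#'
#' Uses the (uncalibrated) disease probability assigned by a diagnostic model
#' to each mild-cognitive-impairment subject as the single covariate of a
#' linear discriminant analysis separating progression classes. Each binary
#' pair (default pMCI vs sMCI and pMCI vs nMCI) is analysed separately: the
#' data are split into `folds` stratified folds, the LDA is fitted on one
#' fold (a `label_fraction` of about 1/folds of the labels) and its AUC is
#' evaluated on the remaining rows, rotating over folds. A fold whose
#' training part misses a class is skipped with a warning.
#'
#' @param probs Disease probability per MCI subject (e.g.
#'   `predict(fit, mci_design)`).
#' @param progression Class label per subject: `"pMCI"`, `"sMCI"` or
#'   `"nMCI"`.
#' @param pairs List of 2-vectors of classes to contrast; the first element
#'   is the positive class.
#' @param folds Number of folds (default 5; with 5 folds the training
#'   fraction is the protocol's 20%).
#' @param seed Integer seed.
#' @return A `progression_result`: tibble of per-pair AUC mean and sd over
#'   folds, with the full-data 1-D LDA parameters per pair in
#'   `attr(, "lda")`.
#' @export
lda_progression <- function(probs, progression,
                            pairs = list(c("pMCI", "sMCI"), c("pMCI", "nMCI")),
                            folds = 5L, seed = 1L) {
  folds <- check_count(folds, "folds", 2L)
  progression <- as.character(progression)
  present <- unique(progression[!is.na(progression)])
  if (length(present) < 2L) abort("need at least 2 progression classes.")
  lda_params <- list()
  rows <- lapply(pairs, function(pr) {
    keep <- which(progression %in% pr)
    x <- probs[keep]
    cls <- progression[keep]
    if (length(unique(cls)) < 2L) {
      warn(sprintf("pair %s vs %s has a missing class; skipped.", pr[1L], pr[2L]))
      return(tibble(positive = pr[1L], negative = pr[2L],
                    auc_mean = NA_real_, auc_sd = NA_real_, folds_used = 0L))
    }
    fold_id <- stratified_folds(cls, folds, seed = child_seed(seed, 1L))
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id == f
      if (length(unique(cls[tr])) < 2L) {
        warn(sprintf("fold %d lacks a class in its training fraction; skipped.", f))
        return(NA_real_)
      }
      fit <- lda_1d(x[tr], cls[tr])
      post <- lda_1d_posterior(fit, x[!tr])
      # orient the score toward the declared positive class
      score <- if (fit$levels[2L] == pr[1L]) post else 1 - post
      auc(score, as.numeric(cls[!tr] == pr[1L]))
    }, numeric(1))
    lda_params[[paste(pr, collapse = "_vs_")]] <<- lda_1d(x, cls)
    tibble(positive = pr[1L], negative = pr[2L],
           auc_mean = mean(aucs, na.rm = TRUE),
           auc_sd = sd(aucs[!is.na(aucs)]),
           folds_used = sum(!is.na(aucs)))
  })
  out <- bind_rows(rows)
  structure(out, lda = lda_params,
            class = c("progression_result", class(out)))
}

#' @exportS3Method generics::tidy
tidy.progression_result <- function(x, ...) as_tibble(x)

#' Brain-age residuals
#'
#' The brain-age residual (BAR, also called the brain-age gap) is the model's
#' predicted age minus the chronological age, in years; positive values
#' suggest accelerated aging. Rows with missing chronological age are dropped
#' and their count reported.
#'
#' @param predicted_age Model predictions (years).
#' @param chronological_age Actual ages (years, positive).
#' @return A `bar_table` tibble with `predicted`, `chronological` and `bar`
#'   columns; `attr(, "n_dropped")` counts rows dropped for missing age.
#' @export
brain_age_residuals <- function(predicted_age, chronological_age) {
  if (length(predicted_age) != length(chronological_age)) abort("length mismatch.")
  keep <- !is.na(chronological_age)
  n_dropped <- sum(!keep)
  if (any(chronological_age[keep] <= 0)) abort("chronological ages must be positive.")
  out <- tibble(
    predicted = predicted_age[keep],
    chronological = chronological_age[keep],
    bar = predicted_age[keep] - chronological_age[keep]
  )
  structure(out, n_dropped = n_dropped,
            class = c("bar_table", class(out)))
}

#' Correlate brain-age residuals with clinical variables
#'
#' Pearson correlation between the BAR and each clinical column, over the
#' subjects where that column is observed, with the two-sided p-value from
#' the exact t-transform of r. Cognitive measures that decline with aging
#' (MMSE-like) are expected to correlate negatively; timed tests that worsen
#' (increase) with aging (TMT-like) positively.
#'
#' @param bar_table A [brain_age_residuals()] result (rows aligned with
#'   `clinical_vars`).
#' @param clinical_vars Data frame of numeric clinical variables.
#' @param sig_level Significance flag threshold on the p-value (default
#'   0.01).
#' @return Tibble with one row per variable: `r`, `p_value`, `n`,
#'   `significant`, and a `reason` for variables where r is undefined.
#' @export
bar_correlations <- function(bar_table, clinical_vars, sig_level = 0.01) {
  if (nrow(clinical_vars) != nrow(bar_table)) {
    abort("`clinical_vars` rows must align with `bar_table`.")
  }
  rows <- lapply(names(clinical_vars), function(vn) {
    v <- clinical_vars[[vn]]
    keep <- !is.na(v) & !is.na(bar_table$bar)
    n_obs <- sum(keep)
    if (n_obs < 3L) {
      return(tibble(variable = vn, r = NA_real_, p_value = NA_real_,
                    n = n_obs, significant = NA,
                    reason = "fewer than 3 paired observations"))
    }
    if (sd(v[keep]) == 0 || sd(bar_table$bar[keep]) == 0) {
      return(tibble(variable = vn, r = NA_real_, p_value = NA_real_,
                    n = n_obs, significant = NA,
                    reason = "constant vector; correlation undefined"))
    }
    ct <- cor.test(bar_table$bar[keep], v[keep], method = "pearson")
    tibble(variable = vn, r = unname(ct$estimate), p_value = ct$p.value,
           n = n_obs, significant = ct$p.value < sig_level,
           reason = NA_character_)
  })
  bind_rows(rows)
}
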