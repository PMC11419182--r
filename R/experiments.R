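# Packaged desk-scale experiments. These fix the study conditions (cohort
# sizes, shift magnitudes, label models) once, so tests, scripts and the
# vignette all exercise the same benchmark rather than each inventing its
# own.

#' Benchmark two-group adaptation cohort
#'
#' The package's reference source-to-target condition: a large source group
#' and a smaller target group over 20 numeric features, with a moderate
#' compound shift — the target's first five features (the label-active ones)
#' are mean-shifted by 0.5 SD, and the label model flips the sign of two of
#' the five active coefficients. A source-only model is therefore
#' systematically miscalibrated on the target, and a handful of target
#' labels carries real information: the regime the alpha-weighted objective
#' is designed for.
#'
#' @param m,n Source and target group sizes (defaults 1000 and 200).
#' @param seed Integer seed.
#' @return A [cohort_spec()] with groups `"S"` (source) and `"T"` (target).
#' @export
example_adaptation_spec <- function(m = 1000L, n = 200L, seed = 1L) {
  beta_s <- c(rep(1, 5), rep(0, 15))
  beta_t <- beta_s
  beta_t[c(1L, 2L)] <- -1
  cohort_spec(
    n_per_group = c(S = m, T = n),
    n_numeric = 20L,
    shift = list(T = c(rep(0.5, 5), rep(0, 15))),
    label_model = list(S = list(coef = beta_s, intercept = 0),
                       T = list(coef = beta_t, intercept = 0)),
    seed = seed
  )
}

#' Replicated adaptation-gain experiment
#'
#' For each replicate: draw a fresh benchmark cohort
#' ([example_adaptation_spec()]), run the 10%-target evaluation protocol with
#' nested-CV alpha selection, and record the target-test AUC of the weighted
#' model against the source-only baseline. The headline mechanism predicts
#' the weighted model wins in the large majority of replicates.
#'
#' @param n_reps Number of seeded replicates (default 50).
#' @param seed Master seed; each replicate derives its own.
#' @param outer_folds Outer folds evaluated per replicate (default 1 for
#'   speed; `NULL` runs all five).
#' @param learner Learner used throughout (default `"logistic"`).
#' @param m,n Cohort sizes passed to [example_adaptation_spec()].
#' @return Tibble with one row per replicate: `auc_weighted`, `auc_source`,
#'   `alpha` (mean of the per-fold nested-CV choices), `win`.
#' @export
adaptation_gain_experiment <- function(n_reps = 50L, seed = 1L,
                                       outer_folds = 1L,
                                       learner = "logistic",
                                       m = 1000L, n = 200L) {
  rows <- lapply(seq_len(n_reps), function(r) {
    rs <- child_seed(seed, r)
    cohort <- generate_cohort(example_adaptation_spec(m = m, n = n, seed = rs))
    rep_eval <- evaluate_adaptation(cohort, "S", "T", setting = "10%",
                                    learner = learner, seed = rs,
                                    outer_folds = outer_folds)
    g <- glance(rep_eval)
    w <- g$mean[g$model == "weighted"]
    s <- g$mean[g$model == "source_only"]
    tibble(rep = r, auc_weighted = w, auc_source = s,
           alpha = g$mean_alpha[g$model == "weighted"],
           alphas_in_grid = all(
             rep_eval$alpha[rep_eval$model == "weighted"] %in% alpha_grid()
           ),
           win = w >= s)
  })
  bind_rows(rows)
}

#' Type-I error of the MMD permutation test under the null
#'
#' Draws `n_reps` pairs of i.i.d. standard-Gaussian samples (no shift), runs
#' the permutation test on each, and reports the rejection rate at `level` —
#' which should sit at the nominal level up to binomial noise.
#'
#' @param n_reps Replicates (default 500).
#' @param n Samples per side (default 100).
#' @param d Feature dimension (default 20).
#' @param B Permutations per test (default 199).
#' @param level Test level (default 0.05).
#' @param seed Master seed (data and permutation streams are decorrelated).
#' @return A list: `rejection_rate`, `n_reps`, plus the binomial 99% interval
#'   around `level` for reference.
#' @export
mmd_calibration_experiment <- function(n_reps = 500L, n = 100L, d = 20L,
                                       B = 199L, level = 0.05, seed = 1L) {
  rej <- vapply(seq_len(n_reps), function(r) {
    rs <- child_seed(seed, r)
    with_seed(rs, {
      x <- matrix(rnorm(n * d), n)
      y <- matrix(rnorm(n * d), n)
    })
    mmd_permutation_test(x, y, B = B,
                         seed = child_seed(rs, 777L))$p_value <= level
  }, logical(1))
  ci <- stats::qbinom(c(0.005, 0.995), n_reps, level) / n_reps
  list(rejection_rate = mean(rej), n_reps = n_reps, level = level,
       binom99 = ci)
}

#' Power of the MMD permutation test under a mean shift
#'
#' As [mmd_calibration_experiment()], but the second sample's first
#' `shifted` features are mean-shifted by `shift` standard deviations.
#'
#' @inheritParams mmd_calibration_experiment
#' @param shifted Number of shifted features (default 5).
#' @param shift Shift size in SD units (default 1).
#' @return A list with the `rejection_rate` and the settings.
#' @export
mmd_power_experiment <- function(n_reps = 200L, n = 100L, d = 20L,
                                 shifted = 5L, shift = 1, B = 199L,
                                 level = 0.05, seed = 1L) {
  rej <- vapply(seq_len(n_reps), function(r) {
    rs <- child_seed(seed, r)
    with_seed(rs, {
      x <- matrix(rnorm(n * d), n)
      y <- matrix(rnorm(n * d), n)
      y[, seq_len(shifted)] <- y[, seq_len(shifted)] + shift
    })
    mmd_permutation_test(x, y, B = B,
                         seed = child_seed(rs, 777L))$p_value <= level
  }, logical(1))
  list(rejection_rate = mean(rej), n_reps = n_reps, level = level,
       shifted = shifted, shift = shift)
}
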