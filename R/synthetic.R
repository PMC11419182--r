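#' Specify a synthetic multi-group cohort
#'
#' Describes a tabular cohort made of several population groups (e.g. strata
#' by sex, age band, race or clinical study) with controlled distribution
#' shift between them. Numeric features are drawn from group-shifted
#' Gaussians (optionally exponentiated to give log-normal, skewed columns);
#' labels come from a per-group generalized linear model, so both covariate
#' shift (means/covariance) and concept shift (label model) can be dialled
#' in independently.
#'
#' @param n_per_group Named integer vector of subjects per group, e.g.
#'   `c(A = 500, B = 50)`. Group imbalance in real consortia can be extreme
#'   (minority groups of 1--2% of the total), which this supports directly.
#' @param n_numeric Number of numeric features (default 20, standing in for
#'   regional brain volumes plus clinical scores).
#' @param categorical_levels Named list of character vectors giving the
#'   categories of each categorical feature (default a sex-like and an
#'   APOE-like column).
#' @param shift Named list (by group) of numeric vectors of length
#'   `n_numeric`: the mean offset of each feature in that group, in units of
#'   the base feature standard deviation. Groups absent from the list get
#'   zero shift. A single number is recycled.
#' @param shift_scale Named numeric vector (by group): multiplier on the
#'   feature standard deviation for that group (covariance scale). Default 1.
#' @param rho Equicorrelation of the numeric features within a subject
#'   (default 0; set small positive values for more realistic collinearity).
#' @param label_model Named list (by group) of `list(coef =, intercept =)`
#'   describing the label-generating model: logistic for
#'   `task = "classification"`, linear for `task = "regression"`. Groups
#'   absent from the list share the model of the first group.
#' @param task `"classification"` (binary label) or `"regression"`
#'   (continuous label, e.g. age in years).
#' @param noise_sd Residual standard deviation of the regression label.
#' @param class_balance Optional target positive fraction in (0, 1); when
#'   given, each group's intercept is re-solved so the expected positive rate
#'   matches it.
#' @param log_normal_cols Integer indices of numeric columns to exponentiate,
#'   producing skewed (log-normal) features that exercise quantile
#'   normalization downstream.
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [inject_missingness()],
#'   [make_progression_labels()]
#' @export
cohort_spec <- function(n_per_group,
                        n_numeric = 20L,
                        categorical_levels = list(
                          sex = c("M", "F"),
                          apoe = c("e2", "e3", "e4")
                        ),
                        shift = list(),
                        shift_scale = NULL,
                        rho = 0,
                        label_model = NULL,
                        task = c("classification", "regression"),
                        noise_sd = 1,
                        class_balance = NULL,
                        log_normal_cols = integer(),
                        seed = 1L) {
  task <- match.arg(task)
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    abort("`n_per_group` must be a named vector of group sizes.")
  }
  for (g in names(n_per_group)) check_count(n_per_group[[g]], paste0("n_per_group[", g, "]"))
  n_numeric <- check_count(n_numeric, "n_numeric")
  check_scalar_number(rho, "rho", lower = 0, upper = 0.99)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(class_balance)) {
    check_scalar_number(class_balance, "class_balance", 0, 1,
                        open_lower = TRUE, open_upper = TRUE)
  }
  if (length(log_normal_cols) &&
      (any(log_normal_cols < 1) || any(log_normal_cols > n_numeric))) {
    abort("`log_normal_cols` must index numeric feature columns.")
  }
  groups <- names(n_per_group)

  expand_shift <- function(x, g) {
    v <- x[[g]] %||% 0
    if (length(v) == 1L) v <- rep(v, n_numeric)
    if (length(v) != n_numeric) {
      abort(sprintf("`shift[[%s]]` must have length 1 or n_numeric.", g))
    }
    v
  }
  shift <- setNames(lapply(groups, function(g) expand_shift(shift, g)), groups)

  if (is.null(shift_scale)) shift_scale <- setNames(rep(1, length(groups)), groups)
  scl <- setNames(rep(1, length(groups)), groups)
  scl[names(shift_scale)] <- shift_scale
  if (any(scl <= 0)) abort("`shift_scale` entries must be positive.")

  if (is.null(label_model)) {
    beta <- c(rep(1, min(5L, n_numeric)), rep(0, max(0L, n_numeric - 5L)))
    label_model <- list(list(coef = beta, intercept = 0))
    names(label_model) <- groups[1L]
  }
  for (g in names(label_model)) {
    lm_g <- label_model[[g]]
    if (!is.list(lm_g) || is.null(lm_g$coef) || is.null(lm_g$intercept)) {
      abort(sprintf("`label_model[[%s]]` needs `coef` and `intercept`.", g))
    }
    if (length(lm_g$coef) != n_numeric) {
      abort(sprintf("`label_model[[%s]]$coef` must have length n_numeric.", g))
    }
  }
  full_lm <- setNames(lapply(groups, function(g) {
    label_model[[g]] %||% label_model[[1L]]
  }), groups)

  structure(
    list(
      n_per_group = setNames(as.integer(n_per_group), groups),
      n_numeric = n_numeric,
      categorical_levels = categorical_levels,
      shift = shift,
      shift_scale = scl,
      rho = rho,
      label_model = full_lm,
      task = task,
      noise_sd = noise_sd,
      class_balance = class_balance,
      log_normal_cols = as.integer(log_normal_cols),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(x$n_per_group), x$n_per_group),
                         collapse = ", "), "\n")
  cat("  features:", x$n_numeric, "numeric,",
      length(x$categorical_levels), "categorical\n")
  cat("  task:", x$task, " seed:", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic grouped cohort
#'
#' Draws one row per subject according to a [cohort_spec()]: numeric features
#' from group-shifted (equi-correlated) Gaussians, categorical features
#' uniformly over their category sets, and labels from the group's label
#' model. No missingness is introduced here; see [inject_missingness()].
#'
#' @param spec A [cohort_spec()].
#' @return A `grouped_cohort`: a tibble with columns `.id`, `group`, numeric
#'   features `x1..xp`, the categorical features, and `label`, plus
#'   attributes recording which columns are features and of what kind.
#' @examples
#' spec <- cohort_spec(c(A = 100, B = 40), n_numeric = 5, seed = 7)
#' cohort <- generate_cohort(spec)
#' dplyr::count(cohort, group)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  p <- spec$n_numeric
  groups <- names(spec$n_per_group)
  with_seed(spec$seed, {
    rows <- lapply(groups, function(g) {
      n <- spec$n_per_group[[g]]
      # Equicorrelated Gaussian: x = sqrt(rho) z0 + sqrt(1-rho) z
      z <- matrix(rnorm(n * p), n, p)
      if (spec$rho > 0) {
        z0 <- rnorm(n)
        z <- sqrt(spec$rho) * z0 + sqrt(1 - spec$rho) * z
      }
      X <- sweep(z * spec$shift_scale[[g]], 2L, spec$shift[[g]], `+`)
      lm_g <- spec$label_model[[g]]
      eta <- drop(X %*% lm_g$coef) + lm_g$intercept
      if (spec$task == "classification") {
        if (!is.null(spec$class_balance)) {
          # re-solve the intercept so E[plogis(eta + b)] hits the target rate
          f <- function(b) mean(plogis(eta + b)) - spec$class_balance
          b <- stats::uniroot(f, c(-50, 50))$root
          eta <- eta + b
        }
        y <- rbinom(n, 1L, plogis(eta))
      } else {
        y <- eta + rnorm(n, sd = spec$noise_sd)
      }
      if (length(spec$log_normal_cols)) {
        X[, spec$log_normal_cols] <- exp(X[, spec$log_normal_cols])
      }
      colnames(X) <- paste0("x", seq_len(p))
      out <- as_tibble(X)
      out$group <- g
      out$label <- y
      for (cn in names(spec$categorical_levels)) {
        lev <- spec$categorical_levels[[cn]]
        out[[cn]] <- sample(lev, n, replace = TRUE)
      }
      out
    })
  })
  cohort <- bind_rows(rows)
  cohort$.id <- seq_len(nrow(cohort))
  cohort <- cohort[, c(".id", "group", paste0("x", seq_len(p)),
                       names(spec$categorical_levels), "label")]
  new_grouped_cohort(
    cohort,
    numeric_cols = paste0("x", seq_len(p)),
    categorical_cols = names(spec$categorical_levels),
    task = spec$task,
    spec = spec
  )
}

new_grouped_cohort <- function(tbl, numeric_cols, categorical_cols, task,
                               spec = NULL) {
  structure(
    as_tibble(tbl),
    numeric_cols = numeric_cols,
    categorical_cols = categorical_cols,
    task = task,
    spec = spec,
    class = c("grouped_cohort", class(as_tibble(tbl)))
  )
}

#' Feature-column bookkeeping for a grouped cohort
#'
#' @param cohort A `grouped_cohort` (or any data frame; columns then have to
#'   be named explicitly by downstream functions).
#' @return Character vectors of column names.
#' @export
numeric_features <- function(cohort) attr(cohort, "numeric_cols")

#' @rdname numeric_features
#' @export
categorical_features <- function(cohort) attr(cohort, "categorical_cols")

#' Introduce missing-completely-at-random gaps into feature columns
#'
#' Sets each designated cell to `NA` independently with its column's rate,
#' emulating the sparsity of clinical, genetic and cognitive variables in
#' pooled consortium tables. The `group` and `label` columns are never
#' masked. The input cohort is not modified.
#'
#' @param cohort A `grouped_cohort` or data frame.
#' @param rates Either a single rate applied to all feature columns or a
#'   named vector of per-column rates, each in \[0, 1\].
#' @param seed Integer seed.
#' @return A cohort of the same shape with `NA`s injected.
#' @export
inject_missingness <- function(cohort, rates, seed = 1L) {
  protected <- c(".id", "group", "label", "progression")
  if (is.null(names(rates))) {
    if (length(rates) != 1L) {
      abort("`rates` must be a single number or a named vector.")
    }
    cols <- setdiff(names(cohort), protected)
    rates <- setNames(rep(rates, length(cols)), cols)
  }
  if (any(rates < 0 | rates > 1)) abort("missingness rates must lie in [0, 1].")
  bad <- intersect(names(rates), protected)
  if (length(bad)) {
    abort(paste0("cannot mask protected column(s): ", paste(bad, collapse = ", ")))
  }
  missing_cols <- setdiff(names(rates), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("unknown column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- cohort
  with_seed(seed, {
    for (cn in names(rates)) {
      r <- rates[[cn]]
      if (r > 0) {
        mask <- runif(nrow(out)) < r
        out[[cn]][mask] <- NA
      }
    }
  })
  out
}

#' Assign progression classes to an intermediate-severity stratum
#'
#' Labels flagged subjects as progressive (`pMCI`), stable (`sMCI`) or
#' reverting (`nMCI`), from a latent severity score aligned with the
#' disease direction of the label model. Severity is blended with
#' independent noise and mapped through the Gaussian CDF, so the marginal
#' class frequencies match `class_priors` exactly while higher-severity
#' subjects are monotonically more likely to progress. A diagnosis model
#' trained on the disease therefore carries signal for separating pMCI
#' from nMCI, without simulating longitudinal follow-up.
#'
#' @param cohort A `grouped_cohort`.
#' @param coef Numeric vector over the numeric feature columns defining the
#'   disease (severity) direction; typically the label-model coefficients.
#' @param flagged Logical vector marking the intermediate stratum to label
#'   (default: all rows).
#' @param class_priors Named probabilities for `pMCI`, `sMCI`, `nMCI`
#'   (summing to 1).
#' @param strength Non-negative alignment between severity and progression;
#'   0 makes classes independent of features.
#' @param seed Integer seed.
#' @return The cohort with a `progression` column (`NA` for unflagged rows).
#' @export
make_progression_labels <- function(cohort, coef,
                                    flagged = NULL,
                                    class_priors = c(pMCI = 0.3, sMCI = 0.5, nMCI = 0.2),
                                    strength = 1,
                                    seed = 1L) {
  if (is.null(flagged)) flagged <- rep(TRUE, nrow(cohort))
  if (!any(flagged)) abort("no flagged subjects to label.")
  if (abs(sum(class_priors) - 1) > 1e-8) abort("`class_priors` must sum to 1.")
  if (!all(c("pMCI", "sMCI", "nMCI") %in% names(class_priors))) {
    abort("`class_priors` must name pMCI, sMCI and nMCI.")
  }
  check_scalar_number(strength, "strength", lower = 0)
  num_cols <- numeric_features(cohort)
  X <- as.matrix(cohort[flagged, num_cols, drop = FALSE])
  if (length(coef) != ncol(X)) abort("`coef` must match the numeric features.")
  sev <- drop(X %*% coef)
  s <- sd(sev)
  sev <- if (s > 0) (sev - mean(sev)) / s else rep(0, length(sev))
  with_seed(seed, {
    e <- rnorm(length(sev))
  })
  # v is Uniform(0,1) marginally; severity shifts it monotonically upward
  v <- pnorm((strength * sev + e) / sqrt(strength^2 + 1))
  cuts <- cumsum(c(class_priors[["nMCI"]], class_priors[["sMCI"]]))
  cls <- ifelse(v < cuts[1L], "nMCI", ifelse(v < cuts[2L], "sMCI", "pMCI"))
  out <- cohort
  out$progression <- NA_character_
  out$progression[flagged] <- cls
  out
}

#' Write / read a cohort as CSV plus JSON sidecar
#'
#' The CSV holds one header row and empty cells for missing values; the
#' sidecar records column kinds, category sets and (if available) the
#' generating spec, so a cohort round-trips exactly.
#'
#' @param cohort A `grouped_cohort`.
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), paste0(path, ".csv"),
                   row.names = FALSE, na = "")
  meta <- list(
    numeric_cols = numeric_features(cohort),
    categorical_cols = categorical_features(cohort),
    task = attr(cohort, "task"),
    categorical_levels = {
      cc <- categorical_features(cohort)
      setNames(lapply(cc, function(cn) sort(unique(stats::na.omit(cohort[[cn]])))), cc)
    }
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tbl <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE,
                         na.strings = "")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_grouped_cohort(tbl,
                     numeric_cols = meta$numeric_cols,
                     categorical_cols = meta$categorical_cols,
                     task = meta$task)
}
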