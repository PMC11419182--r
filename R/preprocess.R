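#' Fit the tabular feature pipeline on training rows
#'
#' Learns, from training rows only, everything needed to turn raw cohort rows
#' into a fully numeric design matrix:
#' \itemize{
#'   \item per numeric column: the median (for imputation), centering and
#'     scaling constants (population variance convention, i.e. divide by
#'     \eqn{n}), a skewness flag, and — for skewed columns — a rank-based
#'     quantile map to standard-normal scores;
#'   \item per categorical column: the category vocabulary plus a reserved
#'     `"(unknown)"` category that absorbs missing and unseen values;
#'   \item the list of columns that had any missing value at fit time, for
#'     which a binary missingness-indicator column is appended at transform
#'     time (absence is informative in sparse clinical tables).
#' }
#' Columns with absolute sample skewness above `skew_threshold` are
#' quantile-normalized: fitted values map to \eqn{\Phi^{-1}((r - 0.5)/n)}
#' with average ranks for ties; new values are interpolated along that map
#' and clamped at its ends. Constant columns are flagged and transform to 0.
#'
#' The state is a pure function of the training rows: held-out rows can never
#' influence it, which is the no-leakage contract the nested cross-validation
#' protocol relies on.
#'
#' @param data Training rows (data frame / `grouped_cohort`).
#' @param numeric_cols,categorical_cols Feature column names; default taken
#'   from the cohort's bookkeeping attributes.
#' @param skew_threshold Absolute skewness above which a column is
#'   quantile-normalized (default 1).
#' @return A `preprocessor` object.
#' @export
fit_preprocessor <- function(data,
                             numeric_cols = numeric_features(data),
                             categorical_cols = categorical_features(data),
                             skew_threshold = 1) {
  if (is.null(numeric_cols) && is.null(categorical_cols)) {
    abort("no feature columns: supply `numeric_cols`/`categorical_cols`.")
  }
  if (nrow(data) < 2L) abort("need at least 2 training rows.")
  numeric_cols <- numeric_cols %||% character()
  categorical_cols <- categorical_cols %||% character()

  num_state <- lapply(numeric_cols, function(cn) {
    x <- data[[cn]]
    obs <- x[!is.na(x)]
    if (!length(obs)) abort(sprintf("numeric column `%s` is fully missing.", cn))
    med <- median(obs)
    imp <- ifelse(is.na(x), med, x)
    skew <- sample_skewness(obs)
    if (abs(skew) > skew_threshold) {
      n <- length(imp)
      r <- rank(imp, ties.method = "average")
      scores <- qnorm((r - 0.5) / n)
      ord <- order(imp)
      xv <- imp[ord]
      sv <- scores[ord]
      keep <- !duplicated(xv)
      list(kind = "quantile", median = med, skewness = skew,
           map_x = xv[keep], map_y = sv[keep], had_missing = anyNA(x))
    } else {
      ctr <- mean(imp)
      scl <- sqrt(mean((imp - ctr)^2))
      list(kind = if (scl > 0) "standard" else "constant",
           median = med, skewness = skew,
           center = ctr, scale = scl, had_missing = anyNA(x))
    }
  })
  names(num_state) <- numeric_cols

  cat_state <- lapply(categorical_cols, function(cn) {
    x <- as.character(data[[cn]])
    lev <- sort(unique(x[!is.na(x)]))
    list(levels = lev, had_missing = anyNA(x))
  })
  names(cat_state) <- categorical_cols

  structure(
    list(numeric = num_state, categorical = cat_state,
         skew_threshold = skew_threshold,
         indicator_cols = c(
           numeric_cols[vapply(num_state, `[[`, TRUE, "had_missing")],
           categorical_cols[vapply(cat_state, `[[`, TRUE, "had_missing")]
         )),
    class = "preprocessor"
  )
}

UNKNOWN_CATEGORY <- "(unknown)"

#' Transform rows with a fitted preprocessor
#'
#' Applies the fitted state to any rows sharing the training schema: numeric
#' columns are median-imputed then standardized (or mapped through the fitted
#' quantile map), categorical columns are one-hot encoded over the fitted
#' vocabulary plus the `"(unknown)"` category (missing and unseen values both
#' land there), and one 0/1 indicator column is appended per feature that had
#' missing values at fit time.
#'
#' @param state A `preprocessor` from [fit_preprocessor()].
#' @param rows Data frame of rows to transform.
#' @return A tibble of numeric columns: transformed features, one-hot
#'   categorical columns (`col__level`), and `col__missing` indicators.
#' @export
apply_preprocessor <- function(state, rows) {
  if (!inherits(state, "preprocessor")) abort("`state` must be a preprocessor.")
  need <- c(names(state$numeric), names(state$categorical))
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    abort(paste0("schema mismatch; missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- list()
  for (cn in names(state$numeric)) {
    st <- state$numeric[[cn]]
    x <- rows[[cn]]
    imp <- ifelse(is.na(x), st$median, x)
    out[[cn]] <- switch(
      st$kind,
      quantile = if (length(st$map_x) == 1L) {
        rep(0, length(imp))
      } else {
        approx(st$map_x, st$map_y, xout = imp, rule = 2)$y
      },
      standard = (imp - st$center) / st$scale,
      constant = rep(0, length(imp))
    )
  }
  for (cn in names(state$categorical)) {
    st <- state$categorical[[cn]]
    x <- as.character(rows[[cn]])
    x[is.na(x) | !(x %in% st$levels)] <- UNKNOWN_CATEGORY
    for (lev in c(st$levels, UNKNOWN_CATEGORY)) {
      out[[paste0(cn, "__", lev)]] <- as.numeric(x == lev)
    }
  }
  for (cn in state$indicator_cols) {
    out[[paste0(cn, "__missing")]] <- as.numeric(is.na(rows[[cn]]))
  }
  as_tibble(out)
}

#' @export
predict.preprocessor <- function(object, newdata, ...) {
  apply_preprocessor(object, newdata)
}

#' @export
print.preprocessor <- function(x, ...) {
  kinds <- vapply(x$numeric, `[[`, "", "kind")
  cat("<preprocessor>\n")
  cat(sprintf("  numeric: %d (%d standardized, %d quantile-mapped, %d constant)\n",
              length(kinds), sum(kinds == "standard"),
              sum(kinds == "quantile"), sum(kinds == "constant")))
  cat(sprintf("  categorical: %d; missingness indicators: %d\n",
              length(x$categorical), length(x$indicator_cols)))
  invisible(x)
}

#' Serialize a preprocessor to / from JSON
#'
#' Exact reuse of a fitted state across folds or sessions.
#'
#' @param state A `preprocessor`.
#' @param path File path for the JSON document.
#' @return `preprocessor_to_json` returns `path` invisibly;
#'   `preprocessor_from_json` returns the `preprocessor`.
#' @export
preprocessor_to_json <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname preprocessor_to_json
#' @export
preprocessor_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$numeric <- lapply(raw$numeric, as.list)
  raw$categorical <- lapply(raw$categorical, as.list)
  raw$indicator_cols <- as.character(raw$indicator_cols %||% character())
  structure(raw, class = "preprocessor")
}
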