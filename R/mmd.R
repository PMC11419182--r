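# Distribution-shift quantification between population groups: unbiased
# MMD^2 on (learned) features, permutation p-values, and pairwise shift
# matrices with a linkage tree for dendrograms.

resolve_kernel <- function(kernel, sigma = NULL) {
  if (is.function(kernel)) return(kernel)
  switch(
    kernel,
    linear = function(X, Y) tcrossprod(X, Y),
    rbf = function(X, Y) {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
      d2[d2 < 0] <- 0
      s <- sigma
      if (is.null(s)) {
        # median heuristic on the pooled pairwise distances
        Z <- rbind(X, Y)
        dz <- outer(rowSums(Z^2), rowSums(Z^2), `+`) - 2 * tcrossprod(Z)
        dz <- dz[upper.tri(dz)]
        s <- sqrt(median(dz[dz > 0]) / 2)
        if (!is.finite(s) || s <= 0) s <- 1
      }
      exp(-d2 / (2 * s^2))
    },
    abort(sprintf("unknown kernel `%s`.", kernel))
  )
}

#' Unbiased squared maximum mean discrepancy between two samples
#'
#' Computes the unbiased U-statistic estimator of the squared MMD between two
#' equal-sized samples,
#' \deqn{\widehat{MMD}^2_u = \frac{1}{n^2-n}\sum_{i \ne j}
#'   \left[k(x_i,x_j) + k(x'_i,x'_j) - k(x_i,x'_j) - k(x_j,x'_i)\right],}
#' which may be negative (its expectation under equal distributions is 0).
#' The default linear kernel is the inner product of the supplied feature
#' vectors — the natural choice when the features are a learned embedding,
#' since the embedding itself plays the role of the canonical feature map.
#'
#' @param x,y Numeric matrices (samples in rows) with the same number of
#'   rows and columns; `n >= 2` per side.
#' @param kernel `"linear"` (default), `"rbf"`, or a function
#'   `function(X, Y)` returning the cross-Gram matrix.
#' @param sigma Bandwidth for the RBF kernel (default: median heuristic).
#' @return The scalar unbiased MMD^2 estimate (dimensionless).
#' @examples
#' mmd2_unbiased(matrix(c(0, 2)), matrix(c(1, 3)))  # = 1, the mean gap squared
#' @export
mmd2_unbiased <- function(x, y, kernel = "linear", sigma = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) {
    abort("`x` and `y` must have equal sample counts (subsample the larger).")
  }
  if (ncol(x) != ncol(y)) abort("`x` and `y` must have the same dimension.")
  if (nrow(x) < 2L) abort("need at least 2 samples per side (n^2 - n > 0).")
  k <- resolve_kernel(kernel, sigma)
  Kxx <- k(x, x); Kyy <- k(y, y); Kxy <- k(x, y)
  n <- nrow(x)
  (sum(Kxx) - sum(diag(Kxx)) +
     sum(Kyy) - sum(diag(Kyy)) -
     2 * (sum(Kxy) - sum(diag(Kxy)))) / (n^2 - n)
}

# Same statistic evaluated from a pooled Gram matrix and index sets; lets a
# permutation test reuse one Gram computation across all resamples.
mmd2_from_gram <- function(K, idx_p, idx_q) {
  n <- length(idx_p)
  Kxx <- K[idx_p, idx_p, drop = FALSE]
  Kyy <- K[idx_q, idx_q, drop = FALSE]
  Kxy <- K[idx_p, idx_q, drop = FALSE]
  (sum(Kxx) - sum(diag(Kxx)) +
     sum(Kyy) - sum(diag(Kyy)) -
     2 * (sum(Kxy) - sum(diag(Kxy)))) / (n^2 - n)
}

#' Permutation two-sample test on the unbiased MMD^2
#'
#' Pools the two samples, recomputes the statistic under `B` random
#' reassignments of group membership (preserving group sizes), and reports
#' the add-one permutation p-value
#' \eqn{p = (1 + \#\{MMD^2_{perm} \ge MMD^2_{obs}\}) / (1 + B)}, so the
#' smallest attainable p-value is \eqn{1/(B+1)}.
#'
#' @inheritParams mmd2_unbiased
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed for the permutations.
#' @return A list with `statistic`, `p_value`, `B` and `n`.
#' @export
mmd_permutation_test <- function(x, y, kernel = "linear", sigma = NULL,
                                 B = 999L, seed = 1L) {
  B <- check_count(B, "B")
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("`x` and `y` must have equal sample counts.")
  n <- nrow(x)
  if (n < 2L) abort("need at least 2 samples per side.")
  k <- resolve_kernel(kernel, sigma)
  Z <- rbind(x, y)
  K <- k(Z, Z)
  obs <- mmd2_from_gram(K, seq_len(n), n + seq_len(n))
  with_seed(seed, {
    perm <- vapply(seq_len(B), function(b) {
      idx <- sample.int(2L * n)
      mmd2_from_gram(K, idx[seq_len(n)], idx[n + seq_len(n)])
    }, numeric(1))
  })
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (1 + B),
       B = B, n = n)
}

#' Learn a shared feature map for shift quantification
#'
#' Fits one multi-layer perceptron with a shared trunk and one classification
#' head per attribute (e.g. sex, age band, race, study): the trunk's
#' penultimate-layer activations are the learned embedding used as the
#' canonical feature map for the MMD. Training a single joint network — rather
#' than one per attribute — keeps the feature space shared, so MMD values are
#' comparable across attributes.
#'
#' @param design Numeric design matrix / data frame (e.g. the output of
#'   [apply_preprocessor()]).
#' @param attributes Data frame with one column per attribute; character or
#'   factor, `NA` allowed. Attributes with fewer than two observed groups are
#'   skipped with a warning; an attribute with no observed values is an
#'   error.
#' @param hidden Hidden-layer widths of the shared trunk; the last entry is
#'   the embedding dimension (default `c(64, 48, 32)`: three ReLU layers,
#'   32-dimensional features).
#' @param epochs,lr,l2 Training budget, Adam step size and weight decay.
#' @param seed Integer seed: same data, config and seed give identical
#'   parameters.
#' @return A `feature_map` object; use [shift_features()] or `predict()` to
#'   embed rows.
#' @export
train_feature_map <- function(design, attributes,
                              hidden = c(64, 48, 32),
                              epochs = 300L, lr = 0.01, l2 = 1e-4,
                              seed = 1L) {
  X <- as_matrix_checked(as.matrix(design), "design")
  if (!is.data.frame(attributes)) attributes <- as.data.frame(attributes)
  if (nrow(attributes) != nrow(X)) abort("`attributes` must align with `design` rows.")
  level_maps <- list()
  targets <- list()
  heads <- list()
  for (cn in names(attributes)) {
    a <- as.character(attributes[[cn]])
    lev <- sort(unique(a[!is.na(a)]))
    if (!length(lev)) abort(sprintf("attribute `%s` has no observed values.", cn))
    if (length(lev) < 2L) {
      warn(sprintf("attribute `%s` has a single group; skipped.", cn))
      next
    }
    level_maps[[cn]] <- lev
    targets[[cn]] <- match(a, lev)
    heads[[cn]] <- list(type = "softmax", n_classes = length(lev))
  }
  if (!length(heads)) abort("no attribute with >= 2 groups to learn from.")
  params <- mlp_train(X, targets, heads, hidden = hidden, epochs = epochs,
                      lr = lr, l2 = l2, seed = seed)
  structure(
    list(params = params, levels = level_maps, hidden = hidden,
         feature_dim = hidden[length(hidden)], seed = seed),
    class = "feature_map"
  )
}

#' Embed rows with a trained feature map
#'
#' @param fmap A `feature_map` from [train_feature_map()].
#' @param design Rows to embed (same columns as at training).
#' @return Numeric matrix, one embedding row per input row.
#' @export
shift_features <- function(fmap, design) {
  if (!inherits(fmap, "feature_map")) abort("`fmap` must be a feature_map.")
  mlp_features(fmap$params, as.matrix(design))
}

#' @export
predict.feature_map <- function(object, newdata, type = c("features", "prob"),
                                head = 1L, ...) {
  type <- match.arg(type)
  if (type == "features") return(shift_features(object, newdata))
  p <- mlp_predict_head(object$params, as.matrix(newdata), head = head)
  colnames(p) <- object$levels[[head]]
  p
}

#' Head accuracy of a feature map (training diagnostics)
#' @param fmap A `feature_map`.
#' @param design,attributes The data used at training (or held-out rows).
#' @return Named vector of per-attribute classification accuracies.
#' @export
feature_map_accuracy <- function(fmap, design, attributes) {
  vapply(seq_along(fmap$levels), function(j) {
    a <- as.character(attributes[[names(fmap$levels)[j]]])
    obs <- !is.na(a)
    p <- mlp_predict_head(fmap$params, as.matrix(design), head = j)
    pred <- fmap$levels[[j]][max.col(p, ties.method = "first")]
    mean(pred[obs] == a[obs])
  }, numeric(1), USE.NAMES = FALSE) |>
    setNames(names(fmap$levels))
}

#' Pairwise shift report between groups
#'
#' For every pair of groups, computes the unbiased MMD^2 on feature rows (a
#' learned embedding or any numeric features) together with a permutation
#' p-value, and builds an average-linkage clustering tree over the resulting
#' distance matrix (negative MMD^2 estimates clamped to 0 for distances) for
#' dendrogram rendering. Unequal group sizes are handled by a seeded
#' subsample of the larger group down to the smaller, and the subsample size
#' is reported. Groups with fewer than two subjects are dropped with a
#' recorded warning.
#'
#' @param features Numeric matrix of (embedded) features, one row per
#'   subject.
#' @param group Group identifier per subject.
#' @param B Number of permutations per pair (default 999; use >= 9999 to
#'   resolve p-values below 1e-4).
#' @param kernel,sigma Kernel specification as in [mmd2_unbiased()].
#' @param seed Integer seed (drives both subsampling and permutations).
#' @return A `shift_report`: symmetric `mmd2` and `p_value` matrices (zero /
#'   `NA` diagonal by convention), the per-pair sample size matrix `n`, an
#'   `hclust` linkage tree, `B`, `seed`, and any dropped groups.
#' @export
pairwise_shift <- function(features, group, B = 999L, kernel = "linear",
                           sigma = NULL, seed = 1L) {
  features <- as.matrix(features)
  group <- as.character(group)
  if (nrow(features) != length(group)) abort("`group` must align with `features`.")
  sizes <- table(group)
  dropped <- names(sizes)[sizes < 2L]
  if (length(dropped)) {
    warn(paste0("dropping group(s) with < 2 subjects: ",
                paste(dropped, collapse = ", ")))
  }
  gs <- sort(setdiff(names(sizes), dropped))
  if (length(gs) < 2L) abort("need at least 2 groups with >= 2 subjects.")
  m <- length(gs)
  mmd2 <- matrix(0, m, m, dimnames = list(gs, gs))
  pval <- matrix(NA_real_, m, m, dimnames = list(gs, gs))
  nmat <- matrix(NA_real_, m, m, dimnames = list(gs, gs))
  pair_id <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      pair_id <- pair_id + 1L
      ia <- which(group == gs[i])
      ib <- which(group == gs[j])
      n_pair <- min(length(ia), length(ib))
      sub_seed <- child_seed(seed, pair_id)
      with_seed(sub_seed, {
        if (length(ia) > n_pair) ia <- sample(ia, n_pair)
        if (length(ib) > n_pair) ib <- sample(ib, n_pair)
      })
      tst <- mmd_permutation_test(features[ia, , drop = FALSE],
                                  features[ib, , drop = FALSE],
                                  kernel = kernel, sigma = sigma,
                                  B = B, seed = child_seed(sub_seed, 1L))
      mmd2[i, j] <- mmd2[j, i] <- tst$statistic
      pval[i, j] <- pval[j, i] <- tst$p_value
      nmat[i, j] <- nmat[j, i] <- n_pair
    }
  }
  dist_mat <- pmax(mmd2, 0)
  linkage <- hclust(as.dist(dist_mat), method = "average")
  structure(
    list(mmd2 = mmd2, p_value = pval, n = nmat, linkage = linkage,
         B = B, seed = seed, groups = gs, dropped = dropped,
         kernel = if (is.function(kernel)) "custom" else kernel),
    class = "shift_report"
  )
}

#' @export
print.shift_report <- function(x, ...) {
  cat("<shift_report>", length(x$groups), "groups,", x$B, "permutations\n")
  print(round(x$mmd2, 4))
  invisible(x)
}

#' @describeIn pairwise_shift One row per group pair with MMD^2, p-value and
#'   the per-pair sample size.
#' @param x A `shift_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.shift_report <- function(x, ...) {
  gs <- x$groups
  pairs <- which(upper.tri(x$mmd2), arr.ind = TRUE)
  tibble(
    group1 = gs[pairs[, 1L]],
    group2 = gs[pairs[, 2L]],
    mmd2 = x$mmd2[pairs],
    p_value = x$p_value[pairs],
    n = x$n[pairs]
  )
}

#' @describeIn pairwise_shift Heatmap of the pairwise MMD^2 matrix.
#' @param object A `shift_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.shift_report <- function(object, ...) {
  df <- tidy(object)
  df2 <- df
  names(df2)[1:2] <- c("group2", "group1")
  both <- bind_rows(df, df2)
  ggplot2::ggplot(both, ggplot2::aes(.data$group1, .data$group2,
                                     fill = .data$mmd2)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f\np=%.3g", .data$mmd2, .data$p_value)
    ), size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "MMD²",
                  title = "Pairwise distribution shift between groups") +
    ggplot2::theme_minimal()
}

#' Serialize a shift report to / from JSON
#'
#' Matrices round-trip at full precision; the linkage tree is rebuilt from
#' the stored MMD^2 matrix on read.
#'
#' @param report A `shift_report`.
#' @param path JSON file path.
#' @export
shift_report_to_json <- function(report, path) {
  payload <- list(
    groups = report$groups,
    mmd2 = report$mmd2,
    p_value = report$p_value,
    n = report$n,
    B = report$B,
    seed = report$seed,
    dropped = report$dropped,
    kernel = report$kernel
  )
  # digits = I(17): 17 significant digits, enough to round-trip any double
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname shift_report_to_json
#' @export
shift_report_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gs <- raw$groups
  fix <- function(M) {
    M <- as.matrix(M)
    dimnames(M) <- list(gs, gs)
    M
  }
  mmd2 <- fix(raw$mmd2)
  structure(
    list(mmd2 = mmd2, p_value = fix(raw$p_value), n = fix(raw$n),
         linkage = hclust(as.dist(pmax(mmd2, 0)), method = "average"),
         B = raw$B, seed = raw$seed, groups = gs,
         dropped = as.character(raw$dropped %||% character()),
         kernel = raw$kernel),
    class = "shift_report"
  )
}
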