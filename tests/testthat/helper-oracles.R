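# Independent reference implementations (oracles) and tiny custom learners
# used across the test files.

# Naive double-loop evaluation of the unbiased MMD^2 U-statistic.
mmd2_naive <- function(x, y, kfun = function(a, b) sum(a * b)) {
  n <- nrow(x)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      total <- total + kfun(x[i, ], x[j, ]) + kfun(y[i, ], y[j, ]) -
        kfun(x[i, ], y[j, ]) - kfun(y[i, ], x[j, ])
    }
  }
  total / (n^2 - n)
}

# Exhaustive pairwise-concordance AUC (ties count one half).
auc_naive <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Small labelled feature frame with a logistic label model.
make_xy <- function(n, d = 3L, beta = rep(1, d), seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n)
    y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  })
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(d))
  df$label <- y
  df
}

# Learner that ignores the data and predicts a constant.
constant_learner <- function(value = 0.5) {
  list(
    name = "constant",
    fit = function(X, y, weights = NULL, task = "classification", seed = 1L) value,
    predict = function(model, X) rep(model, nrow(X))
  )
}

# Learner that predicts 1 exactly when a row was in its training set (by
# exact feature match) - used to certify no self-prediction in OOF matrices.
memorizing_learner <- function() {
  list(
    name = "memorize",
    fit = function(X, y, weights = NULL, task = "classification", seed = 1L) X,
    predict = function(model, X) {
      train_keys <- apply(model, 1L, paste, collapse = "|")
      keys <- apply(X, 1L, paste, collapse = "|")
      as.numeric(keys %in% train_keys)
    }
  )
}
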