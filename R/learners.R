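# Learner registry. Every learner exposes the same weight-aware contract:
#   fit(X, y, weights, task, seed)  -> model
#   predict(model, X)               -> P(y = 1 | x) or E[y | x]
# so the alpha-weighted objective can be realized as normalized per-sample
# weights for any of them, and the stacking layer can mix them freely.
# Learners without native case-weight support (k-NN) use the weights directly
# in their vote; tree ensembles receive them through their own interfaces.

#' Available learners
#' @return Character vector of registered learner names.
#' @export
learner_names <- function() c("logistic", "linear", "knn", "rf", "gbt", "mlp")

#' Fetch a learner by name
#'
#' @param name One of [learner_names()], or a list implementing the
#'   `fit`/`predict` contract (returned unchanged).
#' @param ... Hyper-parameters: `k` (k-NN neighbours, default 10),
#'   `num_trees` (random forest, default 200), `nrounds`/`max_depth`
#'   (boosted trees, defaults 50/3), `hidden`/`epochs`/`lr` (MLP, defaults
#'   `c(32, 16)`/200/0.01), `lambda` (ridge penalty for logistic/linear,
#'   default 0 = unpenalized).
#' @return A `learner` object with `fit(X, y, weights, task, seed)` and
#'   `predict(model, X)`.
#' @export
get_learner <- function(name, ...) {
  if (is.list(name) && !is.null(name$fit) && !is.null(name$predict)) {
    return(name)
  }
  hp <- list(...)
  name <- match.arg(name, learner_names())
  l <- switch(name,
    logistic = ,
    linear = glm_learner(lambda = hp$lambda %||% 0),
    knn = knn_learner(k = hp$k %||% 10L),
    rf = rf_learner(num_trees = hp$num_trees %||% 200L),
    gbt = gbt_learner(nrounds = hp$nrounds %||% 50L,
                      max_depth = hp$max_depth %||% 3L,
                      eta = hp$eta %||% 0.2),
    mlp = mlp_learner(hidden = hp$hidden %||% c(32L, 16L),
                      epochs = hp$epochs %||% 200L,
                      lr = hp$lr %||% 0.01)
  )
  l$name <- name
  structure(l, class = "learner")
}

glm_learner <- function(lambda = 0) {
  list(
    fit = function(X, y, weights = NULL, task = "classification", seed = 1L) {
      X <- as.matrix(X)
      n <- nrow(X)
      if (is.null(weights)) weights <- rep(1 / n, n)
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(X)))
      df$.y <- y
      if (lambda > 0) {
        if (!requireNamespace("glmnet", quietly = TRUE)) {
          abort("ridge-penalized fits need the glmnet package.")
        }
        fam <- if (task == "classification") "binomial" else "gaussian"
        model <- glmnet::glmnet(X, y, family = fam, alpha = 0,
                                lambda = lambda, weights = weights * n)
        return(list(kind = "glmnet", model = model, task = task))
      }
      fam <- if (task == "classification") quasibinomial() else gaussian()
      model <- suppressWarnings(
        glm(.y ~ ., data = df, family = fam, weights = weights)
      )
      list(kind = "glm", model = model, task = task)
    },
    predict = function(model, X) {
      X <- as.matrix(X)
      if (model$kind == "glmnet") {
        drop(predict(model$model, X, type = "response"))
      } else {
        df <- as.data.frame(X)
        names(df) <- paste0("V", seq_len(ncol(X)))
        unname(predict(model$model, newdata = df, type = "response"))
      }
    }
  )
}

knn_learner <- function(k = 10L) {
  list(
    fit = function(X, y, weights = NULL, task = "classification", seed = 1L) {
      X <- as.matrix(X)
      if (is.null(weights)) weights <- rep(1 / nrow(X), nrow(X))
      list(X = X, y = y, w = weights, k = min(k, nrow(X)), task = task)
    },
    predict = function(model, X) {
      X <- as.matrix(X)
      d2 <- outer(rowSums(X^2), rowSums(model$X^2), `+`) -
        2 * tcrossprod(X, model$X)
      apply(d2, 1L, function(row) {
        nb <- order(row)[seq_len(model$k)]
        w <- model$w[nb]
        if (sum(w) <= 0) w <- rep(1, length(nb))
        sum(w * model$y[nb]) / sum(w)
      })
    }
  )
}

rf_learner <- function(num_trees = 200L) {
  list(
    fit = function(X, y, weights = NULL, task = "classification", seed = 1L) {
      if (!requireNamespace("ranger", quietly = TRUE)) {
        abort("random-forest learner needs the ranger package.")
      }
      X <- as.matrix(X)
      df <- as.data.frame(X)
      names(df) <- paste0("V", seq_len(ncol(X)))
      df$.y <- if (task == "classification") factor(y, levels = c(0, 1)) else y
      model <- ranger::ranger(
        .y ~ ., data = df, num.trees = num_trees,
        probability = task == "classification",
        case.weights = weights, seed = seed, num.threads = 1L
      )
      list(model = model, task = task)
    },
    predict = function(model, X) {
      df <- as.data.frame(as.matrix(X))
      names(df) <- paste0("V", seq_len(ncol(df)))
      pr <- predict(model$model, data = df, num.threads = 1L)$predictions
      if (model$task == "classification") pr[, "1"] else pr
    }
  )
}

gbt_learner <- function(nrounds = 50L, max_depth = 3L, eta = 0.2) {
  list(
    fit = function(X, y, weights = NULL, task = "classification", seed = 1L) {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        abort("boosted-tree learner needs the xgboost package.")
      }
      X <- as.matrix(X)
      obj <- if (task == "classification") "binary:logistic" else "reg:squarederror"
      dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = weights)
      model <- xgboost::xgb.train(
        params = list(objective = obj, max_depth = max_depth, eta = eta,
                      nthread = 1L, seed = seed),
        data = dtrain, nrounds = nrounds, verbose = 0
      )
      list(model = model, task = task)
    },
    predict = function(model, X) {
      predict(model$model, xgboost::xgb.DMatrix(as.matrix(X)))
    }
  )
}

mlp_learner <- function(hidden = c(32L, 16L), epochs = 200L, lr = 0.01) {
  list(
    fit = function(X, y, weights = NULL, task = "classification", seed = 1L) {
      X <- as.matrix(X)
      if (is.null(weights)) weights <- rep(1 / nrow(X), nrow(X))
      if (task == "classification") {
        heads <- list(y = list(type = "softmax", n_classes = 2L))
        targets <- list(y = as.integer(y) + 1L)
      } else {
        heads <- list(y = list(type = "linear"))
        targets <- list(y = y)
      }
      params <- mlp_train(X, targets, heads, hidden = hidden, epochs = epochs,
                          lr = lr, weights = weights, seed = seed)
      list(params = params, task = task)
    },
    predict = function(model, X) {
      p <- mlp_predict_head(model$params, as.matrix(X), head = 1L)
      if (model$task == "classification") p[, 2L] else p
    }
  )
}
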