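# Minimal multi-head feed-forward network with a shared ReLU trunk, trained
# full-batch with Adam. Deliberately small: the cohorts here are tabular with
# tens of features, so a three-hidden-layer perceptron trained for a few
# hundred epochs is ample, fully deterministic given a seed, and has no
# compiled dependencies.
#
# Heads are either "softmax" (cross-entropy over K classes, targets are
# integer class indices with NA = unobserved) or "linear" (squared error,
# numeric targets). Per-sample weights are supported everywhere so the
# alpha-weighted objective threads through unchanged.

mlp_init <- function(d_in, hidden, heads, seed = 1L) {
  dims <- c(d_in, hidden)
  with_seed(seed, {
    trunk <- lapply(seq_along(hidden), function(l) {
      list(
        W = matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                   dims[l], dims[l + 1L]),
        b = rep(0, dims[l + 1L])
      )
    })
    d_feat <- dims[length(dims)]
    head_params <- lapply(heads, function(h) {
      k <- if (h$type == "softmax") h$n_classes else 1L
      list(
        W = matrix(rnorm(d_feat * k, sd = sqrt(1 / d_feat)), d_feat, k),
        b = rep(0, k)
      )
    })
  })
  list(trunk = trunk, heads = head_params, hidden = hidden,
       head_spec = heads, d_in = d_in)
}

mlp_trunk_forward <- function(params, X) {
  acts <- vector("list", length(params$trunk) + 1L)
  acts[[1L]] <- X
  H <- X
  for (l in seq_along(params$trunk)) {
    Z <- sweep(H %*% params$trunk[[l]]$W, 2L, params$trunk[[l]]$b, `+`)
    H <- pmax(Z, 0)
    acts[[l + 1L]] <- H
  }
  acts
}

mlp_features <- function(params, X) {
  acts <- mlp_trunk_forward(params, as.matrix(X))
  acts[[length(acts)]]
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# targets: named list matching heads; softmax heads take integer classes
# (1..K, NA allowed), linear heads take numerics. weights: per-sample,
# normalized internally. Returns list(loss, grads) for the flat param vector.
mlp_loss_grad <- function(params, X, targets, weights, l2 = 0) {
  n <- nrow(X)
  acts <- mlp_trunk_forward(params, X)
  H <- acts[[length(acts)]]
  loss <- 0
  dH <- matrix(0, nrow(H), ncol(H))
  head_grads <- vector("list", length(params$heads))
  for (j in seq_along(params$heads)) {
    spec <- params$head_spec[[j]]
    hp <- params$heads[[j]]
    y <- targets[[j]]
    logits <- sweep(H %*% hp$W, 2L, hp$b, `+`)
    if (spec$type == "softmax") {
      obs <- which(!is.na(y))
      if (!length(obs)) {
        head_grads[[j]] <- list(W = hp$W * 0, b = hp$b * 0)
        next
      }
      w <- weights[obs]
      w <- w / sum(w)
      P <- softmax_rows(logits[obs, , drop = FALSE])
      idx <- cbind(seq_along(obs), y[obs])
      loss <- loss - sum(w * log(pmax(P[idx], 1e-12)))
      dL <- P
      dL[idx] <- dL[idx] - 1
      dL <- dL * w
      dlogits <- matrix(0, n, ncol(logits))
      dlogits[obs, ] <- dL
    } else {
      w <- weights / sum(weights)
      r <- drop(logits) - y
      loss <- loss + 0.5 * sum(w * r^2)
      dlogits <- matrix(w * r, n, 1L)
    }
    head_grads[[j]] <- list(W = crossprod(H, dlogits), b = colSums(dlogits))
    dH <- dH + tcrossprod(dlogits, hp$W)
  }
  trunk_grads <- vector("list", length(params$trunk))
  for (l in rev(seq_along(params$trunk))) {
    dZ <- dH * (acts[[l + 1L]] > 0)
    trunk_grads[[l]] <- list(
      W = crossprod(acts[[l]], dZ),
      b = colSums(dZ)
    )
    if (l > 1L) dH <- tcrossprod(dZ, params$trunk[[l]]$W)
  }
  if (l2 > 0) {
    for (l in seq_along(params$trunk)) {
      loss <- loss + 0.5 * l2 * sum(params$trunk[[l]]$W^2)
      trunk_grads[[l]]$W <- trunk_grads[[l]]$W + l2 * params$trunk[[l]]$W
    }
    for (j in seq_along(params$heads)) {
      loss <- loss + 0.5 * l2 * sum(params$heads[[j]]$W^2)
      head_grads[[j]]$W <- head_grads[[j]]$W + l2 * params$heads[[j]]$W
    }
  }
  list(loss = loss, trunk = trunk_grads, heads = head_grads)
}

mlp_train <- function(X, targets, heads,
                      hidden = c(64, 48, 32),
                      epochs = 300L, lr = 0.01, l2 = 1e-4,
                      weights = NULL, seed = 1L, trace = FALSE) {
  X <- as_matrix_checked(X, "X")
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1 / n, n)
  params <- mlp_init(ncol(X), hidden, heads, seed = seed)

  # Adam state mirrors the parameter structure
  zeros_like <- function(p) list(W = p$W * 0, b = p$b * 0)
  m_t <- list(trunk = lapply(params$trunk, zeros_like),
              heads = lapply(params$heads, zeros_like))
  v_t <- m_t
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  log_loss <- numeric(epochs)
  for (t in seq_len(epochs)) {
    lg <- mlp_loss_grad(params, X, targets, weights, l2 = l2)
    log_loss[t] <- lg$loss
    upd <- function(p, g, m, v) {
      m$W <- b1 * m$W + (1 - b1) * g$W; m$b <- b1 * m$b + (1 - b1) * g$b
      v$W <- b2 * v$W + (1 - b2) * g$W^2; v$b <- b2 * v$b + (1 - b2) * g$b^2
      corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
      p$W <- p$W - lr * (m$W / corr1) / (sqrt(v$W / corr2) + eps)
      p$b <- p$b - lr * (m$b / corr1) / (sqrt(v$b / corr2) + eps)
      list(p = p, m = m, v = v)
    }
    for (l in seq_along(params$trunk)) {
      s <- upd(params$trunk[[l]], lg$trunk[[l]], m_t$trunk[[l]], v_t$trunk[[l]])
      params$trunk[[l]] <- s$p; m_t$trunk[[l]] <- s$m; v_t$trunk[[l]] <- s$v
    }
    for (j in seq_along(params$heads)) {
      s <- upd(params$heads[[j]], lg$heads[[j]], m_t$heads[[j]], v_t$heads[[j]])
      params$heads[[j]] <- s$p; m_t$heads[[j]] <- s$m; v_t$heads[[j]] <- s$v
    }
  }
  params$training_loss <- log_loss
  params
}

mlp_predict_head <- function(params, X, head = 1L) {
  H <- mlp_features(params, X)
  hp <- params$heads[[head]]
  logits <- sweep(H %*% hp$W, 2L, hp$b, `+`)
  if (params$head_spec[[head]]$type == "softmax") {
    softmax_rows(logits)
  } else {
    drop(logits)
  }
}
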