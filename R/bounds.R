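# Generalization-bound utilities for the mixing weight. With m source and n
# target samples, hypothesis-class capacity proxy V, confidence delta, and a
# source/target discrepancy d, the excess target risk of the alpha-weighted
# empirical minimizer is bounded (up to the best-in-class target risk) by
#   g(alpha) = 4 * sqrt((alpha^2/n + (1-alpha)^2/m) * (V - log delta))
#              + 2 * (1 - alpha) * d.
# g is convex on [0, 1]; its minimizer gives a theory-side guideline for
# alpha that can be compared with the cross-validated choice.

#' Parameters of the target-risk bound
#'
#' @param m,n Source and target sample counts (>= 1).
#' @param V Capacity (VC-dimension) proxy of the hypothesis class, positive.
#'   Estimating it is hard in practice; a parameter count is a reasonable
#'   stand-in for linear models.
#' @param delta Confidence level in (0, 1): the bound holds with probability
#'   at least `1 - delta`.
#' @param d Discrepancy between the source and target distributions (>= 0).
#'   A heuristic plug-in is the square root of the clamped MMD^2 from
#'   [pairwise_shift()]; see [shift_discrepancy()].
#' @param lam Combined best-achievable source+target risk (carried for
#'   completeness; it offsets the bound but does not move its minimizer).
#' @param c Constant of the plain (single-population) risk inequality
#'   (default 1).
#' @return A `bound_params` list.
#' @export
bound_params <- function(m, n, V = 1, delta = 0.05, d = 0, lam = 0, c = 1) {
  m <- check_count(m, "m"); n <- check_count(n, "n")
  check_scalar_number(V, "V", lower = 0, open_lower = TRUE)
  check_scalar_number(delta, "delta", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar_number(d, "d", lower = 0)
  check_scalar_number(lam, "lam", lower = 0)
  if (V - log(delta) <= 0) abort("V - log(delta) must be positive.")
  structure(list(m = m, n = n, V = V, delta = delta, d = d, lam = lam, c = c),
            class = "bound_params")
}

#' Excess-risk bound as a function of the mixing weight
#'
#' Evaluates
#' \deqn{4\sqrt{\left(\frac{\alpha^2}{n} + \frac{(1-\alpha)^2}{m}\right)(V - \log\delta)}
#'       + 2(1-\alpha)\, d,}
#' the terms of the target-risk bound beyond the best-in-class target risk.
#'
#' @param alpha Mixing weight(s) in \[0, 1\] (vectorized).
#' @param params A [bound_params()].
#' @return Bound value(s), same length as `alpha`.
#' @export
adaptation_bound <- function(alpha, params) {
  if (any(alpha < 0 | alpha > 1)) abort("`alpha` must lie in [0, 1].")
  veff <- params$V - log(params$delta)
  4 * sqrt((alpha^2 / params$n + (1 - alpha)^2 / params$m) * veff) +
    2 * (1 - alpha) * params$d
}

#' Bound-minimizing mixing weight
#'
#' Returns the \eqn{\alpha \in [0,1]} minimizing [adaptation_bound()]. Two
#' regimes have closed forms, honored exactly:
#' \itemize{
#'   \item `d = 0`: the minimizer of \eqn{\alpha^2/n + (1-\alpha)^2/m} is
#'     \eqn{n/(m+n)} — with comparable sample sizes this is about 1/2, and
#'     with `m >> n` it is close to 0 (lean on the source);
#'   \item `n >= 4(V - log delta)/d^2` (see [alpha_one_threshold()]): the
#'     derivative at 1 is non-positive and convexity forces \eqn{\alpha^* = 1}
#'     — enough target data to ignore a shifted source entirely.
#' }
#' Otherwise the interior minimum is found numerically.
#'
#' @param params A [bound_params()].
#' @param tol Numeric tolerance of the interior search (default 1e-9).
#' @return The minimizing alpha.
#' @export
optimal_alpha <- function(params, tol = 1e-9) {
  if (params$d == 0) return(params$n / (params$m + params$n))
  # derivative of the bound at alpha = 1: 4*sqrt(Veff/n) - 2d
  veff <- params$V - log(params$delta)
  if (4 * sqrt(veff / params$n) - 2 * params$d <= 0) return(1)
  opt <- optimize(function(a) adaptation_bound(a, params),
                  interval = c(0, 1), tol = tol)
  cands <- c(0, opt$minimum, 1)
  cands[which.min(adaptation_bound(cands, params))]
}

#' Target-sample threshold above which alpha = 1 is bound-optimal
#'
#' \eqn{4(V - \log\delta)/d^2}: once the target sample count reaches this
#' value, the bound is minimized by training on target data alone.
#'
#' @param params A [bound_params()] with `d > 0`.
#' @return The threshold (a real number; compare `n` against it).
#' @export
alpha_one_threshold <- function(params) {
  if (params$d <= 0) {
    abort("threshold undefined for d = 0 (it is infinite; alpha = 1 is never forced).")
  }
  4 * (params$V - log(params$delta)) / params$d^2
}

#' Plug-in discrepancy from a shift report
#'
#' Heuristic: \eqn{d \approx \sqrt{\max(MMD^2, 0)}} between two groups. This
#' is a practical stand-in, clearly separated from the exact bound
#' arithmetic: both V and d are conceded to be hard to estimate, which is why
#' cross-validation remains the operational way to pick alpha.
#'
#' @param report A `shift_report`.
#' @param group1,group2 Group names.
#' @return Non-negative scalar discrepancy estimate.
#' @export
shift_discrepancy <- function(report, group1, group2) {
  sqrt(max(report$mmd2[group1, group2], 0))
}

#' Bound curve over the alpha grid
#'
#' @param params A [bound_params()].
#' @param alphas Grid to evaluate (default 201 points on \[0, 1\]).
#' @return Tibble with `alpha` and `bound` columns.
#' @export
bound_curve <- function(params, alphas = seq(0, 1, length.out = 201L)) {
  tibble(alpha = alphas, bound = adaptation_bound(alphas, params))
}

#' @describeIn bound_curve Plot of the bound with its minimizer marked.
#' @param object A [bound_params()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.bound_params <- function(object, ...) {
  df <- bound_curve(object)
  a_star <- optimal_alpha(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$alpha, .data$bound)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = a_star, linetype = 2, colour = "red") +
    ggplot2::annotate("text", x = a_star, y = max(df$bound),
                      label = sprintf("alpha* = %.3f", a_star),
                      hjust = -0.1, vjust = 1, colour = "red") +
    ggplot2::labs(x = expression(alpha), y = "excess-risk bound",
                  title = sprintf("m = %d, n = %d, V = %.3g, delta = %.3g, d = %.3g",
                                  object$m, object$n, object$V, object$delta,
                                  object$d)) +
    ggplot2::theme_minimal()
}
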