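#' Analytic Meinshausen-Buhlmann LASSO penalty
#'
#' Computes the neighborhood-selection penalty
#' \deqn{\lambda = \Phi^{-1}\!\bigl(1 - \alpha / (2 p^2)\bigr) / \sqrt{n}}
#' where \eqn{\Phi^{-1}} is the standard normal quantile function, `n` is
#' the per-group sample size, `p` the number of genes over which the
#' network is considered, and `alpha` the significance level controlling
#' the probability of falsely connecting distinct connectivity components.
#' The same single penalty is shared by every per-gene LASSO regression.
#'
#' Note that `p` is the size of the gene universe the error control is
#' calibrated over, which need not equal the number of genes actually
#' entering the regressions (the pipeline calibrates over the
#' post-zero-filter gene count while regressing over the DEG-selected
#' subset; see the methods vignette).
#'
#' @param n Samples per group (>= 1).
#' @param p Number of genes (>= 1).
#' @param alpha Significance level; `alpha / (2 p^2)` must be < 1.
#' @return An object of class `mb_penalty`: a list with fields `n`, `p`,
#'   `alpha` and `lambda`.
#' @examples
#' mb_lambda(n = 50, p = 17649, alpha = 0.1)
#' @export
mb_lambda <- function(n, p, alpha = 0.1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a single value >= 1.")
  }
  if (!is.numeric(p) || length(p) != 1 || p < 1) {
    abort("`p` must be a single value >= 1.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    abort("`alpha` must be a single positive value.")
  }
  tail <- alpha / (2 * p^2)
  if (tail >= 1) {
    abort("`alpha / (2 * p^2)` must be < 1 for the quantile to be defined.")
  }
  ## upper-tail quantile directly: 1 - tail would lose ~7 significant
  ## digits of the tail to cancellation at genome-scale p
  structure(list(n = n, p = p, alpha = alpha,
                 lambda = qnorm(tail, lower.tail = FALSE) / sqrt(n)),
            class = "mb_penalty")
}

#' @export
print.mb_penalty <- function(x, ...) {
  cat(sprintf("<mb_penalty> lambda = %.6f  (n = %g, p = %g, alpha = %g)\n",
              x$lambda, x$n, x$p, x$alpha))
  invisible(x)
}

## Accept either a bare numeric penalty or an mb_penalty object.
as_lambda <- function(lambda) {
  if (inherits(lambda, "mb_penalty")) lambda <- lambda$lambda
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    abort("`lambda` must be a single nonnegative value or an mb_penalty.")
  }
  lambda
}
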