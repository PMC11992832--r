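#' Pearson correlation test
#'
#' Pearson's r with the exact t test:
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-tailed. Used for the difference-score analysis relating
#' probabilistic-learning scores to OCI-R totals.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, finite, each with
#'   nonzero variance.
#' @return A list of class `asrt_cor`: `r`, `statistic` (t), `df`,
#'   `p_value`, `n`.
#' @examples
#' pearson_test(c(1, 2, 3, 4), c(1, 3, 2, 4))$r # 0.8
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.",
                   class = "asrt_precondition_error")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Inputs must be finite.", class = "asrt_precondition_error")
  }
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    abort("Correlation undefined: zero variance in an input.",
          class = "asrt_undefined_correlation")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  df <- n - 2L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  structure(list(r = r, statistic = tstat, df = df,
                 p_value = min(p, 1), n = n),
            class = "asrt_cor")
}

#' @export
print.asrt_cor <- function(x, ...) {
  cat(sprintf("Pearson r(%d) = %.3f, t = %.3f, p = %.4g\n",
              x$df, x$r, x$statistic, x$p_value))
  invisible(x)
}

#' Sidak multiple-comparison adjustment
#'
#' Family-wise adjustment `p_adj = 1 - (1 - p)^m` for a family of `m`
#' comparisons, computed with `expm1`/`log1p` for numerical accuracy and
#' clipped to `[0, 1]`. Monotone in both `p` and `m`, and always
#' `p_adj >= p`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @examples
#' sidak_adjust(0.01, m = 3) # 0.029701
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].", class = "asrt_precondition_error")
  }
  if (m < 1) abort("`m` must be at least 1.")
  pmin(pmax(-expm1(m * log1p(-p)), 0), 1)
}
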