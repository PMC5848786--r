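#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted greenness spline
#'
#' @param x A `gcc_spline` from [detect_outliers()].
#' @param ... Unused.
#' @return A tibble with one row per input point: `t`, `y`, `fitted`,
#'   `residual`, and `flagged` (0/1 outlier flag).
#' @export
tidy.gcc_spline <- function(x, ...) {
  tibble::tibble(t = x$t, y = x$y, fitted = x$fitted,
                 residual = x$y - x$fitted, flagged = x$flags)
}

#' @rdname tidy.gcc_spline
#' @return `glance()` returns a one-row tibble: `n`, `n_flagged`, `edf`,
#'   `spar`, `sigma`, `rmse`, `ci_halfwidth`.
#' @export
glance.gcc_spline <- function(x, ...) {
  tibble::tibble(n = length(x$t), n_flagged = sum(x$flags), edf = x$edf,
                 spar = x$spar, sigma = x$sigma, rmse = x$rmse,
                 ci_halfwidth = x$ci_halfwidth)
}

#' Tidy a sensor response fit
#'
#' @param x A `response_fit` from [fit_response()].
#' @param ... Unused.
#' @return A tibble with one row per parameter of `y = a * exp(b * x)`.
#' @export
tidy.response_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname tidy.response_fit
#' @return `glance()` returns a one-row tibble: `a`, `b`, `rmse`,
#'   `n_used`, `n`.
#' @export
glance.response_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, rmse = x$rmse, n_used = x$n_used,
                 n = length(x$y))
}
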