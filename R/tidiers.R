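# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hypothesis-test result
#'
#' @param x A `yaptaz_htest` (from [mann_whitney()], [spearman_cor()],
#'   [logrank_test()], ...).
#' @param ... Unused.
#' @return One-row tibble: `statistic_name`, `statistic`, `p.value`,
#'   `method`, `exact`, `stars`.
#' @export
tidy.yaptaz_htest <- function(x, ...) {
  tibble::tibble(
    statistic_name = x$statistic_name,
    statistic = x$statistic,
    p.value = x$p_value,
    method = x$method,
    exact = x$exact,
    stars = significance_stars(x$p_value)
  )
}

#' @rdname tidy.yaptaz_htest
#' @export
glance.yaptaz_htest <- function(x, ...) {
  dplyr::bind_cols(
    tidy(x),
    tibble::as_tibble(as.list(stats::setNames(as.integer(x$n), names(x$n))))
  )
}

#' Tidy an OLS fit
#'
#' @param x A `yaptaz_ols` from [ols_fit()] or [density_regression()].
#' @param ... Unused.
#' @return Two-row tibble of `term` / `estimate`.
#' @export
tidy.yaptaz_ols <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.yaptaz_ols
#' @export
glance.yaptaz_ols <- function(x, ...) {
  tibble::tibble(
    intercept = x$intercept, slope = x$slope,
    residual_variance = x$residual_variance, n = x$n
  )
}

#' Tidy a density analysis
#'
#' @param x A `density_analysis` object.
#' @param ... Unused.
#' @return The per-field measurement tibble with the density group column.
#' @export
tidy.density_analysis <- function(x, ...) {
  tibble::as_tibble(x$measurements)
}

#' @rdname tidy.density_analysis
#' @export
glance.density_analysis <- function(x, ...) {
  tibble::tibble(
    n_fields = nrow(x$measurements),
    threshold = x$threshold,
    mw_u = if (!is.null(x$mann_whitney)) x$mann_whitney$statistic else NA_real_,
    mw_p = if (!is.null(x$mann_whitney)) x$mann_whitney$p_value else NA_real_,
    slope = x$regression$slope,
    intercept = x$regression$intercept
  )
}

#' Tidy a Kaplan-Meier curve
#'
#' @param x A `km_curve` object.
#' @param ... Unused.
#' @return Tibble of curve points.
#' @export
tidy.km_curve <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "km_curve")
  tibble::as_tibble(out)
}
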