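#' Two-sample Mann-Whitney U test
#'
#' Rank-sum test with average-rank tie handling. In `"auto"` mode the p-value
#' is computed by exact enumeration of the null U distribution when the pooled
#' sample size is at most 20 and the data contain no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' Two-sided throughout.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`. `"exact"` refuses
#'   tied data, where no exact enumeration distribution is implemented.
#' @return An object of class `yaptaz_htest`: a list with `statistic` (U of
#'   the first sample), `p_value`, `method`, `exact` (logical), and `n`
#'   (per-group sizes). Has [generics::tidy()] and [generics::glance()]
#'   methods.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("both groups must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) rlang::abort("missing values are not supported")
  n_a <- length(x)
  n_b <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  use_exact <- switch(mode,
    exact = {
      if (has_ties) rlang::abort("exact mode requires untied data")
      TRUE
    },
    normal = FALSE,
    auto = !has_ties && (n_a + n_b) <= 20
  )

  if (use_exact) {
    p <- mw_exact_p(u_a, n_a, n_b)
    detail <- "exact enumeration"
  } else {
    mu <- n_a * n_b / 2
    n <- n_a + n_b
    tie_counts <- table(pooled)
    tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      # all pooled values identical: no evidence either way
      p <- 1
    } else {
      z <- (u_a - mu - sign(u_a - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    detail <- "normal approximation, tie and continuity corrected"
  }

  new_htest(
    statistic_name = "U", statistic = u_a, p_value = p,
    method = paste("Mann-Whitney U test,", detail),
    exact = use_exact, n = c(n_a = n_a, n_b = n_b)
  )
}

# Exact two-sided p by full enumeration of rank-subset sums (no ties).
mw_exact_p <- function(u, n_a, n_b) {
  n <- n_a + n_b
  combos <- utils::combn(n, n_a)
  u_all <- colSums(combos) - n_a * (n_a + 1) / 2
  p_le <- mean(u_all <= u)
  p_ge <- mean(u_all >= u)
  min(1, 2 * min(p_le, p_ge))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with a two-sided p-value from the
#' t approximation on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, n >= 4, neither constant.
#' @return A `yaptaz_htest` with `statistic` = r.
#' @export
#' @examples
#' spearman_cor(1:6, c(2, 1, 4, 3, 6, 5))
spearman_cor <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) rlang::abort("x and y must be paired")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) rlang::abort("need at least 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    rlang::abort("rank correlation is undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_htest(
    statistic_name = "rho", statistic = r, p_value = p,
    method = "Spearman rank correlation, t approximation",
    exact = FALSE, n = c(n = n)
  )
}

#' Ordinary least-squares line
#'
#' Closed-form simple linear regression of `y` on `x`.
#'
#' @param x,y Numeric vectors, at least 3 points, `x` non-degenerate.
#' @return An object of class `yaptaz_ols` with `slope`, `intercept`,
#'   `residual_variance` and `n`.
#' @export
ols_fit <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) rlang::abort("x and y must be paired")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) rlang::abort("need at least 3 points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) rlang::abort("x has zero variance; slope is undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rv <- if (n > 2) sum(resid^2) / (n - 2) else NA_real_
  structure(
    list(slope = slope, intercept = intercept, residual_variance = rv, n = n),
    class = "yaptaz_ols"
  )
}

#' Significance star labels
#'
#' `"***"` for p <= 0.001, `"**"` for p <= 0.01, `"*"` for p <= 0.05,
#' `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) rlang::abort("p must lie in [0, 1]")
  dplyr::case_when(
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

new_htest <- function(statistic_name, statistic, p_value, method, exact, n,
                      extra = list()) {
  structure(
    c(
      list(
        statistic_name = statistic_name, statistic = statistic,
        p_value = p_value, method = method, exact = exact, n = n
      ),
      extra
    ),
    class = "yaptaz_htest"
  )
}

#' @export
print.yaptaz_htest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf(
    "%s = %g, p = %.4g %s\n",
    x$statistic_name, x$statistic, x$p_value, significance_stars(x$p_value)
  ))
  cat("n:", paste(names(x$n), x$n, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.yaptaz_ols <- function(x, ...) {
  cat(sprintf(
    "OLS fit: y = %.4g + %.4g x (n = %d, residual variance %.4g)\n",
    x$intercept, x$slope, x$n, x$residual_variance
  ))
  invisible(x)
}
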