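#' Two-sample Student's t test
#'
#' Unpaired two-sided t test as used for per-intron percent-unspliced and
#' log-scale protein-abundance comparisons: pooled-variance ("Student") by
#' default, Welch available. Degenerate inputs (both samples with zero
#' variance) are resolved by convention rather than returning `NaN`: equal
#' means give p = 1, unequal means give p = 0 with a warning, since the data
#' then separate the groups perfectly but carry no variance estimate.
#'
#' @param x,y Numeric vectors, at least two values each.
#' @param pooled Use the pooled-variance statistic (default) instead of the
#'   Welch-Satterthwaite approximation.
#' @return A one-row tibble with `estimate` (mean of `x` minus mean of `y`),
#'   `statistic`, `parameter` (degrees of freedom), `p.value`, `method` and
#'   `alternative`.
#' @examples
#' student_t_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
student_t_test <- function(x, y, pooled = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 2, length(y) >= 2, !anyNA(x), !anyNA(y))
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  est <- mean(x) - mean(y)
  method <- if (pooled) "Student's t-test (pooled variance)" else "Welch's t-test"

  if (v1 == 0 && v2 == 0) {
    if (est == 0) {
      return(t_result(est, 0, n1 + n2 - 2, 1, method))
    }
    warning("zero variance in both samples with unequal means; p = 0 by convention")
    return(t_result(est, sign(est) * Inf, n1 + n2 - 2, 0, method))
  }

  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    stat <- est / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    stat <- est / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_result(est, stat, df, 2 * pt(-abs(stat), df), method)
}

t_result <- function(estimate, statistic, df, p, method) {
  tibble::tibble(
    estimate = estimate, statistic = statistic, parameter = df,
    p.value = p, method = method, alternative = "two.sided"
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two distributions (e.g. dPSI distributions between
#' knockdown contrasts, or per-class log2 fold-change distributions). For
#' small samples (`n1 + n2 <= exact_threshold`) the two-sided p-value is
#' computed by full enumeration of all `choose(n1 + n2, n1)` group
#' assignments of the pooled values (ties handled by midranks); larger
#' samples use the normal approximation with tie and continuity corrections.
#'
#' @param x,y Numeric vectors, non-empty.
#' @param exact_threshold Largest combined sample size for which the exact
#'   enumeration p-value is used.
#' @return A one-row tibble with `statistic` (U for `x`), `p.value`,
#'   `method` and `alternative`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1, length(y) >= 1, !anyNA(x), !anyNA(y))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u_obs <- u_statistic(x, y)

  if (n <= exact_threshold) {
    pooled <- c(x, y)
    dev_obs <- abs(u_obs - n1 * n2 / 2)
    sets <- combn(n, n1)
    devs <- apply(sets, 2, function(idx) {
      abs(u_statistic(pooled[idx], pooled[-idx]) - n1 * n2 / 2)
    })
    p <- mean(devs >= dev_obs - 1e-12)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "Mann-Whitney U (normal approximation)"
  }
  tibble::tibble(
    statistic = u_obs, p.value = p, method = method,
    alternative = "two.sided"
  )
}

u_statistic <- function(x, y) {
  # U for x: pairs where x beats y, ties count one half
  sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
}

#' Chi-squared test on a 2x2 contingency table
#'
#' The textbook chi-squared statistic
#' N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) with one degree of freedom, used
#' for dual-motif overrepresentation and positional two-proportion
#' comparisons. Yates continuity correction is off by default.
#'
#' @param a,b,c,d Non-negative cell counts, laid out as rows `(a, b)` and
#'   `(c, d)`.
#' @param yates Apply the Yates continuity correction.
#' @return A one-row tibble with `statistic`, `parameter` (df = 1),
#'   `p.value` and `method`.
#' @examples
#' chi_squared_2x2(7, 31, 6, 100)  # statistic ~ 5.546
#' @export
chi_squared_2x2 <- function(a, b, c, d, yates = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), !anyNA(cells))
  n <- sum(cells)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("chi_squared_2x2: zero row or column margin")
  }
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  tibble::tibble(
    statistic = stat, parameter = 1,
    p.value = pchisq(stat, df = 1, lower.tail = FALSE),
    method = paste0("Chi-squared test (2x2", if (yates) ", Yates corrected", ")")
  )
}

#' Log2 fold change with pseudocount
#'
#' `log2((a + pseudocount) / (b + pseudocount))`, vectorised. The
#' pseudocount keeps zero abundances finite and should be small relative to
#' the abundance scale in use.
#'
#' @param a,b Non-negative abundances (numerator, denominator).
#' @param pseudocount Positive stabiliser added to both.
#' @return Numeric vector of log2 fold changes.
#' @examples
#' log2_fold_change(3, 1, pseudocount = 1)  # 1
#' @export
log2_fold_change <- function(a, b, pseudocount = 1) {
  stopifnot(all(a >= 0, na.rm = TRUE), all(b >= 0, na.rm = TRUE),
            pseudocount > 0)
  log2((a + pseudocount) / (b + pseudocount))
}
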