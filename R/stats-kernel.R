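# Small correlation / rank-test kernel used by the reaction-norm and
# meta-analysis stages. Contracts kept explicit (min-U statistic, exact
# enumeration under ties) so the plasticity classification is fully
# specified; base R equivalents serve as cross-checks in the test suite.

two_sided_p_from_t <- function(tstat, df) {
  2 * pt(-abs(tstat), df = df)
}

#' Pearson product-moment correlation with two-sided test
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite.
#' @return One-row tibble: `r`, `p` (two-sided, from the t transform with
#'   n - 2 df), `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n != length(y)) stop_input("x and y must have equal length")
  if (n < 3) stop_input("at least 3 paired observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_input("non-finite values in correlation input")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_degenerate("zero variance: correlation undefined")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    two_sided_p_from_t(r * sqrt((n - 2) / (1 - r^2)), n - 2)
  }
  tibble::tibble(r = r, p = p, n = n)
}

# Mid-ranks (average ranks for ties), the convention used throughout.
mid_rank <- function(x) rank(x, ties.method = "average")

#' Spearman rank-order correlation with two-sided test
#'
#' Pearson correlation of mid-ranks (ties get average ranks); the p-value
#' uses the same t transform as [pearson_r()].
#'
#' @inheritParams pearson_r
#' @return One-row tibble: `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) >= 3 &&
      (length(unique(x)) == 1 || length(unique(y)) == 1)) {
    stop_degenerate("all values tied: rank correlation undefined")
  }
  res <- pearson_r(mid_rank(x), mid_rank(y))
  tibble::tibble(rho = res$r, p = res$p, n = res$n)
}

mwu_statistic <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  r <- mid_rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  min(u_a, u_b)
}

#' Mann-Whitney rank-sum test
#'
#' Reports `U = min(U_a, U_b)` from the rank sums (mid-ranks under ties).
#' The two-sided p-value is exact — the proportion of all
#' `choose(n_a + n_b, n_a)` group labelings of the pooled data whose
#' min-U statistic is at most the observed one — whenever that count is at
#' most `exact_limit`; otherwise a normal approximation with tie correction
#' and a 0.5 continuity correction is used.
#'
#' @param a,b Non-empty numeric vectors (the two groups).
#' @param exact_limit Largest number of labelings for which the exact
#'   enumeration is used (default 20000).
#' @return One-row tibble: `u`, `p`, `n_a`, `n_b`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b, exact_limit = 20000) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop_input("both groups must be non-empty")
  }
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  u <- mwu_statistic(a, b)
  n_arrangements <- choose(n, n_a)
  if (n_arrangements <= exact_limit) {
    pooled <- c(a, b)
    idx <- combn(n, n_a)
    us <- apply(idx, 2, function(i) mwu_statistic(pooled[i], pooled[-i]))
    p <- mean(us <= u + 1e-9)
    method <- "exact"
  } else {
    r <- mid_rank(c(a, b))
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n_a * n_b / 12 * (n + 1 - tie_term))
    mu <- n_a * n_b / 2
    z <- (u - mu + 0.5) / sigma  # continuity correction toward the mean
    p <- min(1, 2 * pnorm(z))
    method <- "normal"
  }
  tibble::tibble(u = u, p = p, n_a = n_a, n_b = n_b, method = method)
}
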