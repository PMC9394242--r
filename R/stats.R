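dictime_test <- function(method, statistic, p_value, n, extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   p.value = p_value, n = n), extra),
            class = "dictime_test")
}

#' @export
print.dictime_test <- function(x, ...) {
  cat(sprintf("<%s> %s = %.4g, p = %.4g (n = %s)\n",
              x$method, names(x$statistic)[1] %||% "stat",
              unname(x$statistic)[1], x$p.value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Descriptive statistics for a duration vector
#'
#' Sample mean, SD (n-1 denominator), median, adjusted Fisher-Pearson
#' skewness (G1) and excess kurtosis (G2) with their exact small-sample
#' standard errors:
#' `SE_skew = sqrt(6n(n-1) / ((n-2)(n+1)(n+3)))` and
#' `SE_kurt = 2 SE_skew sqrt((n^2-1) / ((n-3)(n+5)))`.
#'
#' @param x a [duration_sample()] or numeric vector (minutes).
#' @return A one-row data frame: n, mean, sd, median, skewness, skewness_se,
#'   kurtosis_excess, kurtosis_se. Shape statistics are `NA` when undefined
#'   (n too small or zero variance), with a `degenerate` flag column.
#' @export
#' @examples
#' summarize_durations(c(12, 15, 16, 18, 40))
summarize_durations <- function(x) {
  x <- as_duration_vector(x)
  n <- length(x)
  if (n < 1) stop("empty sample")
  m <- mean(x)
  s <- if (n >= 2) sd(x) else NA_real_
  degenerate <- isTRUE(s == 0)
  sk <- sk_se <- ku <- ku_se <- NA_real_
  if (!degenerate && n >= 3 && isTRUE(s > 0)) {
    m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
    g1 <- m3 / m2^1.5
    sk <- g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  if (!degenerate && n >= 4 && isTRUE(s > 0)) {
    m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
    g2 <- m4 / m2^2 - 3
    ku <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    sk_se <- se_skewness(n)
    ku_se <- se_kurtosis(n)
  }
  data.frame(n = n, mean = m, sd = s, median = median(x),
             skewness = sk, skewness_se = sk_se,
             kurtosis_excess = ku, kurtosis_se = ku_se,
             degenerate = degenerate)
}

#' Exact small-sample standard errors of skewness and excess kurtosis
#'
#' @param n sample size (>= 4 for a defined value).
#' @return The standard error.
#' @export
#' @examples
#' round(se_skewness(135), 2)  # 0.21
#' round(se_kurtosis(135), 2)  # 0.41
se_skewness <- function(n) {
  if (n < 4) return(NA_real_)
  sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
}

#' @rdname se_skewness
#' @export
se_kurtosis <- function(n) {
  if (n < 4) return(NA_real_)
  2 * se_skewness(n) * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
}

#' Standard normal deviate
#'
#' Inverse standard-normal CDF, the `z` entering the sample-size formula.
#'
#' @param p probability strictly inside (0, 1).
#' @return The standard normal quantile at `p`.
#' @export
#' @examples
#' z_quantile(0.9)    # 1.282 (power 0.9)
#' z_quantile(0.975)  # 1.960 (two-sided alpha 0.05)
z_quantile <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly inside (0, 1)")
  qnorm(p)
}

#' Sample size to estimate a mean within a CI of total width D
#'
#' Computes `N = 4 sigma^2 (z_crit + z_pwr)^2 / D^2`, the total sample size
#' needed so a mean is estimated within a confidence interval of total width
#' `D` at two-sided significance `alpha` and the given power. `N` is floored
#' to an integer (the raw value is returned alongside).
#'
#' @param sigma assumed SD, minutes.
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level in (0, 1).
#' @param D total width of the expected confidence interval, minutes.
#' @return A `sample_size_spec`: sigma, power, alpha, D, z_crit, z_pwr,
#'   N (integer) and N_raw.
#' @export
#' @examples
#' required_sample_size(sigma = 4.2, power = 0.9, alpha = 0.05, D = 1.5)$N  # 329
required_sample_size <- function(sigma, power, alpha = 0.05, D) {
  stopifnot(is.finite(sigma), sigma > 0, is.finite(D))
  if (D <= 0) stop("D (total CI width) must be > 0")
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("power and alpha must lie strictly inside (0, 1)")
  z_crit <- z_quantile(1 - alpha / 2)
  z_pwr <- z_quantile(power)
  raw <- 4 * sigma^2 * (z_crit + z_pwr)^2 / D^2
  structure(list(sigma = sigma, power = power, alpha = alpha, D = D,
                 z_crit = z_crit, z_pwr = z_pwr,
                 N = as.integer(floor(raw)), N_raw = raw),
            class = "sample_size_spec")
}

#' @export
print.sample_size_spec <- function(x, ...) {
  cat(sprintf("<sample_size_spec> N = %d (raw %.2f) for sigma=%.3g min, power=%.2g, alpha=%.2g, D=%.3g min\n",
              x$N, x$N_raw, x$sigma, x$power, x$alpha, x$D))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-tailed t-test, wrapped with the guards this pipeline
#' needs (each group n >= 2 with positive variance).
#'
#' @param a,b numeric vectors (minutes).
#' @return A `dictime_test` with t statistic, df, p-value, group sizes and means.
#' @export
welch_t_test <- function(a, b) {
  a <- as_duration_vector(a); b <- as_duration_vector(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (sd(a) == 0 && sd(b) == 0)
    stop("degenerate groups (zero variance in both)")
  ht <- t.test(a, b, var.equal = FALSE)
  dictime_test("Welch two-sample t-test",
               statistic = c(t = unname(ht$statistic)),
               p_value = ht$p.value,
               n = c(length(a), length(b)),
               extra = list(df = unname(ht$parameter),
                            means = c(mean(a), mean(b))))
}

# U statistic of a vs b from midranks (counts pairs where a beats b,
# ties counted half).
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. With no ties and both groups at or below
#' `exact_max_n`, the p-value comes from the exact null distribution of U;
#' otherwise a tie-corrected normal approximation with continuity correction
#' is used (and a warning notes the fallback when ties preclude exactness).
#'
#' @param a,b numeric vectors.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact path.
#' @param exact_max_n per-group size up to which the exact distribution is
#'   used by default.
#' @param correct apply the continuity correction in the normal approximation.
#' @return A `dictime_test` with `U` (for `a` vs `b`), p-value, group sizes
#'   and rank sums.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, complete separation
mann_whitney_u <- function(a, b, exact = NULL, exact_max_n = 20L,
                           correct = TRUE) {
  a <- as_duration_vector(a); b <- as_duration_vector(b)
  m <- length(a); n <- length(b)
  if (m < 1 || n < 1) stop("each group needs at least 1 observation")
  u <- u_statistic(a, b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- (m <= exact_max_n && n <= exact_max_n) && !ties
  if (isTRUE(exact) && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  if (exact) {
    p <- if (u > m * n / 2)
      min(1, 2 * pwilcox(u - 1, m, n, lower.tail = FALSE))
    else
      min(1, 2 * pwilcox(u, m, n))
    method <- "Mann-Whitney U test (exact)"
  } else {
    r <- rank(c(a, b))
    N <- m + n
    tie_tab <- table(r)
    sigma2 <- (m * n / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- u - m * n / 2
    cc <- if (correct) sign(z) * 0.5 else 0
    z <- (z - cc) / sqrt(sigma2)
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    method <- "Mann-Whitney U test (normal approximation)"
  }
  dictime_test(method, statistic = c(U = u), p_value = p, n = c(m, n),
               extra = list(rank_sums = c(sum(rank(c(a, b))[seq_len(m)]),
                                          sum(rank(c(a, b))[m + seq_len(n)]))))
}

#' One-sample Kolmogorov-Smirnov test against a given normal
#'
#' @param x numeric vector, n >= 10.
#' @param mu,sigma reference normal parameters; `sigma > 0`.
#' @return A `dictime_test` with the KS `D` statistic and asymptotic p-value.
#' @export
ks_normal_test <- function(x, mu, sigma) {
  x <- as_duration_vector(x)
  if (length(x) < 10)
    stop(sprintf("sample too small for KS test (n = %d < 10)", length(x)))
  stopifnot(is.finite(mu), is.finite(sigma), sigma > 0)
  ht <- suppressWarnings(ks.test(x, "pnorm", mean = mu, sd = sigma,
                                 exact = FALSE))
  dictime_test("One-sample Kolmogorov-Smirnov test",
               statistic = c(D = unname(ht$statistic)),
               p_value = ht$p.value,
               n = length(x),
               extra = list(reference = c(mu = mu, sigma = sigma)))
}
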