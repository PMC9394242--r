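test_that("summary statistics: shape measures, SEs and degenerate flags", {
  x <- c(12, 15, 16, 18, 40)
  s <- summarize_durations(x)
  expect_equal(s$mean, mean(x))
  expect_equal(s$sd, sd(x))
  expect_equal(s$median, 16)
  expect_false(s$degenerate)

  const <- summarize_durations(rep(7, 10))
  expect_equal(const$mean, 7)
  expect_equal(const$sd, 0)
  expect_true(is.na(const$skewness))
  expect_true(const$degenerate)

  tiny <- summarize_durations(c(3, 9, 12))
  expect_true(is.na(tiny$skewness_se))   # SEs need n >= 4
  expect_false(is.na(tiny$skewness))
})

test_that("shift invariance: SD, skewness and kurtosis ignore location", {
  x <- rlnorm(200, log(15), 0.4)
  s1 <- summarize_durations(x)
  s2 <- summarize_durations(x + 37.5)
  expect_equal(s2$sd, s1$sd)
  expect_equal(s2$skewness, s1$skewness)
  expect_equal(s2$kurtosis_excess, s1$kurtosis_excess)
  expect_equal(s2$mean, s1$mean + 37.5)
})

test_that("adjusted skewness/kurtosis match a direct moment computation", {
  x <- c(1, 2, 2, 3, 5, 8, 13, 21)
  n <- length(x)
  m <- mean(x)
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
  g2 <- mean((x - m)^4) / mean((x - m)^2)^2 - 3
  s <- summarize_durations(x)
  expect_equal(s$skewness, g1 * sqrt(n * (n - 1)) / (n - 2))
  expect_equal(s$kurtosis_excess,
               ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)))
})

test_that("z_quantile is the inverse normal CDF with guards and symmetry", {
  expect_equal(z_quantile(0.5), 0)
  for (p in c(0.05, 0.2, 0.77, 0.975, 0.999))
    expect_equal(z_quantile(p) + z_quantile(1 - p), 0, tolerance = 1e-12)
  expect_error(z_quantile(0), "strictly inside")
  expect_error(z_quantile(1), "strictly inside")
})

test_that("sample-size calculator: floor, raw value and scaling laws", {
  base <- required_sample_size(sigma = 4.2, power = 0.9, alpha = 0.05, D = 1.5)
  expect_identical(base$N, 329L)
  expect_equal(base$N_raw, 4 * 4.2^2 * (qnorm(0.975) + qnorm(0.9))^2 / 1.5^2)
  expect_equal(base$z_crit, qnorm(0.975))

  doubled_sigma <- required_sample_size(8.4, 0.9, 0.05, 1.5)
  expect_equal(doubled_sigma$N_raw / base$N_raw, 4)
  doubled_D <- required_sample_size(4.2, 0.9, 0.05, 3.0)
  expect_equal(doubled_D$N_raw / base$N_raw, 1 / 4)

  expect_error(required_sample_size(4.2, 0.9, 0.05, 0), "must be > 0")
  expect_error(required_sample_size(4.2, 1.5, 0.05, 1), "strictly inside")
})

test_that("raw N is monotone: decreasing in D, increasing in sigma and power", {
  Ds <- seq(0.5, 4, by = 0.5)
  nD <- vapply(Ds, function(D) required_sample_size(4, 0.8, 0.05, D)$N_raw, 0)
  expect_true(all(diff(nD) < 0))
  sigmas <- seq(1, 9, by = 1)
  nS <- vapply(sigmas, function(s) required_sample_size(s, 0.8, 0.05, 2)$N_raw, 0)
  expect_true(all(diff(nS) > 0))
  powers <- seq(0.5, 0.99, by = 0.07)
  nP <- vapply(powers, function(p) required_sample_size(4, p, 0.05, 2)$N_raw, 0)
  expect_true(all(diff(nP) > 0))
})

test_that("Welch t-test: identity, power, symmetry and guards", {
  a <- c(10, 12, 14, 16)
  ident <- welch_t_test(a, a)
  expect_equal(unname(ident$statistic), 0)
  expect_equal(ident$p.value, 1)

  g <- with(list(), { set.seed(6); list(a = rnorm(200, 15, 5),
                                        b = rnorm(200, 20, 5)) })
  big <- welch_t_test(g$a, g$b)
  expect_lt(big$p.value, 0.001)
  swapped <- welch_t_test(g$b, g$a)
  expect_equal(swapped$p.value, big$p.value)
  expect_equal(unname(swapped$statistic), -unname(big$statistic))

  expect_error(welch_t_test(5, a), "at least 2")
  expect_error(welch_t_test(rep(3, 5), rep(9, 5)), "degenerate")
})

test_that("Mann-Whitney U: separation, identical groups, tie fallback", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(sep$statistic), 0)

  same <- suppressWarnings(mann_whitney_u(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$p.value, 1)

  expect_warning(mann_whitney_u(c(1, 1, 2), c(1, 3, 4), exact = TRUE),
                 "ties")
  expect_error(mann_whitney_u(numeric(0), c(1, 2)), "at least 1")
})

test_that("exact Mann-Whitney p equals brute-force enumeration (n <= 8)", {
  set.seed(101)
  cases <- list(c(3, 5), c(4, 4), c(5, 7), c(8, 6), c(2, 8))
  for (sz in cases) {
    a <- sample(1000, sz[1]); b <- sample(2000, sz[2]) + 0.5  # tie-free
    got <- mann_whitney_u(a, b)
    expect_match(got$method, "exact")
    expect_equal(got$p.value, mwu_enum_p(a, b), tolerance = 1e-12,
                 label = sprintf("m=%d n=%d", sz[1], sz[2]))
  }
})

test_that("normal-approximation path is close to the exact one near the switch", {
  set.seed(7)
  a <- rnorm(19, 10, 2); b <- rnorm(21, 11, 2)
  approx <- mann_whitney_u(a, b, exact = FALSE)
  exact <- mann_whitney_u(a, b, exact = TRUE)
  expect_lt(abs(approx$p.value - exact$p.value), 0.02)
  expect_match(approx$method, "approximation")
})

test_that("KS against a reference normal: null case, gross misfit, size guard", {
  x <- with(list(), { set.seed(15); rnorm(1000, 16, 5) })
  expect_gt(ks_normal_test(x, 16, 5)$p.value, 0.05)
  expect_lt(ks_normal_test(x + 5 * 5, 16, 5)$p.value, 0.001)
  expect_error(ks_normal_test(0.5, 0, 1), "too small")
})
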