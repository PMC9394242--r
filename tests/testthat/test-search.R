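# Unit tests run the search at reduced settings for speed; the full
# 1000-iteration / vector-100 configuration is exercised in test-acceptance.R.

test_that("single-iteration search returns the best initial candidate, unconverged", {
  d <- generate_durations(uniform_mix_config(n = 500, seed = 1))
  fit <- suppressWarnings(
    fit_stochastic_search(d$durations, n_iterations = 1, seed = 5))
  expect_false(fit$converged)
  expect_equal(nrow(fit$trace), 1)
  expect_s3_class(fit$params, "mixture_params")
})

test_that("search is reproducible for a fixed seed and varies across seeds", {
  d <- generate_durations(uniform_mix_config(n = 400, seed = 2))
  f1 <- suppressWarnings(fit_stochastic_search(d$durations, n_iterations = 50,
                                               vector_size = 20, seed = 42))
  f2 <- suppressWarnings(fit_stochastic_search(d$durations, n_iterations = 50,
                                               vector_size = 20, seed = 42))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$trace, f2$trace)
  f3 <- suppressWarnings(fit_stochastic_search(d$durations, n_iterations = 50,
                                               vector_size = 20, seed = 43))
  expect_false(identical(f1$trace$objective, f3$trace$objective))
})

test_that("search-range widths are non-increasing and lambda stays in (0, 1]", {
  d <- generate_durations(uniform_mix_config(n = 400, seed = 3))
  fit <- suppressWarnings(
    fit_stochastic_search(d$durations, n_iterations = 200, vector_size = 20,
                          seed = 9))
  for (w in c("width_mu", "width_sigma", "width_lam"))
    expect_true(all(diff(fit$trace[[w]]) <= 0), label = w)
  expect_true(all(fit$trace$lam > 0 & fit$trace$lam <= 1))
  expect_true(all(diff(fit$trace$objective) >= 0))  # best-so-far objective
})

test_that("search agrees with the EM oracle on a moderate sample", {
  d <- generate_durations(uniform_mix_config(n = 500, seed = 4))
  em <- fit_em(d$durations)
  fit <- suppressWarnings(
    fit_stochastic_search(d$durations, n_iterations = 400, vector_size = 50,
                          seed = 11))
  expect_params_close(fit$params, em$params$mu, em$params$sigma, em$params$lam)
})

test_that("KS-distance objective lands near the likelihood optimum", {
  d <- generate_durations(uniform_mix_config(n = 800, seed = 6))
  em <- fit_em(d$durations)
  fit <- suppressWarnings(
    fit_stochastic_search(d$durations, n_iterations = 400, vector_size = 50,
                          seed = 12, objective = "ks"))
  expect_lt(abs(fit$params$mu - em$params$mu), 1)
  expect_lt(abs(fit$params$sigma - em$params$sigma), 1)
  expect_gte(fit$objective_value, -0.05)  # fitted CDF within 5% of the ECDF
})

test_that("search input guards mirror the EM ones", {
  expect_error(fit_stochastic_search(rep(7, 40), seed = 1),
               "degenerate sample")
  d <- generate_durations(uniform_mix_config(n = 100, seed = 7))
  expect_error(fit_stochastic_search(d$durations, vector_size = 1, seed = 1))
  expect_error(fit_stochastic_search(d$durations, n_iterations = 0, seed = 1))
})

test_that("fit serialization writes params and trace", {
  d <- generate_durations(uniform_mix_config(n = 300, seed = 8))
  fit <- suppressWarnings(fit_stochastic_search(d$durations, n_iterations = 30,
                                                vector_size = 10, seed = 2))
  path <- tempfile(fileext = ".txt")
  write_fit(fit, path)
  lines <- readLines(path)
  expect_true(any(grepl("^method: search$", lines)))
  expect_true(any(grepl("^lambda:", lines)))
  trace <- read.csv(paste0(path, ".trace.csv"))
  expect_equal(nrow(trace), 30)
  expect_named(trace, c("iteration", "mu", "sigma", "lam", "objective",
                        "width_mu", "width_sigma", "width_lam"))
})
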