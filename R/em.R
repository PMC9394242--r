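#' Mixture parameters
#'
#' @param mu,sigma mean and SD of the normal (true-reading) component, minutes.
#' @param lam weight of the normal component in `(0, 1]`; `1 - lam` is the
#'   contamination fraction.
#' @return A `mixture_params` object.
#' @export
mixture_params <- function(mu, sigma, lam) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma > 0,
            is.finite(lam), lam > 0, lam <= 1)
  structure(list(mu = mu, sigma = sigma, lam = lam), class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("<mixture_params> mu=%.3f min  sigma=%.3f min  lambda=%.4f\n",
              x$mu, x$sigma, x$lam))
  invisible(x)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit method=%s> mu=%.3f sigma=%.3f lambda=%.4f  logLik=%.2f  %s (%d iterations)\n",
              x$method, x$params$mu, x$params$sigma, x$params$lam, x$logLik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations_run))
  invisible(x)
}

check_fit_input <- function(x, min_n = 30L) {
  x <- as_duration_vector(x)
  if (length(x) < min_n)
    stop(sprintf("sample too small for mixture fit (n = %d < %d)", length(x), min_n))
  if (any(!is.finite(x)) || any(x <= 0)) stop("durations must be finite and > 0")
  if (stats::sd(x) == 0) stop("degenerate sample (zero variance)")
  x
}

# Robust starting values ignoring contamination.
auto_init <- function(x) {
  s <- stats::mad(x)
  if (s <= 0) s <- stats::sd(x)
  mixture_params(mu = stats::median(x), sigma = s, lam = 0.8)
}

resolve_init <- function(init, x) {
  if (identical(init, "auto")) return(auto_init(x))
  if (inherits(init, "mixture_params")) return(init)
  if (is.numeric(init) && length(init) == 3)
    return(mixture_params(init[1], init[2], init[3]))
  stop("init must be \"auto\", a mixture_params, or a numeric (mu, sigma, lam)")
}

mixture_loglik <- function(x, cdens, mu, sigma, lam) {
  sum(log(pmax(lam * dnorm(x, mu, sigma) + (1 - lam) * cdens, 1e-320)))
}

warn_negative_mass <- function(params) {
  p0 <- pnorm(0, params$mu, params$sigma)
  if (p0 > 0.01)
    warning(sprintf(
      "fitted normal component puts %.1f%% mass below 0 min; the plain-normal assumption is questionable here",
      100 * p0))
  invisible(p0)
}

#' Fit the contaminated-normal mixture by expectation-maximization
#'
#' Reference maximum-likelihood fitter for the two-component model
#' `lambda * Normal(mu, sigma) + (1 - lambda) * c(x)` with a fixed
#' contamination density `c`. The E-step computes the posterior probability
#' of the normal component per record; the M-step updates `(mu, sigma)` as
#' posterior-weighted moments and `lambda` as the mean posterior. The
#' observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param durations a [duration_sample()] or numeric vector of minutes
#'   (all > 0, n >= 30).
#' @param contamination a [contamination_uniform()] or
#'   [contamination_threepart()] model; data-bound supports are resolved
#'   against the sample.
#' @param init `"auto"` (median / 1.4826 MAD / 0.8), a [mixture_params()], or
#'   a numeric `(mu, sigma, lam)`.
#' @param tol relative parameter-change threshold declaring convergence.
#' @param max_iter maximum EM iterations.
#' @return A `mixture_fit`: `params` ([mixture_params()]), `trace` (data
#'   frame: iteration, mu, sigma, lam, objective, search widths — `NA` for
#'   EM), `converged`, `iterations_run`, `logLik`, `method = "em"`,
#'   `contamination` (resolved), `n`.
#' @seealso [fit_stochastic_search()] for the iterative candidate-vector
#'   search, [classify_records()] to apply the fit.
#' @export
#' @examples
#' x <- generate_durations(generator_config(n = 2000, seed = 1,
#'                                          weights = c(0, 0.9, 0, 0.1)))
#' fit_em(x$durations)
fit_em <- function(durations, contamination = contamination_uniform(),
                   init = "auto", tol = 1e-6, max_iter = 500L) {
  x <- check_fit_input(durations)
  contamination <- resolve_contamination(contamination, x)
  cdens <- cont_density(contamination, x)
  p <- resolve_init(init, x)
  mu <- p$mu; sigma <- p$sigma; lam <- p$lam

  trace <- vector("list", max_iter)
  converged <- FALSE
  it <- 0L
  ll <- mixture_loglik(x, cdens, mu, sigma, lam)
  for (it in seq_len(max_iter)) {
    f1 <- lam * dnorm(x, mu, sigma)
    denom <- f1 + (1 - lam) * cdens
    post <- ifelse(denom > 0, f1 / denom, 1)
    w <- sum(post)
    lam_new <- min(max(mean(post), 1e-8), 1)
    mu_new <- sum(post * x) / w
    sigma_new <- sqrt(max(sum(post * (x - mu_new)^2) / w, 1e-12))
    rel <- max(abs(mu_new - mu) / max(abs(mu), 1e-12),
               abs(sigma_new - sigma) / max(sigma, 1e-12),
               abs(lam_new - lam))
    mu <- mu_new; sigma <- sigma_new; lam <- lam_new
    ll <- mixture_loglik(x, cdens, mu, sigma, lam)
    trace[[it]] <- c(iteration = it, mu = mu, sigma = sigma, lam = lam,
                     objective = ll,
                     width_mu = NA_real_, width_sigma = NA_real_,
                     width_lam = NA_real_)
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations (tol = %g)", max_iter, tol))
  trace <- as.data.frame(do.call(rbind, trace[seq_len(it)]))
  warn_negative_mass(mixture_params(mu, sigma, lam))
  structure(list(params = mixture_params(mu, sigma, lam),
                 trace = trace, converged = converged, iterations_run = it,
                 logLik = ll, method = "em", seed = NULL,
                 contamination = contamination, n = length(x)),
            class = "mixture_fit")
}
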