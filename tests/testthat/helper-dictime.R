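# Shared fixtures: everything is generated in code at test time.

# The stated synthetic world of the recovery criteria: lambda = 0.9 normal
# component Normal(16, 5), uniform contamination on (0, 240].
uniform_mix_config <- function(n, seed) {
  generator_config(n = n, seed = seed,
                   weights = c(0, 0.9, 0, 0.1),
                   normal_mu = 16, normal_sigma = 5,
                   unknown_range = c(0, 240))
}

# Write a small RIS-style CSV; rows = list of c(id, code, start, save).
write_ris_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  lines <- c("exam_id,region_code,dictation_start,first_save",
             vapply(rows, paste, "", collapse = ","))
  writeLines(lines, path)
  path
}

# Brute-force Mann-Whitney oracle: enumerate every assignment of the pooled
# ranks to group a, build the exact null distribution of U, and apply the
# same two-sided doubling convention as the implementation.
mwu_enum_p <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  us <- apply(matrix(idx, nrow = m), 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

expect_params_close <- function(p, mu, sigma, lam,
                                tol = c(0.5, 0.5, 0.05)) {
  expect_lt(abs(p$mu - mu), tol[1])
  expect_lt(abs(p$sigma - sigma), tol[2])
  expect_lt(abs(p$lam - lam), tol[3])
}
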