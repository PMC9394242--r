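#' Configuration for an end-to-end pipeline run
#'
#' @param input path to a RIS timestamp CSV (see [load_timestamps()]).
#' @param region_map a `region_map` or path to a map CSV.
#' @param regions regions to process; `NULL` processes every region found.
#' @param method `"search"` (the iterative stochastic parameter-vector
#'   search, the default), `"em"`, or `"both"`.
#' @param n_iterations,vector_size stochastic-search settings.
#' @param seed master seed; each region/method fit derives its own stream
#'   from it, and it is stamped into every artifact.
#' @param threshold posterior cutoff for [classify_records()].
#' @param min_n smallest per-region sample fitted; smaller regions are
#'   skipped with a warning.
#' @param format_spec column mapping passed to [load_timestamps()].
#' @param out_dir if non-`NULL`, artifacts (summary CSV, fit files, traces,
#'   classifications, run log) are written there.
#' @return A `run_config`.
#' @export
run_config <- function(input, region_map = default_region_map(),
                       regions = NULL, method = c("search", "em", "both"),
                       n_iterations = 1000L, vector_size = 100L,
                       seed = 1L, threshold = 0.5, min_n = 30L,
                       format_spec = c(exam_id = "exam_id",
                                       region_code = "region_code",
                                       dictation_start = "dictation_start",
                                       first_save = "first_save"),
                       out_dir = NULL) {
  method <- match.arg(method)
  if (is.character(region_map) && length(region_map) == 1)
    region_map <- read_region_map(region_map)
  structure(list(input = input, region_map = validate_region_map(region_map),
                 regions = regions, method = method,
                 n_iterations = as.integer(n_iterations),
                 vector_size = as.integer(vector_size),
                 seed = as.integer(seed), threshold = threshold,
                 min_n = as.integer(min_n), format_spec = format_spec,
                 out_dir = out_dir),
            class = "run_config")
}

# Deterministic per-region, per-method child seed below 2^31.
derive_seed <- function(seed, region_idx, method) {
  offset <- if (identical(method, "em")) 0L else 500L
  (seed * 1009L + region_idx * 31L + offset) %% 2147483647L
}

summary_row <- function(method, region, n_total, retained) {
  data.frame(method = method, region = region,
             n_total = n_total, n_norm = length(retained),
             mean_min = mean(retained), sd_min = sd(retained),
             median_min = median(retained),
             stringsAsFactors = FALSE)
}

#' Run the full dictation-time pipeline
#'
#' Ingests the timestamp export, computes per-region dictation times, fits
#' the contaminated-normal mixture per region, classifies records, and emits
#' a summary table in the shape reading-time studies report: one row per
#' region with n total (valid durations), n norm (retained after outlier
#' reduction) and the retained subset's mean, SD and median in minutes, plus
#' an `"All"` row pooling the retained records across regions. With
#' `method = "both"`, rows are produced for both fitters.
#'
#' @param config a [run_config()].
#' @return A `pipeline_run`: `summary` (data frame as above), `fits` (named
#'   list of `mixture_fit` per "region/method"), `classified` (named list of
#'   `classified_sample`), `counts` ([pooled_counts()] table), `log`
#'   (character), `config`, `config_hash`. Artifacts are written when
#'   `config$out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  records <- load_timestamps(config$input, config$format_spec)
  note("read %d rows (%d skipped) from %s",
       attr(records, "rows_read"), attr(records, "rows_skipped"), config$input)
  samples <- compute_dictation_times(records, config$region_map)
  note("excluded %d record(s) with first save at or before dictation start",
       attr(samples, "n_excluded_total"))

  regions <- config$regions %||% names(samples)
  missing_regions <- setdiff(regions, names(samples))
  for (r in missing_regions) note("region %s: no records found, skipped", r)
  regions <- intersect(regions, names(samples))

  methods <- if (config$method == "both") c("em", "search") else config$method
  fits <- list(); classified <- list(); rows <- list()
  for (mth in methods) {
    pooled_retained <- numeric(0); pooled_total <- 0L
    for (ri in seq_along(regions)) {
      r <- regions[ri]
      s <- samples[[r]]
      if (length(s$durations) < config$min_n) {
        warning(sprintf("region %s: n = %d < %d, skipped",
                        r, length(s$durations), config$min_n))
        note("region %s: n = %d < %d, skipped", r, length(s$durations),
             config$min_n)
        next
      }
      child_seed <- derive_seed(config$seed, ri, mth)
      fit <- if (mth == "em") {
        fit_em(s)
      } else {
        fit_stochastic_search(s, n_iterations = config$n_iterations,
                              vector_size = config$vector_size,
                              seed = child_seed)
      }
      cls <- classify_records(s, fit, threshold = config$threshold)
      key <- paste(r, mth, sep = "/")
      fits[[key]] <- fit
      classified[[key]] <- cls
      rows[[key]] <- summary_row(mth, r, length(s$durations), cls$retained)
      pooled_retained <- c(pooled_retained, cls$retained)
      pooled_total <- pooled_total + length(s$durations)
      note("region %s (%s): n=%d n_norm=%d mu=%.2f sigma=%.2f lambda=%.3f converged=%s seed=%d",
           r, mth, length(s$durations), cls$n_norm, fit$params$mu,
           fit$params$sigma, fit$params$lam, fit$converged, child_seed)
    }
    if (length(pooled_retained))
      rows[[paste("All", mth, sep = "/")]] <-
        summary_row(mth, "All", pooled_total, pooled_retained)
  }
  if (!length(rows)) stop("no region had enough records to fit")
  summary <- do.call(rbind, c(unname(rows), make.row.names = FALSE))

  cfg_text <- c(config$input, config$method, config$n_iterations,
                config$vector_size, config$seed, config$threshold,
                config$min_n, paste(regions, collapse = ","))
  hash <- config_hash(as.character(cfg_text))
  note("config_hash: %s seed: %d", hash, config$seed)

  run <- structure(list(summary = summary, fits = fits,
                        classified = classified,
                        counts = pooled_counts(samples),
                        log = log, config = config, config_hash = hash),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_run_artifacts(run, records, samples)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d summary row(s), config %s, seed %d\n",
              nrow(x$summary), x$config_hash, x$config$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

write_run_artifacts <- function(run, records, samples) {
  dir <- run$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash: %s seed: %d", run$config_hash,
                   run$config$seed)

  summary_path <- file.path(dir, "summary.csv")
  con <- file(summary_path, "w")
  writeLines(stamp, con)
  write.csv(run$summary, con, row.names = FALSE, quote = FALSE)
  close(con)

  write.csv(run$counts, file.path(dir, "pooled_counts.csv"), row.names = FALSE)
  for (key in names(run$fits)) {
    safe <- gsub("/", "_", key)
    write_fit(run$fits[[key]], file.path(dir, sprintf("fit_%s.txt", safe)),
              trace_path = file.path(dir, sprintf("trace_%s.csv", safe)))
    write_classification(run$classified[[key]],
                         file.path(dir, sprintf("classified_%s.csv", safe)))
  }
  write_load_report(records, samples, file.path(dir, "load_report.txt"))
  writeLines(c(stamp, run$log), file.path(dir, "run.log"))
  invisible(dir)
}

#' Compare two duration groups
#'
#' Runs the Welch t-test (difference in means) and the Mann-Whitney U test
#' (distributional shift / case-complexity tendency) on a pair of groups,
#' e.g. two readers or two assessment periods.
#'
#' @param a,b [duration_sample()]s or numeric vectors (minutes).
#' @param labels names of the two groups, for the report.
#' @return A `group_comparison`: list with `t` and `u` (`dictime_test`s) and
#'   the labels.
#' @export
compare_groups <- function(a, b, labels = c("group1", "group2")) {
  av <- as_duration_vector(a); bv <- as_duration_vector(b)
  if (length(av) == 0 || length(bv) == 0)
    stop(sprintf("cannot compare '%s' (n=%d) with '%s' (n=%d): empty group",
                 labels[1], length(av), labels[2], length(bv)))
  structure(list(t = welch_t_test(av, bv), u = mann_whitney_u(av, bv),
                 labels = labels, n = c(length(av), length(bv))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d) vs %s (n=%d)\n",
              x$labels[1], x$n[1], x$labels[2], x$n[2]))
  print(x$t); print(x$u)
  invisible(x)
}
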