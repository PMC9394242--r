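#' Configuration for the synthetic dictation-time generator
#'
#' The generator realizes the four-component structure the outlier model
#' assumes: (1) too-short entries from interruptions that force an immediate
#' save, (2) the true radiological reading time, normally distributed,
#' (3) too-long entries from reports paused and resumed later (e.g.
#' overnight), and (4) entries of unknown cause. Component densities:
#' short ~ Exponential(`short_scale`) truncated to `(0, normal_mu)`;
#' normal ~ `Normal(normal_mu, normal_sigma)` resampled until positive;
#' long = normal draw + `long_shift` + Exponential(`long_scale`);
#' unknown ~ Uniform(`unknown_range`), resampled until positive.
#'
#' Defaults: weights `(0.05, 0.85, 0.07, 0.03)`, `mu = 16` min,
#' `sigma = 5` min, `short_scale = 2`, `long_shift = 300`,
#' `long_scale = 200`, `unknown_range = (0.2, 480)` minutes.
#'
#' @param n number of records.
#' @param seed integer seed; output is byte-identical per (config, seed).
#' @param weights component weights `(short, normal, long, unknown)`,
#'   non-negative, summing to 1.
#' @param normal_mu,normal_sigma true reading-time mean and SD, minutes.
#' @param short_scale exponential scale of interrupt-shortened entries, minutes.
#' @param long_shift,long_scale shift and scale of continuation delays, minutes.
#' @param unknown_range `(low, high)` of the unknown component, minutes.
#' @param negative_save_rate proportion of emitted timestamp rows whose first
#'   save precedes the dictation start (to exercise the exclusion rule);
#'   applies to [to_timestamp_table()] only.
#' @return A `generator_config`.
#' @export
generator_config <- function(n, seed = 1L,
                             weights = c(0.05, 0.85, 0.07, 0.03),
                             normal_mu = 16, normal_sigma = 5,
                             short_scale = 2,
                             long_shift = 300, long_scale = 200,
                             unknown_range = c(0.2, 480),
                             negative_save_rate = 0) {
  stopifnot(n >= 0, length(weights) == 4)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  stopifnot(normal_mu > 0, normal_sigma > 0, short_scale > 0,
            long_shift >= 0, long_scale > 0,
            length(unknown_range) == 2, unknown_range[2] > unknown_range[1],
            negative_save_rate >= 0, negative_save_rate < 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 weights = as.numeric(weights),
                 normal_mu = normal_mu, normal_sigma = normal_sigma,
                 short_scale = short_scale,
                 long_shift = long_shift, long_scale = long_scale,
                 unknown_range = as.numeric(unknown_range),
                 negative_save_rate = negative_save_rate),
            class = "generator_config")
}

component_labels <- c("short", "normal", "long", "unknown")

rpositive <- function(n, draw) {
  # resample until strictly positive; expected extra draws negligible for
  # the default parameters
  x <- draw(n)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- draw(length(bad))
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Generate a labeled synthetic dictation-time dataset
#'
#' @param config a [generator_config()].
#' @return A `labeled_dataset`: `durations` (minutes, all > 0), `labels`
#'   (component per record), `config`.
#' @export
#' @examples
#' d <- generate_durations(generator_config(n = 1000, seed = 42))
#' table(d$labels)
generate_durations <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  out <- with_local_seed(config$seed, {
    if (n == 0) {
      list(durations = numeric(0), labels = character(0))
    } else {
      comp <- sample.int(4L, n, replace = TRUE, prob = config$weights)
      x <- numeric(n)
      i <- which(comp == 1L)
      if (length(i)) {
        # inverse-CDF draw from Exponential(short_scale) truncated to (0, mu)
        pmax_trunc <- 1 - exp(-config$normal_mu / config$short_scale)
        u <- runif(length(i))
        x[i] <- -config$short_scale * log(1 - u * pmax_trunc)
      }
      i <- which(comp == 2L)
      if (length(i))
        x[i] <- rpositive(length(i),
                          function(k) rnorm(k, config$normal_mu, config$normal_sigma))
      i <- which(comp == 3L)
      if (length(i))
        x[i] <- rpositive(length(i), function(k)
          rnorm(k, config$normal_mu, config$normal_sigma) + config$long_shift +
            rexp(k, rate = 1 / config$long_scale))
      i <- which(comp == 4L)
      if (length(i))
        x[i] <- rpositive(length(i), function(k)
          runif(k, config$unknown_range[1], config$unknown_range[2]))
      list(durations = x, labels = component_labels[comp])
    }
  })
  structure(list(durations = out$durations, labels = out$labels,
                 config = config),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> n=%d seed=%d components: %s\n",
              length(x$durations), x$config$seed,
              paste(sprintf("%s=%d", component_labels,
                            tabulate(match(x$labels, component_labels), 4L)),
                    collapse = " ")))
  invisible(x)
}

#' Render a labeled dataset as a RIS-style timestamp table
#'
#' Synthesizes dictation-start times over a working calendar (weekdays,
#' 32 slots of 15 minutes from 08:00) and sets `first_save = start +
#' duration`, so the table round-trips through [load_timestamps()] and
#' [compute_dictation_times()] to the original durations. A
#' `negative_save_rate` fraction of rows (from the config) instead gets a
#' first save *before* the dictation start, to exercise the exclusion rule.
#'
#' @param dataset a `labeled_dataset`.
#' @param start_epoch first working day 08:00, POSIXct (UTC).
#' @param region canonical region label; the emitted `region_code` is a raw
#'   code the default map resolves to it (e.g. `CT_HEAD`).
#' @return A `timestamp_records` data frame (exam_id, region_code,
#'   dictation_start, first_save) with attributes `labels` (component per
#'   row) and `injected_negative` (logical per row).
#' @export
to_timestamp_table <- function(dataset,
                               start_epoch = as.POSIXct("2020-01-06 08:00:00",
                                                        tz = "UTC"),
                               region = "head") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- length(dataset$durations)
  slot <- (seq_len(n) - 1L) %% 32L
  day <- (seq_len(n) - 1L) %/% 32L
  day <- (day %/% 5L) * 7L + day %% 5L        # skip weekends
  start <- start_epoch + day * 86400 + slot * 900
  save <- start + dataset$durations * 60

  injected <- rep(FALSE, n)
  rate <- dataset$config$negative_save_rate
  if (rate > 0 && n > 0) {
    inj <- with_local_seed(dataset$config$seed + 1L, {
      flag <- runif(n) < rate
      list(flag = flag, back = runif(sum(flag), 1, 60))
    })
    injected <- inj$flag
    save[injected] <- start[injected] - inj$back * 60
  }

  rec <- data.frame(
    exam_id = sprintf("SYN%06d", seq_len(n)),
    region_code = paste0("CT_", toupper(region)),
    dictation_start = start,
    first_save = save,
    stringsAsFactors = FALSE
  )
  structure(rec, labels = dataset$labels, injected_negative = injected,
            rows_read = n, rows_skipped = 0L,
            class = c("timestamp_records", "data.frame"))
}

#' Write the component labels of a synthetic dataset to CSV
#'
#' @param records a table from [to_timestamp_table()].
#' @param path output CSV (exam_id, component).
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(records, path) {
  write.csv(data.frame(exam_id = records$exam_id,
                       component = attr(records, "labels")),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
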