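#' Default RIS protocol-code to anatomical-region mapping
#'
#' RIS exports carry heterogeneous protocol/entity codes (a head CT may be
#' logged as a native scan, a CT angiography or a stroke protocol); for
#' pooling they are collapsed onto canonical anatomical regions. No
#' institution publishes its code list, so the default map is illustrative:
#' case-insensitive regular expressions tried in order, first match wins,
#' unmatched codes map to `"other"`.
#'
#' @return A `region_map`: data frame with columns `pattern` (regex) and
#'   `label` (canonical region).
#' @seealso [read_region_map()] to supply an institution-specific map,
#'   [map_region()] to apply one.
#' @export
#' @examples
#' map_region(c("CT_HEAD_NATIVE", "CT Stroke Perfusion", "XYZ"), default_region_map())
default_region_map <- function() {
  m <- data.frame(
    pattern = c(
      "head|skull|brain|stroke|neuro",
      "chest|thorax|lung|pulmo",
      "abdom|liver|pancrea|pelvi",
      "foot|ankle",
      "lumbar|l[-_ ]?spine|ls[-_ ]?spine",
      "shoulder",
      "wrist|hand",
      "poly|trauma|whole[-_ ]?body"
    ),
    label = c(
      "head", "chest", "abdomen", "foot",
      "lumbar_spine", "shoulder", "wrist", "polytrauma"
    ),
    stringsAsFactors = FALSE
  )
  validate_region_map(m)
}

#' Canonical anatomical region labels
#' @return Character vector of the nine canonical labels (including `"other"`).
#' @export
canonical_regions <- function() {
  c("head", "chest", "abdomen", "foot", "lumbar_spine",
    "shoulder", "wrist", "polytrauma", "other")
}

validate_region_map <- function(m) {
  stopifnot(is.data.frame(m), all(c("pattern", "label") %in% names(m)))
  if (anyNA(m$pattern) || anyNA(m$label) || any(!nzchar(m$pattern)))
    stop("region map: patterns and labels must be non-empty")
  if (anyDuplicated(m$pattern))
    stop("region map: each pattern must map to exactly one label")
  class(m) <- c("region_map", "data.frame")
  m
}

#' Read a region map from CSV
#'
#' @param path CSV file with columns `pattern,label`.
#' @return A `region_map`.
#' @export
read_region_map <- function(path) {
  if (!file.exists(path)) stop("region map file not found: ", path)
  validate_region_map(read.csv(path, stringsAsFactors = FALSE,
                               colClasses = "character"))
}

#' Map raw RIS codes onto canonical regions
#'
#' @param codes character vector of raw protocol/entity codes.
#' @param map a `region_map`; defaults to [default_region_map()].
#' @return Character vector of region labels; unmatched codes get `"other"`.
#' @export
map_region <- function(codes, map = default_region_map()) {
  map <- validate_region_map(map)
  out <- rep("other", length(codes))
  unmatched <- rep(TRUE, length(codes))
  for (i in seq_len(nrow(map))) {
    hit <- unmatched & grepl(map$pattern[i], codes, ignore.case = TRUE, perl = TRUE)
    out[hit] <- map$label[i]
    unmatched[hit] <- FALSE
  }
  out
}

parse_ris_time <- function(x) {
  # ISO 8601, "T" or space separated, optional fractional seconds;
  # timezone-naive values pinned to UTC so arithmetic ignores DST.
  # Formats are tried per element (a row that fails every format stays NA
  # and is skipped upstream, instead of poisoning the whole column).
  x <- sub("T", " ", trimws(x), fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                "%Y/%m/%d %H:%M:%OS")) {
    miss <- which(is.na(out))
    if (!length(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

#' Load a RIS timestamp export
#'
#' Reads a CSV export of exam-level timestamps (one row per report:
#' identifier, protocol/entity code, dictation start, first save). Rows with
#' unparseable timestamps or empty identifier/code fields are skipped with a
#' warning and counted in the load report attached to the result.
#'
#' @param path CSV file; header row required, UTF-8, comma-separated.
#' @param format_spec named character vector mapping the canonical field
#'   names `exam_id`, `region_code`, `dictation_start`, `first_save` to the
#'   column names used in the export.
#' @return A `timestamp_records` data frame with columns `exam_id`,
#'   `region_code` (character) and `dictation_start`, `first_save` (POSIXct,
#'   UTC). Attributes `rows_read` and `rows_skipped` hold the load report.
#' @export
load_timestamps <- function(path,
                            format_spec = c(exam_id = "exam_id",
                                            region_code = "region_code",
                                            dictation_start = "dictation_start",
                                            first_save = "first_save")) {
  if (!file.exists(path)) stop("timestamp file not found: ", path)
  needed <- c("exam_id", "region_code", "dictation_start", "first_save")
  if (!all(needed %in% names(format_spec)))
    stop("format_spec must name columns for: ", paste(needed, collapse = ", "))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(unname(format_spec[needed]), names(raw))
  if (length(missing_cols))
    stop("declared column(s) not in file: ", paste(missing_cols, collapse = ", "))

  rec <- data.frame(
    exam_id = trimws(raw[[format_spec[["exam_id"]]]]),
    region_code = trimws(raw[[format_spec[["region_code"]]]]),
    dictation_start = parse_ris_time(raw[[format_spec[["dictation_start"]]]]),
    first_save = parse_ris_time(raw[[format_spec[["first_save"]]]]),
    stringsAsFactors = FALSE
  )
  ok <- nzchar(rec$exam_id) & nzchar(rec$region_code) &
    !is.na(rec$dictation_start) & !is.na(rec$first_save)
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    warning(sprintf("skipped %d row(s) with unparseable timestamps or empty fields",
                    n_skipped))
  rec <- rec[ok, , drop = FALSE]
  if (nrow(rec) == 0) stop("no parseable rows in ", path)
  rownames(rec) <- NULL
  structure(rec,
            rows_read = nrow(raw), rows_skipped = n_skipped,
            class = c("timestamp_records", "data.frame"))
}

#' Write timestamp records to CSV
#'
#' Timestamps are written with microsecond precision so durations round-trip
#' through [load_timestamps()].
#'
#' @param records a `timestamp_records` data frame (or compatible).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timestamp_csv <- function(records, path) {
  out <- data.frame(
    exam_id = records$exam_id,
    region_code = records$region_code,
    dictation_start = format(records$dictation_start, "%Y-%m-%d %H:%M:%OS6", tz = "UTC"),
    first_save = format(records$first_save, "%Y-%m-%d %H:%M:%OS6", tz = "UTC"),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a per-region duration sample
#'
#' @param durations numeric vector of dictation times in minutes (all > 0).
#' @param region canonical region label.
#' @param exam_id optional identifiers, same length as `durations`.
#' @param n_excluded count of records removed by validity rules.
#' @return A `duration_sample` object.
#' @export
duration_sample <- function(durations, region = "other", exam_id = NULL,
                            n_excluded = 0L) {
  durations <- as.numeric(durations)
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("durations must be finite and > 0")
  if (!is.null(exam_id) && length(exam_id) != length(durations))
    stop("exam_id length must match durations")
  structure(list(region = region,
                 durations = durations,
                 exam_id = exam_id %||% as.character(seq_along(durations)),
                 n_total = length(durations) + as.integer(n_excluded),
                 n_excluded = as.integer(n_excluded)),
            class = "duration_sample")
}

#' @export
print.duration_sample <- function(x, ...) {
  cat(sprintf("<duration_sample> region=%s n=%d (excluded %d) mean=%.2f min median=%.2f min\n",
              x$region, length(x$durations), x$n_excluded,
              mean(x$durations), median(x$durations)))
  invisible(x)
}

# Accept either a duration_sample or a bare numeric vector.
as_duration_vector <- function(x) {
  if (inherits(x, "duration_sample")) return(x$durations)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected a duration_sample or numeric vector")
}

#' Compute dictation times and pool by anatomical region
#'
#' Dictation time is the interval between dictation start and first save, in
#' fractional minutes. Records whose report was saved at or before the
#' dictation start (duration <= 0) are excluded — a save that precedes the
#' dictation cannot be a reading interval, and a zero-length one cannot be a
#' report — and counted per region.
#'
#' @param records a `timestamp_records` data frame from [load_timestamps()].
#' @param region_map a `region_map`; defaults to [default_region_map()].
#' @return A named list of [duration_sample()] objects (class
#'   `duration_samples`), one per region present in the data, each carrying
#'   its exclusion count. Regions whose records were all excluded are kept
#'   with an empty duration vector.
#' @export
compute_dictation_times <- function(records, region_map = default_region_map()) {
  if (NROW(records) == 0) stop("no records supplied")
  dur <- as.numeric(difftime(records$first_save, records$dictation_start,
                             units = "mins"))
  region <- map_region(records$region_code, region_map)
  keep <- dur > 0
  if (!any(keep))
    stop(sprintf("all %d record(s) excluded (first save at or before dictation start)",
                 length(dur)))
  out <- lapply(split(seq_along(dur), region), function(idx) {
    inc <- idx[keep[idx]]
    s <- structure(list(region = region[idx[1]],
                        durations = dur[inc],
                        exam_id = records$exam_id[inc],
                        n_total = length(idx),
                        n_excluded = length(idx) - length(inc)),
                   class = "duration_sample")
    s
  })
  structure(out, class = "duration_samples",
            n_excluded_total = sum(!keep))
}

#' Per-region record counts before and after exclusion
#'
#' @param samples a `duration_samples` list from [compute_dictation_times()],
#'   or a list of [duration_sample()] objects.
#' @return Data frame with columns `region`, `n_total`,
#'   `n_after_exclusion`, plus an `"All"` row summing the regions.
#' @export
pooled_counts <- function(samples) {
  rows <- lapply(samples, function(s)
    data.frame(region = s$region, n_total = s$n_total,
               n_after_exclusion = length(s$durations),
               stringsAsFactors = FALSE))
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  rbind(tab, data.frame(region = "All",
                        n_total = sum(tab$n_total),
                        n_after_exclusion = sum(tab$n_after_exclusion)))
}

#' Write a plain-text load report
#'
#' @param records a `timestamp_records` object (for read/skip counts).
#' @param samples optional `duration_samples` (for exclusion counts).
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_load_report <- function(records, samples = NULL, path) {
  lines <- c(
    sprintf("rows_read: %d", attr(records, "rows_read") %||% NROW(records)),
    sprintf("rows_skipped: %d", attr(records, "rows_skipped") %||% 0L),
    "note: timestamps treated as timezone-naive local times; intervals across DST changes taken at face value"
  )
  if (!is.null(samples)) {
    lines <- c(lines,
               sprintf("rows_excluded_nonpositive_duration: %d",
                       attr(samples, "n_excluded_total")),
               sprintf("region %s: n_total=%d n_valid=%d excluded=%d",
                       vapply(samples, `[[`, "", "region"),
                       vapply(samples, `[[`, 0L, "n_total"),
                       vapply(samples, function(s) length(s$durations), 0L),
                       vapply(samples, `[[`, 0L, "n_excluded")))
  }
  writeLines(lines, path)
  invisible(path)
}
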