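test_that("load_timestamps reads well-formed rows and reports skips", {
  path <- write_ris_csv(list(
    c("E1", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 10:16:22"),
    c("E2", "CT_CHEST", "2021-01-04T11:00:00", "2021-01-04T11:12:30"),
    c("E3", "CT_HEAD", "2021-01-04 12:00:00", "2021-01-04 12:05:00")
  ))
  rec <- load_timestamps(path)
  expect_s3_class(rec, "timestamp_records")
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "rows_skipped"), 0)

  bad <- write_ris_csv(list(
    c("E1", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 10:16:22"),
    c("E2", "CT_HEAD", "2021-01-04 11:00:00", "not-a-time"),
    c("E3", "CT_HEAD", "2021-01-04 12:00:00", "2021-01-04 12:05:00")
  ))
  expect_warning(rec2 <- load_timestamps(bad), "skipped 1")
  expect_equal(nrow(rec2), 2)
  expect_equal(attr(rec2, "rows_skipped"), 1)
})

test_that("load_timestamps fails fast on bad inputs", {
  expect_error(load_timestamps(tempfile()), "not found")
  empty <- write_ris_csv(list())
  expect_error(load_timestamps(empty), "no parseable rows")
  path <- write_ris_csv(list(c("E1", "CT_HEAD", "2021-01-04 10:00:00",
                               "2021-01-04 10:16:22")))
  expect_error(
    load_timestamps(path, format_spec = c(exam_id = "exam_id",
                                          region_code = "region_code",
                                          dictation_start = "dictation_start",
                                          first_save = "nonexistent")),
    "nonexistent")
})

test_that("custom column names are honored", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,entity,t0,t1",
               "A,CT_HEAD,2021-01-04 10:00:00,2021-01-04 10:10:00"), path)
  rec <- load_timestamps(path, format_spec = c(exam_id = "id",
                                               region_code = "entity",
                                               dictation_start = "t0",
                                               first_save = "t1"))
  expect_equal(rec$exam_id, "A")
})

test_that("dictation times subtract correctly and exclusion rules apply", {
  path <- write_ris_csv(list(
    c("E1", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 10:16:22"),
    c("E2", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 09:59:00"),  # save precedes start
    c("E3", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 10:00:00")   # save == start
  ))
  samples <- suppressWarnings(compute_dictation_times(load_timestamps(path)))
  head <- samples[["head"]]
  expect_equal(head$durations, 16 + 22 / 60, tolerance = 1e-10)
  expect_equal(head$n_excluded, 2)
  expect_equal(head$n_total, 3)
  expect_equal(head$n_total, length(head$durations) + head$n_excluded)
})

test_that("all-excluded input is a hard error naming the count", {
  path <- write_ris_csv(list(
    c("E1", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 09:00:00"),
    c("E2", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 10:00:00")
  ))
  expect_error(compute_dictation_times(load_timestamps(path)),
               "all 2 record")
})

test_that("pooled_counts adds an All row and keeps degenerate regions", {
  path <- write_ris_csv(c(
    lapply(1:3, function(i) c(paste0("H", i), "CT_HEAD",
                              "2021-01-04 10:00:00", "2021-01-04 10:10:00")),
    lapply(1:4, function(i) c(paste0("C", i), "CT_CHEST",
                              "2021-01-04 10:00:00", "2021-01-04 10:12:00")),
    list(c("C5", "CT_CHEST", "2021-01-04 10:00:00", "2021-01-04 09:00:00")),
    list(c("W1", "CT_WRIST", "2021-01-04 10:00:00", "2021-01-04 09:00:00"))
  ))
  samples <- compute_dictation_times(load_timestamps(path))
  tab <- pooled_counts(samples)
  expect_setequal(tab$region, c("head", "chest", "wrist", "All"))
  all_row <- tab[tab$region == "All", ]
  expect_equal(all_row$n_after_exclusion, 7)
  expect_equal(all_row$n_total, sum(tab$n_total[tab$region != "All"]))
  chest <- tab[tab$region == "chest", ]
  expect_equal(c(chest$n_total, chest$n_after_exclusion), c(5, 4))
  wrist <- tab[tab$region == "wrist", ]           # empty after exclusion
  expect_equal(c(wrist$n_total, wrist$n_after_exclusion), c(1, 0))
})

test_that("region mapping pools heterogeneous codes, unmatched -> other", {
  codes <- c("CT Skull native", "CT_STROKE_PERFUSION", "Thorax CTA",
             "CT ABDOMEN MULTIPHASE", "ct_lumbar_spine", "POLYTRAUMA WB",
             "MRI_KNEE")
  expect_equal(map_region(codes),
               c("head", "head", "chest", "abdomen", "lumbar_spine",
                 "polytrauma", "other"))
  expect_error(validate_region_map(data.frame(pattern = c("a", "a"),
                                              label = c("x", "y"))),
               "exactly one")
})

test_that("round-trip through CSV reproduces durations; translation invariant", {
  d <- generate_durations(generator_config(n = 60, seed = 11))
  tab <- to_timestamp_table(d, region = "chest")
  path <- tempfile(fileext = ".csv")
  write_timestamp_csv(tab, path)
  samples <- compute_dictation_times(load_timestamps(path))
  expect_equal(sort(samples[["chest"]]$durations), sort(d$durations),
               tolerance = 1e-7)

  shifted <- tab
  shifted$dictation_start <- shifted$dictation_start + 86400 * 30 + 3600
  shifted$first_save <- shifted$first_save + 86400 * 30 + 3600
  s2 <- compute_dictation_times(shifted)
  expect_equal(s2[["chest"]]$durations, samples[["chest"]]$durations,
               tolerance = 1e-7)
})

test_that("exclusion count is monotone when records are appended", {
  base <- list(
    c("E1", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 10:10:00"),
    c("E2", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 09:50:00")
  )
  extra <- list(
    c("E3", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 10:20:00"),
    c("E4", "CT_HEAD", "2021-01-04 10:00:00", "2021-01-04 09:40:00")
  )
  n_exc <- function(rows) {
    s <- compute_dictation_times(load_timestamps(write_ris_csv(rows)))
    attr(s, "n_excluded_total")
  }
  expect_gte(n_exc(c(base, extra)), n_exc(base))
})
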