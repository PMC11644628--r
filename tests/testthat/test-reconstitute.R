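# Discovery, window enumeration and reconstitution.

test_that("discover indexes only conforming folders", {
  spec <- light_spec(duration_h = 26)  # spans two dates
  spec$subjects <- list(c("S001", "DEVA"), c("S002", "DEVB"),
                        c("S003", "DEVC"))
  fx <- write_fixture(spec)
  pd <- file.path(fx$root, "participant_data")
  # stray folders at date and subject level must be ignored
  dir.create(file.path(pd, "notes"))
  writeLines("x", file.path(pd, "notes", "readme.txt"))
  dir.create(file.path(pd, "2024-01-28", "stray_no_dash_xyzqq"))
  idx <- discover(fx$root)
  groups <- unique(as.data.frame(idx)[c("id", "date")])
  expect_equal(nrow(groups), 6)  # 3 subjects x 2 dates
  expect_false(any(grepl("stray", idx$id)))

  # date_range filter restricts to one day
  idx1 <- discover(fx$root, date_range = c("2024-01-28", "2024-01-28"))
  expect_equal(unique(idx1$date), "2024-01-28")

  # nothing matching: empty index, not an error
  empty <- discover(tempdir())
  expect_s3_class(empty, "chunk_index")
  expect_equal(nrow(empty), 0)
  expect_error(discover(tempfile()), "unreadable root")
})

test_that("default windows are whole civil days, DST-aware", {
  spec <- light_spec(duration_h = 30, start = "2024-03-30 12:00:00",
                     tz = "Europe/Berlin")
  fx <- write_fixture(spec)
  idx <- discover(fx$root)
  cfg <- read_config(fx$root, timezone = "Europe/Berlin")
  w <- enumerate_windows(idx, cfg)
  expect_equal(nrow(w), 2)
  hours <- (w$end_us - w$start_us) / 3.6e9
  # 2024-03-31 is the 23-h spring-forward day in Berlin
  expect_equal(hours, c(24, 23))
})

test_that("custom windows overlap or skip forward per the overlap flag", {
  spec <- light_spec(duration_h = 26, start = "2024-01-28 09:00:00")
  fx <- write_fixture(spec)
  idx <- discover(fx$root)
  tz <- "Asia/Singapore"
  cfg <- read_config(fx$root, read_method = "custom", timezone = tz,
                     window = c("09:30", "10:30"), timespan_h = 24)
  w <- enumerate_windows(idx, cfg)
  expect_equal(nrow(w), 2)
  expect_equal((w$end_us - w$start_us) / 3.6e9, c(25, 25))
  # consecutive 25-h windows anchored a day apart overlap by 1 h
  expect_equal((w$end_us[1] - w$start_us[2]) / 3.6e9, 1)

  cfg2 <- read_config(fx$root, read_method = "custom", timezone = tz,
                      window = c("09:30", "10:30"), timespan_h = 24,
                      allow_overlap = FALSE)
  w2 <- enumerate_windows(idx, cfg2)
  # skip-forward: the second start advances to the first window's end
  expect_equal(w2$start_us[2], w2$end_us[1])
  expect_equal(w2$end_us[2], w$end_us[2])
  # pairwise intersections are empty
  expect_lte(w2$end_us[1], w2$start_us[2])
})

test_that("custom method without a window is a config error", {
  expect_error(read_config(read_method = "custom"), "window")
  spec <- light_spec(duration_h = 1)
  fx <- write_fixture(spec)
  idx <- discover(fx$root)
  cfg <- read_config(fx$root, read_method = "custom",
                     window = c("10:00", "09:00"))
  expect_error(enumerate_windows(idx, cfg), "before its start")
})

test_that("round trip recovers ground truth under every padding policy", {
  spec <- full_spec(duration_h = 2, gaps = list(c(3000, 450)),
                    tags = c(120, 600))
  fx <- write_fixture(spec)
  idx <- discover(fx$root)
  truth <- fx$recs[[1]]
  tz <- "Asia/Singapore"
  for (pol in list(c(FALSE, FALSE), c(TRUE, FALSE), c(TRUE, TRUE))) {
    cfg <- read_config(fx$root, timezone = tz,
                       read_method = "custom", window = c("08:00", "10:00"),
                       pad_discontinuities = pol[1], pad_to_max = pol[2])
    rec <- reconstitute(cfg, idx)[[1]]
    for (m in c("EDA", "BVP", "Temp", "ACC")) {
      tv <- wristflow:::value_matrix(truth$series[[m]])
      got <- finite_values(rec$dat[[m]])
      expect_identical(got, as.numeric(tv[stats::complete.cases(tv), ]),
                       info = paste(m, paste(pol, collapse = "/")))
      # missing accounting matches construction exactly
      n_gap <- sum(!stats::complete.cases(tv))
      expect_equal(rec$summary$pct_missing[rec$summary$modality == m],
                   100 * n_gap / nrow(tv), info = m)
    }
    expect_identical(rec$dat$SystP$times_ns, truth$peaks$times_ns)
    expect_equal(rec$tags$tag_time_us, truth$tags_us)
  }
  # padded-to-max series span the full window on the window grid
  cfg <- read_config(fx$root, timezone = tz, read_method = "custom",
                     window = c("07:00", "11:00"),
                     pad_discontinuities = TRUE, pad_to_max = TRUE)
  rec <- reconstitute(cfg, idx)[[1]]
  expect_equal(wristflow:::n_samples(rec$dat$EDA[[1]]), 4 * 3600 * 4)
  expect_equal(rec$dat$EDA[[1]]$start_us, rec$cfg$window_start_us)
})

test_that("gap policies agree with the worked 1-h/15-min example", {
  spec <- sim_spec(duration_h = 1, fs = c(EDA = 4),
                   gaps = list(c(1800, 900)), chunk_len_min = 15, seed = 8)
  fx <- write_fixture(spec)
  idx <- discover(fx$root)
  tz <- "Asia/Singapore"
  base <- list(read_method = "custom", window = c("08:00", "09:00"),
               timezone = tz, modalities = "EDA")
  cfg_pad <- do.call(read_config, c(list(fx$root), base,
                                    list(pad_discontinuities = TRUE)))
  rec <- reconstitute(cfg_pad, idx)[[1]]
  expect_length(rec$dat$EDA, 1)
  expect_equal(rec$summary$pct_missing, 25)
  expect_equal(sum(is.nan(rec$dat$EDA[[1]]$values)), 900 * 4)
  cfg_seg <- do.call(read_config, c(list(fx$root), base))
  rec2 <- reconstitute(cfg_seg, idx)[[1]]
  expect_length(rec2$dat$EDA, 2)
  expect_equal(sum(vapply(rec2$dat$EDA, wristflow:::n_samples, 0)),
               2700 * 4)
  expect_equal(rec2$summary$pct_missing, 25)
})

test_that("chunk enumeration order does not change the output", {
  spec <- light_spec(duration_h = 1.5)
  fx <- write_fixture(spec)
  idx <- discover(fx$root)
  cfg <- read_config(fx$root, timezone = "Asia/Singapore",
                     modalities = c("EDA", "Temp"))
  w <- enumerate_windows(idx, cfg)
  rec1 <- reconstitute_window(idx, w[1, ], cfg)
  set.seed(4)
  shuf <- idx[sample(nrow(idx)), ]
  attr(shuf, "records") <- attr(idx, "records")
  rec2 <- reconstitute_window(shuf, w[1, ], cfg)
  expect_identical(rec1$dat, rec2$dat)
})

test_that("avro and csv inputs reconstitute identically", {
  spec <- light_spec(duration_h = 1, tags = c(60, 300))
  fx_a <- write_fixture(spec, format = "avro")
  fx_c <- write_fixture(spec, format = "csv")
  for (fmt in c("avro", "csv")) {
    root <- if (fmt == "avro") fx_a$root else fx_c$root
    cfg <- read_config(root, input_format = fmt,
                       timezone = "Asia/Singapore",
                       modalities = c("EDA", "Temp", "SystP"))
    assign(paste0("rec_", fmt), reconstitute(cfg)[[1]])
  }
  for (m in c("EDA", "Temp")) {
    a <- finite_values(rec_avro$dat[[m]])
    b <- finite_values(rec_csv$dat[[m]])
    expect_equal(a, b, tolerance = 1e-9, info = m)
  }
  expect_equal(rec_avro$dat$SystP$times_ns, rec_csv$dat$SystP$times_ns)
})

test_that("a sampling-frequency change mid-window is a hard error", {
  spec <- light_spec(duration_h = 0.5)
  fx <- write_fixture(spec)
  # forge an extra chunk with a different EDA rate in the same folder
  dirs <- list.dirs(fx$root, recursive = TRUE)
  v6 <- dirs[grepl("raw_data/v6$", dirs)][1]
  bad <- chunk_record("S001", "3YK31141P6", list(
    EDA = list(start_us = local_to_us("2024-01-28 09:40:00",
                                      "Asia/Singapore"),
               fs = 8, values = wristflow:::float32(rnorm(100)))))
  write_avro_chunk(bad, file.path(v6, "1-1-S001_9999999999.avro"))
  idx <- discover(fx$root)
  cfg <- read_config(fx$root, timezone = "Asia/Singapore",
                     modalities = "EDA")
  w <- enumerate_windows(idx, cfg)
  expect_error(reconstitute_window(idx, w[1, ], cfg),
               "sampling frequency changes")
})

test_that("the 19-h worked example trims to a single complete series", {
  # 24-h session from 08:00; custom window 10:00 day 1 -> 05:00 day 2
  spec <- light_spec(duration_h = 24, start = "2024-01-28 08:00:00")
  fx <- write_fixture(spec)
  idx <- discover(fx$root)
  cfg <- read_config(fx$root, read_method = "custom",
                     timezone = "Asia/Singapore",
                     window = c("10:00", "05:00"), timespan_h = 24,
                     date_range = c("2024-01-28", "2024-01-28"),
                     modalities = c("EDA", "Temp"))
  w <- enumerate_windows(idx, cfg)
  expect_equal(nrow(w), 1)
  expect_equal((w$end_us - w$start_us) / 3.6e9, 19)
  rec <- reconstitute_window(idx, w[1, ], cfg)
  expect_length(rec$dat$EDA, 1)  # one continuous 19-h series
  expect_equal(wristflow:::n_samples(rec$dat$EDA[[1]]), 19 * 3600 * 4)
  expect_equal(rec$summary$pct_missing, c(0, 0))
})

test_that("duplicate chunk payloads resolve later-wins with a warning", {
  spec <- light_spec(duration_h = 0.5)
  fx <- write_fixture(spec)
  dirs <- list.dirs(fx$root, recursive = TRUE)
  v6 <- dirs[grepl("raw_data/v6$", dirs)][1]
  # duplicate the first chunk file under a new name
  f <- list.files(v6, full.names = TRUE)[1]
  file.copy(f, file.path(v6, "1-1-S001_duplicate.avro"))
  idx <- discover(fx$root)
  cfg <- read_config(fx$root, timezone = "Asia/Singapore",
                     modalities = "EDA")
  w <- enumerate_windows(idx, cfg)
  expect_warning(rec <- reconstitute_window(idx, w[1, ], cfg),
                 "later chunk wins")
  truth <- fx$recs[[1]]$series$EDA
  expect_identical(finite_values(rec$dat$EDA), truth$values)
})
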