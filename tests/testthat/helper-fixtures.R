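# Shared fixtures: small, fast simulated sessions written to temp trees.

# a short two-modality session (keeps most tests light)
light_spec <- function(duration_h = 1, gaps = list(), tags = numeric(0),
                       seed = 11, tz = "Asia/Singapore",
                       start = "2024-01-28 09:00:00", chunk_len_min = 15) {
  sim_spec(start = start, tz = tz, duration_h = duration_h,
           fs = c(EDA = 4, Temp = 1), chunk_len_min = chunk_len_min,
           gaps = gaps, tag_times_s = tags, seed = seed)
}

# full-rate session for pipeline tests
full_spec <- function(duration_h = 2, gaps = list(), tags = numeric(0),
                      seed = 5, tz = "Asia/Singapore",
                      start = "2024-01-28 08:00:00") {
  sim_spec(start = start, tz = tz, duration_h = duration_h, gaps = gaps,
           tag_times_s = tags, seed = seed)
}

write_fixture <- function(spec, format = "avro") {
  root <- tempfile("pdroot")
  recs <- simulate_dataset(spec)
  files <- write_dataset(recs, root, format = format)
  list(root = root, recs = recs, files = files)
}

# concatenate a (possibly segmented) modality into its finite samples,
# rows in time order, then channel-major (matching a ground-truth matrix)
finite_values <- function(dat_entry) {
  if (!length(dat_entry)) return(numeric(0))
  v <- do.call(rbind, lapply(dat_entry, wristflow:::value_matrix))
  as.numeric(v[stats::complete.cases(v), , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_series_equal <- function(got, truth, tol = 0) {
  g <- wristflow:::value_matrix(got)
  tr <- wristflow:::value_matrix(truth)
  expect_equal(dim(g), dim(tr))
  if (tol == 0) expect_identical(unname(g), unname(tr))
  else expect_lt(max(abs(g - tr), na.rm = TRUE), tol)
}
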