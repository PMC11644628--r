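# Avro and CSV chunk files: round trips, error contracts, dialect rules.

make_chunk <- function(n_eda = 240, peaks = TRUE, tags = TRUE, seed = 3) {
  set.seed(seed)
  start <- 1706425200 * 1e6
  acc <- wristflow:::quantize_acc(
    cbind(rnorm(n_eda * 16), rnorm(n_eda * 16), 1 + rnorm(n_eda * 16)))
  dimnames(acc) <- list(NULL, c("x", "y", "z"))
  chunk_record(
    "S001", "3YK31141P6",
    list(EDA = list(start_us = start, fs = 4,
                    values = wristflow:::float32(rnorm(n_eda, 2, 0.1))),
         BVP = list(start_us = start, fs = 64,
                    values = wristflow:::float32(rnorm(n_eda * 16))),
         Temp = list(start_us = start, fs = 1,
                     values = wristflow:::float32(33 + rnorm(n_eda %/% 4,
                                                             0, 0.01))),
         ACC = list(start_us = start, fs = 64, values = acc)),
    peaks_ns = if (peaks) (start + round(cumsum(runif(50, 0.8, 1.2)) *
                                           1e6)) * 1000 else numeric(0),
    tags_us = if (tags) start + c(10, 25, 40) * 1e6 else numeric(0))
}

expect_chunks_equal <- function(a, b, tol = 0) {
  expect_identical(a$subject_id, b$subject_id)
  expect_identical(a$device_sn, b$device_sn)
  expect_setequal(names(a$modalities), names(b$modalities))
  for (m in names(a$modalities)) {
    pa <- a$modalities[[m]]; pb <- b$modalities[[m]]
    expect_equal(pa$start_us, pb$start_us)
    expect_equal(pa$fs, pb$fs)
    if (tol == 0) expect_identical(unname(pa$values), unname(pb$values))
    else expect_lt(max(abs(unname(pa$values) - unname(pb$values))), tol)
  }
  expect_equal(a$peaks_ns, b$peaks_ns)
  expect_equal(a$tags_us, b$tags_us)
}

test_that("avro chunks round-trip bit-exactly", {
  rec <- make_chunk()
  f <- tempfile(fileext = ".avro")
  write_avro_chunk(rec, f)
  expect_chunks_equal(read_avro_chunk(f), rec)
})

test_that("a file with one modality yields a one-modality record", {
  rec <- chunk_record("S9", "DEV", list(
    EDA = list(start_us = 1e15, fs = 4,
               values = wristflow:::float32(rnorm(100)))))
  f <- tempfile(fileext = ".avro")
  write_avro_chunk(rec, f)
  got <- read_avro_chunk(f)
  expect_equal(names(got$modalities), "EDA")
  expect_length(got$peaks_ns, 0)
  expect_length(got$tags_us, 0)
})

test_that("non-avro and truncated files raise format errors, not partials", {
  f <- tempfile()
  writeBin(as.raw(1:64), f)
  expect_error(read_avro_chunk(f), "not an Avro container")
  g <- tempfile(fileext = ".avro")
  write_avro_chunk(make_chunk(), g)
  buf <- readBin(g, raw(), file.size(g))
  writeBin(buf[1:300], g)
  expect_error(read_avro_chunk(g), "truncated")
  expect_error(read_avro_chunk(tempfile()), "no such file")
})

test_that("payloads beyond the 30-min chunk ceiling are rejected", {
  expect_error(
    chunk_record("S1", "D", list(
      EDA = list(start_us = 0, fs = 4, values = numeric(31 * 60 * 4)))),
    "exceeds 30 min")
  # exactly 30 min is allowed
  expect_s3_class(
    chunk_record("S1", "D", list(
      EDA = list(start_us = 0, fs = 4, values = numeric(30 * 60 * 4)))),
    "chunk_record")
})

test_that("tag order is preserved through the avro container", {
  rec <- make_chunk()
  f <- tempfile(fileext = ".avro")
  write_avro_chunk(rec, f)
  expect_equal(read_avro_chunk(f)$tags_us, rec$tags_us)
})

test_that("csv chunks round-trip within float-text precision", {
  rec <- make_chunk()
  d <- tempfile()
  write_csv_chunks(rec, d)
  got <- read_csv_chunks(d)
  expect_length(got, 1)
  expect_chunks_equal(got[[1]], rec, tol = 1e-9)
})

test_that("an empty folder gives an empty chunk list", {
  d <- tempfile()
  dir.create(d)
  expect_identical(read_csv_chunks(d), list()) |> suppressWarnings()
})

test_that("unsorted csv rows are re-sorted with a warning", {
  rec <- chunk_record("S1", "D", list(
    EDA = list(start_us = 0, fs = 1, values = as.numeric(1:10))))
  d <- tempfile()
  write_csv_chunks(rec, d)
  f <- list.files(d, full.names = TRUE)
  df <- read.csv(f)
  set.seed(1)
  write.csv(df[sample(nrow(df)), ], f, row.names = FALSE)
  expect_warning(got <- read_csv_chunks(d), "re-sorted")
  expect_equal(got[[1]]$modalities$EDA$values, as.numeric(1:10))
  expect_equal(got[[1]]$modalities$EDA$start_us, 0)
})

test_that("a csv without a timestamp column is a dialect error", {
  d <- tempfile(); dir.create(d)
  writeLines(c("foo,value", "1,2"), file.path(d, "S1-D_0_EDA.csv"))
  expect_error(read_csv_chunks(d), "dialect error")
})

test_that("avro readers tolerate extra fields in the schema", {
  # hand-build a container whose record has one extra trailing field
  schema <- paste0(
    '{"type":"record","name":"P","fields":[',
    '{"name":"enrollment","type":{"type":"record","name":"E","fields":[',
    '{"name":"participantID","type":"string"},',
    '{"name":"deviceSn","type":"string"}]}},',
    '{"name":"rawData","type":{"type":"record","name":"R","fields":[',
    '{"name":"eda","type":["null",{"type":"record","name":"Eda","fields":[',
    '{"name":"timestampStart","type":"long"},',
    '{"name":"samplingFrequency","type":"float"},',
    '{"name":"values","type":{"type":"array","items":"float"}}]}]},',
    '{"name":"systolicPeaks","type":{"type":"record","name":"SP","fields":[',
    '{"name":"peaksTimeNanos","type":{"type":"array","items":"long"}}]}},',
    '{"name":"tags","type":{"type":"record","name":"T","fields":[',
    '{"name":"tagsTimeMicros","type":{"type":"array","items":"long"}}]}}]}},',
    '{"name":"extraField","type":"string"}]}')
  vals <- wristflow:::float32(c(1.5, 2.5, 3.25))
  body <- c(
    wristflow:::enc_string("S7"), wristflow:::enc_string("DX"),
    wristflow:::enc_varint_vec(1),          # eda branch: present
    wristflow:::enc_varint_vec(4e15),
    wristflow:::enc_float_vec(4),
    wristflow:::enc_prim_array(vals, "float"),
    wristflow:::enc_prim_array(numeric(0), "long"),
    wristflow:::enc_prim_array(numeric(0), "long"),
    wristflow:::enc_string("ignored payload"))
  f <- tempfile(fileext = ".avro")
  wristflow:::avro_write_container(f, schema, body)
  got <- read_avro_chunk(f)
  expect_identical(got$subject_id, "S7")
  expect_identical(got$modalities$EDA$values, vals)
})

test_that("missing identity fields raise a schema error", {
  schema <- paste0('{"type":"record","name":"P","fields":[',
                   '{"name":"whatever","type":"string"}]}')
  f <- tempfile(fileext = ".avro")
  wristflow:::avro_write_container(f, schema,
                                   wristflow:::enc_string("x"))
  expect_error(read_avro_chunk(f), "schema error")
})
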