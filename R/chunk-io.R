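# Reading and writing EmbracePlus-style raw-data chunk files.
#
# Field names mirror the device's published Avro schema for raw data
# (enrollment.participantID / deviceSn; rawData.eda/bvp/temperature with
# timestampStart [us], samplingFrequency [Hz], values; accelerometer as ADC
# counts with imuParams; systolicPeaks.peaksTimeNanos; tags.tagsTimeMicros).
# The reader is schema-driven, so files carrying additional fields decode
# fine and the extras are ignored.

DEFAULT_IMU_PARAMS <- list(physicalMin = -16L, physicalMax = 16L,
                           digitalMin = -32768L, digitalMax = 32767L)

adc_to_g <- function(adc, p = DEFAULT_IMU_PARAMS) {
  p$physicalMin + (adc - p$digitalMin) *
    (p$physicalMax - p$physicalMin) / (p$digitalMax - p$digitalMin)
}

g_to_adc <- function(g, p = DEFAULT_IMU_PARAMS) {
  adc <- round((g - p$physicalMin) / (p$physicalMax - p$physicalMin) *
                 (p$digitalMax - p$digitalMin) + p$digitalMin)
  pmin(pmax(adc, p$digitalMin), p$digitalMax)
}

# quantise accelerometry in g through the ADC round trip (what a written
# chunk will read back as)
quantize_acc <- function(g, p = DEFAULT_IMU_PARAMS) adc_to_g(g_to_adc(g, p), p)

#' One parsed raw-data chunk file
#'
#' @param subject_id participant identifier.
#' @param device_sn device serial number.
#' @param modalities named list; for `EDA`, `BVP`, `Temp`:
#'   `list(start_us, fs, values)`; for `ACC`: `values` is an N x 3 matrix in
#'   g. Absent modalities are simply omitted.
#' @param peaks_ns sorted systolic-peak times, nanoseconds since epoch.
#' @param tags_us sorted event-tag times, microseconds since epoch.
#' @param acc_params ADC-to-physical conversion parameters used for
#'   accelerometry payloads.
#' @return object of class `chunk_record`.
#' @export
chunk_record <- function(subject_id, device_sn, modalities = list(),
                         peaks_ns = numeric(0), tags_us = numeric(0),
                         acc_params = DEFAULT_IMU_PARAMS) {
  bad <- setdiff(names(modalities), MODALITIES)
  if (length(bad))
    stop("unknown modalities: ", paste(bad, collapse = ", "), call. = FALSE)
  for (m in names(modalities)) {
    p <- modalities[[m]]
    if (!is.numeric(p$fs) || p$fs <= 0)
      stop("chunk modality ", m, ": fs must be > 0", call. = FALSE)
    n <- if (is.matrix(p$values)) nrow(p$values) else length(p$values)
    if (n / p$fs > MAX_CHUNK_MIN * 60)
      stop("chunk modality ", m, ": payload exceeds ", MAX_CHUNK_MIN,
           " min (", round(n / p$fs), " s)", call. = FALSE)
    if (m == "ACC") {
      if (!is.matrix(p$values) || ncol(p$values) != 3L)
        stop("ACC payload must be an N x 3 matrix", call. = FALSE)
    }
  }
  if (is.unsorted(peaks_ns)) stop("peaks_ns must be sorted", call. = FALSE)
  if (is.unsorted(tags_us)) stop("tags_us must be sorted", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 device_sn = as.character(device_sn),
                 modalities = modalities,
                 peaks_ns = as.numeric(peaks_ns),
                 tags_us = as.numeric(tags_us),
                 acc_params = acc_params),
            class = "chunk_record")
}

#' @exportS3Method base::print
print.chunk_record <- function(x, ...) {
  cat(sprintf("<chunk_record> %s-%s\n", x$subject_id, x$device_sn))
  for (m in names(x$modalities)) {
    p <- x$modalities[[m]]
    n <- if (is.matrix(p$values)) nrow(p$values) else length(p$values)
    cat(sprintf("  %s: %d sample(s) @ %g Hz from %.0f us\n",
                m, n, p$fs, p$start_us))
  }
  cat(sprintf("  peaks: %d  tags: %d\n", length(x$peaks_ns),
              length(x$tags_us)))
  invisible(x)
}

chunk_schema_json <- function() {
  sig <- function(name) sprintf(paste0(
    '{"type":"record","name":"%s","fields":[',
    '{"name":"timestampStart","type":"long"},',
    '{"name":"samplingFrequency","type":"float"},',
    '{"name":"values","type":{"type":"array","items":"float"}}]}'), name)
  paste0(
    '{"type":"record","name":"EmpaticaPayload","fields":[',
    '{"name":"enrollment","type":{"type":"record","name":"Enrollment",',
    '"fields":[{"name":"participantID","type":"string"},',
    '{"name":"deviceSn","type":"string"}]}},',
    '{"name":"rawData","type":{"type":"record","name":"RawData","fields":[',
    '{"name":"eda","type":["null",', sig("Eda"), '],"default":null},',
    '{"name":"bvp","type":["null",', sig("Bvp"), '],"default":null},',
    '{"name":"temperature","type":["null",', sig("Temperature"),
    '],"default":null},',
    '{"name":"accelerometer","type":["null",',
    '{"type":"record","name":"Accelerometer","fields":[',
    '{"name":"timestampStart","type":"long"},',
    '{"name":"samplingFrequency","type":"float"},',
    '{"name":"imuParams","type":{"type":"record","name":"ImuParams",',
    '"fields":[{"name":"physicalMin","type":"int"},',
    '{"name":"physicalMax","type":"int"},',
    '{"name":"digitalMin","type":"int"},',
    '{"name":"digitalMax","type":"int"}]}},',
    '{"name":"x","type":{"type":"array","items":"int"}},',
    '{"name":"y","type":{"type":"array","items":"int"}},',
    '{"name":"z","type":{"type":"array","items":"int"}}]}],"default":null},',
    '{"name":"systolicPeaks","type":{"type":"record","name":"SystolicPeaks",',
    '"fields":[{"name":"peaksTimeNanos",',
    '"type":{"type":"array","items":"long"}}]}},',
    '{"name":"tags","type":{"type":"record","name":"Tags",',
    '"fields":[{"name":"tagsTimeMicros",',
    '"type":{"type":"array","items":"long"}}]}}]}}]}')
}

#' Write a chunk record as an Avro container file
#'
#' Signal values are stored as 32-bit floats and accelerometry as ADC counts
#' (converted back to g on read), matching the device convention; payloads
#' longer than 30 min are rejected.
#'
#' @param rec a [chunk_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_avro_chunk <- function(rec, path) {
  stopifnot(inherits(rec, "chunk_record"))
  # re-validate invariants (records may have been edited after construction)
  rec <- chunk_record(rec$subject_id, rec$device_sn, rec$modalities,
                      rec$peaks_ns, rec$tags_us, rec$acc_params)
  enc_sig <- function(p) c(enc_varint_vec(p$start_us),
                           enc_float_vec(p$fs),
                           enc_prim_array(p$values, "float"))
  opt <- function(m, f) {
    p <- rec$modalities[[m]]
    if (is.null(p)) enc_varint_vec(0) else c(enc_varint_vec(1), f(p))
  }
  ip <- rec$acc_params
  enc_acc <- function(p) c(
    enc_varint_vec(p$start_us), enc_float_vec(p$fs),
    enc_varint_vec(ip$physicalMin), enc_varint_vec(ip$physicalMax),
    enc_varint_vec(ip$digitalMin), enc_varint_vec(ip$digitalMax),
    enc_prim_array(g_to_adc(p$values[, 1], ip), "int"),
    enc_prim_array(g_to_adc(p$values[, 2], ip), "int"),
    enc_prim_array(g_to_adc(p$values[, 3], ip), "int"))
  body <- c(
    enc_string(rec$subject_id), enc_string(rec$device_sn),
    opt("EDA", enc_sig), opt("BVP", enc_sig), opt("Temp", enc_sig),
    opt("ACC", enc_acc),
    enc_prim_array(rec$peaks_ns, "long"),
    enc_prim_array(rec$tags_us, "long"))
  avro_write_container(path, chunk_schema_json(), body)
}

#' Read one Avro chunk file
#'
#' @param path path to an Avro object-container file in the device raw-data
#'   layout.
#' @return a [chunk_record()]; accelerometry is converted from ADC counts to
#'   g using the file's `imuParams`.
#' @export
read_avro_chunk <- function(path) {
  parsed <- avro_read_container(path)
  if (!length(parsed$objects))
    stop("Avro container holds no records: ", path, call. = FALSE)
  obj <- parsed$objects[[1L]]
  enr <- obj$enrollment
  if (is.null(enr$participantID) || is.null(enr$deviceSn))
    stop("Avro schema error: missing identity fields (enrollment) in ",
         path, call. = FALSE)
  rd <- obj$rawData
  mods <- list()
  put_sig <- function(mods, name, p) {
    if (!is.null(p))
      mods[[name]] <- list(start_us = p$timestampStart,
                           fs = p$samplingFrequency,
                           values = as.numeric(p$values))
    mods
  }
  mods <- put_sig(mods, "EDA", rd$eda)
  mods <- put_sig(mods, "BVP", rd$bvp)
  mods <- put_sig(mods, "Temp", rd$temperature)
  acc_params <- DEFAULT_IMU_PARAMS
  if (!is.null(rd$accelerometer)) {
    a <- rd$accelerometer
    acc_params <- a$imuParams %||% DEFAULT_IMU_PARAMS
    mods[["ACC"]] <- list(
      start_us = a$timestampStart, fs = a$samplingFrequency,
      values = cbind(x = adc_to_g(as.numeric(a$x), acc_params),
                     y = adc_to_g(as.numeric(a$y), acc_params),
                     z = adc_to_g(as.numeric(a$z), acc_params)))
  }
  chunk_record(enr$participantID, enr$deviceSn, mods,
               as.numeric(rd$systolicPeaks$peaksTimeNanos %||% numeric(0)),
               as.numeric(rd$tags$tagsTimeMicros %||% numeric(0)),
               acc_params)
}

# ---- CSV dialect ------------------------------------------------------------
# One file per modality per chunk, named <subject>-<device>_<startus>_<MOD>.csv
# (the direct Avro-to-CSV conversion layout: column 1 = Unix timestamp,
# remaining columns = values; peaks and tags as single-column files).

csv_stem <- function(rec) {
  starts <- vapply(rec$modalities, function(p) p$start_us, 0)
  t0 <- suppressWarnings(min(c(starts, rec$tags_us,
                               rec$peaks_ns / 1000), na.rm = TRUE))
  sprintf("%s-%s_%.0f", rec$subject_id, rec$device_sn, t0)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_csv_file <- function(path, header, cols) {
  lines <- c(paste(header, collapse = ","),
             if (length(cols[[1]]))
               do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
}

#' Write a chunk record as per-modality CSV files
#'
#' @param rec a [chunk_record()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_csv_chunks <- function(rec, dir) {
  stopifnot(inherits(rec, "chunk_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, csv_stem(rec))
  for (m in names(rec$modalities)) {
    p <- rec$modalities[[m]]
    n <- if (is.matrix(p$values)) nrow(p$values) else length(p$values)
    ts <- sprintf("%.0f", p$start_us + round((seq_len(n) - 1) * US / p$fs))
    if (m == "ACC") {
      write_csv_file(paste0(stem, "_ACC.csv"),
                     c("unix_timestamp_us", "x", "y", "z"),
                     list(ts, fmt_num(p$values[, 1]), fmt_num(p$values[, 2]),
                          fmt_num(p$values[, 3])))
    } else {
      write_csv_file(paste0(stem, "_", m, ".csv"),
                     c("unix_timestamp_us", "value"),
                     list(ts, fmt_num(p$values)))
    }
  }
  if (length(rec$peaks_ns))
    write_csv_file(paste0(stem, "_SystP.csv"), "unix_timestamp_ns",
                   list(sprintf("%.0f", rec$peaks_ns)))
  if (length(rec$tags_us))
    write_csv_file(paste0(stem, "_Tags.csv"), "unix_timestamp_us",
                   list(sprintf("%.0f", rec$tags_us)))
  invisible(dir)
}

infer_fs <- function(ts) {
  if (length(ts) < 2L) {
    warning("single-sample CSV chunk: assuming 1 Hz")
    return(1)
  }
  d <- stats::median(diff(ts))
  fs <- US / d
  if (abs(fs - round(fs)) < 1e-6) fs <- round(fs)
  fs
}

#' Read all CSV chunk files in a folder
#'
#' Files are grouped into chunks by their `<subject>-<device>_<start>` stem.
#' Rows with out-of-order timestamps are re-sorted with a warning.
#'
#' @param dir folder holding the per-modality CSV files.
#' @return list of [chunk_record()] (empty list if the folder has no CSVs).
#' @export
read_csv_chunks <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) return(list())
  base <- sub("\\.csv$", "", basename(files))
  mod <- sub(".*_", "", base)
  stem <- sub("_[^_]*$", "", base)
  out <- list()
  for (s in unique(stem)) {
    grp <- files[stem == s]
    gmod <- mod[stem == s]
    id <- sub("_[0-9]+$", "", s)
    subject <- sub("-[^-]*$", "", id)
    device <- sub(".*-", "", id)
    mods <- list()
    peaks <- numeric(0)
    tags <- numeric(0)
    for (i in seq_along(grp)) {
      df <- utils::read.csv(grp[i], colClasses = "numeric")
      if (!grepl("^unix_timestamp", names(df)[1]))
        stop("CSV dialect error: missing timestamp column in ", grp[i],
             call. = FALSE)
      if (gmod[i] == "SystP") { peaks <- sort(df[[1]]); next }
      if (gmod[i] == "Tags") { tags <- sort(df[[1]]); next }
      if (nrow(df) && is.unsorted(df[[1]])) {
        warning("unsorted timestamps in ", grp[i], "; rows re-sorted")
        df <- df[order(df[[1]]), , drop = FALSE]
      }
      if (!nrow(df)) next
      vals <- if (gmod[i] == "ACC") as.matrix(df[, c("x", "y", "z")])
              else df[[2]]
      if (is.matrix(vals)) dimnames(vals) <- list(NULL, c("x", "y", "z"))
      mods[[gmod[i]]] <- list(start_us = df[[1]][1], fs = infer_fs(df[[1]]),
                              values = vals)
    }
    out[[length(out) + 1L]] <- chunk_record(subject, device, mods, peaks, tags)
  }
  out
}
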