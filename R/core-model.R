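#' wristflow: reconstitution and preprocessing of chunked wristband data
#'
#' EmbracePlus-style wearables store raw signals as short (at most 30 min)
#' chunk files timestamped in universal standard time. This package pieces
#' those chunks back together into unified per-modality timeseries over
#' user-chosen windows, and provides tag editing, preprocessing, epoching and
#' MAT/XLSX export. A synthetic device generator makes the whole pipeline
#' testable without hardware.
#'
#' All internal times are microseconds since the Unix epoch (UTC), held as
#' R doubles (exact for integers up to 2^53); systolic-peak events are
#' nanoseconds since the epoch. Local civil time is a projection applied at
#' display/export, never the primary key. Windows are half-open
#' `[start, end)` everywhere: a sample, peak or tag at exactly `end` is
#' excluded, which prevents double counting at seams between windows.
#'
#' @name wristflow-package
"_PACKAGE"

MODALITIES <- c("EDA", "BVP", "Temp", "ACC")
MAX_CHUNK_MIN <- 30  # device chunk files hold at most 30 min of signal

US <- 1e6  # microseconds per second

#' Uniform-grid signal series
#'
#' One reconstituted (or simulated) modality on a uniform sampling grid.
#' Sample `i` (0-based) has nominal time `start_us + round(i * 1e6 / fs)`
#' microseconds since the Unix epoch; no per-sample timestamps are stored.
#' Missing samples are `NaN`.
#'
#' @param modality one of `"EDA"`, `"BVP"`, `"Temp"`, `"ACC"`.
#' @param start_us start time, integer-valued microseconds since epoch (UTC).
#' @param fs sampling frequency in Hz, `> 0`.
#' @param values numeric vector, or an N x 3 matrix (columns x, y, z) for
#'   accelerometry. `NaN` marks missing samples.
#' @return an object of class `uniform_series`.
#' @export
uniform_series <- function(modality, start_us, fs, values) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("invalid series: fs must be a single positive number", call. = FALSE)
  if (is.matrix(values)) {
    if (ncol(values) != 3L)
      stop("multi-channel series must have exactly 3 columns (x, y, z)",
           call. = FALSE)
  } else {
    values <- as.numeric(values)
  }
  structure(
    list(modality = as.character(modality), start_us = as.numeric(start_us),
         fs = as.numeric(fs), values = values),
    class = "uniform_series")
}

n_samples <- function(x) if (is.matrix(x$values)) nrow(x$values) else length(x$values)

n_channels <- function(x) if (is.matrix(x$values)) ncol(x$values) else 1L

#' Nominal sample times of a uniform series
#'
#' @param x a [uniform_series()].
#' @return numeric vector of microseconds since epoch, one per sample.
#' @export
series_times_us <- function(x) {
  n <- n_samples(x)
  if (n == 0L) return(numeric(0))
  x$start_us + round((seq_len(n) - 1) * US / x$fs)
}

# values as a matrix view (N x channels), for channel-generic internals
value_matrix <- function(x) {
  if (is.matrix(x$values)) x$values else matrix(x$values, ncol = 1L)
}

set_values <- function(x, m) {
  x$values <- if (is.matrix(x$values)) m else as.numeric(m[, 1L])
  x
}

#' @exportS3Method base::print
print.uniform_series <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf("<uniform_series> %s: %d sample%s x %d channel(s) @ %g Hz\n",
              x$modality, n, if (n == 1) "" else "s", n_channels(x), x$fs))
  if (n > 0) {
    cat(sprintf("  start: %s (%.0f us)\n",
                to_local(x$start_us, "UTC"), x$start_us))
    cat(sprintf("  missing: %d sample(s)\n",
                sum(!stats::complete.cases(value_matrix(x)))))
  }
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.uniform_series <- function(x, ..., max_points = 20000L) {
  t <- (series_times_us(x) - x$start_us) / US
  v <- value_matrix(x)
  idx <- if (length(t) > max_points)
    unique(round(seq(1L, length(t), length.out = max_points))) else seq_along(t)
  graphics::matplot(t[idx], v[idx, , drop = FALSE], type = "l", lty = 1,
                    xlab = "time since start [s]", ylab = x$modality, ...)
  invisible(x)
}

#' Event (non-uniform) series of systolic-peak times
#'
#' @param times_ns sorted numeric vector of nanoseconds since epoch.
#' @param modality event-series name; the device emits `"SystP"`.
#' @return an object of class `event_series`.
#' @export
event_series <- function(times_ns = numeric(0), modality = "SystP") {
  times_ns <- as.numeric(times_ns)
  if (is.unsorted(times_ns)) times_ns <- sort(times_ns)
  structure(list(modality = modality, times_ns = times_ns),
            class = "event_series")
}

#' @exportS3Method base::print
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s: %d event(s)\n", x$modality,
              length(x$times_ns)))
  invisible(x)
}

#' Read configuration
#'
#' Settings controlling discovery, window enumeration and reconstitution.
#' The `default` method reads each subject's data one local civil day at a
#' time; the `custom` method reads a wall-clock window (optionally extended
#' by `timespan_h` hours beyond the end time, so that a window may span more
#' than 24 h).
#'
#' @param parent_folder path to the `participant_data` root.
#' @param input_format `"avro"` or `"csv"`.
#' @param modalities character vector of requested signals, from
#'   `c("EDA","BVP","Temp","ACC","SystP")`.
#' @param read_method `"default"` (whole civil days) or `"custom"`.
#' @param timezone IANA zone name used for civil-time windows and display.
#' @param window for the custom method, `c(start, end)` wall times
#'   (`"HH:MM"` or `"HH:MM:SS"`).
#' @param timespan_h extra hours appended to the window end (custom method).
#' @param date_range optional `c(first, last)` ISO dates restricting input.
#' @param allow_overlap allow consecutive custom windows to overlap; when
#'   `FALSE`, a window whose start falls inside the previous window is
#'   advanced to the previous window's end.
#' @param pad_discontinuities fill within-window gaps with `NaN` so each
#'   modality is one continuous series.
#' @param pad_to_max `NaN`-extend each series to the full window length.
#' @return an object of class `read_config`.
#' @export
read_config <- function(parent_folder = ".",
                        input_format = c("avro", "csv"),
                        modalities = c("EDA", "BVP", "Temp", "ACC", "SystP"),
                        read_method = c("default", "custom"),
                        timezone = "UTC",
                        window = NULL,
                        timespan_h = 0,
                        date_range = NULL,
                        allow_overlap = TRUE,
                        pad_discontinuities = FALSE,
                        pad_to_max = FALSE) {
  input_format <- match.arg(input_format)
  read_method <- match.arg(read_method)
  if (!timezone %in% OlsonNames())
    stop("unknown time zone: ", timezone, call. = FALSE)
  if (read_method == "custom" && (is.null(window) || length(window) != 2L))
    stop("custom read method requires window = c(start, end)", call. = FALSE)
  if (read_method == "default") { window <- NULL; timespan_h <- 0 }
  if (timespan_h < 0) stop("timespan_h must be >= 0", call. = FALSE)
  structure(
    list(parent_folder = parent_folder, input_format = input_format,
         modalities = modalities, read_method = read_method,
         timezone = timezone, window = window,
         timespan_h = as.numeric(timespan_h), date_range = date_range,
         allow_overlap = isTRUE(allow_overlap),
         pad_discontinuities = isTRUE(pad_discontinuities),
         pad_to_max = isTRUE(pad_to_max),
         toolkit = "wristflow",
         version = tryCatch(
           as.character(utils::packageVersion("wristflow")),
           error = function(e) "dev"),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "read_config")
}

#' @exportS3Method base::print
print.read_config <- function(x, ...) {
  cat("<read_config>\n")
  cat(sprintf("  parent folder: %s\n  format: %s  method: %s  zone: %s\n",
              x$parent_folder, x$input_format, x$read_method, x$timezone))
  if (!is.null(x$window))
    cat(sprintf("  window: %s - %s (+%g h)\n", x$window[1], x$window[2],
                x$timespan_h))
  cat(sprintf("  modalities: %s\n", paste(x$modalities, collapse = ", ")))
  cat(sprintf("  overlap: %s  pad gaps: %s  pad to max: %s\n",
              x$allow_overlap, x$pad_discontinuities, x$pad_to_max))
  invisible(x)
}

#' Missing-data summary
#'
#' Percent missing is counted on the window's nominal sampling grid: the
#' expected number of points over a half-open window `[start, end)` at `fs`
#' Hz is `floor((end - start) * fs / 1e6)`, and any expected point without a
#' finite sample counts as missing. The result is invariant to whether
#' missingness is realised as absent chunks or as explicit `NaN` padding.
#'
#' @param series a [uniform_series()] (one continuous segment) or a list of
#'   segments of the same modality.
#' @param window numeric `c(start_us, end_us)`, half-open.
#' @return one-row data.frame: `modality`, `total_duration_s`,
#'   `total_points`, `pct_missing`.
#' @export
summarize_missing <- function(series, window) {
  segs <- if (inherits(series, "uniform_series")) list(series) else series
  stopifnot(length(window) == 2L, window[2] > window[1])
  fs <- if (length(segs)) segs[[1L]]$fs else NA_real_
  modality <- if (length(segs)) segs[[1L]]$modality else NA_character_
  if (length(segs) && (!is.finite(fs) || fs <= 0))
    stop("invalid series: fs must be positive", call. = FALSE)
  expected <- if (length(segs)) floor((window[2] - window[1]) * fs / US) else 0
  finite <- 0
  for (s in segs) {
    t <- series_times_us(s)
    keep <- t >= window[1] & t < window[2]
    finite <- finite + sum(stats::complete.cases(value_matrix(s)) & keep)
  }
  missing <- max(expected - finite, 0)
  data.frame(
    modality = modality,
    total_duration_s = if (expected > 0) expected / fs else 0,
    total_points = expected,
    pct_missing = if (expected > 0) 100 * missing / expected else 100,
    stringsAsFactors = FALSE)
}

#' Event-tag table
#'
#' Ordered event markers. `chunk_ts_us` is the timestamp of the chunk file
#' that contained the tag (0 for user-added tags, which have no source
#' file); `tag_time_us` is the tag time in microseconds since epoch. Local
#' date and wall time (to the nearest ms) are projections in the selected
#' zone. `pending` holds `""`, `"add"` or `"delete"` for edits not yet
#' applied with [apply_edits()].
#'
#' @param tag_time_us numeric vector of tag times (microseconds since epoch).
#' @param chunk_ts_us source-chunk timestamps, recycled; 0 = user-added.
#' @param zone IANA zone for the local-time projection.
#' @param annotation free-text annotations, recycled.
#' @return a data.frame of class `tag_table`.
#' @export
tag_table <- function(tag_time_us = numeric(0), chunk_ts_us = 0,
                      zone = "UTC", annotation = "") {
  n <- length(tag_time_us)
  tag_time_us <- round(as.numeric(tag_time_us) / 1000) * 1000  # ms precision
  df <- data.frame(
    label = if (n) sprintf("Tag %d", seq_len(n)) else character(0),
    chunk_ts_us = rep_len(as.numeric(chunk_ts_us), n),
    tag_time_us = tag_time_us,
    local_date = local_date_str(tag_time_us, zone),
    local_time_ms = local_walltime_str(tag_time_us, zone),
    annotation = rep_len(as.character(annotation), n),
    pending = rep_len("", n),
    stringsAsFactors = FALSE)
  attr(df, "zone") <- zone
  class(df) <- c("tag_table", "data.frame")
  df
}

#' @exportS3Method base::print
print.tag_table <- function(x, ...) {
  cat(sprintf("<tag_table> %d tag(s), zone %s\n", nrow(x), attr(x, "zone")))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' A reconstituted recording
#'
#' Couples the read settings (`cfg`) with the reconstituted data (`dat`):
#' per-modality series (one entry per continuous segment unless gaps were
#' padded), systolic-peak events, the event-tag table, and the missing-data
#' summary. A deep snapshot of the tags as first loaded backs
#' [reset_tags()].
#'
#' @param cfg a [read_config()], augmented with subject/device/window fields.
#' @param dat named list: for each uniform modality a list of
#'   `uniform_series` segments; `"SystP"` an [event_series()].
#' @param tags a [tag_table()].
#' @param summary missing-data summary data.frame (see
#'   [summarize_missing()]).
#' @return an object of class `recording`.
#' @export
recording <- function(cfg, dat, tags, summary) {
  structure(list(cfg = cfg, dat = dat, tags = tags, summary = summary,
                 tags_original = tags),
            class = "recording")
}

#' @exportS3Method base::print
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s-%s\n", x$cfg$subject, x$cfg$device))
  cat(sprintf("  window: %s -> %s (%s)\n",
              to_local(x$cfg$window_start_us, x$cfg$timezone),
              to_local(x$cfg$window_end_us, x$cfg$timezone),
              x$cfg$timezone))
  for (m in names(x$dat)) {
    d <- x$dat[[m]]
    if (inherits(d, "event_series")) {
      cat(sprintf("  %s: %d event(s)\n", m, length(d$times_ns)))
    } else {
      ns <- vapply(d, n_samples, 0)
      cat(sprintf("  %s: %d segment(s), %d sample(s) @ %g Hz\n",
                  m, length(d), sum(ns), if (length(d)) d[[1]]$fs else NA))
    }
  }
  cat(sprintf("  tags: %d\n", nrow(x$tags)))
  if (nrow(x$summary)) {
    cat("  missing-data summary:\n")
    print.data.frame(x$summary, row.names = FALSE)
  }
  invisible(x)
}

# ---- civil-time helpers -----------------------------------------------------

#' Convert epoch microseconds to local civil time
#'
#' @param t_us numeric vector, microseconds since Unix epoch (UTC).
#' @param zone IANA zone name.
#' @return ISO-8601 strings with millisecond precision and UTC offset, e.g.
#'   `"1970-01-01T07:30:00.000+07:30"`.
#' @export
to_local <- function(t_us, zone) {
  if (!zone %in% OlsonNames())
    stop("unknown time zone: ", zone, call. = FALSE)
  if (!length(t_us)) return(character(0))
  # round to ms first so formatting cannot truncate x.9995 down
  ms <- round(as.numeric(t_us) / 1000)
  tt <- as.POSIXct(ms / 1e3, origin = "1970-01-01", tz = zone)
  base <- format(tt, "%Y-%m-%dT%H:%M:%S", tz = zone)
  frac <- sprintf(".%03.0f", ms %% 1000)
  off <- format(tt, "%z", tz = zone)
  sprintf("%s%s%s:%s", base, frac, substr(off, 1, 3), substr(off, 4, 5))
}

local_date_str <- function(t_us, zone) {
  if (!length(t_us)) return(character(0))
  format(as.POSIXct(as.numeric(t_us) / US, origin = "1970-01-01", tz = zone),
         "%Y-%m-%d", tz = zone)
}

local_walltime_str <- function(t_us, zone) {
  if (!length(t_us)) return(character(0))
  ms <- round(as.numeric(t_us) / 1000)
  tt <- as.POSIXct(ms / 1e3, origin = "1970-01-01", tz = zone)
  sprintf("%s.%03.0f", format(tt, "%H:%M:%S", tz = zone), ms %% 1000)
}

#' Convert a local civil time to epoch microseconds
#'
#' @param when `"YYYY-MM-DD HH:MM:SS"` (fractional seconds allowed) or a
#'   POSIXct.
#' @param zone IANA zone name.
#' @return microseconds since epoch (double).
#' @export
local_to_us <- function(when, zone) {
  if (!zone %in% OlsonNames())
    stop("unknown time zone: ", zone, call. = FALSE)
  if (inherits(when, "POSIXct")) return(round(as.numeric(when) * US))
  tt <- as.POSIXct(when, tz = zone,
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (any(is.na(tt))) stop("unparseable local time: ", when, call. = FALSE)
  round(as.numeric(tt) * US)
}
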