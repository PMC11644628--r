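# Serialisation of recordings and epochs. Each MAT file carries two
# top-level structures, cfg (read settings/metadata) and dat (one cell of
# continuous-segment tables per modality, plus the event-tag table and the
# missing-data summary). Timeseries tables have columns for universal
# standard time (numeric microseconds), local time in the configured zone
# (ISO-8601 strings with offset), and the raw value column(s).

series_table <- function(s, zone) {
  t_us <- series_times_us(s)
  v <- value_matrix(s)
  df <- data.frame(unix_time_us = t_us,
                   local_time = to_local(t_us, zone),
                   stringsAsFactors = FALSE)
  if (ncol(v) == 3L) { df$x <- v[, 1]; df$y <- v[, 2]; df$z <- v[, 3] }
  else df$value <- v[, 1]
  df
}

cfg_to_list <- function(cfg) {
  list(parent_folder = cfg$parent_folder %||% "",
       input_format = cfg$input_format, read_method = cfg$read_method,
       modalities = as.list(cfg$modalities),
       timezone = cfg$timezone,
       window = as.list(cfg$window %||% character(0)),
       timespan_h = cfg$timespan_h %||% 0,
       date_range = as.list(cfg$date_range %||% character(0)),
       allow_overlap = as.numeric(cfg$allow_overlap),
       pad_discontinuities = as.numeric(cfg$pad_discontinuities),
       pad_to_max = as.numeric(cfg$pad_to_max),
       toolkit = cfg$toolkit %||% "wristflow",
       version = cfg$version %||% "dev",
       created = cfg$created %||% "",
       subject = cfg$subject %||% "", device = cfg$device %||% "",
       window_start_us = cfg$window_start_us %||% NaN,
       window_end_us = cfg$window_end_us %||% NaN)
}

cfg_from_list <- function(l) {
  cfg <- list(parent_folder = l$parent_folder,
              input_format = l$input_format,
              modalities = unlist(l$modalities) %||% character(0),
              read_method = l$read_method, timezone = l$timezone,
              window = if (length(l$window)) unlist(l$window) else NULL,
              timespan_h = l$timespan_h,
              date_range = if (length(l$date_range)) unlist(l$date_range)
                           else NULL,
              allow_overlap = l$allow_overlap != 0,
              pad_discontinuities = l$pad_discontinuities != 0,
              pad_to_max = l$pad_to_max != 0,
              toolkit = l$toolkit, version = l$version, created = l$created,
              subject = l$subject, device = l$device,
              window_start_us = l$window_start_us,
              window_end_us = l$window_end_us)
  class(cfg) <- "read_config"
  cfg
}

tags_to_list <- function(tags) {
  list(label = tags$label, chunk_ts_us = tags$chunk_ts_us,
       tag_time_us = tags$tag_time_us, local_date = tags$local_date,
       local_time_ms = tags$local_time_ms, annotation = tags$annotation,
       pending = tags$pending)
}

tags_from_list <- function(l, zone) {
  as_chr <- function(x, n) {
    x <- if (is.null(x) || identical(x, "")) character(0) else x
    rep_len(as.character(x), n)
  }
  n <- length(l$tag_time_us)
  df <- data.frame(label = as_chr(l$label, n),
                   chunk_ts_us = as.numeric(l$chunk_ts_us),
                   tag_time_us = as.numeric(l$tag_time_us),
                   local_date = as_chr(l$local_date, n),
                   local_time_ms = as_chr(l$local_time_ms, n),
                   annotation = as_chr(l$annotation, n),
                   pending = as_chr(l$pending, n),
                   stringsAsFactors = FALSE)
  df$annotation[is.na(df$annotation)] <- ""
  df$pending[is.na(df$pending)] <- ""
  attr(df, "zone") <- zone
  class(df) <- c("tag_table", "data.frame")
  df
}

#' Save a recording (or epochs) as a MAT-file
#'
#' The file holds `cfg` and `dat` structures; `dat` has one cell per
#' continuous segment per modality (tables of universal time, local time
#' and values), the event-tag table, and the missing-data summary.
#' `load_mat(save_mat(x))` reproduces the recording.
#'
#' @param x a [recording()] or a list of epochs from [epoch_data()].
#' @param path output path; defaults to
#'   `<subject>-<device>_<local start date>.mat` in the working directory.
#' @param overwrite allow replacing an existing file.
#' @param refresh_snapshot when saving with edited tags, also move the
#'   recording's reset snapshot forward to the saved state (the state
#'   [reset_tags()] will restore).
#' @return the saved recording (snapshot possibly refreshed), invisibly;
#'   for epochs, `path`.
#' @export
save_mat <- function(x, path = NULL, overwrite = FALSE,
                     refresh_snapshot = FALSE) {
  if (inherits(x, "recording")) {
    path <- path %||% paste0(recording_stem(x), ".mat")
    if (file.exists(path) && !overwrite)
      stop("refusing to overwrite ", path, " (set overwrite = TRUE)",
           call. = FALSE)
    zone <- x$cfg$timezone
    dat <- list()
    for (m in names(x$dat)) {
      d <- x$dat[[m]]
      if (inherits(d, "event_series")) {
        dat[[m]] <- list(modality = d$modality, times_ns = d$times_ns)
      } else {
        dat[[m]] <- lapply(d, function(s)
          c(list(modality = s$modality, start_us = s$start_us, fs = s$fs),
            lapply(series_table(s, zone), identity)))
      }
    }
    dat$tags <- tags_to_list(x$tags)
    dat$summary <- list(modality = x$summary$modality,
                        total_duration_s = x$summary$total_duration_s,
                        total_points = x$summary$total_points,
                        pct_missing = x$summary$pct_missing)
    mat_write(list(cfg = cfg_to_list(x$cfg), dat = dat), path)
    if (refresh_snapshot) x$tags_original <- x$tags
    return(invisible(x))
  }
  # epochs
  stopifnot(is.list(x), length(x) > 0L, inherits(x[[1]], "epoch"))
  path <- path %||% "epochs.mat"
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite ", path, " (set overwrite = TRUE)",
         call. = FALSE)
  eps <- lapply(x, function(ep) {
    dat <- list()
    for (m in names(ep$dat)) {
      d <- ep$dat[[m]]
      dat[[m]] <- if (inherits(d, "event_series"))
        list(modality = d$modality, times_ns = d$times_ns)
      else lapply(d, function(s)
        c(list(modality = s$modality, start_us = s$start_us, fs = s$fs),
          lapply(series_table(s, ep$zone), identity)))
    }
    list(label = ep$label, start_us = ep$start_us, end_us = ep$end_us,
         truncated = as.numeric(ep$truncated), zone = ep$zone, dat = dat)
  })
  mat_write(list(cfg = list(content = "epochs", n = length(x)),
                 dat = list(epochs = eps)), path)
  invisible(path)
}

#' Load a recording saved with [save_mat()]
#'
#' @param path a `.mat` file produced by this package.
#' @return a [recording()].
#' @export
load_mat <- function(path) {
  vars <- mat_read(path)
  if (is.null(vars$cfg) || is.null(vars$dat))
    stop("not a recording MAT-file (missing cfg/dat): ", path,
         call. = FALSE)
  cfg <- cfg_from_list(vars$cfg)
  dat <- list()
  for (m in setdiff(names(vars$dat), c("tags", "summary"))) {
    d <- vars$dat[[m]]
    if (!is.null(d$times_ns) || identical(d$modality, "SystP")) {
      dat[[m]] <- event_series(as.numeric(d$times_ns), d$modality)
    } else {
      dat[[m]] <- lapply(d, function(s) {
        v <- if (!is.null(s$x)) {
          vm <- cbind(x = as.numeric(s$x), y = as.numeric(s$y),
                      z = as.numeric(s$z))
          vm
        } else as.numeric(s$value)
        uniform_series(s$modality, s$start_us, s$fs, v)
      })
    }
  }
  tags <- tags_from_list(vars$dat$tags, cfg$timezone)
  sm <- vars$dat$summary
  chr <- function(x) if (is.null(x)) character(0) else as.character(x)
  summary <- data.frame(modality = chr(sm$modality),
                        total_duration_s = as.numeric(sm$total_duration_s),
                        total_points = as.numeric(sm$total_points),
                        pct_missing = as.numeric(sm$pct_missing),
                        stringsAsFactors = FALSE)
  recording(cfg, dat, tags, summary)
}

#' Load every recording MAT-file in a folder
#'
#' @param dir folder to scan (non-recursive), in filename order.
#' @return named list of [recording()]s.
#' @export
load_mat_batch <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.mat$", full.names = TRUE))
  out <- lapply(paths, load_mat)
  names(out) <- sub("\\.mat$", "", basename(paths))
  out
}

#' Save a recording (or epochs) as an XLSX workbook
#'
#' One worksheet per modality segment group (or per epoch x modality), with
#' the same universal-time / local-time / value columns as the MAT tables,
#' plus a final sheet for the event tags. Cells store numeric microseconds
#' (not spreadsheet datetimes) so tag times keep their millisecond
#' precision exactly.
#'
#' @param x a [recording()] or list of epochs.
#' @param path output `.xlsx` path.
#' @param overwrite allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
save_xlsx <- function(x, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite ", path, " (set overwrite = TRUE)",
         call. = FALSE)
  sheets <- list()
  add_modality <- function(sheets, m, d, zone, prefix = "") {
    if (inherits(d, "event_series")) {
      sheets[[paste0(prefix, m)]] <-
        data.frame(unix_time_ns = d$times_ns,
                   local_time = to_local(d$times_ns / 1000, zone),
                   stringsAsFactors = FALSE)
    } else {
      tabs <- lapply(d, series_table, zone = zone)
      if (length(tabs) > 1L)
        for (i in seq_along(tabs)) tabs[[i]]$segment <- i
      sheets[[paste0(prefix, m)]] <-
        if (length(tabs)) do.call(rbind, tabs)
        else data.frame(unix_time_us = numeric(0), local_time = character(0),
                        value = numeric(0))
    }
    sheets
  }
  if (inherits(x, "recording")) {
    for (m in names(x$dat))
      sheets <- add_modality(sheets, m, x$dat[[m]], x$cfg$timezone)
    sheets$tags <- as.data.frame(x$tags)
  } else {
    stopifnot(is.list(x), length(x) > 0L, inherits(x[[1]], "epoch"))
    for (ep in x)
      for (m in names(ep$dat))
        sheets <- add_modality(sheets, m, ep$dat[[m]], ep$zone,
                               prefix = paste0(ep$label, " "))
    sheets$tags <- as.data.frame(do.call(rbind, lapply(x, `[[`, "tags")))
  }
  xlsx_write(sheets, path)
  invisible(path)
}
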