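# Discovery of participant_data trees and reconstitution of chunk payloads
# into unified per-modality series over default (per-civil-day) or custom
# wall-clock windows.

DATE_RE <- "^\\d{4}-\\d{2}-\\d{2}$"

#' Discover chunk files under a participant_data root
#'
#' Walks `root` (or `root/participant_data`) for folders named
#' `YYYY-MM-DD/<subject>-<device>`; anything not fitting that structure is
#' ignored. Each chunk file found is parsed and indexed with its
#' per-modality start time, sampling frequency and sample count; parsed
#' records are cached on the returned index so reconstitution does not
#' re-read files.
#'
#' @param root folder containing (or named) `participant_data`.
#' @param date_range optional `c(first, last)` ISO dates; only date folders
#'   within the range (inclusive) are indexed.
#' @param input_format `"avro"` or `"csv"`.
#' @return a data.frame of class `chunk_index` with one row per
#'   (file, modality) plus `SystP`/`Tags` rows; empty when nothing matches.
#' @export
discover <- function(root, date_range = NULL,
                     input_format = c("avro", "csv")) {
  input_format <- match.arg(input_format)
  if (!dir.exists(root)) stop("unreadable root: ", root, call. = FALSE)
  if (basename(root) != "participant_data" &&
      dir.exists(file.path(root, "participant_data")))
    root <- file.path(root, "participant_data")
  dates <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  dates <- dates[grepl(DATE_RE, dates)]
  if (!is.null(date_range))
    dates <- dates[dates >= date_range[1] & dates <= date_range[2]]
  cache <- new.env(parent = emptyenv())
  rows <- list()
  for (d in sort(dates)) {
    ids <- list.dirs(file.path(root, d), recursive = FALSE,
                     full.names = FALSE)
    ids <- ids[grepl("^.+-.+$", ids)]
    for (id in ids) {
      subdir <- file.path(root, d, id)
      recs <- if (input_format == "avro") {
        paths <- list.files(subdir, pattern = "\\.avro$", recursive = TRUE,
                            full.names = TRUE)
        stats::setNames(lapply(paths, read_avro_chunk), paths)
      } else {
        csvdirs <- unique(dirname(list.files(subdir, pattern = "\\.csv$",
                                             recursive = TRUE,
                                             full.names = TRUE)))
        rl <- list()
        for (cd in csvdirs) {
          got <- read_csv_chunks(cd)
          names(got) <- file.path(cd, vapply(got, csv_stem, ""))
          rl <- c(rl, got)
        }
        rl
      }
      for (p in names(recs)) {
        rec <- recs[[p]]
        assign(p, rec, envir = cache)
        for (m in names(rec$modalities)) {
          pl <- rec$modalities[[m]]
          n <- if (is.matrix(pl$values)) nrow(pl$values) else
            length(pl$values)
          rows[[length(rows) + 1L]] <- data.frame(
            date = d, id = id, path = p, modality = m,
            start_us = pl$start_us, fs = pl$fs, n = n,
            stringsAsFactors = FALSE)
        }
        if (length(rec$peaks_ns))
          rows[[length(rows) + 1L]] <- data.frame(
            date = d, id = id, path = p, modality = "SystP",
            start_us = rec$peaks_ns[1] / 1000, fs = NA_real_,
            n = length(rec$peaks_ns), stringsAsFactors = FALSE)
        if (length(rec$tags_us))
          rows[[length(rows) + 1L]] <- data.frame(
            date = d, id = id, path = p, modality = "Tags",
            start_us = rec$tags_us[1], fs = NA_real_,
            n = length(rec$tags_us), stringsAsFactors = FALSE)
      }
    }
  }
  idx <- if (length(rows)) do.call(rbind, rows) else
    data.frame(date = character(0), id = character(0), path = character(0),
               modality = character(0), start_us = numeric(0),
               fs = numeric(0), n = numeric(0), stringsAsFactors = FALSE)
  idx <- idx[order(idx$id, idx$start_us), , drop = FALSE]
  rownames(idx) <- NULL
  attr(idx, "records") <- cache
  attr(idx, "root") <- root
  class(idx) <- c("chunk_index", "data.frame")
  idx
}

#' @exportS3Method base::print
print.chunk_index <- function(x, ...) {
  cat(sprintf("<chunk_index> %d file(s), %d subject-date group(s)\n",
              length(unique(x$path)),
              nrow(unique(as.data.frame(x)[c("id", "date")]))))
  invisible(x)
}

parse_wall <- function(w) {
  if (grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", w))
    return(if (grepl(":\\d{2}:", w)) w else paste0(w, ":00"))
  stop("cannot parse wall time: ", w, call. = FALSE)
}

#' Enumerate read windows for every subject
#'
#' The default method yields one window per (subject, date with data):
#' local midnight to next local midnight in the configured zone (23/25 h
#' across daylight-saving transitions). The custom method anchors the
#' configured wall-clock window on each date with data and extends it by
#' `timespan_h`; with `allow_overlap = FALSE`, a window starting inside the
#' previous one is advanced to the previous window's end (skip-forward
#' rule).
#'
#' @param index a [discover()] result.
#' @param cfg a [read_config()].
#' @return data.frame with columns `id`, `start_us`, `end_us` (half-open).
#' @export
enumerate_windows <- function(index, cfg) {
  stopifnot(inherits(cfg, "read_config"))
  out <- list()
  for (id in unique(index$id)) {
    dates <- sort(unique(index$date[index$id == id]))
    if (!is.null(cfg$date_range))
      dates <- dates[dates >= cfg$date_range[1] & dates <= cfg$date_range[2]]
    prev_end <- -Inf
    for (d in dates) {
      if (cfg$read_method == "default") {
        ws <- local_to_us(paste(d, "00:00:00"), cfg$timezone)
        we <- local_to_us(paste(as.Date(d) + 1, "00:00:00"), cfg$timezone)
      } else {
        if (is.null(cfg$window))
          stop("custom read method requires a window", call. = FALSE)
        ws <- local_to_us(paste(d, parse_wall(cfg$window[1])), cfg$timezone)
        we <- local_to_us(paste(d, parse_wall(cfg$window[2])), cfg$timezone) +
          cfg$timespan_h * 3600 * US
        if (we <= ws)
          stop("custom window ends at or before its start; ",
               "use timespan_h to span past midnight", call. = FALSE)
      }
      if (!cfg$allow_overlap && ws < prev_end) ws <- prev_end
      if (we > ws) {
        out[[length(out) + 1L]] <- data.frame(id = id, start_us = ws,
                                              end_us = we,
                                              stringsAsFactors = FALSE)
        prev_end <- max(prev_end, we)
      }
    }
  }
  if (!length(out))
    return(data.frame(id = character(0), start_us = numeric(0),
                      end_us = numeric(0)))
  do.call(rbind, out)
}

# assemble sorted payloads of one modality into contiguous segments;
# 'later chunk wins' on overlap, tolerance of half a sample period on
# contiguity so microsecond rounding never opens a false gap
assemble_segments <- function(payloads, paths) {
  fs <- vapply(payloads, function(p) p$fs, 0)
  if (length(unique(round(fs * 1e6))) > 1L)
    stop("sampling frequency changes across chunks (",
         paste(unique(fs), collapse = ", "), " Hz) in files: ",
         paste(basename(paths), collapse = ", "), call. = FALSE)
  fs <- fs[1]
  half <- 0.5 * US / fs
  ord <- order(vapply(payloads, function(p) p$start_us, 0))
  segs <- list()
  cur_start <- NULL; cur_vals <- NULL
  for (p in payloads[ord]) {
    v <- if (is.matrix(p$values)) p$values else matrix(p$values, ncol = 1L)
    if (is.null(cur_start)) {
      cur_start <- p$start_us; cur_vals <- v
      next
    }
    expected <- cur_start + nrow(cur_vals) * US / fs
    if (p$start_us < expected - half) {
      # duplicate/overlapping payload: later chunk wins
      warning("overlapping chunk payloads; later chunk wins", call. = FALSE)
      keep <- max(0L, round((p$start_us - cur_start) * fs / US))
      cur_vals <- cur_vals[seq_len(min(keep, nrow(cur_vals))), ,
                           drop = FALSE]
      expected <- cur_start + nrow(cur_vals) * US / fs
    }
    if (abs(p$start_us - expected) <= half) {
      cur_vals <- rbind(cur_vals, v)
    } else {
      segs[[length(segs) + 1L]] <- list(start_us = cur_start,
                                        values = cur_vals)
      cur_start <- p$start_us; cur_vals <- v
    }
  }
  if (!is.null(cur_start))
    segs[[length(segs) + 1L]] <- list(start_us = cur_start,
                                      values = cur_vals)
  list(fs = fs, segs = segs)
}

#' Reconstitute one subject window into a recording
#'
#' Chunks intersecting the half-open window are sorted, concatenated and
#' trimmed. Consecutive chunks are contiguous iff the next start deviates
#' from the previous end by at most half a sample period; larger deviations
#' open a discontinuity. With `cfg$pad_discontinuities` the gaps are filled
#' with `NaN` on the nominal grid, yielding one continuous series per
#' modality; otherwise each continuous run is kept as its own segment. With
#' `cfg$pad_to_max` the grid is anchored at the window start and
#' `NaN`-extended to the full window length. Peaks and tags are filtered to
#' the window and the missing-data summary is computed on the window grid.
#'
#' @param index a [discover()] result.
#' @param window one row of [enumerate_windows()] (or a list with `id`,
#'   `start_us`, `end_us`).
#' @param cfg the [read_config()].
#' @return a [recording()].
#' @export
reconstitute_window <- function(index, window, cfg) {
  cache <- attr(index, "records")
  ws <- window$start_us; we <- window$end_us
  id <- window$id
  uniform_req <- intersect(cfg$modalities, MODALITIES)
  dat <- list()
  summary <- list()
  for (m in uniform_req) {
    sel <- index$id == id & index$modality == m &
      index$start_us < we & (index$start_us + index$n / index$fs * US) > ws
    rows <- index[sel, , drop = FALSE]
    segs <- list(); fs <- NA_real_
    if (nrow(rows)) {
      payloads <- lapply(rows$path,
                         function(p) get(p, envir = cache)$modalities[[m]])
      asm <- assemble_segments(payloads, rows$path)
      fs <- asm$fs
      for (s in asm$segs) {
        t <- s$start_us + round((seq_len(nrow(s$values)) - 1) * US / fs)
        keep <- t >= ws & t < we
        if (!any(keep)) next
        i0 <- which.max(keep)
        segs[[length(segs) + 1L]] <-
          list(start_us = t[i0],
               values = s$values[keep, , drop = FALSE])
      }
    }
    mat1 <- length(segs) && ncol(segs[[1]]$values) > 1L
    mk <- function(start, vals) {
      v <- if (mat1) vals else as.numeric(vals[, 1L])
      if (mat1 && is.matrix(v)) dimnames(v) <- list(NULL, c("x", "y", "z"))
      uniform_series(m, start, fs, v)
    }
    if (length(segs) && (cfg$pad_discontinuities || cfg$pad_to_max)) {
      anchor <- if (cfg$pad_to_max) ws else segs[[1L]]$start_us
      last <- segs[[length(segs)]]
      n_grid <- if (cfg$pad_to_max) floor((we - ws) * fs / US) else
        round((last$start_us + nrow(last$values) * US / fs - anchor) *
                fs / US)
      nc <- ncol(segs[[1L]]$values)
      gridv <- matrix(NaN, nrow = n_grid, ncol = nc)
      for (s in segs) {
        at <- round((s$start_us - anchor) * fs / US)
        ii <- at + seq_len(nrow(s$values))
        ok <- ii >= 1L & ii <= n_grid
        gridv[ii[ok], ] <- s$values[ok, , drop = FALSE]
      }
      dat[[m]] <- list(mk(anchor, gridv))
    } else {
      dat[[m]] <- lapply(segs, function(s) mk(s$start_us, s$values))
    }
    summary[[m]] <- if (length(dat[[m]])) {
      summarize_missing(dat[[m]], c(ws, we))
    } else {
      data.frame(modality = m, total_duration_s = 0, total_points = 0,
                 pct_missing = 100, stringsAsFactors = FALSE)
    }
  }
  paths_id <- unique(index$path[index$id == id])
  if ("SystP" %in% cfg$modalities) {
    pk <- sort(unique(unlist(lapply(
      paths_id, function(p) get(p, envir = cache)$peaks_ns))))
    pk <- pk[pk >= ws * 1000 & pk < we * 1000]
    dat[["SystP"]] <- event_series(pk %||% numeric(0))
  }
  tag_us <- numeric(0); tag_src <- numeric(0)
  for (p in paths_id) {
    rec <- get(p, envir = cache)
    if (length(rec$tags_us)) {
      tag_us <- c(tag_us, rec$tags_us)
      tag_src <- c(tag_src, rep(chunk_start_us(rec), length(rec$tags_us)))
    }
  }
  keep <- tag_us >= ws & tag_us < we
  ord <- order(tag_us[keep])
  tags <- tag_table(tag_us[keep][ord], tag_src[keep][ord], cfg$timezone)
  cfg$subject <- sub("-[^-]*$", "", id)
  cfg$device <- sub(".*-", "", id)
  cfg$window_start_us <- ws
  cfg$window_end_us <- we
  recording(cfg, dat, tags,
            do.call(rbind, c(summary, list(make.row.names = FALSE))))
}

chunk_start_us <- function(rec) {
  starts <- vapply(rec$modalities, function(p) p$start_us, 0)
  suppressWarnings(min(c(starts, rec$tags_us, rec$peaks_ns / 1000),
                       na.rm = TRUE))
}

#' Discover, window and reconstitute in one call
#'
#' @param cfg a [read_config()]; `cfg$parent_folder` is the data root.
#' @param index optionally a pre-computed [discover()] index.
#' @return named list of [recording()]s, one per (subject, window), named
#'   `<subject>-<device>_<local start date>`.
#' @export
reconstitute <- function(cfg, index = NULL) {
  if (is.null(index))
    index <- discover(cfg$parent_folder, cfg$date_range, cfg$input_format)
  windows <- enumerate_windows(index, cfg)
  out <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    rec <- reconstitute_window(index, w, cfg)
    out[[recording_stem(rec)]] <- rec
  }
  out
}

recording_stem <- function(rec) {
  sprintf("%s-%s_%s", rec$cfg$subject, rec$cfg$device,
          local_date_str(rec$cfg$window_start_us, rec$cfg$timezone))
}
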