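# Epoching: segment a recording into fixed-extent slices relative to event
# tags or timepoints. Slicing never resamples -- an epoch start is snapped
# to the nearest parent grid sample at or after its nominal start.

#' Epoching specification
#'
#' Four modes: `"event"` / `"timepoint"` cut one `[anchor - pre_s,
#' anchor + post_s)` epoch around a tag or clock time; `"sequential"` cuts
#' `n` epochs of `length_s` seconds stepping `length_s - overlap_s` from the
#' anchor (forward, or mirrored backward ending at the anchor); `"a_to_b"`
#' cuts the span between two tags.
#'
#' @param mode `"event"`, `"timepoint"`, `"sequential"` or `"a_to_b"`.
#' @param anchor tag label (e.g. `"Tag 2"`) for event/sequential modes, or
#'   a local timestamp `"YYYY-MM-DD HH:MM:SS"` for timepoint mode.
#' @param pre_s,post_s seconds before/after the anchor (event/timepoint).
#' @param n,length_s,overlap_s,direction sequential-mode parameters;
#'   `overlap_s < length_s`, direction `"forward"` or `"backward"`.
#' @param tag_a,tag_b tag labels bounding an `a_to_b` epoch.
#' @return object of class `epoch_spec`.
#' @export
epoch_spec <- function(mode = c("event", "timepoint", "sequential",
                                "a_to_b"),
                       anchor = NULL, pre_s = 0, post_s = 0,
                       n = 1, length_s = 30, overlap_s = 0,
                       direction = c("forward", "backward"),
                       tag_a = NULL, tag_b = NULL) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (pre_s < 0 || post_s < 0) stop("pre_s/post_s must be >= 0",
                                    call. = FALSE)
  if (mode == "sequential") {
    if (n < 1 || length_s <= 0) stop("need n >= 1 and length_s > 0",
                                     call. = FALSE)
    if (overlap_s >= length_s) stop("overlap_s must be < length_s",
                                    call. = FALSE)
  }
  if (mode == "a_to_b" && (is.null(tag_a) || is.null(tag_b)))
    stop("a_to_b epoching needs tag_a and tag_b", call. = FALSE)
  structure(list(mode = mode, anchor = anchor, pre_s = pre_s,
                 post_s = post_s, n = n, length_s = length_s,
                 overlap_s = overlap_s, direction = direction,
                 tag_a = tag_a, tag_b = tag_b),
            class = "epoch_spec")
}

resolve_anchor <- function(anchor, rec) {
  if (is.numeric(anchor)) return(anchor)
  if (grepl("^Tag ", anchor)) {
    hit <- rec$tags$tag_time_us[rec$tags$label == anchor]
    if (!length(hit)) stop("tag not found: ", anchor, call. = FALSE)
    return(hit[1])
  }
  local_to_us(anchor, rec$cfg$timezone)
}

recording_extent <- function(rec) {
  lo <- Inf; hi <- -Inf
  for (m in names(rec$dat)) {
    d <- rec$dat[[m]]
    if (inherits(d, "event_series")) next
    for (s in d) {
      if (n_samples(s) == 0L) next
      lo <- min(lo, s$start_us)
      hi <- max(hi, s$start_us + n_samples(s) * US / s$fs)
    }
  }
  if (!is.finite(lo)) c(rec$cfg$window_start_us, rec$cfg$window_end_us)
  else c(lo, hi)
}

slice_series <- function(s, es, ee) {
  t <- series_times_us(s)
  keep <- t >= es & t < ee
  if (!any(keep)) return(NULL)
  v <- value_matrix(s)[keep, , drop = FALSE]
  out <- uniform_series(s$modality, t[which.max(keep)], s$fs,
                        if (is.matrix(s$values)) v else as.numeric(v[, 1L]))
  if (is.matrix(out$values)) dimnames(out$values) <- list(NULL,
                                                          c("x", "y", "z"))
  out
}

#' Cut epochs from a recording
#'
#' Epochs exceeding the data extent are truncated and flagged (set
#' `truncate = FALSE` to make that an error instead). Every uniform
#' modality is sliced on its own grid; systolic peaks and tags are filtered
#' into each epoch.
#'
#' @param rec a [recording()].
#' @param spec an [epoch_spec()].
#' @param truncate allow epochs to be truncated at the data extent.
#' @return list of `epoch` objects (`label`, `start_us`, `end_us`,
#'   `truncated`, per-modality `dat`, `tags`).
#' @export
epoch_data <- function(rec, spec, truncate = TRUE) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "epoch_spec"))
  bounds <- switch(spec$mode,
    event = , timepoint = {
      t0 <- resolve_anchor(spec$anchor, rec)
      cbind(t0 - spec$pre_s * US, t0 + spec$post_s * US)
    },
    sequential = {
      t0 <- resolve_anchor(spec$anchor, rec)
      step <- (spec$length_s - spec$overlap_s) * US
      len <- spec$length_s * US
      k <- seq_len(spec$n) - 1
      if (spec$direction == "forward") {
        starts <- t0 + k * step
      } else {
        # generated anchor-first going back, labelled in temporal order
        starts <- rev(t0 - len - k * step)
      }
      cbind(starts, starts + len)
    },
    a_to_b = {
      ta <- resolve_anchor(spec$tag_a, rec)
      tb <- resolve_anchor(spec$tag_b, rec)
      if (tb <= ta)
        stop("empty epoch: ", spec$tag_a, " does not precede ", spec$tag_b,
             call. = FALSE)
      cbind(ta, tb)
    })
  dimnames(bounds) <- NULL
  ext <- recording_extent(rec)
  out <- vector("list", nrow(bounds))
  for (i in seq_len(nrow(bounds))) {
    es <- bounds[i, 1]; ee <- bounds[i, 2]
    trunc <- es < ext[1] || ee > ext[2]
    if (trunc && !truncate)
      stop("epoch ", i, " [", to_local(es, rec$cfg$timezone), ", ",
           to_local(ee, rec$cfg$timezone),
           ") exceeds the data extent", call. = FALSE)
    dat <- list()
    for (m in names(rec$dat)) {
      d <- rec$dat[[m]]
      if (inherits(d, "event_series")) {
        tns <- d$times_ns
        dat[[m]] <- event_series(tns[tns >= es * 1000 & tns < ee * 1000],
                                 d$modality)
      } else {
        sl <- lapply(d, slice_series, es = es, ee = ee)
        dat[[m]] <- sl[!vapply(sl, is.null, TRUE)]
      }
    }
    tg <- rec$tags[rec$tags$tag_time_us >= es & rec$tags$tag_time_us < ee, ,
                   drop = FALSE]
    out[[i]] <- structure(
      list(label = sprintf("Epoch %d", i), start_us = es, end_us = ee,
           truncated = trunc, dat = dat, tags = tg,
           zone = rec$cfg$timezone),
      class = "epoch")
  }
  out
}

#' @exportS3Method base::print
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch> %s [%s, %s)%s\n", x$label,
              to_local(x$start_us, x$zone), to_local(x$end_us, x$zone),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}
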