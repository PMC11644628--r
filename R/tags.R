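# Event-tag editing: add, delete, annotate, apply (sort + relabel), reset.
# Edits are staged as pending rows and only take effect on apply_edits(),
# mirroring an edit-then-apply workflow. Equal-time tags keep insertion
# order (stable sort). User-added tags carry chunk_ts_us = 0 since no
# source chunk file exists.

#' Stage a new event tag
#'
#' The new tag is appended with the next provisional label and a pending
#' `"add"` flag; [apply_edits()] sorts it into temporal order and relabels
#' the table. Its annotation records when it was created.
#'
#' @param tags a [tag_table()].
#' @param when local date+time of the tag (to the ms),
#'   `"YYYY-MM-DD HH:MM:SS.sss"` or POSIXct.
#' @param zone IANA zone `when` is expressed in; defaults to the table's
#'   zone.
#' @param note optional free-text annotation appended to the creation
#'   record.
#' @param extent_us optional recording extent `c(start_us, end_us)`; a tag
#'   outside it is allowed but warned about.
#' @return the tag table with one staged row appended.
#' @export
add_tag <- function(tags, when, zone = attr(tags, "zone"), note = "",
                    extent_us = NULL) {
  stopifnot(inherits(tags, "tag_table"))
  t_us <- round(local_to_us(when, zone) / 1000) * 1000
  if (!is.null(extent_us) && (t_us < extent_us[1] || t_us >= extent_us[2]))
    warning("new tag at ", to_local(t_us, zone),
            " lies outside the recording extent", call. = FALSE)
  ann <- paste0("added ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (nzchar(note)) ann <- paste0(ann, "; ", note)
  row <- data.frame(
    label = sprintf("Tag %d", nrow(tags) + 1L),
    chunk_ts_us = 0,                      # user-added: no source chunk file
    tag_time_us = t_us,
    local_date = local_date_str(t_us, attr(tags, "zone")),
    local_time_ms = local_walltime_str(t_us, attr(tags, "zone")),
    annotation = ann,
    pending = "add",
    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(tags), row)
  attr(out, "zone") <- attr(tags, "zone")
  class(out) <- class(tags)
  out
}

#' Stage tag deletions
#'
#' @param tags a [tag_table()].
#' @param labels labels of existing tags (e.g. `"Tag 3"`).
#' @return the tag table with the rows flagged pending-delete.
#' @export
delete_tags <- function(tags, labels) {
  stopifnot(inherits(tags, "tag_table"))
  missing <- setdiff(labels, tags$label)
  if (length(missing))
    stop("tag not found: ", paste(missing, collapse = ", "), call. = FALSE)
  tags$pending[tags$label %in% labels] <- "delete"
  tags
}

#' Apply staged tag edits
#'
#' Executes pending deletions, sorts rows into temporal order (stable, so
#' equal-time tags keep insertion order), rewrites labels as a dense
#' `"Tag 1".."Tag n"` sequence, and clears the pending flags. Idempotent.
#'
#' @param tags a [tag_table()].
#' @return the applied tag table.
#' @export
apply_edits <- function(tags) {
  stopifnot(inherits(tags, "tag_table"))
  keep <- tags$pending != "delete"
  out <- as.data.frame(tags)[keep, , drop = FALSE]
  out <- out[order(out$tag_time_us), , drop = FALSE]  # stable in R
  if (nrow(out)) out$label <- sprintf("Tag %d", seq_len(nrow(out)))
  out$pending <- rep_len("", nrow(out))
  rownames(out) <- NULL
  attr(out, "zone") <- attr(tags, "zone")
  class(out) <- class(tags)
  out
}

#' Restore the tags loaded with a recording
#'
#' Returns the deep snapshot taken when the recording was reconstituted or
#' loaded; [save_mat()] with `refresh_snapshot = TRUE` moves the snapshot
#' forward to the saved state.
#'
#' @param rec a [recording()].
#' @return the original [tag_table()].
#' @export
reset_tags <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  rec$tags_original
}
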