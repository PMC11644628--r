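# Minimal XLSX (OOXML spreadsheet) writer: one workbook, plain worksheets,
# inline strings, no styling. Numeric cells carry full double precision;
# times are exported as numeric microseconds plus ISO local-time strings so
# millisecond tag precision survives spreadsheet round trips.

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

col_letter <- function(j) {
  out <- character(length(j))
  for (i in seq_along(j)) {
    n <- j[i]; s <- ""
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[i] <- s
  }
  out
}

sheet_xml <- function(df) {
  nc <- ncol(df)
  cl <- col_letter(seq_len(nc))
  header <- paste0(
    '<row r="1">',
    paste0('<c r="', cl, '1" t="inlineStr"><is><t>',
           xml_escape(names(df)), "</t></is></c>", collapse = ""),
    "</row>")
  rows <- character(nrow(df))
  cells <- vector("list", nc)
  for (j in seq_len(nc)) {
    x <- df[[j]]
    if (is.numeric(x)) {
      val <- sprintf("%.17g", x)
      # missing samples become empty cells (read back as NA)
      cells[[j]] <- ifelse(is.finite(x),
                           paste0('<c r="', cl[j], seq_len(nrow(df)) + 1L,
                                  '"><v>', val, "</v></c>"),
                           "")
    } else {
      cells[[j]] <- paste0('<c r="', cl[j], seq_len(nrow(df)) + 1L,
                           '" t="inlineStr"><is><t>',
                           xml_escape(as.character(x)), "</t></is></c>")
    }
  }
  if (nrow(df))
    rows <- paste0('<row r="', seq_len(nrow(df)) + 1L, '">',
                   do.call(paste0, cells), "</row>")
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/',
         'spreadsheetml/2006/main"><sheetData>',
         header, paste(rows, collapse = ""),
         "</sheetData></worksheet>")
}

#' Write data frames to an XLSX workbook
#'
#' @param sheets named list of data.frames; one worksheet each.
#' @param path output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
xlsx_write <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) > 0L, !is.null(names(sheets)))
  dir <- tempfile("xlsx")
  dir.create(file.path(dir, "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "worksheets"), recursive = TRUE)
  n <- length(sheets)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/',
    'content-types">',
    '<Default Extension="rels" ContentType="application/vnd.',
    'openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.',
    'openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste0('<Override PartName="/xl/worksheets/sheet', seq_len(n),
           '.xml" ContentType="application/vnd.openxmlformats-',
           'officedocument.spreadsheetml.worksheet+xml"/>',
           collapse = ""),
    "</Types>"), file.path(dir, "[Content_Types].xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/',
    '2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/',
    'officeDocument/2006/relationships/officeDocument" ',
    'Target="xl/workbook.xml"/></Relationships>'),
    file.path(dir, "_rels", ".rels"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/',
    '2006/main" xmlns:r="http://schemas.openxmlformats.org/',
    'officeDocument/2006/relationships"><sheets>',
    paste0('<sheet name="', xml_escape(names(sheets)), '" sheetId="',
           seq_len(n), '" r:id="rId', seq_len(n), '"/>', collapse = ""),
    "</sheets></workbook>"), file.path(dir, "xl", "workbook.xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/',
    '2006/relationships">',
    paste0('<Relationship Id="rId', seq_len(n),
           '" Type="http://schemas.openxmlformats.org/officeDocument/',
           '2006/relationships/worksheet" Target="worksheets/sheet',
           seq_len(n), '.xml"/>', collapse = ""),
    "</Relationships>"), file.path(dir, "xl", "_rels", "workbook.xml.rels"))
  for (i in seq_len(n))
    writeLines(sheet_xml(sheets[[i]]),
               file.path(dir, "xl", "worksheets",
                         paste0("sheet", i, ".xml")))
  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE),
           files = c("[Content_Types].xml", "_rels", "xl"),
           root = dir, mode = "mirror")
  invisible(path)
}
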