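# MAT-file level 5 container (the widely readable uncompressed variant).
# Writer maps R objects: numeric -> double array, character -> char array
# (vectors become fixed-width char matrices), unnamed list -> cell, named
# list -> 1x1 struct. Reader supports double/integer/char/cell/struct
# classes in both long and small element formats (what this package and
# scipy.io/Matlab write without compression).

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MI_UTF8 <- 16L; MI_UTF16 <- 17L
MX_CELL <- 1L; MX_STRUCT <- 2L; MX_OBJECT <- 3L; MX_CHAR <- 4L
MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                            endian = "little")

mat_tagged <- function(type, data) {
  pad <- (8L - length(data) %% 8L) %% 8L
  c(u32(c(type, length(data))), data, raw(pad))
}

# mat_elem returns a flat *list* of raw chunks whose concatenation is the
# miMATRIX element; building chunk lists instead of one raw vector avoids
# re-copying megabytes at every struct/cell nesting level.
mat_elem <- function(obj, name = "") {
  if (is.null(obj)) obj <- numeric(0)
  if (is.logical(obj) || is.integer(obj)) obj <- as.numeric(obj)
  body <- if (is.numeric(obj)) {
    dims <- if (is.matrix(obj)) dim(obj) else c(length(obj), 1L)
    if (length(obj) == 0L) dims <- c(0L, 0L)
    list(mat_tagged(MI_UINT32, u32(c(MX_DOUBLE, 0L))),
         mat_tagged(MI_INT32, u32(dims)),
         mat_tagged(MI_INT8, charToRaw(name)),
         mat_tagged(MI_DOUBLE, writeBin(as.numeric(obj), raw(), size = 8L,
                                        endian = "little")))
  } else if (is.character(obj)) {
    if (length(obj) == 0L) obj <- ""
    w <- max(nchar(obj, type = "chars"))
    m <- length(obj)
    if (w == 0L) {
      codes <- integer(0); dims <- c(0L, 0L)
    } else {
      padded <- formatC(obj, width = -w)  # left-justified, space padded
      cm <- matrix(utf8ToInt(paste(padded, collapse = "")), nrow = w)
      codes <- as.integer(as.vector(t(cm)))  # column-major m x w
      dims <- c(m, w)
    }
    list(mat_tagged(MI_UINT32, u32(c(MX_CHAR, 0L))),
         mat_tagged(MI_INT32, u32(dims)),
         mat_tagged(MI_INT8, charToRaw(name)),
         mat_tagged(MI_UINT16, writeBin(codes, raw(), size = 2L,
                                        endian = "little")))
  } else if (is.list(obj) && (is.null(names(obj)) || length(obj) == 0L)) {
    cells <- unlist(lapply(obj, mat_elem), recursive = FALSE)
    c(list(mat_tagged(MI_UINT32, u32(c(MX_CELL, 0L))),
           mat_tagged(MI_INT32, u32(c(1L, length(obj)))),
           mat_tagged(MI_INT8, charToRaw(name))),
      cells %||% list())
  } else if (is.list(obj)) {
    fn <- names(obj)
    if (any(nchar(fn) > 31L))
      stop("struct field name longer than 31 characters", call. = FALSE)
    namebytes <- do.call(c, lapply(fn, function(f) {
      b <- charToRaw(f); c(b, raw(32L - length(b)))
    }))
    fields <- unlist(lapply(obj, mat_elem), recursive = FALSE)
    c(list(mat_tagged(MI_UINT32, u32(c(MX_STRUCT, 0L))),
           mat_tagged(MI_INT32, u32(c(1L, 1L))),
           mat_tagged(MI_INT8, charToRaw(name)),
           mat_tagged(MI_INT32, u32(32L)),
           mat_tagged(MI_INT8, namebytes)),
      fields %||% list())
  } else {
    stop("cannot map object of class ", class(obj)[1], " to MAT",
         call. = FALSE)
  }
  nbytes <- sum(vapply(body, length, 0L))
  c(list(c(u32(MI_MATRIX), u32(nbytes))), body)
}

#' Write variables to a MAT-file (level 5)
#'
#' @param vars named list of variables; numeric arrays, strings, unnamed
#'   lists (cell arrays) and named lists (structs), nested freely.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
mat_write <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)))
  txt <- sprintf("MATLAB 5.0 MAT-file, Platform: R, Created: %s",
                 format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  hdr <- charToRaw(txt)
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  hdr <- c(hdr, raw(8L),
           writeBin(c(256L), raw(), size = 2L, endian = "little"),
           charToRaw("IM"))
  parts <- unlist(lapply(names(vars),
                         function(nm) mat_elem(vars[[nm]], nm)),
                  recursive = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  for (p in parts) writeBin(p, con)
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

mat_rd_int <- function(buf, pos, n, size, signed = TRUE) {
  readBin(buf[pos:(pos + n * size - 1L)], "integer", n = n, size = size,
          endian = "little", signed = signed)
}

# read one tagged sub-element; returns list(type, data(raw), nextpos)
mat_sub <- function(buf, pos) {
  head <- mat_rd_int(buf, pos, 2L, 4L)
  type <- head[1]
  small <- bitwShiftR(type, 16L) != 0L  # small element format packs len|type
  if (small) {
    len <- bitwShiftR(type, 16L)
    type <- bitwAnd(type, 65535L)
    data <- if (len > 0) buf[(pos + 4L):(pos + 3L + len)] else raw(0)
    list(type = type, data = data, nextpos = pos + 8L)
  } else {
    len <- head[2]
    data <- if (len > 0) buf[(pos + 8L):(pos + 7L + len)] else raw(0)
    pad <- (8L - len %% 8L) %% 8L
    list(type = type, data = data, nextpos = pos + 8L + len + pad)
  }
}

mat_numeric_from <- function(type, data) {
  switch(as.character(type),
    "1" = as.numeric(readBin(data, "integer", length(data), 1L,
                             endian = "little")),
    "2" = as.numeric(readBin(data, "integer", length(data), 1L,
                             signed = FALSE, endian = "little")),
    "3" = as.numeric(readBin(data, "integer", length(data) / 2L, 2L,
                             endian = "little")),
    "4" = as.numeric(readBin(data, "integer", length(data) / 2L, 2L,
                             signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(data, "integer", length(data) / 4L, 4L,
                             endian = "little")),
    "6" = {
      v <- readBin(data, "integer", length(data) / 4L, 4L,
                   endian = "little")
      ifelse(v < 0, v + 2^32, v)
    },
    "7" = readBin(data, "double", length(data) / 4L, 4L,
                  endian = "little"),
    "9" = readBin(data, "double", length(data) / 8L, 8L,
                  endian = "little"),
    "12" = , "13" = readBin(data, "double", length(data) / 8L, 8L,
                            endian = "little"),
    stop("unsupported MAT numeric type ", type, call. = FALSE))
}

# parse a miMATRIX body; returns list(name, value)
mat_parse_matrix <- function(body) {
  pos <- 1L
  af <- mat_sub(body, pos); pos <- af$nextpos
  flags <- readBin(af$data, "integer", 2L, 4L, endian = "little")
  cls <- bitwAnd(flags[1], 255L)
  dm <- mat_sub(body, pos); pos <- dm$nextpos
  dims <- readBin(dm$data, "integer", length(dm$data) / 4L, 4L,
                  endian = "little")
  nm <- mat_sub(body, pos); pos <- nm$nextpos
  name <- rawToChar(nm$data)
  n <- prod(dims)
  value <- if (cls %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8,
                          MX_INT16, MX_UINT16, MX_INT32, MX_UINT32)) {
    pr <- mat_sub(body, pos); pos <- pr$nextpos
    v <- mat_numeric_from(pr$type, pr$data)
    if (length(dims) == 2L && all(dims > 1L)) matrix(v, dims[1], dims[2])
    else as.numeric(v)
  } else if (cls == MX_CHAR) {
    pr <- mat_sub(body, pos); pos <- pr$nextpos
    codes <- if (pr$type %in% c(MI_UTF8, MI_UINT8, MI_INT8))
      as.integer(pr$data)
    else readBin(pr$data, "integer", length(pr$data) / 2L, 2L,
                 signed = FALSE, endian = "little")
    if (!length(codes)) ""
    else {
      m <- dims[1]; w <- dims[2]
      cm <- matrix(codes, nrow = m)
      out <- vapply(seq_len(m), function(i) intToUtf8(cm[i, ]), "")
      out <- sub(" +$", "", out)
      if (m == 1L) out[1] else out
    }
  } else if (cls == MX_CELL) {
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      el <- mat_sub(body, pos); pos <- el$nextpos
      cells[[i]] <- mat_parse_matrix(el$data)$value
    }
    cells
  } else if (cls %in% c(MX_STRUCT, MX_OBJECT)) {
    if (cls == MX_OBJECT) { cn <- mat_sub(body, pos); pos <- cn$nextpos }
    fl <- mat_sub(body, pos); pos <- fl$nextpos
    flen <- readBin(fl$data, "integer", 1L, 4L, endian = "little")
    fn <- mat_sub(body, pos); pos <- fn$nextpos
    nf <- length(fn$data) / flen
    fnames <- vapply(seq_len(nf), function(i) {
      b <- fn$data[((i - 1L) * flen + 1L):(i * flen)]
      rawToChar(b[b != as.raw(0)])
    }, "")
    out <- vector("list", nf)
    names(out) <- fnames
    for (i in seq_len(nf)) {
      el <- mat_sub(body, pos); pos <- el$nextpos
      out[[i]] <- mat_parse_matrix(el$data)$value
    }
    out
  } else {
    stop("unsupported MAT array class ", cls, call. = FALSE)
  }
  list(name = name, value = value)
}

#' Read a MAT-file (level 5, uncompressed)
#'
#' @param path path to a `.mat` file.
#' @return named list of top-level variables.
#' @export
mat_read <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 128L)
    stop("not a MAT-file (too short): ", path, call. = FALSE)
  endian <- rawToChar(buf[127:128])
  if (endian != "IM")
    stop("unsupported MAT-file byte order or format: ", path, call. = FALSE)
  pos <- 129L
  out <- list()
  while (pos + 8L <= length(buf) + 1L) {
    el <- mat_sub(buf, pos)
    pos <- el$nextpos
    if (el$type == MI_COMPRESSED)
      stop("compressed MAT elements are not supported: ", path,
           call. = FALSE)
    if (el$type != MI_MATRIX) next
    parsed <- mat_parse_matrix(el$data)
    out[[parsed$name]] <- parsed$value
  }
  out
}
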