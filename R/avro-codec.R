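# Minimal Apache Avro object-container codec (binary encoding, null codec).
#
# Longs are held as R doubles. Values above 2^53 (systolic-peak nanosecond
# timestamps) are not exact integers in double; encoding/decoding works on
# exact 32-bit halves so that any integer value representable in double
# round-trips bit-exactly.

AVRO_MAGIC <- as.raw(c(0x4f, 0x62, 0x6a, 0x01))  # "Obj\x01"

# ---- varint / zigzag --------------------------------------------------------

# zigzag-varint encode a numeric vector of integer-valued doubles -> raw
enc_varint_vec <- function(v) {
  if (!length(v)) return(raw(0))
  if (all(abs(v) < 2^52)) {
    z <- ifelse(v >= 0, 2 * v, -2 * v - 1)
    n <- length(z)
    D <- matrix(0, n, 10L)
    r <- z
    for (j in 1:10) { D[, j] <- r %% 128; r <- r %/% 128 }
    nz <- D != 0
    nd <- ifelse(rowSums(nz) == 0, 1L, max.col(nz, ties.method = "last"))
    sel <- col(D) <= nd
    B <- D + 128 * (col(D) < nd)
    as.raw(t(B)[t(sel)])
  } else {
    do.call(c, lapply(v, enc_varint_one))
  }
}

# exact single-value path, valid for any integer-valued double in [0, 2^62)
enc_varint_one <- function(v) {
  if (abs(v) < 2^52) return(enc_varint_vec(v))
  if (v < 0) stop("cannot encode negative long beyond 2^52", call. = FALSE)
  hi <- floor(v / 2^32)
  lo <- v - hi * 2^32
  # zigzag: logical shift left by one across the 64-bit pair
  carry <- lo %/% 2^31
  lo <- (lo * 2) %% 2^32
  hi <- hi * 2 + carry
  out <- integer(10)
  k <- 0L
  repeat {
    k <- k + 1L
    out[k] <- lo %% 128
    lo <- lo %/% 128 + (hi %% 128) * 2^25
    hi <- hi %/% 128
    if (hi == 0 && lo == 0) break
  }
  out <- out[seq_len(k)]
  if (k > 1L) out[seq_len(k - 1L)] <- out[seq_len(k - 1L)] + 128
  as.raw(out)
}

# decode n zigzag varints from buf starting at pos (1-based).
# Returns list(values, pos). Values are assembled in exact 28-bit halves
# (one vectorised pass per digit position) so any integer representable in
# double round-trips bit-exactly.
dec_varint_vec <- function(buf, pos, n) {
  if (n == 0) return(list(values = numeric(0), pos = pos))
  b <- as.integer(buf[pos:length(buf)])
  term <- which(b < 128L)
  if (length(term) < n) stop("truncated Avro data (varint)", call. = FALSE)
  endn <- term[n]
  ends <- term[seq_len(n)]
  starts <- c(1L, ends[-n] + 1L)
  extra <- ends - starts  # digits beyond the first, per value
  val <- b[seq_len(endn)] %% 128L
  zlo <- numeric(n)
  zhi <- numeric(n)
  for (j in 0:max(extra)) {
    sel <- extra >= j
    d <- val[starts[sel] + j]
    if (j <= 3L) zlo[sel] <- zlo[sel] + d * 2^(7 * j)
    else zhi[sel] <- zhi[sel] + d * 2^(7 * j - 28)
  }
  z <- zhi * 2^28 + zlo
  v <- ifelse(z %% 2 == 0, z / 2, -(z + 1) / 2)
  list(values = v, pos = pos + endn)
}

enc_string <- function(s) {
  b <- charToRaw(enc2utf8(s))
  c(enc_varint_vec(length(b)), b)
}

enc_bytes <- function(b) c(enc_varint_vec(length(b)), b)

enc_float_vec <- function(v) writeBin(as.numeric(v), raw(), size = 4L,
                                      endian = "little")
enc_double_vec <- function(v) writeBin(as.numeric(v), raw(), size = 8L,
                                       endian = "little")

# Avro array of primitives: one block (count, items), then end marker 0
enc_prim_array <- function(v, items) {
  body <- switch(items,
    float = enc_float_vec(v),
    double = enc_double_vec(v),
    int = , long = enc_varint_vec(v),
    stop("unsupported array item type: ", items, call. = FALSE))
  if (!length(v)) return(enc_varint_vec(0))
  c(enc_varint_vec(length(v)), body, enc_varint_vec(0))
}

# float32 quantisation: the value a float payload will read back as
float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L, endian = "little"),
          "double", n = length(v), size = 4L, endian = "little")
}

# ---- schema-driven generic decoder ------------------------------------------

# decoder state: environment with $buf (raw), $pos (next byte, 1-based)
new_dec <- function(buf) {
  e <- new.env(parent = emptyenv())
  e$buf <- buf
  e$pos <- 1L
  e
}

take <- function(e, n) {
  if (e$pos + n - 1L > length(e$buf))
    stop("truncated Avro data", call. = FALSE)
  out <- e$buf[seq.int(e$pos, length.out = n)]
  e$pos <- e$pos + as.integer(n)
  out
}

dec_long1 <- function(e) {
  r <- dec_varint_vec(e$buf, e$pos, 1L)
  e$pos <- r$pos
  r$values
}

dec_string1 <- function(e) {
  n <- dec_long1(e)
  if (n == 0) return("")
  rawToChar(take(e, n))
}

# resolve a schema node; named-type references resolved through registry
avro_decode_value <- function(schema, e, reg) {
  if (is.character(schema) && length(schema) == 1L) {
    switch(schema,
      null = NULL,
      boolean = as.integer(take(e, 1L)) != 0L,
      int = , long = dec_long1(e),
      float = readBin(take(e, 4L), "double", size = 4L, endian = "little"),
      double = readBin(take(e, 8L), "double", size = 8L, endian = "little"),
      bytes = take(e, dec_long1(e)),
      string = dec_string1(e),
      {
        if (!is.null(reg[[schema]]))
          avro_decode_value(reg[[schema]], e, reg)
        else stop("unknown Avro type reference: ", schema, call. = FALSE)
      })
  } else if (is.list(schema) && is.null(names(schema))) {
    # union: branch index then branch value
    idx <- dec_long1(e) + 1L
    if (idx < 1L || idx > length(schema))
      stop("invalid Avro union branch", call. = FALSE)
    avro_decode_value(schema[[idx]], e, reg)
  } else {
    t <- schema$type
    if (identical(t, "record")) {
      if (!is.null(schema$name)) reg[[schema$name]] <- schema
      out <- vector("list", length(schema$fields))
      nm <- character(length(out))
      for (i in seq_along(schema$fields)) {
        f <- schema$fields[[i]]
        nm[i] <- f$name
        v <- avro_decode_value(f$type, e, reg)
        out[i] <- list(v)
      }
      names(out) <- nm
      out
    } else if (identical(t, "array")) {
      items <- schema$items
      prim <- is.character(items) && length(items) == 1L &&
        items %in% c("int", "long", "float", "double")
      acc <- list()
      repeat {
        n <- dec_long1(e)
        if (n == 0) break
        if (n < 0) { dec_long1(e); n <- -n }  # block byte size, unused
        if (prim) {
          acc[[length(acc) + 1L]] <- switch(items,
            int = , long = { r <- dec_varint_vec(e$buf, e$pos, n)
                             e$pos <- r$pos; r$values },
            float = readBin(take(e, 4L * n), "double", n = n, size = 4L,
                            endian = "little"),
            double = readBin(take(e, 8L * n), "double", n = n, size = 8L,
                             endian = "little"))
        } else {
          acc[[length(acc) + 1L]] <-
            lapply(seq_len(n), function(i) avro_decode_value(items, e, reg))
        }
      }
      if (prim) unlist(acc) %||% numeric(0) else do.call(c, acc) %||% list()
    } else if (identical(t, "map")) {
      out <- list()
      repeat {
        n <- dec_long1(e)
        if (n == 0) break
        if (n < 0) { dec_long1(e); n <- -n }
        for (i in seq_len(n)) {
          k <- dec_string1(e)
          out[[k]] <- avro_decode_value(schema$values, e, reg)
        }
      }
      out
    } else if (identical(t, "fixed")) {
      take(e, schema$size)
    } else if (identical(t, "enum")) {
      schema$symbols[[dec_long1(e) + 1L]]
    } else if (is.character(t)) {
      avro_decode_value(t, e, reg)  # {"type": "long"} style wrapper
    } else {
      stop("unsupported Avro schema node", call. = FALSE)
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- container read/write ---------------------------------------------------

AVRO_SYNC <- as.raw(c(0x77, 0x72, 0x69, 0x73, 0x74, 0x66, 0x6c, 0x6f,
                      0x77, 0x2d, 0x73, 0x79, 0x6e, 0x63, 0x21, 0x21))

avro_write_container <- function(path, schema_json, body) {
  header <- c(
    AVRO_MAGIC,
    enc_varint_vec(2),
    enc_string("avro.schema"), enc_bytes(charToRaw(schema_json)),
    enc_string("avro.codec"), enc_bytes(charToRaw("null")),
    enc_varint_vec(0),
    AVRO_SYNC)
  block <- c(enc_varint_vec(1), enc_varint_vec(length(body)), body, AVRO_SYNC)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, block), con)
  invisible(path)
}

# read all objects from an Avro container; returns list(schema, objects)
avro_read_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 4L || !identical(buf[1:4], AVRO_MAGIC))
    stop("not an Avro container file: ", path, call. = FALSE)
  e <- new_dec(buf)
  e$pos <- 5L
  meta <- list()
  repeat {
    n <- dec_long1(e)
    if (n == 0) break
    if (n < 0) { dec_long1(e); n <- -n }
    for (i in seq_len(n)) {
      k <- dec_string1(e)
      meta[[k]] <- take(e, dec_long1(e))
    }
  }
  codec <- if (is.null(meta[["avro.codec"]])) "null"
           else rawToChar(meta[["avro.codec"]])
  if (!codec %in% c("null", ""))
    stop("unsupported Avro codec '", codec, "' in ", path,
         " (only the null codec is supported)", call. = FALSE)
  if (is.null(meta[["avro.schema"]]))
    stop("Avro container missing schema: ", path, call. = FALSE)
  schema <- jsonlite::fromJSON(rawToChar(meta[["avro.schema"]]),
                               simplifyVector = FALSE)
  sync <- take(e, 16L)
  reg <- new.env(parent = emptyenv())
  objects <- list()
  while (e$pos <= length(buf)) {
    cnt <- dec_long1(e)
    size <- dec_long1(e)
    for (i in seq_len(cnt))
      objects[[length(objects) + 1L]] <- avro_decode_value(schema, e, reg)
    blocksync <- take(e, 16L)
    if (!identical(blocksync, sync))
      stop("corrupt Avro container (sync marker mismatch): ", path,
           call. = FALSE)
  }
  list(schema = schema, objects = objects)
}
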