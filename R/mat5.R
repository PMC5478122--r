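# Minimal MAT v5 container support for the contest clip dialect.
# Covers exactly what those files need: numeric arrays, char arrays, cell
# arrays and (1x1) structs, plus zlib-compressed top-level elements.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MI_UTF8 <- 16L

MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L
MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L

mat5_pad <- function(n) (8L - n %% 8L) %% 8L

# ---- reading ---------------------------------------------------------------

mat5_read_tag <- function(buf, pos) {
  word1 <- readBin(buf[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  small_size <- bitwAnd(bitwShiftR(word1, 16L), 0xFFFFL)
  type_small <- bitwAnd(word1, 0xFFFFL)
  if (small_size > 0L && type_small != MI_MATRIX) {
    # small data element: 2-byte type + 2-byte size, 4 bytes of data
    list(type = type_small, size = small_size, data_pos = pos + 4L,
         next_pos = pos + 8L)
  } else {
    size <- readBin(buf[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                    endian = "little")
    list(type = word1, size = size, data_pos = pos + 8L,
         next_pos = pos + 8L + size + mat5_pad(size))
  }
}

mat5_decode_numeric <- function(bytes, type) {
  switch(as.character(type),
    "1" = as.numeric(readBin(bytes, "integer", n = length(bytes), size = 1L,
                             signed = TRUE, endian = "little")),
    "2" = as.numeric(readBin(bytes, "integer", n = length(bytes), size = 1L,
                             signed = FALSE, endian = "little")),
    "3" = as.numeric(readBin(bytes, "integer", n = length(bytes) / 2L,
                             size = 2L, signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(bytes, "integer", n = length(bytes) / 2L,
                             size = 2L, signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(bytes, "integer", n = length(bytes) / 4L,
                             size = 4L, endian = "little")),
    "6" = {
      v <- readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                   endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    "7" = as.numeric(readBin(bytes, "double", n = length(bytes) / 4L,
                             size = 4L, endian = "little")),
    "9" = readBin(bytes, "double", n = length(bytes) / 8L, size = 8L,
                  endian = "little"),
    "12" = as.numeric(readBin(bytes, "integer", n = length(bytes) / 8L,
                              size = 8L, endian = "little")),
    "16" = rawToChar(bytes),
    abort(sprintf("unsupported MAT data type mi=%d", type))
  )
}

mat5_parse_matrix <- function(buf, pos, end) {
  flags_tag <- mat5_read_tag(buf, pos)
  flags <- readBin(buf[flags_tag$data_pos:(flags_tag$data_pos + 3L)],
                   "integer", size = 4L, endian = "little")
  klass <- bitwAnd(flags, 0xFFL)
  pos <- flags_tag$next_pos

  dims_tag <- mat5_read_tag(buf, pos)
  dims <- readBin(buf[dims_tag$data_pos:(dims_tag$data_pos + dims_tag$size - 1L)],
                  "integer", size = 4L, n = dims_tag$size / 4L, endian = "little")
  pos <- dims_tag$next_pos

  name_tag <- mat5_read_tag(buf, pos)
  name <- if (name_tag$size > 0L) {
    rawToChar(buf[name_tag$data_pos:(name_tag$data_pos + name_tag$size - 1L)])
  } else ""
  pos <- name_tag$next_pos

  value <- if (klass %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8, MX_INT16,
                            MX_UINT16, MX_INT32, MX_UINT32)) {
    pr <- mat5_read_tag(buf, pos)
    v <- if (pr$size > 0L) {
      mat5_decode_numeric(buf[pr$data_pos:(pr$data_pos + pr$size - 1L)], pr$type)
    } else numeric(0)
    pos <- pr$next_pos
    if (length(dims) == 2L) matrix(v, dims[1L], dims[2L]) else array(v, dims)
  } else if (klass == MX_CHAR) {
    pr <- mat5_read_tag(buf, pos)
    bytes <- if (pr$size > 0L) buf[pr$data_pos:(pr$data_pos + pr$size - 1L)] else raw(0)
    pos <- pr$next_pos
    if (pr$type %in% c(MI_UINT16, MI_INT16)) {
      codes <- readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                       signed = FALSE, endian = "little")
      intToUtf8(codes)
    } else {
      rawToChar(bytes)
    }
  } else if (klass == MX_CELL) {
    n <- prod(dims)
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      tag <- mat5_read_tag(buf, pos)
      el <- mat5_parse_matrix(buf, tag$data_pos, tag$next_pos)
      cells[[i]] <- el$value
      pos <- tag$next_pos
    }
    cells
  } else if (klass == MX_STRUCT) {
    fl_tag <- mat5_read_tag(buf, pos)
    field_len <- readBin(buf[fl_tag$data_pos:(fl_tag$data_pos + 3L)], "integer",
                         size = 4L, endian = "little")
    pos <- fl_tag$next_pos
    fn_tag <- mat5_read_tag(buf, pos)
    nfields <- fn_tag$size %/% field_len
    fields <- character(nfields)
    for (i in seq_len(nfields)) {
      start <- fn_tag$data_pos + (i - 1L) * field_len
      bytes <- buf[start:(start + field_len - 1L)]
      bytes <- bytes[bytes != as.raw(0)]
      fields[i] <- rawToChar(bytes)
    }
    pos <- fn_tag$next_pos
    out <- vector("list", nfields)
    names(out) <- fields
    for (i in seq_len(nfields * max(1L, prod(dims)))) {
      if (i > nfields) break  # only 1x1 structs are supported/needed
      tag <- mat5_read_tag(buf, pos)
      el <- mat5_parse_matrix(buf, tag$data_pos, tag$next_pos)
      out[[i]] <- el$value
      pos <- tag$next_pos
    }
    class(out) <- "mat5_struct"
    out
  } else {
    abort(sprintf("unsupported MAT array class mx=%d", klass))
  }
  list(name = name, value = value)
}

#' Read a MAT v5 file (minimal dialect)
#'
#' Parses the subset of the MATLAB level-5 format used by the contest clip
#' files: numeric arrays, char arrays, cell arrays and scalar structs, with
#' optional zlib-compressed top-level elements.
#'
#' @param path File path.
#' @return Named list of top-level variables. Structs are returned as named
#'   lists of class `mat5_struct`, cell arrays as plain lists.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) abort(sprintf("unreadable file: '%s' does not exist", path))
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 128L) abort("unreadable file: too short for a MAT v5 header")
  magic <- rawToChar(buf[127:128])
  if (magic != "IM") {
    abort("unreadable file: missing MAT v5 endian indicator (big-endian or not MAT v5)")
  }
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(buf)) {
    tag <- mat5_read_tag(buf, pos)
    if (tag$type == MI_COMPRESSED) {
      payload <- buf[tag$data_pos:(tag$data_pos + tag$size - 1L)]
      inner <- memDecompress(payload, type = "gzip")
      itag <- mat5_read_tag(inner, 1L)
      if (itag$type != MI_MATRIX) abort("unsupported compressed element")
      el <- mat5_parse_matrix(inner, itag$data_pos, itag$next_pos)
      out[[el$name]] <- el$value
    } else if (tag$type == MI_MATRIX) {
      el <- mat5_parse_matrix(buf, tag$data_pos, tag$next_pos)
      out[[el$name]] <- el$value
    }
    pos <- tag$next_pos
  }
  out
}

# ---- writing ---------------------------------------------------------------

mat5_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4L, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4L, endian = "little"))
}

mat5_element <- function(type, bytes) {
  c(mat5_tag(type, length(bytes)), bytes, raw(mat5_pad(length(bytes))))
}

mat5_encode_doubles <- function(x) {
  writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
}

mat5_encode_int32 <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

# value -> raw bytes of a full miMATRIX element (tag included)
mat5_matrix_element <- function(value, name = "") {
  if (is.numeric(value)) {
    dims <- if (is.matrix(value)) dim(value) else c(1L, length(value))
    klass <- MX_DOUBLE
    body <- mat5_element(MI_DOUBLE, mat5_encode_doubles(value))
  } else if (is.character(value) && length(value) == 1L) {
    codes <- utf8ToInt(value)
    dims <- c(1L, length(codes))
    klass <- MX_CHAR
    body <- mat5_element(
      MI_UINT16,
      writeBin(as.integer(codes), raw(), size = 2L, endian = "little")
    )
  } else if (is.list(value) && is.null(names(value))) {
    dims <- c(1L, length(value))
    klass <- MX_CELL
    body <- do.call(c, c(list(raw(0)),
                         lapply(value, mat5_matrix_element, name = "")))
  } else if (is.list(value)) {
    dims <- c(1L, 1L)
    klass <- MX_STRUCT
    fields <- names(value)
    field_len <- 32L
    fn <- raw(field_len * length(fields))
    for (i in seq_along(fields)) {
      b <- charToRaw(fields[i])
      if (length(b) >= field_len) abort("struct field name too long")
      fn[((i - 1L) * field_len + 1L):((i - 1L) * field_len + length(b))] <- b
    }
    body <- c(
      mat5_element(MI_INT32, mat5_encode_int32(field_len)),
      mat5_element(MI_INT8, fn),
      do.call(c, c(list(raw(0)),
                   lapply(unname(value), mat5_matrix_element, name = "")))
    )
  } else {
    abort("unsupported value type for MAT writing")
  }
  flags <- mat5_element(MI_UINT32, mat5_encode_int32(c(klass, 0L)))
  dims_el <- mat5_element(MI_INT32, mat5_encode_int32(dims))
  name_el <- mat5_element(MI_INT8, charToRaw(name))
  payload <- c(flags, dims_el, name_el, body)
  c(mat5_tag(MI_MATRIX, length(payload)), payload)
}

#' Write a MAT v5 file (minimal dialect)
#'
#' @param vars Named list of variables. Numeric vectors/matrices become double
#'   arrays, character scalars char arrays, unnamed lists cell arrays and
#'   named lists scalar structs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by seizecast on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  header <- raw(128L)
  db <- charToRaw(desc)
  header[seq_along(db)] <- db
  header[117:124] <- as.raw(0L)
  header[125:126] <- writeBin(256L, raw(), size = 2L, endian = "little")
  header[127:128] <- charToRaw("IM")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (nm in names(vars)) {
    writeBin(mat5_matrix_element(vars[[nm]], name = nm), con)
  }
  invisible(path)
}
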