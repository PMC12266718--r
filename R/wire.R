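# Wire encoding for packet payload items.
#
# Every message travelling on a link is a list of payload items, one per
# declared output of the emitting node. An item is either a numeric tensor
# (an n-dimensional array of integers, doubles or logicals) or a record
# (a named list of atomic vectors). The encoding is self-describing:
# a type tag, then shape/field metadata, then the raw buffer. All multi-byte
# fields are little-endian so the byte stream is platform independent, and
# integer tensors round-trip bit-exact.

WIRE_MAGIC <- charToRaw("RGF1")
WIRE_TAG_INT <- 1L
WIRE_TAG_DOUBLE <- 2L
WIRE_TAG_LOGICAL <- 3L
WIRE_TAG_RECORD <- 4L
WIRE_TAG_CHARACTER <- 5L

wire_write_int <- function(con, x) writeBin(as.integer(as.vector(x)), con, size = 4L, endian = "little")

wire_write_string <- function(con, s) {
  b <- charToRaw(enc2utf8(s))
  wire_write_int(con, length(b))
  writeBin(b, con)
}

wire_read_int <- function(con, n = 1L) readBin(con, integer(), n = n, size = 4L, endian = "little")

wire_read_string <- function(con) {
  n <- wire_read_int(con)
  s <- rawToChar(readBin(con, raw(), n = n))
  Encoding(s) <- "UTF-8"
  s
}

wire_write_atomic <- function(con, x) {
  if (is.character(x)) {
    wire_write_int(con, WIRE_TAG_CHARACTER)
    wire_write_int(con, length(x))
    for (s in x) wire_write_string(con, s)
  } else if (is.integer(x)) {
    wire_write_int(con, WIRE_TAG_INT)
    wire_write_dims(con, x)
    writeBin(as.vector(x), con, size = 4L, endian = "little")
  } else if (is.double(x)) {
    wire_write_int(con, WIRE_TAG_DOUBLE)
    wire_write_dims(con, x)
    writeBin(as.vector(x), con, size = 8L, endian = "little")
  } else if (is.logical(x)) {
    wire_write_int(con, WIRE_TAG_LOGICAL)
    wire_write_dims(con, x)
    writeBin(as.integer(as.vector(x)), con, size = 4L, endian = "little")
  } else {
    stop("unsupported payload value of class ", paste(class(x), collapse = "/"))
  }
}

wire_write_dims <- function(con, x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  wire_write_int(con, length(d))
  wire_write_int(con, d)
}

wire_read_dims <- function(con) {
  nd <- wire_read_int(con)
  wire_read_int(con, nd)
}

wire_shape <- function(values, d) {
  if (length(d) == 1L) values else array(values, dim = d)
}

wire_read_atomic <- function(con) {
  tag <- wire_read_int(con)
  if (tag == WIRE_TAG_CHARACTER) {
    n <- wire_read_int(con)
    return(vapply(seq_len(n), function(i) wire_read_string(con), character(1)))
  }
  d <- wire_read_dims(con)
  n <- prod(d)
  values <- switch(as.character(tag),
    "1" = readBin(con, integer(), n = n, size = 4L, endian = "little"),
    "2" = readBin(con, double(), n = n, size = 8L, endian = "little"),
    "3" = as.logical(readBin(con, integer(), n = n, size = 4L, endian = "little")),
    stop("unknown wire tag ", tag)
  )
  wire_shape(values, d)
}

#' Encode one payload item to its wire representation
#'
#' Payload items are either tensors (atomic integer/double/logical vectors or
#' arrays) or records (named lists whose elements are atomic vectors,
#' including character vectors). The encoding is a compact self-describing
#' binary frame; integer data round-trips bit-exact.
#'
#' @param item a tensor or a record.
#' @return a raw vector.
#' @seealso [wire_decode()]
#' @export
#' @examples
#' identical(wire_decode(wire_encode(matrix(1:6, 2))), matrix(1:6, 2))
wire_encode <- function(item) {
  con <- rawConnection(raw(0), open = "wb")
  on.exit(close(con))
  writeBin(WIRE_MAGIC, con)
  if (is.list(item)) {
    nm <- names(item)
    if (length(item) > 0L && (is.null(nm) || any(!nzchar(nm)))) {
      stop("record payload items must have non-empty field names")
    }
    wire_write_int(con, WIRE_TAG_RECORD)
    wire_write_int(con, length(item))
    for (i in seq_along(item)) {
      wire_write_string(con, nm[[i]])
      wire_write_atomic(con, item[[i]])
    }
  } else {
    wire_write_atomic(con, item)
  }
  rawConnectionValue(con)
}

#' Decode one payload item from its wire representation
#'
#' @param bytes a raw vector produced by [wire_encode()].
#' @return the original tensor or record.
#' @export
wire_decode <- function(bytes) {
  con <- rawConnection(bytes, open = "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), n = 4L)
  if (!identical(magic, WIRE_MAGIC)) stop("not a wire-encoded payload item")
  tag <- wire_read_int(con)
  if (tag == WIRE_TAG_RECORD) {
    n <- wire_read_int(con)
    out <- vector("list", n)
    nm <- character(n)
    for (i in seq_len(n)) {
      nm[[i]] <- wire_read_string(con)
      out[[i]] <- wire_read_atomic(con)
    }
    names(out) <- nm
    return(out)
  }
  seek(con, 4L)
  wire_read_atomic(con)
}

#' Encode a full payload list
#'
#' @param payload list of payload items.
#' @return list of raw vectors.
#' @keywords internal
wire_encode_payload <- function(payload) lapply(payload, wire_encode)

#' @keywords internal
wire_decode_payload <- function(raws) lapply(raws, wire_decode)
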