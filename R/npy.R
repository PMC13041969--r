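# Minimal reader/writer for NumPy .npy files (format version 1.0), covering
# the 1-D (or single-column 2-D) numeric arrays used by the Kilosort/Phy
# spike-sorting convention: spike times as unsigned 64-bit sample indices and
# cluster ids as 32-bit integers. Little-endian only, C order only, which is
# what NumPy emits on every platform the sorters run on.
#
# 64-bit integers do not exist natively in R; they are decoded into doubles,
# exact for magnitudes up to 2^53 (~ 9.5 billion years of samples at 30 kHz).

NPY_MAGIC <- as.raw(c(0x93, 0x4E, 0x55, 0x4D, 0x50, 0x59)) # \x93NUMPY

#' Read a 1-D numeric NPY array
#'
#' Supports little-endian integer (1/2/4/8 byte, signed and unsigned) and
#' float (4/8 byte) dtypes, with shape `(n,)` or `(n, 1)`. Values are
#' returned as a double vector.
#'
#' @param path Path to a `.npy` file.
#' @return A double vector.
#' @keywords internal
read_npy <- function(path) {
  if (!file.exists(path)) nm_stop("missing_file", "NPY file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  magic <- readBin(con, "raw", 6L)
  if (length(magic) < 6L || !identical(magic, NPY_MAGIC)) {
    nm_stop("malformed_npy", "not an NPY file: %s", path)
  }
  ver <- readBin(con, "raw", 2L)
  if (as.integer(ver[1L]) == 1L) {
    hlen <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  } else {
    hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))

  descr <- regmatches(header, regexpr("'descr':\\s*'[^']+'", header))
  if (length(descr) != 1L) nm_stop("malformed_npy", "NPY header lacks descr: %s", path)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", descr)
  if (grepl(">", descr, fixed = TRUE)) {
    nm_stop("malformed_npy", "big-endian NPY not supported: %s", descr)
  }
  if (grepl("'fortran_order':\\s*True", header)) {
    nm_stop("malformed_npy", "fortran-order NPY not supported")
  }
  shape_txt <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.numeric(strsplit(gsub("\\s", "", shape_txt), ",")[[1]])
  dims <- dims[!is.na(dims)]
  if (length(dims) == 0L) dims <- 1           # 0-d scalar
  if (length(dims) > 1L && any(dims[-1L] != 1)) {
    nm_stop("malformed_npy", "only 1-D (or n x 1) arrays supported, got shape (%s)", shape_txt)
  }
  n <- prod(dims)

  kind <- sub("^[<|=]", "", descr)
  out <- switch(kind,
    "f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "i4" = as.double(readBin(con, "integer", n, size = 4L, endian = "little")),
    "i2" = as.double(readBin(con, "integer", n, size = 2L, endian = "little")),
    "i1" = as.double(readBin(con, "integer", n, size = 1L)),
    "u2" = as.double(readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "little")),
    "u1" = as.double(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "u4" = read_uint_wide(con, n, 4L),
    "u8" = read_uint_wide(con, n, 8L),
    "i8" = {
      v <- read_uint_wide(con, n, 8L)
      ifelse(v >= 2^63, v - 2^64, v)
    },
    nm_stop("malformed_npy", "unsupported NPY dtype: %s", descr)
  )
  if (length(out) != n) nm_stop("malformed_npy", "truncated NPY data in %s", path)
  out
}

# Decode n little-endian unsigned integers of `width` bytes into doubles.
read_uint_wide <- function(con, n, width) {
  if (n == 0) return(double(0))
  bytes <- readBin(con, "raw", n * width)
  if (length(bytes) != n * width) nm_stop("malformed_npy", "truncated NPY data")
  m <- matrix(as.numeric(bytes), nrow = width)
  as.vector(256^(seq_len(width) - 1) %*% m)
}

#' Write a numeric vector as a 1-D NPY array
#'
#' @param x Numeric vector. For integer dtypes values must be whole numbers
#'   within the dtype's range (and below 2^53 so doubles represent them
#'   exactly).
#' @param path Output path.
#' @param dtype One of `"float64"`, `"int64"`, `"uint64"`, `"int32"`.
#' @keywords internal
write_npy <- function(x, path, dtype = c("float64", "int64", "uint64", "int32")) {
  dtype <- match.arg(dtype)
  x <- as.double(x)
  n <- length(x)
  descr <- switch(dtype, float64 = "<f8", int64 = "<i8", uint64 = "<u8", int32 = "<i4")
  if (dtype != "float64") {
    if (any(x != trunc(x))) nm_stop("bad_value", "non-integer values for dtype %s", dtype)
    if (any(abs(x) >= 2^53)) nm_stop("bad_value", "values too large for exact integer encoding")
    if (dtype == "uint64" && any(x < 0)) nm_stop("bad_value", "negative values for uint64")
    if (dtype == "int32" && any(x < -2^31 | x >= 2^31)) {
      nm_stop("bad_value", "values out of int32 range")
    }
  }

  dict <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%d,), }", descr, n)
  # Pad with spaces so the full preamble (10 bytes + header) is 64-aligned,
  # terminating in a newline, per the NPY 1.0 spec.
  total <- 10L + nchar(dict) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(dict, strrep(" ", pad), "\n")

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(NPY_MAGIC, con)
  writeBin(as.raw(c(0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)

  if (dtype == "float64") {
    writeBin(x, con, size = 8L, endian = "little")
  } else if (dtype == "int32") {
    writeBin(as.integer(x), con, size = 4L, endian = "little")
  } else {
    v <- x
    if (dtype == "int64") v <- ifelse(v < 0, v + 2^64, v)
    bytes <- vapply(0:7, function(k) (v %/% 256^k) %% 256, numeric(n))
    if (n == 1L) bytes <- matrix(bytes, nrow = 1L)
    writeBin(as.raw(t(bytes)), con)
  }
  invisible(path)
}
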