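#' Minimal MAT-file reader and writer
#'
#' Reads and writes the subset of the MATLAB Level-5 MAT format needed for
#' SEED-style extracted-feature files: named numeric arrays of arbitrary
#' dimension. Three dialects are handled:
#'
#' * `"v5"` — uncompressed Level-5 elements;
#' * `"v7"` — Level-5 with zlib-compressed elements (the `-v7` default of
#'   MATLAB and `scipy.io.savemat(..., do_compression=True)`);
#' * `"v7.3"` — HDF5-based container (one dataset per variable), read and
#'   written through the rhdf5 package.
#'
#' The dialect is auto-detected on read from the file magic. Cell arrays,
#' structs, sparse and character matrices are out of scope and raise a format
#' error naming the offending file and variable.
#'
#' @param path file path.
#' @param vars named list of numeric vectors/matrices/arrays to write.
#' @param dialect one of `"v5"`, `"v7"`, `"v7.3"`.
#' @return `read_mat()` returns a named list of numeric arrays; `write_mat()`
#'   returns `path` invisibly.
#' @name mat_io
NULL

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L

pad8 <- function(n) (8L - n %% 8L) %% 8L

mat_element_raw <- function(name, a) {
  a <- as.array(a)
  dims <- dim(a)
  if (is.null(dims)) dims <- c(length(a), 1L)
  if (length(dims) == 1L) dims <- c(dims, 1L)
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  # array flags subelement: class double, no flags
  writeBin(c(MI_UINT32, 8L), con, size = 4L, endian = "little")
  writeBin(c(MX_DOUBLE, 0L), con, size = 4L, endian = "little")
  # dimensions
  nd <- length(dims)
  writeBin(c(MI_INT32, 4L * nd), con, size = 4L, endian = "little")
  writeBin(as.integer(dims), con, size = 4L, endian = "little")
  writeBin(raw(pad8(4L * nd)), con)
  # name
  nm <- charToRaw(name)
  writeBin(c(MI_INT8, length(nm)), con, size = 4L, endian = "little")
  writeBin(nm, con)
  writeBin(raw(pad8(length(nm))), con)
  # real part (double)
  writeBin(c(MI_DOUBLE, 8L * length(a)), con, size = 4L, endian = "little")
  writeBin(as.double(a), con, size = 8L, endian = "little")
  body <- rawConnectionValue(con)
  hdr <- writeBin(c(MI_MATRIX, length(body)), raw(), size = 4L, endian = "little")
  c(hdr, body)
}

#' @rdname mat_io
#' @export
write_mat <- function(path, vars, dialect = c("v5", "v7", "v7.3")) {
  dialect <- match.arg(dialect)
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  if (dialect == "v7.3") return(write_mat_hdf5(path, vars))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by tddann %s",
                  format(Sys.Date()))
  hdr <- raw(116L)
  db <- charToRaw(desc)
  hdr[seq_along(db)] <- db
  hdr[hdr == as.raw(0L)] <- charToRaw(" ")
  writeBin(hdr, con)
  writeBin(raw(8L), con)                       # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)         # version 0x0100, little-endian
  writeBin(charToRaw("IM"), con)               # endian indicator
  for (nm in names(vars)) {
    el <- mat_element_raw(nm, vars[[nm]])
    if (dialect == "v7") {
      z <- memCompress(el, type = "gzip")      # RFC-1950 zlib stream
      # compressed elements are the one element kind that is never padded
      writeBin(c(MI_COMPRESSED, length(z)), con, size = 4L, endian = "little")
      writeBin(z, con)
    } else {
      writeBin(el, con)
    }
  }
  invisible(path)
}

read_u32 <- function(r, off) {
  readBin(r[off + 1:4], "integer", size = 4L, endian = "little")
}

# parse one tag at byte offset `off` (0-based); returns list(type, nbytes,
# data_off, next_off) handling the packed small-element format
mat_read_tag <- function(r, off) {
  word1 <- read_u32(r, off)
  small_nbytes <- bitwAnd(bitwShiftR(word1, 16L), 0xFFFFL)
  if (small_nbytes != 0L) {
    type <- bitwAnd(word1, 0xFFFFL)
    list(type = type, nbytes = small_nbytes, data_off = off + 4L,
         next_off = off + 8L)
  } else {
    nbytes <- read_u32(r, off + 4L)
    list(type = word1, nbytes = nbytes, data_off = off + 8L,
         next_off = off + 8L + nbytes + pad8(nbytes))
  }
}

mat_numeric_payload <- function(r, type, nbytes, off, file, name) {
  sub <- r[off + seq_len(nbytes)]
  switch(as.character(type),
    "1" = as.double(readBin(sub, "integer", n = nbytes, size = 1L, signed = TRUE)),
    "2" = as.double(readBin(sub, "integer", n = nbytes, size = 1L, signed = FALSE)),
    "3" = as.double(readBin(sub, "integer", n = nbytes / 2L, size = 2L,
                            signed = TRUE, endian = "little")),
    "4" = as.double(readBin(sub, "integer", n = nbytes / 2L, size = 2L,
                            signed = FALSE, endian = "little")),
    "5" = as.double(readBin(sub, "integer", n = nbytes / 4L, size = 4L,
                            endian = "little")),
    "6" = as.double(readBin(sub, "integer", n = nbytes / 4L, size = 4L,
                            endian = "little")),
    "7" = as.double(readBin(sub, "double", n = nbytes / 4L, size = 4L,
                            endian = "little")),
    "9" = readBin(sub, "double", n = nbytes / 8L, size = 8L, endian = "little"),
    stop(sprintf("%s: variable '%s' uses unsupported MAT data type %d",
                 file, name, type), call. = FALSE))
}

mat_parse_matrix <- function(el, file) {
  # array flags
  tg <- mat_read_tag(el, 0L)
  if (tg$type != MI_UINT32 || tg$nbytes < 8L) {
    stop(sprintf("%s: malformed array-flags subelement", file), call. = FALSE)
  }
  flags <- read_u32(el, tg$data_off)
  cls <- bitwAnd(flags, 0xFFL)
  # dimensions
  tg2 <- mat_read_tag(el, tg$next_off)
  dims <- readBin(el[tg2$data_off + seq_len(tg2$nbytes)], "integer",
                  n = tg2$nbytes / 4L, size = 4L, endian = "little")
  # name
  tg3 <- mat_read_tag(el, tg2$next_off)
  name <- rawToChar(el[tg3$data_off + seq_len(tg3$nbytes)])
  if (!(cls %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8, MX_INT16,
                   MX_UINT16, MX_INT32, MX_UINT32))) {
    stop(sprintf("%s: variable '%s' has unsupported MAT class %d (only numeric arrays are handled)",
                 file, name, cls), call. = FALSE)
  }
  # real part
  tg4 <- mat_read_tag(el, tg3$next_off)
  vals <- mat_numeric_payload(el, tg4$type, tg4$nbytes, tg4$data_off, file, name)
  if (length(vals) != prod(dims)) {
    stop(sprintf("%s: variable '%s' has %d values for dimensions [%s]",
                 file, name, length(vals), paste(dims, collapse = "x")),
         call. = FALSE)
  }
  a <- array(vals, dim = dims)
  list(name = name, value = a)
}

#' @rdname mat_io
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop(sprintf("MAT file not found: %s", path), call. = FALSE)
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) >= 8L && identical(magic[1:4], as.raw(c(0x89, 0x48, 0x44, 0x46)))) {
    return(read_mat_hdf5(path))
  }
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 128L) {
    stop(sprintf("%s: too short to be a Level-5 MAT file", path), call. = FALSE)
  }
  endian <- rawToChar(r[127:128])
  if (endian != "IM") {
    stop(sprintf("%s: unsupported MAT endianness marker '%s'", path, endian),
         call. = FALSE)
  }
  out <- list()
  off <- 128L
  n <- length(r)
  while (off + 8L <= n) {
    if (read_u32(r, off) == 0L) { off <- off + 4L; next }  # stray padding
    tg <- mat_read_tag(r, off)
    if (tg$type == MI_COMPRESSED) {
      el <- memDecompress(r[tg$data_off + seq_len(tg$nbytes)], type = "gzip")
      itg <- mat_read_tag(el, 0L)
      if (itg$type != MI_MATRIX) {
        stop(sprintf("%s: compressed element is not a matrix", path), call. = FALSE)
      }
      parsed <- mat_parse_matrix(el[itg$data_off + seq_len(itg$nbytes)], path)
      out[[parsed$name]] <- parsed$value
    } else if (tg$type == MI_MATRIX) {
      parsed <- mat_parse_matrix(r[tg$data_off + seq_len(tg$nbytes)], path)
      out[[parsed$name]] <- parsed$value
    }
    # other top-level element types are skipped
    off <- if (tg$type == MI_COMPRESSED) tg$data_off + tg$nbytes else tg$next_off
  }
  out
}

write_mat_hdf5 <- function(path, vars) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the v7.3 MAT dialect requires the rhdf5 package", call. = FALSE)
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (nm in names(vars)) {
    a <- as.array(vars[[nm]])
    rhdf5::h5write(a, path, nm)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

read_mat_hdf5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("reading HDF5 (v7.3) MAT files requires the rhdf5 package", call. = FALSE)
  }
  info <- rhdf5::h5ls(path)
  dsets <- info$name[info$otype == "H5I_DATASET" & info$group == "/"]
  out <- lapply(dsets, function(nm) {
    v <- rhdf5::h5read(path, nm)
    storage.mode(v) <- "double"
    as.array(v)
  })
  rhdf5::h5closeAll()
  names(out) <- dsets
  out
}
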