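# Minimal reader for MATLAB level-5 MAT-files.
#
# Supports the element types needed to ingest deposited tabular source data:
# numeric arrays (double/single/integer classes), logical, character arrays,
# cell arrays and structs, plus zlib-compressed data elements. Written in R
# because no MAT-file reader is available among the package's dependencies;
# cross-checked in the test suite against files produced by an independent
# writer. MAT v7.3 files are HDF5 containers and are rejected with a clear
# error.

MI_TYPES <- c("miINT8", "miUINT8", "miINT16", "miUINT16", "miINT32",
              "miUINT32", "miSINGLE", NA, "miDOUBLE", NA, NA, "miINT64",
              "miUINT64", "miMATRIX", "miCOMPRESSED", "miUTF8", "miUTF16",
              "miUTF32")

MX_CLASSES <- c("cell", "struct", "object", "char", "sparse", "double",
                "single", "int8", "uint8", "int16", "uint16", "int32",
                "uint32", "int64", "uint64")

#' Read a MATLAB level-5 MAT-file
#'
#' Parses numeric, logical and character arrays, cell arrays and structs from
#' a (possibly zlib-compressed) MAT v5 file into R objects: numeric arrays
#' become vectors/matrices/arrays, char arrays become character vectors (one
#' element per row), cells become lists and structs named lists.
#'
#' @param path Path to the `.mat` file.
#' @return Named list of the file's top-level variables.
#' @export
read_mat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 128)
  if (length(header) < 128) stopf("not a MAT v5 file: %s", path)
  if (identical(rawToChar(header[1:8]), "\x89HDF\r\n\x1a\n") ||
      identical(rawToChar(header[1:4]), "\x89HDF")) {
    stopf("'%s' is a MAT v7.3 (HDF5) file, which this reader does not support; convert it to v5 or CSV", path)
  }
  endian_tag <- rawToChar(header[127:128])
  endian <- if (endian_tag == "IM") "little" else if (endian_tag == "MI") "big" else
    stopf("'%s' does not look like a MAT v5 file (bad endian tag)", path)
  raw_all <- readBin(con, "raw", file.size(path))
  env <- new.env()
  env$vars <- list()
  parse_elements(raw_all, endian, function(name, value) {
    env$vars[[name %||% paste0("var", length(env$vars) + 1)]] <- value
  })
  env$vars
}

# Walk top-level data elements of a raw buffer.
parse_elements <- function(buf, endian, emit) {
  pos <- 1L
  n <- length(buf)
  while (pos + 7L <= n) {
    hd <- parse_tag(buf, pos, endian)
    if (!length(hd$type) || is.na(hd$type) || hd$type < 1 || hd$type > length(MI_TYPES)) {
      stopf("malformed MAT element at byte offset %d", pos)
    }
    tname <- MI_TYPES[hd$type]
    if (identical(tname, "miCOMPRESSED")) {
      payload <- buf[(pos + 8L):(pos + 7L + hd$nbytes)]
      inflated <- memDecompress(payload, type = "gzip")
      parse_elements(inflated, endian, emit)
      # compressed elements are not padded to the 8-byte boundary
      pos <- pos + hd$hdr + hd$nbytes
    } else {
      if (identical(tname, "miMATRIX") && hd$nbytes > 0) {
        el <- parse_matrix(buf[(pos + hd$hdr):(pos + hd$hdr - 1L + hd$nbytes)], endian)
        emit(el$name, el$value)
      }
      pos <- pos + hd$hdr + hd$nbytes + pad8(hd$nbytes, hd$small)
    }
  }
}

pad8 <- function(nbytes, small) {
  if (small) 0L else (8L - nbytes %% 8L) %% 8L
}

int_at <- function(buf, pos, size, endian, signed = TRUE) {
  readBin(buf[pos:(pos + size - 1L)], "integer", n = 1L, size = size,
          endian = endian, signed = signed)
}

# Parse an element tag at pos; returns type, nbytes, header size, small flag.
# The small-data-element format stores nbytes in the upper 16 bits of the
# type word, i.e. in the second uint16 of a little-endian file (first of a
# big-endian one).
parse_tag <- function(buf, pos, endian) {
  h1 <- readBin(buf[pos:(pos + 1L)], "integer", 1L, 2L, signed = FALSE,
                endian = endian)
  h2 <- readBin(buf[(pos + 2L):(pos + 3L)], "integer", 1L, 2L, signed = FALSE,
                endian = endian)
  small_n <- if (endian == "little") h2 else h1
  type16 <- if (endian == "little") h1 else h2
  if (small_n != 0L) {
    list(type = type16, nbytes = small_n, hdr = 4L, small = TRUE)
  } else {
    list(type = int_at(buf, pos, 4L, endian),
         nbytes = int_at(buf, pos + 4L, 4L, endian), hdr = 8L, small = FALSE)
  }
}

# Read the data of a subelement starting at pos; returns value and next pos.
read_subelement <- function(buf, pos, endian) {
  tag <- parse_tag(buf, pos, endian)
  dat <- if (tag$nbytes > 0) {
    buf[(pos + tag$hdr):(pos + tag$hdr - 1L + tag$nbytes)]
  } else raw(0)
  adv <- tag$hdr + tag$nbytes +
    if (tag$small) (4L - tag$nbytes %% 4L) %% 4L else pad8(tag$nbytes, FALSE)
  # small elements pad to the 8-byte boundary of the whole (tag+data) block
  if (tag$small) adv <- 8L
  list(type = tag$type, data = dat, next_pos = pos + adv)
}

decode_numeric <- function(type, data, endian) {
  tn <- MI_TYPES[type]
  switch(tn,
    miINT8   = readBin(data, "integer", length(data), 1, signed = TRUE, endian = endian),
    miUINT8  = readBin(data, "integer", length(data), 1, signed = FALSE, endian = endian),
    miINT16  = readBin(data, "integer", length(data) / 2, 2, signed = TRUE, endian = endian),
    miUINT16 = readBin(data, "integer", length(data) / 2, 2, signed = FALSE, endian = endian),
    miINT32  = readBin(data, "integer", length(data) / 4, 4, endian = endian),
    miUINT32 = readBin(data, "integer", length(data) / 4, 4, endian = endian),
    miSINGLE = readBin(data, "numeric", length(data) / 4, 4, endian = endian),
    miDOUBLE = readBin(data, "numeric", length(data) / 8, 8, endian = endian),
    miINT64  = as.numeric(readBin(data, "integer", length(data) / 8, 8, endian = endian)),
    miUINT64 = as.numeric(readBin(data, "integer", length(data) / 8, 8, endian = endian)),
    miUTF8   = rawToChar(data),
    stopf("unsupported MAT data type %s", tn %||% type)
  )
}

# Parse one miMATRIX payload (without its outer tag).
parse_matrix <- function(buf, endian) {
  pos <- 1L
  flags <- read_subelement(buf, pos, endian); pos <- flags$next_pos
  fl <- readBin(flags$data[1:4], "integer", 1, 4, endian = endian)
  cls <- bitwAnd(fl, 255L)
  class_name <- MX_CLASSES[cls]
  dims_el <- read_subelement(buf, pos, endian); pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) / 4, 4,
                  endian = endian)
  name_el <- read_subelement(buf, pos, endian); pos <- name_el$next_pos
  name <- if (length(name_el$data)) rawToChar(name_el$data) else NULL

  if (is.na(class_name)) stopf("unsupported MAT array class code %d", cls)
  value <- switch(class_name,
    cell = {
      cells <- vector("list", prod(dims))
      for (i in seq_along(cells)) {
        el <- read_subelement(buf, pos, endian); pos <- el$next_pos
        cells[[i]] <- if (length(el$data)) parse_matrix(el$data, endian)$value else NULL
      }
      if (length(dims) == 2 && dims[1] == 1) cells else
        structure(cells, dim = dims)
    },
    struct = {
      fl_len <- read_subelement(buf, pos, endian); pos <- fl_len$next_pos
      flen <- decode_numeric(fl_len$type, fl_len$data, endian)[1]
      fn_el <- read_subelement(buf, pos, endian); pos <- fn_el$next_pos
      nf <- length(fn_el$data) / flen
      fields <- vapply(seq_len(nf), function(i) {
        chunk <- fn_el$data[((i - 1) * flen + 1):(i * flen)]
        rawToChar(chunk[chunk != as.raw(0)])
      }, character(1))
      out <- stats::setNames(vector("list", nf), fields)
      for (i in seq_len(nf)) {
        el <- read_subelement(buf, pos, endian); pos <- el$next_pos
        out[[i]] <- if (length(el$data)) parse_matrix(el$data, endian)$value else NULL
      }
      out
    },
    char = {
      el <- read_subelement(buf, pos, endian); pos <- el$next_pos
      chars <- if (MI_TYPES[el$type] == "miUTF8") {
        strsplit(rawToChar(el$data), "")[[1]]
      } else {
        ints <- decode_numeric(el$type, el$data, endian)
        vapply(ints, function(i) intToUtf8(i), character(1))
      }
      m <- matrix(chars, nrow = dims[1], ncol = dims[2])
      apply(m, 1, function(r) trimws(paste(r, collapse = ""), "right"))
    },
    sparse = stopf("sparse MAT arrays are not supported"),
    { # numeric / logical classes
      el <- read_subelement(buf, pos, endian); pos <- el$next_pos
      v <- as.numeric(decode_numeric(el$type, el$data, endian))
      if (length(dims) > 2 || (length(dims) == 2 && dims[2] > 1 && dims[1] > 1)) {
        structure(v, dim = dims)
      } else v
    }
  )
  list(name = name, value = value)
}
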