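#' Read a NumPy `.npy` array file
#'
#' Minimal reader for the `.npy` format (versions 1.0/2.0, little-endian
#' numeric dtypes) used by the MRNet volume layout. Data stored in C order
#' are permuted into R's column-major convention, so `dim()` of the result
#' equals the NumPy shape.
#'
#' @param path File path.
#' @return A numeric array with the stored shape.
#' @seealso [write_npy()]
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop("not a .npy file: ", path)
  }
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  hlen <- if (ver[1] >= 2) {
    readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))

  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_str <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  if (length(shape) == 0) shape <- integer(0)

  n <- if (length(shape)) prod(shape) else 1L
  dat <- switch(descr,
    "<f8" = , "=f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<f4" = , "=f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "|u1" = , "<u1" = readBin(con, "integer", n, size = 1, signed = FALSE),
    "|i1" = readBin(con, "integer", n, size = 1, signed = TRUE),
    "<i2" = readBin(con, "integer", n, size = 2, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    stop("unsupported .npy dtype: ", descr)
  )
  dat <- as.double(dat)
  if (length(shape) <= 1) {
    return(dat)
  }
  if (fortran) {
    array(dat, dim = shape)
  } else {
    aperm(array(dat, dim = rev(shape)), rev(seq_along(shape)))
  }
}

#' Write a NumPy `.npy` array file
#'
#' Writes an R numeric array as a C-ordered `.npy` (format 1.0) so the file
#' round-trips with `numpy.load`.
#'
#' @param x Numeric array (or vector).
#' @param path Destination path.
#' @param dtype One of `"float32"`, `"float64"`, `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path, dtype = c("float32", "float64", "uint8")) {
  dtype <- match.arg(dtype)
  shape <- dim(x)
  if (is.null(shape)) shape <- length(x)
  descr <- switch(dtype, float32 = "<f4", float64 = "<f8", uint8 = "|u1")
  shape_str <- if (length(shape) == 1) paste0("(", shape, ",)") else
    paste0("(", paste(shape, collapse = ", "), ")")
  dict <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                  descr, shape_str)
  # pad header so that 10 + length is a multiple of 64, ending in newline
  total <- 10L + nchar(dict) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(dict, strrep(" ", pad), "\n")

  vals <- if (length(shape) > 1) as.vector(aperm(x, rev(seq_along(shape)))) else as.vector(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  switch(dtype,
    float32 = writeBin(vals, con, size = 4, endian = "little"),
    float64 = writeBin(vals, con, size = 8, endian = "little"),
    uint8 = writeBin(as.integer(round(vals)), con, size = 1)
  )
  invisible(path)
}
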