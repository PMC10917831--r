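# Minimal NRRD volume I/O (attached header, raw or gzip encoding), enough
# for annotation/template volumes on the 10 um grid. Little-endian only.

nrrd_types <- c(
  "uint8" = "integer", "int16" = "integer", "uint16" = "integer",
  "int32" = "integer", "float" = "double", "double" = "double"
)
nrrd_sizes <- c(
  "uint8" = 1L, "int16" = 2L, "uint16" = 2L,
  "int32" = 4L, "float" = 4L, "double" = 8L
)

#' Read a 3D NRRD volume
#'
#' Supports attached-header NRRD with `raw` or `gzip` encoding and
#' little-endian scalar types uint8/int16/uint16/int32/float/double.
#'
#' @param path NRRD file.
#' @return A numeric or integer 3D array.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1, warn = FALSE)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":\\s*")[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  type <- fields[["type"]]
  if (type %in% c("unsigned char")) type <- "uint8"
  if (type %in% c("int", "signed int")) type <- "int32"
  if (!type %in% names(nrrd_types)) stop("unsupported NRRD type: ", type)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (as.integer(fields[["dimension"]]) != 3 || length(sizes) != 3) {
    stop("only 3D NRRD volumes are supported")
  }
  n <- prod(sizes)
  enc <- fields[["encoding"]]
  payload <- readBin(con, "raw", n = file.size(path))
  if (identical(enc, "gzip")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (!identical(enc, "raw")) {
    stop("unsupported NRRD encoding: ", enc)
  }
  what <- nrrd_types[[type]]
  sz <- nrrd_sizes[[type]]
  signed <- !type %in% c("uint8", "uint16")
  vals <- readBin(payload, what = what, n = n, size = sz,
                  signed = if (sz < 4) signed else TRUE, endian = "little")
  if (length(vals) != n) stop("NRRD payload shorter than header sizes imply")
  array(vals, dim = sizes)
}

#' Write a 3D NRRD volume
#'
#' @param vol 3D array.
#' @param path output file.
#' @param type NRRD scalar type; defaults to `int32` for integer data and
#'   `double` otherwise.
#' @param encoding `"gzip"` (default) or `"raw"`.
#' @export
write_nrrd <- function(vol, path, type = NULL,
                       encoding = c("gzip", "raw")) {
  stopifnot(length(dim(vol)) == 3)
  encoding <- match.arg(encoding)
  if (is.null(type)) type <- if (is.integer(vol)) "int32" else "double"
  if (!type %in% names(nrrd_types)) stop("unsupported NRRD type: ", type)
  sz <- nrrd_sizes[[type]]
  what <- nrrd_types[[type]]
  vals <- if (what == "integer") as.integer(vol) else as.double(vol)
  payload <- writeBin(vals, raw(), size = sz, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(vol), collapse = " ")),
    "endian: little",
    paste0("encoding: ", encoding),
    ""
  )
  writeLines(header, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}

read_volume <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "nrrd") return(read_nrrd(path))
  if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI volumes requires the RNifti package")
    }
    a <- RNifti::readNifti(path)
    return(array(as.numeric(a), dim = dim(a)))
  }
  stop("unsupported volume format: ", path)
}
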