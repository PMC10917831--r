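#' Assign anterior-to-posterior section ordinals
#'
#' Suffixes each filename stem with `s` plus a zero-padded three-digit
#' ordinal in the given order, e.g. the first section becomes `..._s001`.
#' The input order is the user-asserted anterior-to-posterior order.
#'
#' @param filenames ordered character vector of section image filenames.
#' @return Data frame with `filename`, `ordinal` and the derived `stem`.
#' @export
assign_ordinals <- function(filenames) {
  if (length(filenames) == 0) stop("empty section series")
  if (anyDuplicated(filenames)) {
    stop("duplicate filenames: ",
         paste(unique(filenames[duplicated(filenames)]), collapse = ", "))
  }
  ord <- seq_along(filenames)
  base <- tools::file_path_sans_ext(basename(filenames))
  data.frame(
    filename = filenames,
    ordinal = ord,
    stem = sprintf("%s_s%03d", base, ord),
    stringsAsFactors = FALSE
  )
}

#' Series-wide downsampling factor
#'
#' Every section of a series is subsampled by the same factor n (keep every
#' n-th pixel per axis) so that each image ends below the 16-megapixel input
#' bound of the anchoring tools. Per image the factor is
#' `ceiling(sqrt(height * width / 15e6))`; the series factor is the highest
#' value over its sections, floored at 1. So a series where rostral
#' sections could keep 1 of 4 pixels but a caudal one only 1 of 5 is
#' downsampled at 1 of 5 throughout.
#'
#' @param series_dims list of `c(height, width)` pixel dimensions, or an
#'   n x 2 matrix.
#' @param pixel_budget target maximum pixel count (15e6 by default).
#' @return Integer downsampling factor n >= 1.
#' @export
downsample_factor <- function(series_dims, pixel_budget = 15e6) {
  if (is.matrix(series_dims)) {
    series_dims <- lapply(seq_len(nrow(series_dims)), function(i) series_dims[i, ])
  }
  if (length(series_dims) == 0) stop("empty section series")
  per <- vapply(series_dims, function(d) {
    stopifnot(length(d) == 2, all(d > 0))
    ceiling(sqrt(prod(as.numeric(d)) / pixel_budget))
  }, numeric(1))
  as.integer(max(1, per))
}

orientation_ops <- c(
  "rotate90", "rotate180", "rotate270", "mirror_horizontal", "mirror_vertical"
)

apply_orientation <- function(m, op) {
  switch(op,
    rotate90 = t(m[nrow(m):1, , drop = FALSE]),         # 90 deg clockwise
    rotate180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    rotate270 = t(m)[ncol(m):1, , drop = FALSE],
    mirror_horizontal = m[, ncol(m):1, drop = FALSE],
    mirror_vertical = m[nrow(m):1, , drop = FALSE],
    stop("unknown orientation op: ", op)
  )
}

#' Downsample and re-orient a section image
#'
#' Subsamples by keeping every n-th pixel per axis starting at pixel (0,0),
#' then applies the user-declared orientation fixes in order. Rotations are
#' clockwise; `mirror_horizontal` flips left-right, `mirror_vertical`
#' top-bottom.
#'
#' @param pixels 2D image matrix (rows = image height).
#' @param n integer subsampling factor from [downsample_factor()].
#' @param ops character vector of orientation operations (possibly empty).
#' @return The preprocessed image matrix.
#' @export
preprocess_section <- function(pixels, n = 1, ops = character(0)) {
  stopifnot(is.matrix(pixels), n >= 1)
  bad <- setdiff(ops, orientation_ops)
  if (length(bad) > 0) stop("unknown orientation op: ", paste(bad, collapse = ", "))
  out <- pixels[seq(1, nrow(pixels), by = n), seq(1, ncol(pixels), by = n),
                drop = FALSE]
  for (op in ops) out <- apply_orientation(out, op)
  out
}

#' Read a grayscale section image
#'
#' Reads PNG (and TIFF when the tiff package is installed) into a numeric
#' matrix; RGB(A) inputs are collapsed to their first channel.
#'
#' @param path image file.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_section_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the tiff package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
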