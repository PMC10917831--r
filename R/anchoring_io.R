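#' Per-section anchoring vectors
#'
#' A section anchor places a 2D section image as a plane in the reference
#' volume: `o` is the reference-space position (voxel units) of the image's
#' top-left pixel, `u` spans the full image width and `v` the full height.
#' Pixel `p = (px, py)` (x rightward, y downward, measured from the
#' top-left corner) maps to `o + (px / width) * u + (py / height) * v`.
#'
#' @param o,u,v numeric 3-vectors in voxel units.
#' @param width_px,height_px pixel dimensions the anchor was produced for.
#' @param stem section stem the anchor belongs to.
#' @return A `section_anchor` object.
#' @export
section_anchor <- function(o, u, v, width_px, height_px, stem = NULL) {
  stopifnot(length(o) == 3, length(u) == 3, length(v) == 3,
            width_px > 0, height_px > 0)
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  if (sqrt(sum(cr^2)) < 1e-12) stop("anchoring vectors u and v are parallel")
  structure(
    list(o = as.numeric(o), u = as.numeric(u), v = as.numeric(v),
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         stem = stem),
    class = "section_anchor"
  )
}

anchor_scalar_names <- c("ox", "oy", "oz", "ux", "uy", "uz", "vx", "vy", "vz")

# Field-name dialect table; override entries to absorb upstream version drift.
default_anchoring_dialect <- function() {
  list(
    slice = "slice", filename = "filename", width = "width",
    height = "height", anchoring = "anchoring", markers = "markers"
  )
}

stem_of_filename <- function(filename) {
  m <- regmatches(filename, regexpr(".*_s[0-9]{3}", basename(filename)))
  if (length(m) == 1) m else tools::file_path_sans_ext(basename(filename))
}

#' Read linear anchoring (QuickNII-dialect XML)
#'
#' Parses a `<series>` of `<slice>` elements, each carrying `filename`,
#' `width`, `height` and the nine anchoring scalars `ox..vz` as attributes.
#'
#' @param path XML file.
#' @param dialect field-name table, see `default_anchoring_dialect()`.
#' @return Named list of [section_anchor()]s keyed by section stem.
#' @export
read_linear_anchoring <- function(path, dialect = default_anchoring_dialect()) {
  doc <- xml2::read_xml(path)
  slices <- xml2::xml_find_all(doc, paste0(".//", dialect$slice))
  out <- list()
  for (sl in slices) {
    fn <- xml2::xml_attr(sl, dialect$filename)
    vals <- vapply(anchor_scalar_names, function(nm) {
      s <- xml2::xml_attr(sl, nm)
      if (is.na(s)) stop(sprintf("slice '%s': missing anchoring scalar '%s'", fn, nm))
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop(sprintf("slice '%s': unparseable scalar '%s'='%s'", fn, nm, s))
      v
    }, numeric(1))
    w <- as.integer(xml2::xml_attr(sl, dialect$width))
    h <- as.integer(xml2::xml_attr(sl, dialect$height))
    if (is.na(w) || is.na(h)) stop(sprintf("slice '%s': missing width/height", fn))
    stem <- stem_of_filename(fn)
    if (!is.null(out[[stem]])) stop("stem collision in anchoring file: ", stem)
    out[[stem]] <- section_anchor(vals[1:3], vals[4:6], vals[7:9], w, h, stem)
  }
  out
}

#' Write linear anchoring (QuickNII-dialect XML)
#'
#' Scalars are serialized with 17 significant digits so a write/read
#' round-trip is bit-faithful.
#'
#' @param anchors named list of [section_anchor()]s.
#' @param path output XML file.
#' @export
write_linear_anchoring <- function(anchors, path) {
  doc <- xml2::xml_new_root("series")
  for (stem in names(anchors)) {
    a <- anchors[[stem]]
    attrs <- c(
      filename = paste0(stem, ".png"),
      width = as.character(a$width_px), height = as.character(a$height_px),
      stats::setNames(sprintf("%.17g", c(a$o, a$u, a$v)), anchor_scalar_names)
    )
    node <- xml2::xml_add_child(doc, "slice")
    for (nm in names(attrs)) xml2::xml_set_attr(node, nm, attrs[[nm]])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read nonlinear anchoring (VisuAlign-dialect JSON)
#'
#' The JSON dialect mirrors the XML one: per-slice `filename`, `width`,
#' `height`, an `anchoring` array of the nine scalars `ox..vz`, plus a
#' `markers` array of `[section_x, section_y, template_x, template_y]`
#' rows giving corresponding points in the section's pixel frame.
#'
#' @param path JSON file.
#' @param dialect field-name table.
#' @return Named list keyed by stem; each element has `$anchor`
#'   ([section_anchor()]) and `$markers` (m x 4 numeric matrix, possibly
#'   zero rows).
#' @export
read_nonlinear_anchoring <- function(path, dialect = default_anchoring_dialect()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  slices <- doc$slices %||% doc
  out <- list()
  for (sl in slices) {
    fn <- sl[[dialect$filename]] %||% "<unnamed>"
    anch <- unlist(sl[[dialect$anchoring]])
    if (length(anch) != 9 || anyNA(suppressWarnings(as.numeric(anch)))) {
      stop(sprintf("slice '%s': anchoring must hold 9 numeric scalars", fn))
    }
    anch <- as.numeric(anch)
    w <- sl[[dialect$width]]
    h <- sl[[dialect$height]]
    if (is.null(w) || is.null(h)) stop(sprintf("slice '%s': missing width/height", fn))
    mk <- sl[[dialect$markers]] %||% list()
    markers <- if (length(mk) == 0) {
      matrix(numeric(0), 0, 4)
    } else {
      do.call(rbind, lapply(mk, function(r) as.numeric(unlist(r))))
    }
    if (ncol(markers) != 4 && nrow(markers) > 0) {
      stop(sprintf("slice '%s': markers must be 4-column rows", fn))
    }
    if (nrow(markers) > 0) {
      key <- paste(markers[, 1], markers[, 2])
      if (anyDuplicated(key)) stop(sprintf("slice '%s': duplicated marker section points", fn))
    }
    colnames(markers) <- c("sx", "sy", "tx", "ty")
    stem <- stem_of_filename(fn)
    if (!is.null(out[[stem]])) stop("stem collision in anchoring file: ", stem)
    out[[stem]] <- list(
      anchor = section_anchor(anch[1:3], anch[4:6], anch[7:9], w, h, stem),
      markers = markers
    )
  }
  out
}

#' Write nonlinear anchoring (VisuAlign-dialect JSON)
#'
#' @param slices named list as returned by [read_nonlinear_anchoring()].
#' @param path output JSON file.
#' @export
write_nonlinear_anchoring <- function(slices, path) {
  payload <- list(slices = lapply(names(slices), function(stem) {
    s <- slices[[stem]]
    a <- s$anchor
    list(
      filename = paste0(stem, ".png"),
      width = a$width_px, height = a$height_px,
      anchoring = c(a$o, a$u, a$v),
      markers = if (nrow(s$markers) == 0) list() else
        lapply(seq_len(nrow(s$markers)), function(i) unname(s$markers[i, ]))
    )
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Evaluate the linear pixel-to-reference transform
#'
#' `p -> o + (px / width) * u + (py / height) * v`, the affine form that
#' converts section pixel coordinates to continuous 3D reference
#' coordinates in voxel units.
#'
#' @param anchor a [section_anchor()].
#' @param p length-2 pixel coordinate or n x 2 matrix, in
#'   `[0, width] x [0, height]`.
#' @param image_dims `c(width, height)` of the image being mapped; defaults
#'   to the anchor's own geometry.
#' @return n x 3 matrix of reference coordinates (a plain vector when `p`
#'   was a single coordinate).
#' @export
linear_pixel_to_ccf <- function(anchor, p, image_dims = NULL) {
  if (is.null(image_dims)) image_dims <- c(anchor$width_px, anchor$height_px)
  if (any(image_dims <= 0)) stop("zero-sized image")
  single <- !is.matrix(p)
  if (single) p <- matrix(as.numeric(p), 1, 2)
  fx <- p[, 1] / image_dims[1]
  fy <- p[, 2] / image_dims[2]
  out <- cbind(
    anchor$o[1] + fx * anchor$u[1] + fy * anchor$v[1],
    anchor$o[2] + fx * anchor$u[2] + fy * anchor$v[2],
    anchor$o[3] + fx * anchor$u[3] + fy * anchor$v[3]
  )
  if (single) as.numeric(out[1, ]) else out
}
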