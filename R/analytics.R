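layer_bins <- c("1", "2/3", "4", "5", "6a", "6b")

#' Laminar distribution of axonal segments within a cortical area
#'
#' For the target (axon) voxels of a population that fall within the named
#' area, pixel counts are summed per cortical layer and normalized to 100%
#' across layers, giving the percentage of axonal segments per layer for
#' that population. Counts landing in in-area regions without a layer tag
#' are reported in a `"none"` row and included in the normalization.
#' Groupings such as "layer 5 or 6" are obtained downstream by summing
#' bins.
#'
#' @param record a [population_record()].
#' @param space a [reference_space()].
#' @param hier a [region_hierarchy()]; defaults to the space's own.
#' @param area_acronym cortical area acronym.
#' @return Data frame with `layer`, `count`, `percent` (six layer rows,
#'   plus `"none"` when nonzero). With zero in-area axon count, all
#'   percentages are zero and a warning is raised.
#' @export
layer_distribution <- function(record, space, hier = space$hierarchy,
                               area_acronym) {
  region_id_of(hier, area_acronym)
  tgt <- record$target
  counts <- stats::setNames(numeric(length(layer_bins)), layer_bins)
  none <- 0
  if (nrow(tgt$coords) > 0) {
    ids <- region_at(space, tgt$coords)
    keep <- ids != 0 & is_within(hier, ids, area_acronym)
    if (any(keep)) {
      tags <- layer_tag_of(hier, ids[keep])
      cs <- tgt$counts[keep]
      for (b in layer_bins) counts[b] <- sum(cs[!is.na(tags) & tags == b])
      none <- sum(cs[is.na(tags)])
    }
  }
  total <- sum(counts) + none
  if (total == 0) {
    warning("no axonal segments within ", area_acronym)
    pct <- counts
  } else {
    pct <- 100 * counts / total
  }
  out <- data.frame(layer = layer_bins, count = as.numeric(counts),
                    percent = as.numeric(pct), stringsAsFactors = FALSE)
  if (none > 0) {
    out <- rbind(out, data.frame(layer = "none", count = none,
                                 percent = 100 * none / total))
  }
  out
}

axis_index <- function(axis) {
  switch(axis, coronal = 1L, horizontal = 2L, sagittal = 3L,
         stop("axis must be one of coronal, sagittal, horizontal"))
}

#' Maximum-projection subcortical view
#'
#' Builds the three overlaid layers of a maximum-projection plot along the
#' chosen anatomical plane: the per-pixel maximum of the gray-matter
#' template as background, black contour lines where projected region
#' labels differ (delineating nucleus borders), and the per-pixel maximum
#' of the population's soma counts as overlay. Projected labels are the
#' maximum region id along the axis among voxels inside `scope_acronym`'s
#' subtree (0 elsewhere), which confines the contours to the nuclei of
#' interest.
#'
#' @param record a [population_record()].
#' @param space a [reference_space()].
#' @param hier a [region_hierarchy()]; defaults to the space's own.
#' @param axis `"coronal"` (project along x), `"sagittal"` (along z) or
#'   `"horizontal"` (along y).
#' @param scope_acronym subtree whose labels are projected for the contour
#'   layer; defaults to the hierarchy root.
#' @return List with `background`, `labels`, `contours` (logical) and
#'   `soma` matrices over the in-plane axes (remaining axes in x, y, z
#'   order).
#' @export
max_projection <- function(record, space, hier = space$hierarchy,
                           axis = c("coronal", "sagittal", "horizontal"),
                           scope_acronym = NULL) {
  axis <- match.arg(axis)
  ax <- axis_index(axis)
  keep_axes <- setdiff(1:3, ax)
  background <- apply(space$template, keep_axes, max)
  ann <- space$annotation
  if (!is.null(scope_acronym)) {
    ids <- region_subtree(hier, scope_acronym)
    ann <- array(ifelse(ann %in% ids, ann, 0L), dim = dim(ann))
  }
  labels <- apply(ann, keep_axes, max)
  nr <- nrow(labels); nc <- ncol(labels)
  contours <- matrix(FALSE, nr, nc)
  if (nr > 1) {
    d <- labels[-1, , drop = FALSE] != labels[-nr, , drop = FALSE]
    contours[-1, ] <- contours[-1, ] | d
    contours[-nr, ] <- contours[-nr, ] | d
  }
  if (nc > 1) {
    d <- labels[, -1, drop = FALSE] != labels[, -nc, drop = FALSE]
    contours[, -1] <- contours[, -1] | d
    contours[, -nc] <- contours[, -nc] | d
  }
  soma <- matrix(0, nr, nc)
  src <- record$source
  if (nrow(src$coords) > 0) {
    ij <- src$coords[, keep_axes, drop = FALSE] + 1
    for (k in seq_len(nrow(ij))) {
      soma[ij[k, 1], ij[k, 2]] <- max(soma[ij[k, 1], ij[k, 2]], src$counts[k])
    }
  }
  list(background = background, labels = labels, contours = contours,
       soma = soma, axis = axis)
}

region_fill_colors <- function(hier) {
  ids <- sort(hier$id)
  stats::setNames(grDevices::hcl(
    h = (seq_along(ids) * 137.50776) %% 360, c = 40, l = 80
  ), ids)
}

svg_rect <- function(x, y, w, h, fill) {
  sprintf('<rect x="%g" y="%g" width="%g" height="%g" fill="%s"/>', x, y, w, h, fill)
}

#' Atlas-overlay SVG for one registered segmented section
#'
#' Reconstructs the template section the anchor addresses (each anatomical
#' region filled with its colour), delineates region boundaries in black,
#' and overlays the warped segmented pixels in black. Swapping `space` for
#' one holding an alternative parcellation on the same grid (e.g.
#' EUAL-style instead of ARA-style) changes only colours and boundaries,
#' never the geometry.
#'
#' @param seg label matrix over `{0, 129, 255}`.
#' @param anchor a [section_anchor()].
#' @param warp a [build_warp()] field.
#' @param space a [reference_space()] carrying the parcellation to draw.
#' @param hier a [region_hierarchy()]; defaults to the space's own.
#' @param path optional output file for the SVG document.
#' @param step pixel sampling step for the template raster (SVG size
#'   control).
#' @return The SVG document as a character string (invisibly when written
#'   to `path`).
#' @export
atlas_overlay_svg <- function(seg, anchor, warp, space, hier = space$hierarchy,
                              path = NULL, step = 1) {
  w <- anchor$width_px; h <- anchor$height_px
  xs <- seq(0, w - 1, by = step) + step / 2
  ys <- seq(0, h - 1, by = step) + step / 2
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  cc <- linear_pixel_to_ccf(anchor, grid, c(w, h))
  vox <- floor(cc)
  inb <- vox[, 1] >= 0 & vox[, 1] < space$dims[1] &
    vox[, 2] >= 0 & vox[, 2] < space$dims[2] &
    vox[, 3] >= 0 & vox[, 3] < space$dims[3]
  ids <- integer(nrow(vox))
  ids[inb] <- region_at(space, vox[inb, , drop = FALSE])
  idmat <- matrix(ids, length(xs), length(ys))  # [ix, iy]
  cols <- region_fill_colors(hier)
  parts <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    w, h, w, h
  ))
  # region fill, run-length encoded per raster row
  for (iy in seq_along(ys)) {
    rowids <- idmat[, iy]
    r <- rle(rowids)
    x0 <- 0
    for (k in seq_along(r$lengths)) {
      len <- r$lengths[k]
      id <- r$values[k]
      if (id != 0) {
        parts <- c(parts, svg_rect(x0 * step, (iy - 1) * step, len * step, step,
                                   cols[[as.character(id)]]))
      }
      x0 <- x0 + len
    }
  }
  # black boundary pixels where the region id changes between neighbours
  nb <- matrix(FALSE, nrow(idmat), ncol(idmat))
  nb[-1, ] <- nb[-1, ] | idmat[-1, ] != idmat[-nrow(idmat), ]
  nb[, -1] <- nb[, -1] | idmat[, -1] != idmat[, -ncol(idmat)]
  bidx <- which(nb, arr.ind = TRUE)
  for (k in seq_len(nrow(bidx))) {
    parts <- c(parts, svg_rect((bidx[k, 1] - 1) * step, (bidx[k, 2] - 1) * step,
                               step, step, "#000000"))
  }
  # segmented pixels, warped into the template frame, drawn in black
  idx <- which(seg != 0)
  if (length(idx) > 0) {
    py <- (idx - 1) %% nrow(seg)
    px <- (idx - 1) %/% nrow(seg)
    wp <- warp_points(warp, cbind(px + 0.5, py + 0.5))
    if (!is.matrix(wp)) wp <- matrix(wp, 1, 2)
    for (k in seq_len(nrow(wp))) {
      parts <- c(parts, svg_rect(floor(wp[k, 1]), floor(wp[k, 2]), 1, 1, "#000000"))
    }
  }
  parts <- c(parts, "</svg>")
  doc <- paste(parts, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
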