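# Piecewise-affine nonlinear deformation over a Delaunay triangulation of
# the marker points, with the four image corners pinned to themselves. The
# field is built directly in the section -> template direction from the
# marker pairs, which is what lets cleaned segmented images be pushed
# straight into the reference volume rather than rendering the template
# onto the section.

# Bowyer-Watson Delaunay triangulation. pts: n x 2 matrix, n >= 3.
# Returns an m x 3 integer matrix of row indices into pts. Cocircular point
# sets (e.g. rectangle corners) get an arbitrary but valid diagonal.
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  span <- max(apply(pts, 2, function(c) diff(range(c))), 1)
  cx <- mean(range(pts[, 1]))
  cy <- mean(range(pts[, 2]))
  big <- 50 * span
  super <- rbind(c(cx - big, cy - big), c(cx + big, cy - big), c(cx, cy + big))
  all_pts <- rbind(super, pts)
  tris <- matrix(c(1L, 2L, 3L), 1, 3)
  eps <- 1e-9 * span^2

  orient2 <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  in_circumcircle <- function(tri, p) {
    a <- all_pts[tri[1], ]; b <- all_pts[tri[2], ]; c <- all_pts[tri[3], ]
    if (orient2(a, b, c) < 0) { tmp <- b; b <- c; c <- tmp }
    m <- rbind(
      c(a[1] - p[1], a[2] - p[2], (a[1] - p[1])^2 + (a[2] - p[2])^2),
      c(b[1] - p[1], b[2] - p[2], (b[1] - p[1])^2 + (b[2] - p[2])^2),
      c(c[1] - p[1], c[2] - p[2], (c[1] - p[1])^2 + (c[2] - p[2])^2)
    )
    det(m) > eps * span^2
  }

  for (ip in seq_len(n) + 3L) {
    p <- all_pts[ip, ]
    bad <- which(vapply(seq_len(nrow(tris)),
                        function(t) in_circumcircle(tris[t, ], p), logical(1)))
    if (length(bad) == 0) {
      # numerically on an edge/outside: take the nearest triangle's cavity
      d <- vapply(seq_len(nrow(tris)), function(t) {
        ctr <- colMeans(all_pts[tris[t, ], ])
        sum((ctr - p)^2)
      }, numeric(1))
      bad <- which.min(d)
    }
    edges <- do.call(rbind, lapply(bad, function(t) {
      tr <- tris[t, ]
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    new_tris <- cbind(boundary, ip)
    tris <- rbind(tris, new_tris)
  }
  keep <- apply(tris, 1, function(tr) all(tr > 3))
  tris <- tris[keep, , drop = FALSE] - 3L
  storage.mode(tris) <- "integer"
  tris
}

#' Build a piecewise-affine warp field from marker pairs
#'
#' Markers are `(section_point, template_point)` pixel-coordinate pairs.
#' The four image corners are added as fixed points mapping to themselves,
#' the section points are Delaunay-triangulated, and each triangle carries
#' the affine map sending its section vertices to their template partners.
#' The resulting field is continuous, exact at every marker, the identity
#' at the corners, and the global identity when no markers are given.
#'
#' @param markers m x 4 matrix `(sx, sy, tx, ty)` or a zero-row matrix.
#' @param image_dims `c(width, height)` of the section image the markers
#'   were placed on.
#' @return A `warp_field` object.
#' @export
build_warp <- function(markers, image_dims) {
  stopifnot(length(image_dims) == 2, all(image_dims > 0))
  w <- image_dims[1]; h <- image_dims[2]
  if (is.null(markers) || nrow(markers) == 0) {
    return(structure(list(identity = TRUE, image_dims = image_dims),
                     class = "warp_field"))
  }
  markers <- as.matrix(markers)
  stopifnot(ncol(markers) == 4)
  src <- markers[, 1:2, drop = FALSE]
  dst <- markers[, 3:4, drop = FALSE]
  if (any(src[, 1] < 0 | src[, 1] > w | src[, 2] < 0 | src[, 2] > h)) {
    stop("marker section points must lie within the image rectangle")
  }
  key <- paste(src[, 1], src[, 2])
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    rows <- which(key == dup)
    if (nrow(unique(dst[rows, , drop = FALSE])) > 1) {
      stop("contradictory markers: identical section point, different template points")
    }
    keep <- !duplicated(key)
    src <- src[keep, , drop = FALSE]; dst <- dst[keep, , drop = FALSE]
  }
  corners <- rbind(c(0, 0), c(w, 0), c(0, h), c(w, h))
  keep_corner <- vapply(seq_len(4), function(i) {
    min(colSums((t(src) - corners[i, ])^2)) > 1e-18
  }, logical(1))
  src <- rbind(src, corners[keep_corner, , drop = FALSE])
  dst <- rbind(dst, corners[keep_corner, , drop = FALSE])
  tris <- delaunay_triangulate(src)
  structure(
    list(identity = FALSE, src = src, dst = dst, triangles = tris,
         image_dims = image_dims),
    class = "warp_field"
  )
}

#' Evaluate a warp field at pixel coordinates
#'
#' @param warp a [build_warp()] field.
#' @param p length-2 coordinate or n x 2 matrix of section pixel
#'   coordinates.
#' @return Mapped template pixel coordinates, same shape as `p`.
#' @export
warp_points <- function(warp, p) {
  single <- !is.matrix(p)
  if (single) p <- matrix(as.numeric(p), 1, 2)
  if (isTRUE(warp$identity)) {
    return(if (single) as.numeric(p[1, ]) else p)
  }
  n <- nrow(p)
  out <- matrix(NA_real_, n, 2)
  best_tri <- rep(NA_integer_, n)
  best_score <- rep(-Inf, n)
  src <- warp$src; dst <- warp$dst
  for (t in seq_len(nrow(warp$triangles))) {
    tr <- warp$triangles[t, ]
    a <- src[tr[1], ]; b <- src[tr[2], ]; c <- src[tr[3], ]
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-12) next
    px <- p[, 1] - a[1]; py <- p[, 2] - a[2]
    wb <- (px * (c[2] - a[2]) - py * (c[1] - a[1])) / det
    wc <- (py * (b[1] - a[1]) - px * (b[2] - a[2])) / det
    wa <- 1 - wb - wc
    score <- pmin(wa, wb, wc)
    inside <- score >= -1e-9 & is.na(out[, 1])
    if (any(inside)) {
      out[inside, 1] <- wa[inside] * dst[tr[1], 1] + wb[inside] * dst[tr[2], 1] +
        wc[inside] * dst[tr[3], 1]
      out[inside, 2] <- wa[inside] * dst[tr[1], 2] + wb[inside] * dst[tr[2], 2] +
        wc[inside] * dst[tr[3], 2]
    }
    improve <- is.na(out[, 1]) & score > best_score
    best_score[improve] <- score[improve]
    best_tri[improve] <- t
  }
  # points numerically outside every triangle: use the closest triangle's map
  left <- which(is.na(out[, 1]))
  for (i in left) {
    tr <- warp$triangles[best_tri[i], ]
    a <- src[tr[1], ]; b <- src[tr[2], ]; c <- src[tr[3], ]
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    px <- p[i, 1] - a[1]; py <- p[i, 2] - a[2]
    wb <- (px * (c[2] - a[2]) - py * (c[1] - a[1])) / det
    wc <- (py * (b[1] - a[1]) - px * (b[2] - a[2])) / det
    wa <- 1 - wb - wc
    out[i, ] <- wa * dst[tr[1], ] + wb * dst[tr[2], ] + wc * dst[tr[3], ]
  }
  if (single) as.numeric(out[1, ]) else out
}

#' Map section pixels to continuous reference coordinates
#'
#' Applies the nonlinear warp (section -> template pixel frame) and then the
#' linear anchoring transform. Warped points that leave the image rectangle
#' are clamped to it and flagged, so pixel-count conservation diagnostics
#' can account for them.
#'
#' @param anchor a [section_anchor()].
#' @param warp a [build_warp()] field (identity when no markers exist).
#' @param p length-2 pixel coordinate or n x 2 matrix.
#' @param image_dims `c(width, height)`; defaults to the anchor geometry.
#' @return List with `coords` (n x 3 reference coordinates, voxel units)
#'   and `clamped` (logical, which points had to be clamped).
#' @export
section_pixel_to_reference <- function(anchor, warp, p, image_dims = NULL) {
  if (is.null(image_dims)) image_dims <- c(anchor$width_px, anchor$height_px)
  single <- !is.matrix(p)
  if (single) p <- matrix(as.numeric(p), 1, 2)
  wp <- warp_points(warp, p)
  if (!is.matrix(wp)) wp <- matrix(wp, 1, 2)
  clamped <- wp[, 1] < 0 | wp[, 1] > image_dims[1] |
    wp[, 2] < 0 | wp[, 2] > image_dims[2]
  wp[, 1] <- pmin(pmax(wp[, 1], 0), image_dims[1])
  wp[, 2] <- pmin(pmax(wp[, 2], 0), image_dims[2])
  coords <- linear_pixel_to_ccf(anchor, wp, image_dims)
  if (!is.matrix(coords)) coords <- matrix(coords, 1, 3)
  list(coords = coords, clamped = clamped)
}
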