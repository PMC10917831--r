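#' Full-scale dimensions of the 10 um common coordinate volume
#'
#' The 10 um isotropic reference volume spans 1320 voxels along x
#' (anterior to posterior), 800 along y (superior to inferior) and 1140
#' along z (left to right), with the origin at the
#' anterior-superior-left corner.
#'
#' @return Named integer vector `c(x, y, z)`.
#' @export
ccf_dims <- function() c(x = 1320L, y = 800L, z = 1140L)

#' Construct a reference space
#'
#' Bundles an integer annotation volume (region id per voxel, 0 outside the
#' brain), a scalar template volume on the same grid, and the region
#' hierarchy the annotation ids index into. Voxel indices throughout the
#' package are 0-based; a voxel is the half-open unit cube `[i, i+1)` per
#' axis. Axis semantics: x anterior->posterior, y superior->inferior,
#' z left->right.
#'
#' @param annotation 3D integer array of region ids.
#' @param template 3D numeric array, same dimensions.
#' @param hierarchy a [region_hierarchy()] covering every nonzero
#'   annotation value.
#' @param resolution_um voxel edge length in micrometres (10 at full scale).
#' @return A `reference_space` object.
#' @export
reference_space <- function(annotation, template, hierarchy,
                            resolution_um = 10) {
  stopifnot(length(dim(annotation)) == 3, length(dim(template)) == 3)
  if (!identical(dim(annotation), dim(template))) {
    stop(sprintf(
      "annotation dims (%s) differ from template dims (%s)",
      paste(dim(annotation), collapse = ", "),
      paste(dim(template), collapse = ", ")
    ))
  }
  ids <- sort(unique(as.vector(annotation)))
  ids <- ids[ids != 0]
  missing <- setdiff(ids, hierarchy$id)
  if (length(missing) > 0) {
    stop("annotation ids absent from hierarchy: ",
         paste(missing, collapse = ", "))
  }
  structure(
    list(
      annotation = annotation, template = template, hierarchy = hierarchy,
      resolution_um = resolution_um, dims = unname(dim(annotation))
    ),
    class = "reference_space"
  )
}

#' @export
print.reference_space <- function(x, ...) {
  cat(sprintf(
    "<reference_space> %s voxels at %g um, %d regions\n",
    paste(x$dims, collapse = " x "), x$resolution_um, nrow(x$hierarchy)
  ))
  invisible(x)
}

#' Load a reference space from volume and hierarchy files
#'
#' @param annotation_path NRRD or NIfTI annotation volume (integer region ids).
#' @param template_path NRRD or NIfTI template volume on the same grid.
#' @param hierarchy_path JSON hierarchy ([read_region_hierarchy()] dialect);
#'   a nested Allen-style structure graph is also accepted.
#' @param resolution_um voxel size in micrometres.
#' @return A [reference_space()].
#' @export
load_reference_space <- function(annotation_path, template_path,
                                 hierarchy_path, resolution_um = 10) {
  annotation <- read_volume(annotation_path)
  storage.mode(annotation) <- "integer"
  template <- read_volume(template_path)
  hier <- tryCatch(
    read_region_hierarchy(hierarchy_path),
    error = function(e) read_allen_structure_graph(hierarchy_path)
  )
  reference_space(annotation, template, hier, resolution_um)
}

#' Region id at voxel(s)
#'
#' @param space a [reference_space()].
#' @param voxel 0-based integer triple, or an n x 3 matrix of triples.
#' @return Integer region id(s); 0 means outside the brain.
#' @export
region_at <- function(space, voxel) {
  v <- as_voxel_matrix(voxel)
  check_in_bounds(v, space$dims)
  idx <- 1 + vox_key(v, space$dims)
  as.integer(space$annotation[idx])
}

#' Mirror voxel(s) across the left-right midplane
#'
#' Reflection about the centre plane of the voxel grid:
#' `(x, y, z) -> (x, y, nz - 1 - z)`. An involution that keeps indices in
#' bounds; used to map right-hemisphere coordinates onto the left
#' hemisphere, exploiting the left-right symmetry of the reference volume.
#'
#' @param space a [reference_space()].
#' @param voxel 0-based triple or n x 3 matrix.
#' @return Mirrored triple(s), same shape as the input.
#' @export
mirror_to_left <- function(space, voxel) {
  v <- as_voxel_matrix(voxel)
  check_in_bounds(v, space$dims)
  v[, 3] <- space$dims[3] - 1 - v[, 3]
  if (is.matrix(voxel)) v else as.numeric(v[1, ])
}

#' Hemisphere of voxel(s)
#'
#' The left hemisphere is `z < nz / 2` (the origin sits at the left corner,
#' so low z is left).
#'
#' @param space a [reference_space()].
#' @param voxel 0-based triple or n x 3 matrix.
#' @return Character vector `"left"` / `"right"`.
#' @export
hemisphere_of <- function(space, voxel) {
  v <- as_voxel_matrix(voxel)
  ifelse(v[, 3] < space$dims[3] / 2, "left", "right")
}
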