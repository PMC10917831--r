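#' Flatmap lookup from reference voxels to 2D cortical pixels
#'
#' Wraps a dorsal-flatmap style lookup: a dense integer volume assigning
#' each voxel either 0 (no flat position; non-cortical) or the 1-based
#' linear index of its flat pixel, together with the flat dimensions, the
#' cortex mask and a per-pixel area label taken from the parcellation.
#'
#' @param assign 3D integer array (same dims as the reference space); 0 or
#'   1-based linear flat-pixel index.
#' @param flat_dims `c(nfx, nfy)` flat pixel grid.
#' @param cortex_mask logical `nfx x nfy` matrix of cortical-surface pixels.
#' @param area_label integer `nfx x nfy` matrix of region ids (0 where
#'   none).
#' @return A `flatmap_lookup` object.
#' @export
flatmap_lookup <- function(assign, flat_dims, cortex_mask, area_label) {
  stopifnot(length(dim(assign)) == 3, length(flat_dims) == 2)
  stopifnot(identical(dim(cortex_mask), as.integer(flat_dims)),
            identical(dim(area_label), as.integer(flat_dims)))
  if (max(assign) > prod(flat_dims)) stop("flat assignment exceeds flat_dims")
  structure(
    list(assign = assign, flat_dims = as.integer(flat_dims),
         cortex_mask = cortex_mask, area_label = area_label),
    class = "flatmap_lookup"
  )
}

#' Project a voxel cloud onto the cortical flatmap
#'
#' Sums each voxel's pixel count into its flat pixel (the flat intensity is
#' the number of detected axonal segments above that surface position).
#' Voxels without a flat assignment are skipped and counted in the
#' `"skipped"` attribute, so total flat intensity equals the total count of
#' mapped voxels.
#'
#' @param cloud a [voxel_cloud()] sharing the lookup's space dims.
#' @param lookup a [flatmap_lookup()].
#' @return Numeric `nfx x nfy` intensity matrix with attribute `"skipped"`.
#' @export
flatmap_project <- function(cloud, lookup) {
  stopifnot(identical(as.integer(cloud$dims), as.integer(dim(lookup$assign))))
  flat <- matrix(0, lookup$flat_dims[1], lookup$flat_dims[2])
  skipped <- 0
  if (nrow(cloud$coords) > 0) {
    idx <- 1 + vox_key(cloud$coords, cloud$dims)
    fl <- lookup$assign[idx]
    mapped <- fl > 0
    skipped <- sum(cloud$counts[!mapped])
    if (any(mapped)) {
      agg <- rowsum(cloud$counts[mapped], group = fl[mapped])
      flat[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  attr(flat, "skipped") <- skipped
  flat
}

#' Fraction of cortical surface covered by a projection
#'
#' Number of cortex-mask flat pixels with intensity above the threshold,
#' divided by the number of cortex-mask pixels.
#'
#' @param flat intensity matrix from [flatmap_project()].
#' @param lookup a [flatmap_lookup()].
#' @param threshold intensity cut; a pixel counts as covered when its
#'   intensity is strictly greater (default 0).
#' @return Coverage fraction in `[0, 1]`.
#' @export
cortical_coverage <- function(flat, lookup, threshold = 0) {
  denom <- sum(lookup$cortex_mask)
  if (denom == 0) stop("empty cortex mask")
  sum(flat > threshold & lookup$cortex_mask) / denom
}

#' Flat-pixel mask of a named cortical area
#'
#' @param lookup a [flatmap_lookup()].
#' @param hier a [region_hierarchy()].
#' @param area_acronym acronym of the area (ancestors count, so layer
#'   leaves roll up to their area).
#' @return Logical matrix over the flat grid.
#' @export
flatmap_area_mask <- function(lookup, hier, area_acronym) {
  ids <- unique(as.vector(lookup$area_label))
  ids <- ids[ids != 0]
  inside <- ids[is_within(hier, ids, area_acronym)]
  matrix(lookup$area_label %in% inside, nrow(lookup$area_label),
         ncol(lookup$area_label))
}

#' Serialize a flatmap lookup to JSON
#' @param lookup a [flatmap_lookup()].
#' @param path output file.
#' @export
write_flatmap_lookup <- function(lookup, path) {
  occ <- which(lookup$assign > 0)
  keys <- occ - 1
  jsonlite::write_json(
    list(
      space_dims = dim(lookup$assign), flat_dims = lookup$flat_dims,
      entries = cbind(keys, lookup$assign[occ]),
      cortex_mask = which(lookup$cortex_mask) - 1,
      area_label = cbind(which(lookup$area_label > 0) - 1,
                         lookup$area_label[lookup$area_label > 0])
    ),
    path, digits = NA
  )
  invisible(path)
}

#' Read a flatmap lookup from JSON
#' @param path file written by [write_flatmap_lookup()].
#' @return A [flatmap_lookup()].
#' @export
read_flatmap_lookup <- function(path) {
  doc <- jsonlite::fromJSON(path)
  sd <- as.integer(doc$space_dims)
  fd <- as.integer(doc$flat_dims)
  assign <- array(0L, dim = sd)
  if (length(doc$entries) > 0) assign[doc$entries[, 1] + 1] <- doc$entries[, 2]
  cm <- matrix(FALSE, fd[1], fd[2])
  cm[doc$cortex_mask + 1] <- TRUE
  al <- matrix(0L, fd[1], fd[2])
  if (length(doc$area_label) > 0) al[doc$area_label[, 1] + 1] <- doc$area_label[, 2]
  flatmap_lookup(assign, fd, cm, al)
}
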