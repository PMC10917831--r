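#' Sparse voxel-to-count cloud
#'
#' A voxel cloud records, for each occupied 0-based voxel of a reference
#' grid, the number of segmented pixels registered into it: a voxel with
#' value 100 reflects 100 segmented pixels falling within its cubical
#' volume. Duplicate coordinates are summed on construction.
#'
#' @param coords n x 3 matrix of 0-based voxel triples (may be empty).
#' @param counts positive integer counts, one per row.
#' @param dims reference-space dimensions the coordinates index.
#' @return A `voxel_cloud` object.
#' @export
voxel_cloud <- function(coords = matrix(numeric(0), 0, 3),
                        counts = numeric(0), dims) {
  coords <- as.matrix(coords)
  if (nrow(coords) > 0) {
    storage.mode(coords) <- "double"
    stopifnot(length(counts) == nrow(coords))
    if (any(counts < 1)) stop("voxel counts must be >= 1")
    check_in_bounds(coords, dims)
    keys <- vox_key(coords, dims)
    agg <- rowsum(as.numeric(counts), group = keys)
    coords <- key_to_vox(as.numeric(rownames(agg)), dims)
    counts <- as.numeric(agg[, 1])
    o <- order(vox_key(coords, dims))
    coords <- coords[o, , drop = FALSE]
    counts <- counts[o]
  } else {
    coords <- matrix(numeric(0), 0, 3)
    counts <- numeric(0)
  }
  colnames(coords) <- c("x", "y", "z")
  structure(list(coords = coords, counts = counts, dims = as.integer(dims)),
            class = "voxel_cloud")
}

#' @export
print.voxel_cloud <- function(x, ...) {
  cat(sprintf("<voxel_cloud> %d voxels, total count %g, dims (%s)\n",
              nrow(x$coords), sum(x$counts), paste(x$dims, collapse = ", ")))
  invisible(x)
}

#' Total pixel count of a cloud
#' @param cloud a [voxel_cloud()].
#' @return Numeric total of all voxel counts.
#' @export
cloud_total <- function(cloud) sum(cloud$counts)

#' Count stored at a voxel
#' @param cloud a [voxel_cloud()].
#' @param voxel 0-based triple.
#' @return The count, or 0 when the voxel is unoccupied.
#' @export
cloud_count_at <- function(cloud, voxel) {
  if (nrow(cloud$coords) == 0) return(0)
  key <- vox_key(matrix(as.numeric(voxel), 1, 3), cloud$dims)
  hit <- match(key, vox_key(cloud$coords, cloud$dims))
  if (is.na(hit)) 0 else cloud$counts[hit]
}

#' Merge voxel clouds, summing counts
#' @param ... [voxel_cloud()]s on the same grid.
#' @return The element-wise sum cloud.
#' @export
cloud_merge <- function(...) {
  clouds <- list(...)
  if (length(clouds) == 1 && is.list(clouds[[1]]) &&
      !inherits(clouds[[1]], "voxel_cloud")) {
    clouds <- clouds[[1]]
  }
  dims <- clouds[[1]]$dims
  for (cl in clouds) {
    if (!identical(cl$dims, dims)) {
      stop(sprintf("mixed cloud dims: (%s) vs (%s)",
                   paste(dims, collapse = ", "),
                   paste(cl$dims, collapse = ", ")))
    }
  }
  voxel_cloud(
    do.call(rbind, lapply(clouds, function(cl) cl$coords)),
    unlist(lapply(clouds, function(cl) cl$counts)),
    dims
  )
}

#' Per-experiment population record
#'
#' Couples the `source` cloud (soma / injection-volume pixels, gray label
#' 129) and the `target` cloud (axon pixels, white label 255) of one
#' tracing experiment, plus the unique RGB colour assigned to the
#' population for visualization.
#'
#' @param experiment_id experiment identifier.
#' @param source,target [voxel_cloud()]s on the same grid.
#' @param color hex RGB colour for the population.
#' @return A `population_record` object.
#' @export
population_record <- function(experiment_id, source, target, color = "#000000") {
  if (!identical(source$dims, target$dims)) {
    stop("source and target clouds must share space dims")
  }
  structure(
    list(experiment_id = experiment_id, source = source, target = target,
         color = color),
    class = "population_record"
  )
}

#' @export
print.population_record <- function(x, ...) {
  cat(sprintf("<population_record> %s: %d source voxels (%g px), %d target voxels (%g px)\n",
              x$experiment_id, nrow(x$source$coords), cloud_total(x$source),
              nrow(x$target$coords), cloud_total(x$target)))
  invisible(x)
}

#' Serialize a population record to JSON
#'
#' Entries are `[x, y, z, count]` rows; the format round-trips through
#' [read_population_record()].
#'
#' @param record a [population_record()].
#' @param path output JSON file.
#' @export
write_population_record <- function(record, path) {
  ser <- function(cl) {
    if (nrow(cl$coords) == 0) return(list())
    m <- cbind(cl$coords, cl$counts)
    lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  }
  jsonlite::write_json(
    list(experiment_id = record$experiment_id, color = record$color,
         space_dims = record$source$dims,
         source = ser(record$source), target = ser(record$target)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a population record from JSON
#' @param path JSON file written by [write_population_record()].
#' @return A [population_record()].
#' @export
read_population_record <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dims <- as.integer(doc$space_dims)
  de <- function(m) {
    if (length(m) == 0) return(voxel_cloud(dims = dims))
    m <- matrix(as.numeric(m), ncol = 4)
    voxel_cloud(m[, 1:3, drop = FALSE], m[, 4], dims)
  }
  population_record(doc$experiment_id, de(doc$source), de(doc$target),
                    doc$color %||% "#000000")
}
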