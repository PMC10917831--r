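#' Medoid of a population's injection volume
#'
#' The k-medoids solution with k = 1: the occupied voxel minimizing the
#' (count-weighted) sum of Euclidean distances to all occupied voxels.
#' Unlike a centroid, the medoid is a de facto labeled voxel of the
#' injection volume. Distances are in voxel units on the isotropic grid.
#'
#' @param source a nonempty [voxel_cloud()] of soma voxels.
#' @param weighted weight each voxel by its pixel count (default); set
#'   `FALSE` to treat unique voxels equally.
#' @return 0-based voxel triple of the medoid.
#' @export
population_medoid <- function(source, weighted = TRUE) {
  n <- nrow(source$coords)
  if (n == 0) stop("empty source cloud")
  co <- source$coords
  wts <- if (weighted) source$counts else rep(1, n)
  # pairwise distances in blocks; fixture-scale clouds are small
  d2 <- outer(rowSums(co^2), rowSums(co^2), "+") - 2 * tcrossprod(co)
  d2[d2 < 0] <- 0
  cost <- sqrt(d2) %*% wts
  as.numeric(co[which.min(cost), ])
}

#' Membership radius around a population medoid
#'
#' The maximum Euclidean distance between the medoid and any other
#' soma-member voxel, multiplied by `radius_factor` (default 1.5) to
#' account for incomplete sampling of the population by the tracer.
#'
#' @param source a [voxel_cloud()] of soma voxels.
#' @param medoid voxel triple from [population_medoid()].
#' @param radius_factor inflation factor (> 0), default 1.5.
#' @return Radius in voxel units.
#' @export
membership_radius <- function(source, medoid, radius_factor = 1.5) {
  stopifnot(radius_factor > 0)
  if (nrow(source$coords) == 0) stop("empty source cloud")
  d <- sqrt(rowSums((source$coords - matrix(medoid, nrow(source$coords), 3,
                                            byrow = TRUE))^2))
  radius_factor * max(d)
}

#' Classify single-neuron morphologies as putative population members
#'
#' A neuron whose soma lies within the membership radius of the medoid
#' (closed ball) is classified as a potential member of the population;
#' the members' axon terminal points are pooled into one voxel cloud
#' (floor-binned, unit count each) standing in for the population's axons.
#'
#' @param morphologies list of morphology objects (see [read_swc()]), each
#'   with `neuron_id`, `soma` (3D coordinate, voxel units) and `terminals`
#'   (n x 3 matrix).
#' @param medoid,radius from [population_medoid()] / [membership_radius()].
#' @param dims reference-space dims for the pooled terminal cloud.
#' @return List with `members` (character ids), `morphologies` (the member
#'   subset) and `terminals` (pooled [voxel_cloud()]).
#' @export
classify_members <- function(morphologies, medoid, radius, dims) {
  is_member <- vapply(morphologies, function(m) {
    sqrt(sum((m$soma - medoid)^2)) <= radius
  }, logical(1))
  members <- morphologies[is_member]
  pts <- do.call(rbind, c(list(matrix(numeric(0), 0, 3)),
                          lapply(members, `[[`, "terminals")))
  pts <- floor(pts)
  keep <- pts[, 1] >= 0 & pts[, 1] < dims[1] &
    pts[, 2] >= 0 & pts[, 2] < dims[2] &
    pts[, 3] >= 0 & pts[, 3] < dims[3]
  cloud <- if (any(keep)) {
    voxel_cloud(pts[keep, , drop = FALSE], rep(1, sum(keep)), dims)
  } else {
    voxel_cloud(dims = dims)
  }
  list(
    members = vapply(members, `[[`, character(1), "neuron_id"),
    morphologies = members, terminals = cloud
  )
}

#' Most proximal bulk tract-tracing experiment
#'
#' Selects from a catalogue of bulk experiments the one whose injection
#' centroid is nearest (Euclidean) to the population's source medoid; ties
#' break lexicographically on experiment id.
#'
#' @param record a [population_record()] (or a [voxel_cloud()] used as the
#'   source directly).
#' @param catalogue data frame with `experiment_id` and centroid columns
#'   `x`, `y`, `z` (voxel units).
#' @return The matching experiment id.
#' @export
nearest_bulk_experiment <- function(record, catalogue) {
  if (is.null(catalogue) || nrow(catalogue) == 0) stop("empty bulk catalogue")
  src <- if (inherits(record, "population_record")) record$source else record
  medoid <- population_medoid(src)
  d <- sqrt((catalogue$x - medoid[1])^2 + (catalogue$y - medoid[2])^2 +
              (catalogue$z - medoid[3])^2)
  best <- which(d == min(d))
  sort(as.character(catalogue$experiment_id[best]))[1]
}

#' Read a bulk-experiment catalogue
#'
#' CSV or JSON records of `{experiment_id, centroid_x, centroid_y,
#' centroid_z}` (plain `x`, `y`, `z` also accepted).
#'
#' @param path catalogue file.
#' @return Data frame with `experiment_id`, `x`, `y`, `z`.
#' @export
read_bulk_catalogue <- function(path) {
  df <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  for (ax in c("x", "y", "z")) {
    if (is.null(df[[ax]])) df[[ax]] <- df[[paste0("centroid_", ax)]]
  }
  df[, c("experiment_id", "x", "y", "z")]
}

overlap_state_levels <- c("neither", "overlap", "population_only", "other_only")

#' Three-state overlap map between two flat intensities
#'
#' Pixel-wise comparison of a population's flatmap intensity with another
#' modality's (single-neuron terminals or a bulk experiment): both positive
#' is `overlap`, only the population `population_only`, only the other
#' modality `other_only`, else `neither`. The states partition every pixel.
#'
#' @param pop_flat,other_flat intensity matrices of equal dimensions.
#' @return An `overlap_map`: integer matrix of state codes with a `levels`
#'   attribute; use [overlap_fractions()] to summarize.
#' @export
overlap_states <- function(pop_flat, other_flat) {
  if (!identical(dim(pop_flat), dim(other_flat))) {
    stop(sprintf("flat dims differ: (%s) vs (%s)",
                 paste(dim(pop_flat), collapse = ", "),
                 paste(dim(other_flat), collapse = ", ")))
  }
  p <- pop_flat > 0
  o <- other_flat > 0
  states <- matrix(0L, nrow(pop_flat), ncol(pop_flat))
  states[p & o] <- 1L
  states[p & !o] <- 2L
  states[!p & o] <- 3L
  structure(states, levels = overlap_state_levels, class = "overlap_map")
}

#' Per-state fractions of targeted flatmap points within an area
#'
#' Counts the pixels of each overlap state inside the area mask. With the
#' default `"targeted"` denominator the three states are normalized by all
#' targeted (state != neither) in-area points and sum to 1; with
#' `"area"` they are normalized by all in-area points.
#'
#' @param states an [overlap_states()] map.
#' @param area_mask logical matrix over the flat grid.
#' @param denominator `"targeted"` (default) or `"area"`.
#' @return Named numeric vector of fractions for `overlap`,
#'   `population_only`, `other_only`; attribute `"counts"` holds the raw
#'   pixel counts. Empty result (all zero, with a warning) when no in-area
#'   pixel is targeted.
#' @export
overlap_fractions <- function(states, area_mask,
                              denominator = c("targeted", "area")) {
  denominator <- match.arg(denominator)
  stopifnot(identical(dim(states), dim(area_mask)))
  s <- unclass(states)[area_mask]
  counts <- c(
    overlap = sum(s == 1L),
    population_only = sum(s == 2L),
    other_only = sum(s == 3L)
  )
  denom <- if (denominator == "targeted") sum(counts) else length(s)
  if (sum(counts) == 0) {
    warning("no targeted pixels within the area")
    frac <- counts * 0
  } else {
    frac <- counts / denom
  }
  attr(frac, "counts") <- counts
  frac
}
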