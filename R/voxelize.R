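#' Map a cleaned segmented section into reference-space voxels
#'
#' Each nonzero pixel (its centre) is pushed through the nonlinear warp and
#' linear anchoring into continuous reference coordinates, floored to a
#' 0-based voxel triple, and counted into the soma (`source`) or axon
#' (`target`) cloud according to its label. Pixels whose mapped coordinate
#' leaves the reference volume are dropped and reported, so
#' `sum(counts) + out_of_space == number of segmented pixels`.
#'
#' @param seg label matrix over `{0, 129, 255}` with geometry equal to the
#'   anchored image.
#' @param anchor a [section_anchor()] for the section.
#' @param warp a [build_warp()] field (identity when no markers).
#' @param space a [reference_space()].
#' @return List with `source` and `target` [voxel_cloud()] increments and a
#'   `report` of warp-clamped and out-of-space pixel counts.
#' @export
voxelize_section <- function(seg, anchor, warp, space) {
  h <- nrow(seg); w <- ncol(seg)
  if (w != anchor$width_px || h != anchor$height_px) {
    stop(sprintf(
      "segmentation geometry (%d x %d) does not match anchor geometry (%d x %d)",
      w, h, anchor$width_px, anchor$height_px
    ))
  }
  one_label <- function(value) {
    idx <- which(seg == value)
    if (length(idx) == 0) {
      return(list(cloud = voxel_cloud(dims = space$dims), clamped = 0L, oob = 0L))
    }
    py <- (idx - 1) %% h      # 0-based row
    px <- (idx - 1) %/% h     # 0-based column
    centers <- cbind(px + 0.5, py + 0.5)
    mapped <- section_pixel_to_reference(anchor, warp, centers, c(w, h))
    vox <- floor(mapped$coords)
    inb <- vox[, 1] >= 0 & vox[, 1] < space$dims[1] &
      vox[, 2] >= 0 & vox[, 2] < space$dims[2] &
      vox[, 3] >= 0 & vox[, 3] < space$dims[3]
    cloud <- if (any(inb)) {
      voxel_cloud(vox[inb, , drop = FALSE], rep(1, sum(inb)), space$dims)
    } else {
      voxel_cloud(dims = space$dims)
    }
    list(cloud = cloud, clamped = sum(mapped$clamped), oob = sum(!inb))
  }
  soma <- one_label(SEG_SOMA)
  axon <- one_label(SEG_AXON)
  list(
    source = soma$cloud, target = axon$cloud,
    report = list(
      warp_clamped = soma$clamped + axon$clamped,
      out_of_space = soma$oob + axon$oob,
      soma_pixels = sum(seg == SEG_SOMA),
      axon_pixels = sum(seg == SEG_AXON)
    )
  )
}

#' Assemble per-section voxel increments into one experiment record
#'
#' Element-wise sum of counts across sections, per label; the result is the
#' outcome of registering the entire image stack. Assembly is
#' order-independent.
#'
#' @param increments list of [voxelize_section()] results.
#' @param experiment_id experiment identifier.
#' @param color RGB colour for the population.
#' @return A [population_record()]; attribute `"report"` aggregates the
#'   per-section conservation numbers.
#' @export
assemble_experiment <- function(increments, experiment_id, color = "#000000") {
  stopifnot(length(increments) > 0)
  source <- cloud_merge(lapply(increments, `[[`, "source"))
  target <- cloud_merge(lapply(increments, `[[`, "target"))
  rec <- population_record(experiment_id, source, target, color)
  reps <- lapply(increments, `[[`, "report")
  attr(rec, "report") <- list(
    warp_clamped = sum(vapply(reps, `[[`, numeric(1), "warp_clamped")),
    out_of_space = sum(vapply(reps, `[[`, numeric(1), "out_of_space")),
    soma_pixels = sum(vapply(reps, `[[`, numeric(1), "soma_pixels")),
    axon_pixels = sum(vapply(reps, `[[`, numeric(1), "axon_pixels"))
  )
  rec
}

#' Relabel injection-volume voxels found outside the injected nucleus
#'
#' Soma-labeled voxels whose annotation region does not lie within the
#' named nucleus are false negatives of neurite pixels (dense axon
#' convergence can resemble an injection volume); their counts are moved
#' from the source cloud to the target cloud. The a-priori knowledge of the
#' injection site makes this curation safe. Total source + target count is
#' conserved.
#'
#' @param record a [population_record()].
#' @param space a [reference_space()].
#' @param hier a [region_hierarchy()]; defaults to the space's own.
#' @param nucleus_acronym acronym of the injected nucleus (e.g. `"VPM"`).
#' @return The curated [population_record()].
#' @export
curate_injection_volume <- function(record, space, hier = space$hierarchy,
                                    nucleus_acronym) {
  region_id_of(hier, nucleus_acronym)  # validates the acronym
  src <- record$source
  if (nrow(src$coords) == 0) return(record)
  ids <- region_at(space, src$coords)
  inside <- ids != 0 & is_within(hier, ids, nucleus_acronym)
  if (all(inside)) return(record)
  moved <- voxel_cloud(src$coords[!inside, , drop = FALSE],
                       src$counts[!inside], src$dims)
  kept <- if (any(inside)) {
    voxel_cloud(src$coords[inside, , drop = FALSE], src$counts[inside], src$dims)
  } else {
    voxel_cloud(dims = src$dims)
  }
  out <- population_record(record$experiment_id, kept,
                           cloud_merge(record$target, moved), record$color)
  attr(out, "report") <- c(
    attr(record, "report"),
    list(curated_voxels = nrow(moved$coords), curated_pixels = cloud_total(moved))
  )
  out
}

split_cloud_hemi <- function(cloud, space) {
  if (nrow(cloud$coords) == 0) {
    return(list(left = cloud, right_mapped = cloud))
  }
  left <- cloud$coords[, 3] < space$dims[3] / 2
  mk <- function(sel, mirror) {
    if (!any(sel)) return(voxel_cloud(dims = cloud$dims))
    co <- cloud$coords[sel, , drop = FALSE]
    if (mirror) co <- mirror_to_left(space, co)
    voxel_cloud(co, cloud$counts[sel], cloud$dims)
  }
  list(left = mk(left, FALSE), right_mapped = mk(!left, TRUE))
}

#' Split a record by hemisphere and mirror the right onto the left
#'
#' Voxels are partitioned by hemisphere (left: `z < nz / 2`); the
#' right-hemisphere coordinates are inverted along the left-right axis via
#' [mirror_to_left()] so every population can be visualized on one
#' hemisphere. Counts are preserved; mirrored coordinates colliding with
#' each other are summed.
#'
#' @param record a [population_record()].
#' @param space a [reference_space()].
#' @return List with `left` and `right_mapped` [population_record()]s.
#' @export
split_and_mirror <- function(record, space) {
  s <- split_cloud_hemi(record$source, space)
  t <- split_cloud_hemi(record$target, space)
  list(
    left = population_record(record$experiment_id, s$left, t$left, record$color),
    right_mapped = population_record(record$experiment_id, s$right_mapped,
                                     t$right_mapped, record$color)
  )
}

#' Dominant population at a coordinate
#'
#' When several registered populations occupy the same voxel, the voxel is
#' attributed to the population with the highest segmented-pixel count
#' there (target clouds); ties break lexicographically on experiment id.
#'
#' @param records list of [population_record()]s.
#' @param coordinate 0-based voxel triple.
#' @param which `"target"` (default) or `"source"` clouds.
#' @return The winning experiment id, or `NA_character_` when no record
#'   occupies the coordinate.
#' @export
dominant_population <- function(records, coordinate, which = c("target", "source")) {
  which <- match.arg(which)
  ids <- vapply(records, `[[`, character(1), "experiment_id")
  counts <- vapply(records, function(r) cloud_count_at(r[[which]], coordinate),
                   numeric(1))
  if (all(counts == 0)) return(NA_character_)
  best <- counts == max(counts)
  sort(ids[best])[1]
}

#' Assign unique population colours
#'
#' Deterministic, maximally-spaced hues; override per experiment via the
#' pipeline config when specific colours are wanted.
#'
#' @param experiment_ids character vector.
#' @return Named vector of hex colours.
#' @export
assign_population_colors <- function(experiment_ids) {
  stats::setNames(population_palette(length(experiment_ids)), experiment_ids)
}
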