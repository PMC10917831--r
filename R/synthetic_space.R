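# Synthetic miniature reference space with known ground truth. The default
# fixture is 1/10 linear scale (132 x 80 x 114 voxels) with the same axis
# semantics as the full-scale volume, so every code path runs unchanged.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic reference space with hierarchy
#'
#' Builds a small annotation/template volume with nested region geometry: a
#' cortical shell of `n_areas` areas along the anterior-posterior axis, each
#' with six layer bands (tags 1, 2/3, 4, 5, 6a, 6b) when `layered_cortex`,
#' plus a thalamic "VPM"-role nucleus and a neighbouring "PO" nucleus.
#' With `symmetric = TRUE` the annotation equals its left-right mirror,
#' emulating the symmetry assumption of the real reference volume.
#'
#' @param dims voxel dimensions, each at least 20; default `c(132, 80, 114)`.
#' @param n_areas number of cortical areas (acronyms `CTX-A1`, ...).
#' @param layered_cortex give each area six layer leaves.
#' @param symmetric mirror the left-hemisphere geometry to the right.
#' @param seed RNG seed (the gentle template texture).
#' @return A [reference_space()]; attributes `"areas"` and `"nucleus"` name
#'   the cortical areas and the injected-nucleus acronym.
#' @export
make_reference_space <- function(dims = c(132, 80, 114), n_areas = 4,
                                 layered_cortex = TRUE, symmetric = TRUE,
                                 seed = 1) {
  dims <- as.integer(dims)
  if (any(dims < 20)) {
    stop("dims too small for the synthetic geometry (need >= 20 per axis)")
  }
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ann <- array(0L, dim = dims)

  layer_tags <- c("1", "2/3", "4", "5", "6a", "6b")
  lt <- max(2L, ny %/% 30L)           # layer band thickness
  y_cortex0 <- 2L
  zl <- nz %/% 2L                     # left hemisphere: z < zl
  z_ctx <- 3:(zl - 2)                 # 0-based z range of cortex, left side
  x0 <- floor(nx * 0.15); x1 <- floor(nx * 0.85)
  area_breaks <- floor(seq(x0, x1, length.out = n_areas + 1))

  rows <- list(
    data.frame(id = 8L, acronym = "root", parent_id = NA_integer_,
               layer = NA_character_),
    data.frame(id = 315L, acronym = "Isocortex", parent_id = 8L,
               layer = NA_character_),
    data.frame(id = 549L, acronym = "TH", parent_id = 8L,
               layer = NA_character_),
    data.frame(id = 733L, acronym = "VPM", parent_id = 549L,
               layer = NA_character_),
    data.frame(id = 1020L, acronym = "PO", parent_id = 549L,
               layer = NA_character_)
  )
  areas <- character(n_areas)
  for (i in seq_len(n_areas)) {
    acr <- paste0("CTX-A", i)
    areas[i] <- acr
    area_id <- 100L * i
    rows[[length(rows) + 1]] <- data.frame(
      id = area_id, acronym = acr, parent_id = 315L, layer = NA_character_
    )
    xs <- area_breaks[i]:(area_breaks[i + 1] - 1)
    if (layered_cortex) {
      for (j in seq_along(layer_tags)) {
        leaf_id <- area_id + j
        rows[[length(rows) + 1]] <- data.frame(
          id = leaf_id, acronym = paste0(acr, " layer ", layer_tags[j]),
          parent_id = area_id, layer = layer_tags[j]
        )
        ys <- (y_cortex0 + (j - 1) * lt):(y_cortex0 + j * lt - 1)
        ann[xs + 1, ys + 1, z_ctx + 1] <- leaf_id
      }
    } else {
      ys <- y_cortex0:(y_cortex0 + 6 * lt - 1)
      ann[xs + 1, ys + 1, z_ctx + 1] <- area_id
    }
  }
  # thalamic nuclei, left hemisphere
  vx <- floor(nx * 0.35):(floor(nx * 0.60) - 1)
  vy <- floor(ny * 0.45):(floor(ny * 0.70) - 1)
  vz_vpm <- floor(nz * 0.12):(floor(nz * 0.32) - 1)
  vz_po <- floor(nz * 0.32):(floor(nz * 0.42) - 1)
  ann[vx + 1, vy + 1, vz_vpm + 1] <- 733L
  ann[vx + 1, vy + 1, vz_po + 1] <- 1020L

  if (symmetric) {
    for (z in 0:(zl - 1)) ann[, , nz - z] <- ann[, , z + 1]
  }

  template <- with_seed(seed, {
    base <- 0.15 + 0.55 * (ann > 0)
    grad <- array(rep((0:(ny - 1)) / ny * 0.2, each = nx), dim = dims)
    tex <- array(stats::runif(prod(dims), 0, 0.02), dim = dims)
    if (symmetric) for (z in 0:(zl - 1)) tex[, , nz - z] <- tex[, , z + 1]
    base + grad + tex
  })

  hier <- region_hierarchy(do.call(rbind, rows))
  space <- reference_space(ann, template, hier)
  attr(space, "areas") <- areas
  attr(space, "nucleus") <- "VPM"
  space
}

#' Generate a dorsal flatmap lookup for a synthetic space
#'
#' Emulates a dorsal cortical flatmap: every cortical voxel in a vertical
#' `(x, z)` column maps to the flat pixel `(x, z)`, so flat intensity sums
#' counts over cortical depth. The cortex mask marks columns containing any
#' cortical voxel; the per-pixel area label is the area (layer leaves
#' rolled up) of the topmost cortical voxel.
#'
#' @param space a [make_reference_space()] result (any [reference_space()]
#'   whose hierarchy has an `Isocortex` node works).
#' @return A [flatmap_lookup()] with `flat_dims = c(nx, nz)`.
#' @export
make_flatmap_lookup <- function(space) {
  dims <- space$dims
  hier <- space$hierarchy
  ctx_ids <- region_subtree(hier, "Isocortex")
  area_of <- function(id) {
    chain <- region_ancestors(hier, id)
    parents <- hier$parent_id[match(chain, hier$id)]
    # the node whose parent is Isocortex
    cand <- chain[!is.na(parents) & parents == region_id_of(hier, "Isocortex")]
    if (length(cand) >= 1) cand[1] else id
  }
  assign <- array(0L, dim = dims)
  nfx <- dims[1]; nfy <- dims[3]
  cortex_mask <- matrix(FALSE, nfx, nfy)
  area_label <- matrix(0L, nfx, nfy)
  is_ctx <- array(space$annotation %in% ctx_ids, dim = dims)
  for (x in seq_len(dims[1])) {
    sl <- is_ctx[x, , ]                       # ny x nz
    cols <- which(colSums(sl) > 0)
    for (z in cols) {
      flat_idx <- x + nfx * (z - 1)
      assign[x, which(sl[, z]), z] <- flat_idx
      cortex_mask[x, z] <- TRUE
      top_y <- which(sl[, z])[1]
      area_label[x, z] <- area_of(space$annotation[x, top_y, z])
    }
  }
  flatmap_lookup(assign, c(nfx, nfy), cortex_mask, area_label)
}
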