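#' Generate a synthetic tracing experiment with known ground truth
#'
#' Plants a soma blob inside the injected nucleus and laminar axon blobs in
#' a cortical area, then renders per-section raw 3-label classifier images
#' (1 = axon, 2 = background, 3 = soma) whose pixels, mapped through the
#' emitted anchoring and warp, land exactly on the planted truth voxels.
#' Sections are coronal planes; each truth voxel is rendered as a
#' `px_per_vox` x `px_per_vox` pixel patch. Small decoy objects (1-11 px)
#' are planted in the background to exercise the object-size filter, and
#' anchoring is written in both the linear XML and nonlinear JSON dialects.
#'
#' @param space a [make_reference_space()] result.
#' @param n_sections number of coronal sections spanning nucleus and area.
#' @param soma_blob_spec list with `nucleus` acronym and in-plane `radius`
#'   (voxels) of the planted soma disk.
#' @param axon_blob_specs list of `list(area, layer, n_voxels)` laminar
#'   blobs planted on every section that intersects the area; the defaults
#'   plant a 40/30/20/10 profile across layers 4, 2/3, 5 and 6a.
#' @param warp_magnitude_px maximum marker displacement in pixels; 0 gives
#'   identity warps and exact recovery.
#' @param seed RNG seed; the study is a pure function of its parameters and
#'   this seed.
#' @param experiment_id id used for stems and records.
#' @param n_decoys total decoy objects distributed over the sections.
#' @param px_per_vox section-image pixels per voxel edge.
#' @param out_dir when given, writes section PNGs, `<id>_linear.xml`,
#'   `<id>_nonlinear.json` and `<id>_truth.json` there.
#' @return A `synthetic_study` list: per-`sections` raw images, anchors and
#'   markers; `truth_source` / `truth_target` voxel clouds (the exact
#'   expected pipeline output); `planted_source` / `planted_target` support
#'   matrices; decoy and pixel bookkeeping.
#' @export
make_experiment <- function(space, n_sections = 10,
                            soma_blob_spec = list(nucleus = "VPM", radius = 2),
                            axon_blob_specs = NULL,
                            warp_magnitude_px = 0, seed = 1,
                            experiment_id = "exp1", n_decoys = 6,
                            px_per_vox = 2, out_dir = NULL) {
  hier <- space$hierarchy
  dims <- space$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  if (is.null(axon_blob_specs)) {
    area <- (attr(space, "areas") %||% "CTX-A1")[1]
    axon_blob_specs <- list(
      list(area = area, layer = "4", n_voxels = 40),
      list(area = area, layer = "2/3", n_voxels = 30),
      list(area = area, layer = "5", n_voxels = 20),
      list(area = area, layer = "6a", n_voxels = 10)
    )
  }
  nuc_id <- region_id_of(hier, soma_blob_spec$nucleus)
  nuc_vox <- which(space$annotation == nuc_id, arr.ind = TRUE) - 1
  nuc_vox <- nuc_vox[nuc_vox[, 3] < nz / 2, , drop = FALSE]
  if (nrow(nuc_vox) == 0) stop("nucleus blob outside space: no voxels for ",
                               soma_blob_spec$nucleus)
  nuc_center <- floor(colMeans(nuc_vox))
  leaf_ids <- vapply(axon_blob_specs, function(s) {
    region_id_of(hier, paste0(s$area, " layer ", s$layer))
  }, integer(1))

  # section planes span the nucleus and the targeted area(s)
  target_x <- unlist(lapply(leaf_ids, function(id) {
    v <- which(space$annotation == id, arr.ind = TRUE)[, 1] - 1
    range(v)
  }))
  xr <- range(c(nuc_vox[, 1], target_x))
  x_positions <- unique(round(seq(xr[1], xr[2], length.out = n_sections)))

  W <- px_per_vox * nz
  H <- px_per_vox * ny

  with_seed(seed, {
    sections <- list()
    src_keys_all <- numeric(0); tgt_keys_all <- numeric(0)
    src_counts <- list(); tgt_counts <- list()
    planted_src <- list(); planted_tgt <- list()
    total_decoy_px <- 0L
    decoys_per_section <- diff(floor(seq(0, n_decoys,
                                         length.out = length(x_positions) + 1)))
    # pixel centres, shared across sections
    px <- rep(0:(W - 1), times = H) + 0.5
    py <- rep(0:(H - 1), each = W) + 0.5
    centers <- cbind(px, py)

    for (si in seq_along(x_positions)) {
      x0 <- x_positions[si]
      plane <- space$annotation[x0 + 1, , ]    # ny x nz
      # planted truth voxels on this plane
      soma_yz <- which(plane == nuc_id, arr.ind = TRUE) - 1
      if (nrow(soma_yz) > 0) {
        d2 <- (soma_yz[, 1] - nuc_center[2])^2 + (soma_yz[, 2] - nuc_center[3])^2
        soma_yz <- soma_yz[d2 <= soma_blob_spec$radius^2 &
                             soma_yz[, 2] < nz / 2, , drop = FALSE]
      }
      axon_yz <- do.call(rbind, lapply(seq_along(axon_blob_specs), function(k) {
        yz <- which(plane == leaf_ids[k], arr.ind = TRUE) - 1
        yz <- yz[yz[, 2] < nz / 2, , drop = FALSE]
        if (nrow(yz) == 0) return(yz)
        yz <- yz[order(yz[, 2], yz[, 1]), , drop = FALSE]
        utils::head(yz, axon_blob_specs[[k]]$n_voxels)
      }))
      soma_vox <- if (nrow(soma_yz) > 0) cbind(x0, soma_yz) else
        matrix(numeric(0), 0, 3)
      axon_vox <- if (!is.null(axon_yz) && nrow(axon_yz) > 0) cbind(x0, axon_yz) else
        matrix(numeric(0), 0, 3)
      planted_src[[si]] <- soma_vox
      planted_tgt[[si]] <- axon_vox

      anchor <- section_anchor(o = c(x0 + 0.5, 0, 0), u = c(0, 0, nz),
                               v = c(0, ny, 0), width_px = W, height_px = H)
      markers <- matrix(numeric(0), 0, 4)
      if (warp_magnitude_px > 0) {
        m <- 6
        sx <- stats::runif(m, 0.15 * W, 0.85 * W)
        sy <- stats::runif(m, 0.15 * H, 0.85 * H)
        ang <- stats::runif(m, 0, 2 * pi)
        mag <- stats::runif(m, 0.3, 1) * warp_magnitude_px
        markers <- cbind(sx, sy, sx + mag * cos(ang), sy + mag * sin(ang))
        colnames(markers) <- c("sx", "sy", "tx", "ty")
      }
      warp <- build_warp(markers, c(W, H))

      mapped <- warp_points(warp, centers)
      if (!is.matrix(mapped)) mapped <- matrix(mapped, 1, 2)
      vy <- floor(mapped[, 2] / H * ny)
      vz <- floor(mapped[, 1] / W * nz)
      inb <- vy >= 0 & vy < ny & vz >= 0 & vz < nz
      keys <- rep(NA_real_, length(vy))
      keys[inb] <- vox_key(cbind(x0, vy[inb], vz[inb]), dims)
      s_keys <- if (nrow(soma_vox) > 0) vox_key(soma_vox, dims) else numeric(0)
      a_keys <- if (nrow(axon_vox) > 0) vox_key(axon_vox, dims) else numeric(0)

      raw <- matrix(2L, H, W)
      is_soma <- !is.na(keys) & keys %in% s_keys
      is_axon <- !is.na(keys) & keys %in% a_keys
      # centers are ordered x-fastest; raw is indexed [row=py, col=px]
      idx_mat <- cbind(py + 0.5, px + 0.5)  # row, col (1-based after +0.5)
      raw[idx_mat[is_soma, , drop = FALSE]] <- 3L
      raw[idx_mat[is_axon, , drop = FALSE]] <- 1L

      # truth counts from the rendered pixels themselves
      if (any(is_soma)) {
        agg <- rowsum(rep(1, sum(is_soma)), group = keys[is_soma])
        src_keys_all <- c(src_keys_all, as.numeric(rownames(agg)))
        src_counts[[length(src_counts) + 1]] <- agg[, 1]
      }
      if (any(is_axon)) {
        agg <- rowsum(rep(1, sum(is_axon)), group = keys[is_axon])
        tgt_keys_all <- c(tgt_keys_all, as.numeric(rownames(agg)))
        tgt_counts[[length(tgt_counts) + 1]] <- agg[, 1]
      }

      # decoy artifacts: small connected clusters straddling nothing real
      decoy_px <- 0L
      offsets <- as.matrix(expand.grid(dr = 0:3, dc = 0:2))
      occupied <- raw != 2L
      for (d in seq_len(decoys_per_section[si])) {
        k <- sample(1:11, 1)
        for (attempt in 1:100) {
          r0 <- sample(3:(H - 6), 1)
          c0 <- sample(3:(W - 5), 1)
          win <- occupied[max(1, r0 - 2):min(H, r0 + 5),
                          max(1, c0 - 2):min(W, c0 + 4)]
          if (!any(win)) {
            cells <- cbind(r0 + offsets[1:k, 1], c0 + offsets[1:k, 2])
            raw[cells] <- 1L
            occupied[cells] <- TRUE
            decoy_px <- decoy_px + k
            break
          }
        }
      }
      total_decoy_px <- total_decoy_px + decoy_px

      stem <- sprintf("%s_s%03d", experiment_id, si)
      sections[[stem]] <- list(
        stem = stem, x0 = x0, raw = raw, anchor = anchor, markers = markers,
        decoy_px = decoy_px,
        soma_px = sum(is_soma), axon_px = sum(is_axon)
      )
    }

    mk_cloud <- function(keys, counts) {
      if (length(keys) == 0) return(voxel_cloud(dims = dims))
      voxel_cloud(key_to_vox(keys, dims), unlist(counts), dims)
    }
    planted_support <- function(lst) {
      m <- do.call(rbind, c(list(matrix(numeric(0), 0, 3)), lst))
      unique(m)
    }
    study <- structure(list(
      experiment_id = experiment_id, space_dims = dims,
      sections = sections,
      anchors = lapply(sections, `[[`, "anchor"),
      truth_source = mk_cloud(src_keys_all, src_counts),
      truth_target = mk_cloud(tgt_keys_all, tgt_counts),
      planted_source = planted_support(planted_src),
      planted_target = planted_support(planted_tgt),
      decoy_px = total_decoy_px,
      warp_magnitude_px = warp_magnitude_px, seed = seed
    ), class = "synthetic_study")

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (s in sections) {
        write_label_image(s$raw, file.path(out_dir, paste0(s$stem, ".png")))
      }
      anchors <- stats::setNames(lapply(sections, `[[`, "anchor"),
                                 names(sections))
      write_linear_anchoring(anchors, file.path(
        out_dir, paste0(experiment_id, "_linear.xml")))
      nl <- stats::setNames(lapply(sections, function(s) {
        list(anchor = s$anchor, markers = s$markers)
      }), names(sections))
      write_nonlinear_anchoring(nl, file.path(
        out_dir, paste0(experiment_id, "_nonlinear.json")))
      jsonlite::write_json(
        list(experiment_id = experiment_id,
             decoy_px = total_decoy_px,
             soma_px = sum(vapply(sections, `[[`, integer(1), "soma_px")),
             axon_px = sum(vapply(sections, `[[`, integer(1), "axon_px"))),
        file.path(out_dir, paste0(experiment_id, "_truth.json")),
        auto_unbox = TRUE
      )
      study$dir <- out_dir
    }
    study
  })
}

#' Jaccard index between a recovered cloud and planted truth support
#'
#' @param cloud recovered [voxel_cloud()].
#' @param planted n x 3 matrix of planted truth voxels.
#' @return `|intersection| / |union|` of the two voxel sets.
#' @export
support_jaccard <- function(cloud, planted) {
  a <- vox_key(cloud$coords, cloud$dims)
  b <- vox_key(as.matrix(planted), cloud$dims)
  length(intersect(a, b)) / length(union(a, b))
}
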