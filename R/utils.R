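`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear key for 0-based voxel triples; double arithmetic so full-scale
# grids (1320*800*1140 voxels) stay exact within 2^53.
vox_key <- function(coords, dims) {
  coords[, 1] + dims[1] * (coords[, 2] + dims[2] * coords[, 3])
}

key_to_vox <- function(keys, dims) {
  x <- keys %% dims[1]
  rest <- (keys - x) / dims[1]
  y <- rest %% dims[2]
  z <- (rest - y) / dims[2]
  cbind(x = x, y = y, z = z)
}

as_voxel_matrix <- function(voxel) {
  if (is.matrix(voxel)) {
    stopifnot(ncol(voxel) == 3)
    storage.mode(voxel) <- "double"
    voxel
  } else {
    stopifnot(length(voxel) == 3)
    matrix(as.numeric(voxel), 1, 3)
  }
}

check_in_bounds <- function(coords, dims, what = "voxel") {
  bad <- coords[, 1] < 0 | coords[, 1] >= dims[1] |
    coords[, 2] < 0 | coords[, 2] >= dims[2] |
    coords[, 3] < 0 | coords[, 3] >= dims[3]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "%s (%s) out of bounds for dims (%s)", what,
      paste(coords[i, ], collapse = ", "), paste(dims, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic, well-spread RGB palette for population colours.
population_palette <- function(n) {
  stopifnot(n >= 1)
  hues <- (seq_len(n) - 1) * 360 / n
  grDevices::hcl(h = hues, c = 90, l = 55)
}
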