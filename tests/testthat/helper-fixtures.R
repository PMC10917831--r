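# Shared fixtures, built once per test run.
fixture_env <- new.env()

fx_space <- function() {
  if (is.null(fixture_env$space)) {
    fixture_env$space <- make_reference_space(seed = 42)
  }
  fixture_env$space
}

fx_lookup <- function() {
  if (is.null(fixture_env$lookup)) {
    fixture_env$lookup <- make_flatmap_lookup(fx_space())
  }
  fixture_env$lookup
}

fx_study <- function() {
  if (is.null(fixture_env$study)) {
    fixture_env$study <- make_experiment(fx_space(), seed = 7)
  }
  fixture_env$study
}

key_to_vox_for_test <- function(key, dims) {
  x <- key %% dims[1]
  rest <- (key - x) / dims[1]
  y <- rest %% dims[2]
  c(x, y, (rest - y) / dims[2])
}

# A minimal space: one labeled box (id 42) inside zeros.
tiny_space <- function(dims = c(10, 10, 10), box_id = 42L) {
  ann <- array(0L, dim = dims)
  ann[3:6, 3:6, 3:6] <- box_id
  hier <- region_hierarchy(data.frame(
    id = c(1L, box_id), acronym = c("root", "box"),
    parent_id = c(NA, 1L), layer = c(NA, NA)
  ))
  reference_space(ann, array(1, dim = dims), hier)
}

# Random recoded segmentation image with clustered blobs.
random_seg <- function(nr = 30, nc = 30, n_blobs = 5) {
  m <- matrix(0L, nr, nc)
  for (b in seq_len(n_blobs)) {
    r0 <- sample(seq_len(nr - 4), 1)
    c0 <- sample(seq_len(nc - 4), 1)
    h <- sample(1:4, 1); w <- sample(1:4, 1)
    val <- sample(c(129L, 255L), 1)
    m[r0:(r0 + h), c0:(c0 + w)] <- val
  }
  m
}
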