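identity_warp <- build_warp(matrix(numeric(0), 0, 4), c(10, 10))

test_that("pixels registered to one voxel accumulate its count", {
  sp <- tiny_space()
  seg <- matrix(255L, 10, 10)  # 100 axon pixels
  anchor <- section_anchor(o = c(5.2, 5.2, 5.2), u = c(0.5, 0, 0),
                           v = c(0, 0.5, 0), width_px = 10, height_px = 10)
  out <- voxelize_section(seg, anchor, identity_warp, sp)
  expect_equal(nrow(out$target$coords), 1)
  expect_equal(unname(out$target$coords[1, ]), c(5, 5, 5))
  expect_equal(out$target$counts, 100)
  expect_equal(cloud_total(out$source), 0)
})

test_that("empty segmentations yield empty clouds; geometry is checked", {
  sp <- tiny_space()
  anchor <- section_anchor(c(5, 5, 5), c(1, 0, 0), c(0, 1, 0), 10, 10)
  out <- voxelize_section(matrix(0L, 10, 10), anchor, identity_warp, sp)
  expect_equal(nrow(out$source$coords), 0)
  expect_equal(nrow(out$target$coords), 0)
  expect_error(
    voxelize_section(matrix(0L, 8, 10), anchor, identity_warp, sp),
    "geometry.*does not match")
})

test_that("out-of-space pixels are dropped but reported", {
  sp <- tiny_space()
  seg <- matrix(255L, 10, 10)
  # u pushes half of the image past the x upper bound
  anchor <- section_anchor(c(8, 4, 4), c(4, 0, 0), c(0, 1, 0), 10, 10)
  out <- voxelize_section(seg, anchor, identity_warp, sp)
  expect_gt(out$report$out_of_space, 0)
  expect_equal(cloud_total(out$target) + out$report$out_of_space, 100)
})

test_that("assembly sums counts across sections and conserves pixels", {
  sp <- tiny_space()
  mk_inc <- function(voxel, count) {
    list(source = voxel_cloud(dims = sp$dims),
         target = voxel_cloud(matrix(voxel, 1, 3), count, sp$dims),
         report = list(warp_clamped = 0, out_of_space = 0,
                       soma_pixels = 0, axon_pixels = count))
  }
  rec <- assemble_experiment(list(mk_inc(c(1, 1, 1), 3), mk_inc(c(2, 2, 2), 5)),
                             "e1")
  expect_equal(cloud_total(rec$target), 8)
  expect_equal(nrow(rec$target$coords), 2)
  rec2 <- assemble_experiment(list(mk_inc(c(1, 1, 1), 3), mk_inc(c(1, 1, 1), 4)),
                              "e1")
  expect_equal(rec2$target$counts, 7)

  set.seed(4)
  for (i in 1:20) {
    incs <- lapply(1:4, function(j) mk_inc(sample(0:9, 3, TRUE), sample(1:50, 1)))
    rec <- assemble_experiment(incs, "e")
    expect_equal(cloud_total(rec$target),
                 sum(vapply(incs, function(x) cloud_total(x$target), numeric(1))))
  }
  bad <- mk_inc(c(1, 1, 1), 2)
  bad$target <- voxel_cloud(matrix(c(1, 1, 1), 1, 3), 2, c(5, 5, 5))
  expect_error(assemble_experiment(list(mk_inc(c(1, 1, 1), 1), bad), "e"),
               "mixed cloud dims")
})

test_that("voxelization is order-independent across sections", {
  st <- fx_study()
  sp <- fx_space()
  incs <- lapply(st$sections, function(sec) {
    seg <- clean_small_objects(recode_labels(sec$raw))
    voxelize_section(seg, sec$anchor, build_warp(sec$markers,
                     c(sec$anchor$width_px, sec$anchor$height_px)), sp)
  })
  a <- assemble_experiment(incs, "e")
  b <- assemble_experiment(rev(incs), "e")
  expect_identical(a$target$coords, b$target$coords)
  expect_identical(a$target$counts, b$target$counts)
})

test_that("curation moves extranuclear soma voxels to the target cloud", {
  sp <- fx_space()
  hier <- sp$hierarchy
  vpm_vox <- which(sp$annotation == region_id_of(hier, "VPM"),
                   arr.ind = TRUE)[1, ] - 1
  ctx_vox <- which(sp$annotation == region_id_of(hier, "CTX-A1 layer 4"),
                   arr.ind = TRUE)[1, ] - 1
  rec <- population_record(
    "e1",
    voxel_cloud(rbind(vpm_vox, ctx_vox), c(10, 4), sp$dims),
    voxel_cloud(matrix(ctx_vox, 1, 3), 2, sp$dims)
  )
  cur <- curate_injection_volume(rec, sp, hier, "VPM")
  expect_equal(nrow(cur$source$coords), 1)
  expect_equal(unname(cur$source$coords[1, ]), unname(vpm_vox))
  expect_equal(cur$source$counts, 10)
  expect_equal(cloud_count_at(cur$target, ctx_vox), 6)  # 2 + 4 moved
  expect_equal(cloud_total(cur$source) + cloud_total(cur$target),
               cloud_total(rec$source) + cloud_total(rec$target))
  expect_error(curate_injection_volume(rec, sp, hier, "NOPE"), "unknown acronym")
})

test_that("hemisphere split mirrors right-side voxels and conserves counts", {
  sp <- fx_space()
  nz <- sp$dims[3]
  left_rec <- population_record(
    "e", voxel_cloud(matrix(c(5, 5, 5), 1, 3), 3, sp$dims),
    voxel_cloud(matrix(c(6, 6, 6), 1, 3), 2, sp$dims))
  halves <- split_and_mirror(left_rec, sp)
  expect_equal(cloud_total(halves$right_mapped$source), 0)
  expect_equal(cloud_total(halves$left$source), 3)

  right_voxel <- c(10, 10, nz - 3)
  rec <- population_record(
    "e", voxel_cloud(matrix(right_voxel, 1, 3), 5, sp$dims),
    voxel_cloud(dims = sp$dims))
  halves <- split_and_mirror(rec, sp)
  expect_equal(unname(halves$right_mapped$source$coords[1, ]),
               c(10, 10, nz - 1 - (nz - 3)))

  set.seed(77)
  vox <- cbind(sample(0:(sp$dims[1] - 1), 40, TRUE),
               sample(0:(sp$dims[2] - 1), 40, TRUE),
               sample(0:(nz - 1), 40, TRUE))
  rec <- population_record("e", voxel_cloud(vox, rep(2, 40), sp$dims),
                           voxel_cloud(dims = sp$dims))
  halves <- split_and_mirror(rec, sp)
  expect_equal(cloud_total(halves$left$source) +
                 cloud_total(halves$right_mapped$source), 80)
  # mirrored-collision counts sum when recombined onto the left hemisphere
  pair <- population_record(
    "e", voxel_cloud(rbind(c(3, 3, 4), c(3, 3, nz - 5)), c(2, 7), sp$dims),
    voxel_cloud(dims = sp$dims))
  halves <- split_and_mirror(pair, sp)
  combined <- cloud_merge(halves$left$source, halves$right_mapped$source)
  expect_equal(cloud_count_at(combined, c(3, 3, 4)), 9)
})

test_that("the dominant population wins by count with lexicographic ties", {
  dims <- c(10, 10, 10)
  mk <- function(id, count) {
    population_record(id, voxel_cloud(dims = dims),
                      voxel_cloud(matrix(c(1, 1, 1), 1, 3), count, dims))
  }
  expect_equal(dominant_population(list(mk("A", 5), mk("B", 9)), c(1, 1, 1)), "B")
  expect_equal(dominant_population(list(mk("B", 4), mk("A", 4)), c(1, 1, 1)), "A")
  expect_equal(dominant_population(list(mk("A", 5)), c(1, 1, 1)), "A")
  expect_true(is.na(dominant_population(list(mk("A", 5)), c(2, 2, 2))))
})

test_that("population records round trip through JSON", {
  dims <- c(20, 20, 20)
  rec <- population_record(
    "e9", voxel_cloud(rbind(c(1, 2, 3), c(4, 5, 6)), c(10, 20), dims),
    voxel_cloud(matrix(c(7, 8, 9), 1, 3), 5, dims), "#FF0000")
  d <- withr::local_tempdir()
  p <- file.path(d, "rec.json")
  write_population_record(rec, p)
  back <- read_population_record(p)
  expect_equal(back$experiment_id, "e9")
  expect_equal(back$color, "#FF0000")
  expect_equal(back$source$coords, rec$source$coords)
  expect_equal(back$source$counts, rec$source$counts)
  expect_equal(back$target$counts, rec$target$counts)
})
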