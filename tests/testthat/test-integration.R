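test_that("the population medoid is the exhaustive argmin and a member voxel", {
  dims <- c(50, 50, 50)
  single <- voxel_cloud(matrix(c(3, 4, 5), 1, 3), 1, dims)
  expect_equal(population_medoid(single), c(3, 4, 5))

  line <- voxel_cloud(rbind(c(0, 0, 0), c(2, 0, 0), c(10, 0, 0)),
                      rep(1, 3), dims)
  expect_equal(population_medoid(line), c(2, 0, 0))

  set.seed(19)
  for (rep in 1:3) {
    n <- 200
    co <- unique(cbind(sample(0:49, n, TRUE), sample(0:49, n, TRUE),
                       sample(0:49, n, TRUE)))
    cts <- sample(1:5, nrow(co), TRUE)
    cl <- voxel_cloud(co, cts, dims)
    got <- population_medoid(cl)
    oracle <- oracle_medoid(cl$coords, cl$counts)
    expect_equal(medoid_cost(got, cl$coords, cl$counts),
                 medoid_cost(oracle, cl$coords, cl$counts), tolerance = 1e-9)
    # the medoid is a de facto occupied voxel
    expect_true(any(colSums(abs(t(cl$coords) - got)) == 0))
  }
  expect_error(population_medoid(voxel_cloud(dims = dims)), "empty")
})

test_that("count weighting can move the medoid; a flag disables it", {
  dims <- c(50, 50, 50)
  cl <- voxel_cloud(rbind(c(0, 0, 0), c(10, 0, 0)), c(100, 1), dims)
  expect_equal(population_medoid(cl, weighted = TRUE), c(0, 0, 0))
  cl2 <- voxel_cloud(rbind(c(0, 0, 0), c(4, 0, 0), c(10, 0, 0)), c(1, 1, 100),
                     dims)
  expect_equal(population_medoid(cl2, weighted = TRUE), c(10, 0, 0))
  expect_equal(population_medoid(cl2, weighted = FALSE), c(4, 0, 0))
})

test_that("the membership radius is 1.5x the maximum soma distance", {
  dims <- c(50, 50, 50)
  single <- voxel_cloud(matrix(c(3, 4, 5), 1, 3), 1, dims)
  expect_equal(membership_radius(single, c(3, 4, 5)), 0)

  cl <- voxel_cloud(rbind(c(10, 10, 10), c(18, 10, 10)), c(5, 1), dims)
  expect_equal(membership_radius(cl, c(10, 10, 10)), 12)  # 1.5 * 8

  set.seed(23)
  for (rep in 1:5) {
    co <- cbind(sample(0:49, 30, TRUE), sample(0:49, 30, TRUE),
                sample(0:49, 30, TRUE))
    cl <- voxel_cloud(co, rep(1, 30), dims)
    med <- population_medoid(cl)
    maxd <- max(sqrt(rowSums((cl$coords -
                                matrix(med, nrow(cl$coords), 3, TRUE))^2)))
    if (maxd > 0) {
      expect_equal(membership_radius(cl, med) / maxd, 1.5)
    }
  }
})

test_that("membership uses a closed ball and is monotone in radius", {
  dims <- c(100, 100, 100)
  mk <- function(id, soma) list(neuron_id = id, soma = soma,
                                terminals = matrix(c(50, 50, 50), 1, 3))
  medoid <- c(50, 50, 50)
  at_r <- mk("edge", c(50 + 12, 50, 50))
  out <- classify_members(list(at_r), medoid, 12, dims)
  expect_equal(out$members, "edge")
  beyond <- mk("out", c(50 + 12 * 1.01, 50, 50))
  expect_length(classify_members(list(beyond), medoid, 12, dims)$members, 0)
  none <- classify_members(list(), medoid, 12, dims)
  expect_length(none$members, 0)
  expect_equal(nrow(none$terminals$coords), 0)

  set.seed(29)
  morphs <- lapply(1:20, function(i) mk(sprintf("n%02d", i),
                                        runif(3, 0, 99)))
  prev <- character(0)
  for (r in c(10, 25, 40, 80)) {
    cur <- classify_members(morphs, medoid, r, dims)$members
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("pooled member terminals are floor-binned with unit counts", {
  dims <- c(20, 20, 20)
  m1 <- list(neuron_id = "a", soma = c(5, 5, 5),
             terminals = rbind(c(1.2, 1.7, 1.9), c(1.8, 1.1, 1.3), c(3.5, 2, 2)))
  out <- classify_members(list(m1), c(5, 5, 5), 10, dims)
  expect_equal(cloud_count_at(out$terminals, c(1, 1, 1)), 2)
  expect_equal(cloud_count_at(out$terminals, c(3, 2, 2)), 1)
})

test_that("the nearest bulk experiment matches an exhaustive scan", {
  dims <- c(50, 50, 50)
  rec <- population_record(
    "pop", voxel_cloud(matrix(c(25, 25, 25), 1, 3), 1, dims),
    voxel_cloud(dims = dims))
  one <- data.frame(experiment_id = "only", x = 1, y = 2, z = 3)
  expect_equal(nearest_bulk_experiment(rec, one), "only")

  cat3 <- data.frame(experiment_id = c("d5", "d3", "d9"),
                     x = c(30, 28, 34), y = 25, z = 25)
  expect_equal(nearest_bulk_experiment(rec, cat3), "d3")
  expect_error(nearest_bulk_experiment(rec, cat3[0, ]), "empty")

  set.seed(37)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    cat <- data.frame(experiment_id = sprintf("b%02d", sample(99, k)),
                      x = runif(k, 0, 49), y = runif(k, 0, 49),
                      z = runif(k, 0, 49))
    d <- sqrt((cat$x - 25)^2 + (cat$y - 25)^2 + (cat$z - 25)^2)
    expect_equal(nearest_bulk_experiment(rec, cat),
                 sort(cat$experiment_id[d == min(d)])[1])
  }
  tie <- data.frame(experiment_id = c("zz", "aa"), x = c(26, 24), y = 25, z = 25)
  expect_equal(nearest_bulk_experiment(rec, tie), "aa")
})

test_that("overlap states partition the flat grid into the three-state map", {
  a <- matrix(0, 10, 10); b <- matrix(0, 10, 10)
  a[1:5, ] <- 2; b[1:5, ] <- 7
  st <- overlap_states(a, b)
  expect_equal(sum(unclass(st) == 1), 50)        # all nonzero is overlap
  expect_equal(sum(unclass(st) == 0), 50)

  disj_a <- matrix(0, 10, 10); disj_b <- matrix(0, 10, 10)
  disj_a[1:3, ] <- 1; disj_b[8:10, ] <- 1
  st2 <- overlap_states(disj_a, disj_b)
  expect_equal(sum(unclass(st2) == 1), 0)

  # constructed 10x10 with 20 overlap / 30 population / 10 other pixels
  p <- matrix(0, 10, 10); o <- matrix(0, 10, 10)
  p[1:50] <- 1
  o[1:20] <- 1; o[51:60] <- 1
  st3 <- overlap_states(p, o)
  counts <- attr(overlap_fractions(st3, matrix(TRUE, 10, 10)), "counts")
  expect_equal(unname(counts), c(20, 30, 10))
  expect_equal(sum(unclass(st3) %in% 0:3), 100)  # exhaustive partition
  expect_error(overlap_states(p, matrix(0, 9, 10)), "flat dims differ")
})

test_that("overlap fractions normalize over targeted points (or the area)", {
  p <- matrix(0, 10, 10); o <- matrix(0, 10, 10)
  p[1:45] <- 1; o[1:45] <- 1
  all_over <- overlap_fractions(overlap_states(p, o), matrix(TRUE, 10, 10))
  expect_equal(as.numeric(all_over), c(1, 0, 0))

  p2 <- matrix(0, 9, 10); o2 <- matrix(0, 9, 10)
  p2[1:30] <- 1; o2[16:45] <- 1   # 15 overlap, 15 pop-only, 15 other-only
  fr <- overlap_fractions(overlap_states(p2, o2), matrix(TRUE, 9, 10))
  expect_equal(as.numeric(fr), rep(1 / 3, 3))
  expect_equal(sum(fr), 1, tolerance = 1e-9)

  # planted 45/35/20 split over 100 targeted pixels
  p3 <- matrix(0, 10, 10); o3 <- matrix(0, 10, 10)
  p3[1:80] <- 1          # 45 overlap + 35 pop-only
  o3[1:45] <- 1; o3[81:100] <- 1
  fr3 <- overlap_fractions(overlap_states(p3, o3), matrix(TRUE, 10, 10))
  expect_equal(as.numeric(fr3), c(0.45, 0.35, 0.20))
  fr3area <- overlap_fractions(overlap_states(p3, o3), matrix(TRUE, 10, 10),
                               denominator = "area")
  expect_equal(as.numeric(fr3area), c(0.45, 0.35, 0.20))  # all 100 pixels targeted

  mask <- matrix(FALSE, 10, 10)
  mask[1, 1] <- TRUE
  p4 <- matrix(0, 10, 10)
  expect_warning(overlap_fractions(overlap_states(p4, p4), mask), "no targeted")
})

test_that("SWC morphologies round trip and expose axon terminal leaves", {
  d <- withr::local_tempdir()
  nodes <- data.frame(
    id = 1:5, type = c(1, 2, 2, 2, 2),
    x = c(10, 12, 14.25, 13, 16.5), y = c(20, 21, 22, 23, 24.125),
    z = c(30, 31, 32, 33, 34), radius = 1,
    parent = c(-1, 1, 2, 2, 4)
  )
  p <- file.path(d, "n1.swc")
  write_swc(nodes, p)
  m <- read_swc(p)
  expect_equal(m$neuron_id, "n1")
  expect_identical(m$soma, c(10, 20, 30))
  # leaves of the axon subtree: nodes 3 and 5 (4 has a child)
  expect_equal(m$terminals, rbind(c(14.25, 22, 32), c(16.5, 24.125, 34)),
               ignore_attr = TRUE)
})
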