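make_anchor <- function() {
  section_anchor(o = c(100, 200, 300), u = c(500, 0, 0), v = c(0, 400, 0),
                 width_px = 1000, height_px = 800, stem = "exp_s001")
}

test_that("linear anchoring XML parses, validates and round-trips bit-exactly", {
  d <- withr::local_tempdir()
  anchors <- list(
    exp_s001 = make_anchor(),
    exp_s002 = section_anchor(o = c(1 / 3, sqrt(2), pi), u = c(500.25, 1e-7, 0),
                              v = c(0, 400.125, -2 / 7), 1000, 800, "exp_s002")
  )
  p <- file.path(d, "linear.xml")
  write_linear_anchoring(anchors, p)
  back <- read_linear_anchoring(p)
  expect_equal(names(back), names(anchors))
  for (stem in names(anchors)) {
    expect_identical(back[[stem]]$o, anchors[[stem]]$o)
    expect_identical(back[[stem]]$u, anchors[[stem]]$u)
    expect_identical(back[[stem]]$v, anchors[[stem]]$v)
    expect_equal(back[[stem]]$width_px, anchors[[stem]]$width_px)
  }

  xml <- paste0(
    '<series><slice filename="exp_s003.png" width="10" height="10" ',
    'ox="1" oy="2" oz="3" ux="4" uy="5" uz="6" vx="7" vy="8"/></series>'
  )
  bad <- file.path(d, "bad.xml")
  writeLines(xml, bad)
  expect_error(read_linear_anchoring(bad), "exp_s003.*vz|vz.*exp_s003")
})

test_that("nonlinear anchoring JSON carries anchors plus markers", {
  d <- withr::local_tempdir()
  mk <- cbind(sx = c(100, 200, 300, 400), sy = c(100, 150, 650, 700),
              tx = c(110, 200, 290, 400), ty = c(100, 160, 650, 690))
  slices <- list(exp_s001 = list(anchor = make_anchor(), markers = mk),
                 exp_s002 = list(anchor = make_anchor(),
                                 markers = matrix(numeric(0), 0, 4)))
  slices$exp_s002$anchor$stem <- "exp_s002"
  pj <- file.path(d, "nl.json")
  write_nonlinear_anchoring(slices, pj)
  back <- read_nonlinear_anchoring(pj)
  expect_equal(nrow(back$exp_s001$markers), 4)
  expect_equal(unname(back$exp_s001$markers), unname(mk))
  expect_equal(nrow(back$exp_s002$markers), 0)
  w <- build_warp(back$exp_s002$markers, c(1000, 800))
  expect_true(w$identity)

  # anchors in the JSON dialect equal anchors in the paired XML dialect
  px <- file.path(d, "lin.xml")
  write_linear_anchoring(lapply(slices, `[[`, "anchor"), px)
  xml_anchors <- read_linear_anchoring(px)
  for (stem in names(slices)) {
    expect_identical(back[[stem]]$anchor$o, xml_anchors[[stem]]$o)
    expect_identical(back[[stem]]$anchor$u, xml_anchors[[stem]]$u)
    expect_identical(back[[stem]]$anchor$v, xml_anchors[[stem]]$v)
  }
})

test_that("the linear pixel transform evaluates the anchoring form", {
  a <- make_anchor()
  expect_equal(linear_pixel_to_ccf(a, c(0, 0)), a$o)
  expect_equal(linear_pixel_to_ccf(a, c(1000, 0)), a$o + a$u)
  expect_equal(linear_pixel_to_ccf(a, c(0, 800)), a$o + a$v)
  b <- section_anchor(c(100, 200, 300), c(500, 0, 0), c(0, 400, 0), 1000, 1000)
  expect_equal(linear_pixel_to_ccf(b, c(500, 250)), c(350, 300, 300))
  expect_error(linear_pixel_to_ccf(b, c(0, 0), image_dims = c(0, 10)), "zero-sized")
  expect_error(section_anchor(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 10, 10),
               "parallel")
})

test_that("zero-marker warps are the identity everywhere", {
  w <- build_warp(matrix(numeric(0), 0, 4), c(100, 80))
  pts <- as.matrix(expand.grid(x = seq(0, 100, 10), y = seq(0, 80, 8)))
  expect_equal(warp_points(w, pts), pts)
})

test_that("warps are exact at markers and pinned at corners", {
  mk <- cbind(50, 50, 40, 50)  # pulled 10 px left
  w <- build_warp(mk, c(100, 100))
  expect_equal(warp_points(w, c(50, 50)), c(40, 50), tolerance = 1e-12)
  for (corner in list(c(0, 0), c(100, 0), c(0, 100), c(100, 100))) {
    expect_equal(warp_points(w, corner), corner, tolerance = 1e-12)
  }
  # the reference-space shift at the marker is exactly (10/width) * u
  a <- make_anchor()
  shifted <- section_pixel_to_reference(a, w, c(50, 50), c(100, 100))
  straight <- linear_pixel_to_ccf(a, c(50, 50), c(100, 100))
  expect_equal(shifted$coords[1, ] - straight, -10 / 100 * a$u, tolerance = 1e-12)
})

test_that("random warps agree with the per-triangle affine oracle", {
  set.seed(14)
  for (rep in 1:3) {
    sx <- runif(6, 10, 90); sy <- runif(6, 10, 90)
    mk <- cbind(sx, sy, sx + runif(6, -8, 8), sy + runif(6, -8, 8))
    w <- build_warp(mk, c(100, 100))
    # exactness at markers
    at_mk <- warp_points(w, mk[, 1:2])
    expect_equal(at_mk, mk[, 3:4], tolerance = 1e-9, ignore_attr = TRUE)
    # interior points against the oracle
    pts <- cbind(runif(350, 0, 100), runif(350, 0, 100))
    got <- warp_points(w, pts)
    for (i in seq_len(nrow(pts))) {
      expected <- oracle_warp_point(w, pts[i, ])
      if (!is.null(expected)) {
        expect_equal(got[i, ], expected, tolerance = 1e-7, ignore_attr = TRUE)
      }
    }
  }
})

test_that("warps are continuous across shared triangle edges", {
  set.seed(15)
  sx <- runif(6, 10, 90); sy <- runif(6, 10, 90)
  w <- build_warp(cbind(sx, sy, sx + runif(6, -6, 6), sy + runif(6, -6, 6)),
                  c(100, 100))
  tris <- w$triangles
  edge_key <- function(i, j) paste(min(i, j), max(i, j))
  edges <- list()
  for (t in seq_len(nrow(tris))) {
    for (pair in list(tris[t, c(1, 2)], tris[t, c(2, 3)], tris[t, c(1, 3)])) {
      k <- edge_key(pair[1], pair[2])
      edges[[k]] <- c(edges[[k]], t)
    }
  }
  shared <- Filter(function(ts) length(ts) == 2, edges)
  expect_gt(length(shared), 0)
  for (k in names(shared)) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    a <- w$src[ij[1], ]; b <- w$src[ij[2], ]
    for (lam in c(0.2, 0.5, 0.8)) {
      p <- matrix(a + lam * (b - a), 1, 2)
      vals <- lapply(shared[[k]], function(t) {
        tr <- tris[t, ]
        triangle_affine_apply(w$src[tr, ], w$dst[tr, ], p)
      })
      expect_equal(vals[[1]], vals[[2]], tolerance = 1e-9)
    }
  }
})

test_that("the piecewise map preserves collinearity within one triangle", {
  set.seed(16)
  sx <- runif(5, 20, 80); sy <- runif(5, 20, 80)
  w <- build_warp(cbind(sx, sy, sx + runif(5, -5, 5), sy + runif(5, -5, 5)),
                  c(100, 100))
  tr <- w$triangles[1, ]
  ctr <- colMeans(w$src[tr, ])
  v1 <- (w$src[tr[1], ] - ctr) * 0.3
  pts <- rbind(ctr - v1, ctr, ctr + v1)  # collinear, inside the triangle
  out <- warp_points(w, pts)
  mid <- (out[1, ] + out[3, ]) / 2
  expect_equal(out[2, ], mid, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("contradictory and out-of-rectangle markers are rejected", {
  expect_error(
    build_warp(rbind(c(10, 10, 20, 20), c(10, 10, 30, 30)), c(100, 100)),
    "contradictory")
  expect_error(build_warp(cbind(150, 50, 140, 50), c(100, 100)),
               "within the image rectangle")
})

test_that("points warped out of the rectangle are clamped and flagged", {
  # marker near the left edge pushing further left
  w <- build_warp(cbind(5, 50, -10, 50), c(100, 100))
  a <- make_anchor()
  res <- section_pixel_to_reference(a, w, rbind(c(5, 50), c(80, 50)), c(100, 100))
  expect_true(res$clamped[1])
  expect_false(res$clamped[2])
  expect_equal(res$coords[1, ], linear_pixel_to_ccf(a, c(0, 50), c(100, 100)))
})
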