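# Independent oracles, deliberately implemented with different algorithms
# than the package (breadth-first flood fill, exhaustive search, direct
# per-triangle solves).

# Flood-fill connected components under the squared-distance <= 3 rule.
bfs_components <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  comp <- matrix(0L, nr, nc)
  next_id <- 0L
  for (start in which(labels != 0)) {
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    queue <- start
    comp[start] <- next_id
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1) %% nr + 1
      c <- (cur - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        if (dr^2 + dc^2 > 3) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        i2 <- (c2 - 1) * nr + r2
        if (labels[i2] != 0 && comp[i2] == 0L) {
          comp[i2] <- next_id
          queue <- c(queue, i2)
        }
      }
    }
  }
  comp
}

oracle_clean <- function(labels, min_px = 12) {
  comp <- bfs_components(labels)
  out <- labels
  if (max(comp) > 0) {
    sizes <- tabulate(comp[comp > 0])
    out[comp > 0 & comp %in% which(sizes < min_px)] <- 0L
  }
  out
}

# Exhaustive weighted-medoid cost of one candidate.
medoid_cost <- function(candidate, coords, counts) {
  sum(counts * sqrt(rowSums((coords - matrix(candidate, nrow(coords), 3,
                                             byrow = TRUE))^2)))
}

oracle_medoid <- function(coords, counts) {
  costs <- vapply(seq_len(nrow(coords)),
                  function(i) medoid_cost(coords[i, ], coords, counts),
                  numeric(1))
  coords[which.min(costs), ]
}

# Solve the affine map of one triangle directly and apply it.
triangle_affine_apply <- function(src3, dst3, p) {
  A <- cbind(src3, 1)            # 3 x 3
  bx <- solve(A, dst3[, 1])
  by <- solve(A, dst3[, 2])
  cbind(p[, 1] * bx[1] + p[, 2] * bx[2] + bx[3],
        p[, 1] * by[1] + p[, 2] * by[2] + by[3])
}

# Locate the triangle containing p (min barycentric >= -tol), brute force.
oracle_warp_point <- function(warp, p, tol = 1e-9) {
  for (t in seq_len(nrow(warp$triangles))) {
    tr <- warp$triangles[t, ]
    src3 <- warp$src[tr, , drop = FALSE]
    a <- src3[1, ]; b <- src3[2, ]; c <- src3[3, ]
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-12) next
    wb <- ((p[1] - a[1]) * (c[2] - a[2]) - (p[2] - a[2]) * (c[1] - a[1])) / det
    wc <- ((p[2] - a[2]) * (b[1] - a[1]) - (p[1] - a[1]) * (b[2] - a[2])) / det
    wa <- 1 - wb - wc
    if (min(wa, wb, wc) >= -tol) {
      dst3 <- warp$dst[tr, , drop = FALSE]
      return(as.numeric(triangle_affine_apply(src3, dst3, matrix(p, 1, 2))))
    }
  }
  NULL
}
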