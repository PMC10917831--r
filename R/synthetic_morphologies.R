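#' Generate synthetic single-neuron morphologies around a population
#'
#' Places member somata strictly inside the population's membership ball
#' (medoid plus 1.5x max soma distance) and non-member somata strictly
#' outside it, with axon terminal points drawn near the population's axon
#' target for members and at a displaced location for non-members. Each
#' neuron is emitted as a small SWC tree whose axon leaves are exactly its
#' terminal points.
#'
#' @param space a [reference_space()] (for bounds).
#' @param population_truth nonempty [voxel_cloud()] of the population's
#'   soma voxels.
#' @param n_members,n_nonmembers how many morphologies of each role.
#' @param seed RNG seed.
#' @param target_center optional 3D coordinate terminals of members cluster
#'   around; defaults to the centroid of `population_truth` shifted toward
#'   low y (a cortical stand-in).
#' @param radius_factor membership-ball inflation factor (1.5).
#' @param out_dir when given, writes one `.swc` per neuron plus
#'   `catalogue.csv` (neuron_id, member flag, soma coordinates).
#' @return List with `morphologies` (see [read_swc()] shape), `catalogue`
#'   data frame, `medoid` and `radius` used.
#' @export
make_morphologies <- function(space, population_truth, n_members = 3,
                              n_nonmembers = 3, seed = 1,
                              target_center = NULL, radius_factor = 1.5,
                              out_dir = NULL) {
  if (nrow(population_truth$coords) == 0) stop("population truth is empty")
  dims <- space$dims
  medoid <- population_medoid(population_truth)
  maxd <- max(sqrt(rowSums((population_truth$coords -
                              matrix(medoid, nrow(population_truth$coords), 3,
                                     byrow = TRUE))^2)))
  radius <- radius_factor * max(maxd, 1)
  if (is.null(target_center)) {
    target_center <- colMeans(population_truth$coords)
    target_center[2] <- max(2, target_center[2] - dims[2] * 0.4)
  }
  clamp <- function(p) pmin(pmax(p, 0.5), dims - 0.51)

  with_seed(seed, {
    rand_dir <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2))
    }
    mk <- function(i, member) {
      soma <- if (member) {
        medoid + rand_dir() * stats::runif(1, 0, 0.9 * radius)
      } else {
        medoid + rand_dir() * stats::runif(1, 1.15 * radius, 1.6 * radius)
      }
      soma <- clamp(soma)
      # non-members can be clamped back inside the ball at the volume edge;
      # push along y (plenty of room) until genuinely outside
      if (!member) {
        tries <- 0
        while (sqrt(sum((soma - medoid)^2)) <= radius && tries < 50) {
          soma <- clamp(medoid + rand_dir() * stats::runif(1, 1.15, 1.6) * radius)
          tries <- tries + 1
        }
      }
      ctr <- if (member) target_center else clamp(target_center + c(0, 0, dims[3] * 0.3))
      terminals <- t(vapply(1:5, function(j) {
        clamp(ctr + stats::rnorm(3, 0, 1.5))
      }, numeric(3)))
      id <- sprintf("%s%02d", if (member) "member" else "far", i)
      list(neuron_id = id, soma = soma, terminals = terminals, member = member)
    }
    morphs <- c(
      lapply(seq_len(n_members), mk, member = TRUE),
      lapply(seq_len(n_nonmembers), mk, member = FALSE)
    )
    catalogue <- data.frame(
      neuron_id = vapply(morphs, `[[`, character(1), "neuron_id"),
      member = vapply(morphs, `[[`, logical(1), "member"),
      x = vapply(morphs, function(m) m$soma[1], numeric(1)),
      y = vapply(morphs, function(m) m$soma[2], numeric(1)),
      z = vapply(morphs, function(m) m$soma[3], numeric(1)),
      stringsAsFactors = FALSE
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (m in morphs) {
        nt <- nrow(m$terminals)
        nodes <- data.frame(
          id = 1, type = 1, x = m$soma[1], y = m$soma[2], z = m$soma[3],
          radius = 1, parent = -1
        )
        for (j in seq_len(nt)) {
          mid <- (m$soma + m$terminals[j, ]) / 2
          nodes <- rbind(
            nodes,
            data.frame(id = 2 * j, type = 2, x = mid[1], y = mid[2], z = mid[3],
                       radius = 0.5, parent = 1),
            data.frame(id = 2 * j + 1, type = 2, x = m$terminals[j, 1],
                       y = m$terminals[j, 2], z = m$terminals[j, 3],
                       radius = 0.5, parent = 2 * j)
          )
        }
        write_swc(nodes, file.path(out_dir, paste0(m$neuron_id, ".swc")))
      }
      utils::write.csv(catalogue, file.path(out_dir, "catalogue.csv"),
                       row.names = FALSE)
    }
    list(morphologies = morphs, catalogue = catalogue,
         medoid = medoid, radius = radius)
  })
}
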