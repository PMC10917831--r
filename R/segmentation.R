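# Post-processing of raw 3-label pixel-classifier output.

#' Segmentation label values
#'
#' Raw classifier labels (1 = axon, 2 = background, 3 = soma/injection) are
#' recoded to well-separated gray values: axon 255 (white), background 0
#' (black), soma 129 (gray).
#' @name seg_labels
NULL

SEG_AXON <- 255L
SEG_BACKGROUND <- 0L
SEG_SOMA <- 129L

#' Recode raw classifier labels to the gray-value convention
#'
#' Maps 1 -> 255 (axon), 2 -> 0 (background), 3 -> 129 (soma). Images that
#' already use the recoded values pass through unchanged, so the operation
#' is idempotent.
#'
#' @param raw 2D integer matrix over `{1, 2, 3}` (or already-recoded
#'   `{0, 129, 255}`).
#' @return Integer matrix over `{0, 129, 255}`, same shape.
#' @export
recode_labels <- function(raw) {
  stopifnot(is.matrix(raw))
  vals <- as.integer(raw)
  allowed <- c(1L, 2L, 3L, 0L, 129L, 255L)
  bad <- !vals %in% allowed
  if (any(bad)) {
    tab <- table(vals[bad])
    stop("unexpected label values: ",
         paste(sprintf("{%s: %d}", names(tab), tab), collapse = ", "))
  }
  out <- vals
  out[vals == 1L] <- SEG_AXON
  out[vals == 2L] <- SEG_BACKGROUND
  out[vals == 3L] <- SEG_SOMA
  matrix(out, nrow(raw), ncol(raw))
}

# 8-connectivity component labelling over the nonzero pixels. Two pixels
# belong to the same object when their squared Euclidean distance is <= 3
# (up to 3 orthogonal steps in a 3D generalization); in 2D that admits the
# diagonals (squared distance 2) and excludes distance-2 jumps.
label_components <- function(labels) {
  nz <- which(labels != 0)
  comp <- integer(length(labels))
  if (length(nz) == 0) return(matrix(comp, nrow(labels), ncol(labels)))
  nr <- nrow(labels); nc <- ncol(labels)
  row <- (nz - 1) %% nr + 1
  col <- (nz - 1) %/% nr + 1
  pos <- integer(length(labels))
  pos[nz] <- seq_along(nz)
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- (c2[ok] - 1) * nr + r2[ok]
    hit <- labels[nb] != 0
    if (any(hit)) {
      edges <- c(edges, rbind(pos[nz[ok]][hit], pos[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(nz), directed = FALSE)
  comp[nz] <- igraph::components(g)$membership
  matrix(comp, nr, nc)
}

#' Remove small false-positive objects from a segmented section
#'
#' Objects (8-connected components over the union of axon and soma pixels;
#' neighbour rule: squared Euclidean distance <= 3) with fewer than
#' `min_object_px` pixels are classified as false positives and set to
#' background. Surviving pixels keep their original labels. The default
#' threshold removes objects with less than 12 pixels.
#'
#' @param labels 2D matrix over `{0, 129, 255}` ([recode_labels()] output).
#' @param min_object_px minimum object size to survive (default 12).
#' @return Cleaned matrix; attribute `"report"` lists components found and
#'   removed and pixels removed per label.
#' @export
clean_small_objects <- function(labels, min_object_px = 12) {
  stopifnot(min_object_px >= 1)
  comp <- label_components(labels)
  if (max(comp) == 0) {
    out <- labels
    attr(out, "report") <- list(components = 0L, removed = 0L,
                                pixels_removed = c(axon = 0L, soma = 0L))
    return(out)
  }
  sizes <- tabulate(comp[comp > 0])
  kill <- which(sizes < min_object_px)
  out <- labels
  drop_mask <- comp > 0 & comp %in% kill
  removed_ax <- sum(out[drop_mask] == SEG_AXON)
  removed_soma <- sum(out[drop_mask] == SEG_SOMA)
  out[drop_mask] <- 0L
  attr(out, "report") <- list(
    components = length(sizes), removed = length(kill),
    pixels_removed = c(axon = removed_ax, soma = removed_soma)
  )
  out
}

#' Read a raw or recoded label image from PNG
#'
#' Gray PNG values are rescaled from `[0, 1]` back to 8-bit integers, so a
#' raw classifier image stores labels `{1, 2, 3}` as `{1, 2, 3} / 255`.
#'
#' @param path PNG file.
#' @return Integer label matrix.
#' @export
read_label_image <- function(path) {
  img <- read_section_image(path)
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Write a label image as PNG
#' @param labels integer matrix of 8-bit label values.
#' @param path output PNG.
#' @export
write_label_image <- function(labels, path) {
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Shell command for an external headless pixel classifier
#'
#' Adapter contract only: given a trained classifier project and input
#' images, returns the command line that would produce sibling files
#' suffixed `_SimpleSegmentation`. The package never invokes it in tests;
#' classifier training itself is out of scope.
#'
#' @param classifier_path trained classifier project file.
#' @param image_paths input section images.
#' @param executable classifier executable name.
#' @return The command string.
#' @export
headless_segmentation_command <- function(classifier_path, image_paths,
                                          executable = "ilastik") {
  paste(
    executable, "--headless",
    paste0("--project=", shQuote(classifier_path)),
    "--export_source=\"Simple Segmentation\"",
    paste(shQuote(image_paths), collapse = " ")
  )
}
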