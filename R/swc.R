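# SWC single-neuron morphology I/O. Coordinates are kept in the units of
# the file; synthetic fixtures store reference-space voxel units directly.

SWC_SOMA_TYPE <- 1L
SWC_AXON_TYPE <- 2L

#' Read a single-neuron morphology from SWC
#'
#' Parses the standard 7-column SWC table (`id type x y z radius parent`).
#' The soma is the first type-1 node; the axon terminal points are the leaf
#' nodes of axon-typed (type 2) subtrees, i.e. axon nodes that no other
#' node names as parent — the endpoints of the terminal branches.
#'
#' @param path SWC file.
#' @param neuron_id identifier; defaults to the file stem.
#' @return A `morphology` list: `neuron_id`, `soma` (3D coordinate),
#'   `terminals` (n x 3 matrix), `nodes` (full table).
#' @export
read_swc <- function(path, neuron_id = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("empty SWC file: ", path)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  nodes <- as.data.frame(m)
  soma_row <- which(nodes$type == SWC_SOMA_TYPE)[1]
  if (is.na(soma_row)) soma_row <- 1L
  soma <- as.numeric(nodes[soma_row, c("x", "y", "z")])
  axon <- nodes$type == SWC_AXON_TYPE
  has_child <- nodes$id %in% nodes$parent
  term <- axon & !has_child
  terminals <- as.matrix(nodes[term, c("x", "y", "z"), drop = FALSE])
  rownames(terminals) <- NULL
  list(
    neuron_id = neuron_id %||% tools::file_path_sans_ext(basename(path)),
    soma = soma, terminals = terminals, nodes = nodes
  )
}

#' Write a morphology node table to SWC
#' @param nodes data frame with SWC columns `id type x y z radius parent`.
#' @param path output file.
#' @export
write_swc <- function(nodes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  apply(nodes, 1, function(r) {
    writeLines(paste(sprintf("%.17g", as.numeric(r)), collapse = " "), con)
  })
  invisible(path)
}

#' Read pre-extracted terminal points from a JSON point list
#'
#' Dialect for morphologies distributed as point lists rather than SWC
#' trees: `{neuron_id, soma: [x,y,z], terminals: [[x,y,z], ...]}`.
#'
#' @param path JSON file.
#' @return A `morphology` list as from [read_swc()] (without `nodes`).
#' @export
read_morphology_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  term <- doc$terminals
  if (is.null(dim(term))) term <- matrix(as.numeric(term), ncol = 3, byrow = TRUE)
  list(neuron_id = doc$neuron_id, soma = as.numeric(doc$soma),
       terminals = term)
}

#' Read all SWC morphologies in a directory
#' @param dir directory containing `.swc` files.
#' @return List of morphologies.
#' @export
read_swc_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.swc$", full.names = TRUE))
  lapply(files, read_swc)
}
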