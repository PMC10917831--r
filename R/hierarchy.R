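#' Region hierarchy for a parcellation
#'
#' A `region_hierarchy` is a validated data frame with one row per brain
#' region: integer `id`, unique `acronym`, `parent_id` (`NA` for the single
#' root) and a cortical `layer` tag, one of `"1"`, `"2/3"`, `"4"`, `"5"`,
#' `"6a"`, `"6b"` or `NA` for non-laminar regions.
#'
#' @param df data frame with columns `id`, `acronym`, `parent_id`, `layer`.
#' @return A `region_hierarchy` object.
#' @export
region_hierarchy <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "acronym", "parent_id") %in% names(df)))
  if (is.null(df$layer)) df$layer <- NA_character_
  df$id <- as.integer(df$id)
  df$parent_id <- as.integer(df$parent_id)
  df$acronym <- as.character(df$acronym)
  df$layer <- as.character(df$layer)
  if (anyDuplicated(df$id)) stop("duplicated region ids in hierarchy")
  if (anyDuplicated(df$acronym)) stop("duplicated acronyms in hierarchy")
  roots <- which(is.na(df$parent_id))
  if (length(roots) != 1) {
    stop(sprintf("hierarchy must have exactly one root, found %d", length(roots)))
  }
  known_layers <- c("1", "2/3", "4", "5", "6a", "6b")
  bad <- !is.na(df$layer) & !(df$layer %in% known_layers)
  if (any(bad)) stop("unknown layer tags: ", paste(unique(df$layer[bad]), collapse = ", "))
  # acyclicity: walk every chain to the root
  idx <- match(df$parent_id, df$id)
  if (any(!is.na(df$parent_id) & is.na(idx))) stop("parent_id not present in hierarchy")
  for (i in seq_len(nrow(df))) {
    seen <- integer(0)
    j <- i
    while (!is.na(j)) {
      if (j %in% seen) stop("cycle detected in hierarchy at id ", df$id[i])
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  structure(df, class = c("region_hierarchy", "data.frame"))
}

#' Read a region hierarchy from JSON
#'
#' Expects a JSON array of records `{id, acronym, parent_id, layer}`;
#' `parent_id` null marks the root, `layer` null a non-laminar region.
#'
#' @param path JSON file path.
#' @return A [region_hierarchy()].
#' @export
read_region_hierarchy <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(recs$layer)) recs$layer <- NA_character_
  region_hierarchy(recs)
}

#' Write a region hierarchy to JSON
#' @param hier a [region_hierarchy()].
#' @param path output file.
#' @export
write_region_hierarchy <- function(hier, path) {
  jsonlite::write_json(as.data.frame(hier), path, auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Convert an Allen-style structure graph to a flat hierarchy
#'
#' Consumes the nested `{id, acronym, children: [...]}` JSON dialect used by
#' common atlas services and flattens it to the package's hierarchy records,
#' deriving layer tags from acronym suffixes via [parse_layer_tag()].
#'
#' @param path JSON file with a nested structure graph (a single root object
#'   or a list `msg` containing it).
#' @return A [region_hierarchy()].
#' @export
read_allen_structure_graph <- function(path) {
  root <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(root$msg)) root <- root$msg[[1]]
  rows <- list()
  walk <- function(node, parent_id) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = as.integer(node$id), acronym = as.character(node$acronym),
      parent_id = if (is.null(parent_id)) NA_integer_ else as.integer(parent_id),
      layer = parse_layer_tag(as.character(node$acronym)),
      stringsAsFactors = FALSE
    )
    for (ch in node$children %||% list()) walk(ch, node$id)
  }
  walk(root, NULL)
  region_hierarchy(do.call(rbind, rows))
}

#' Derive a cortical layer tag from an ARA-style acronym
#'
#' Fallback parser for hierarchies that do not carry explicit layer tags:
#' recognises suffixes such as `"SSp-bfd4"`, `"SSp-bfd2/3"`, `"SSs6a"` and
#' the spelled-out `"... layer 4"` form.
#'
#' @param acronym character vector of region acronyms.
#' @return character vector of layer tags (`NA` where none is recognised).
#' @export
parse_layer_tag <- function(acronym) {
  out <- rep(NA_character_, length(acronym))
  pat <- "(?:\\s*layer\\s*)?(1|2/3|4|5|6a|6b)$"
  m <- regexpr(pat, acronym, perl = TRUE)
  hit <- m > 0
  out[hit] <- sub(pat, "\\1", regmatches(acronym, m), perl = TRUE)
  # bare trailing digits only count when preceded by a letter or '-x' area stem
  out
}

hier_index <- function(hier, region_id) {
  i <- match(region_id, hier$id)
  if (anyNA(i)) {
    stop("region id(s) not in hierarchy: ",
         paste(region_id[is.na(i)], collapse = ", "))
  }
  i
}

#' Ancestor chain of a region
#'
#' @param hier a [region_hierarchy()].
#' @param region_id single region id.
#' @return Integer vector of ids from the region itself up to the root.
#' @export
region_ancestors <- function(hier, region_id) {
  i <- hier_index(hier, region_id)
  out <- integer(0)
  while (!is.na(i)) {
    out <- c(out, hier$id[i])
    i <- match(hier$parent_id[i], hier$id)
  }
  out
}

#' Test whether a region lies within a named ancestor
#'
#' True iff the ancestor chain of `region_id` (the region itself included)
#' contains the region whose acronym is `ancestor_acronym`. This is the
#' membership test behind curation rules such as "soma voxels outside the
#' injected nucleus are neurite false negatives".
#'
#' @param hier a [region_hierarchy()].
#' @param region_id region id(s) to test; must exist in the hierarchy.
#' @param ancestor_acronym acronym of the candidate ancestor.
#' @return Logical vector.
#' @export
is_within <- function(hier, region_id, ancestor_acronym) {
  anc <- hier$id[match(ancestor_acronym, hier$acronym)]
  if (is.na(anc)) stop("unknown acronym: ", ancestor_acronym)
  vapply(region_id, function(id) anc %in% region_ancestors(hier, id), logical(1))
}

#' Layer tag of regions
#' @param hier a [region_hierarchy()].
#' @param region_id region id(s).
#' @return Character vector of layer tags (`NA` for non-laminar regions).
#' @export
layer_tag_of <- function(hier, region_id) {
  hier$layer[hier_index(hier, region_id)]
}

#' Id of the region with a given acronym
#' @param hier a [region_hierarchy()].
#' @param acronym region acronym.
#' @return Integer region id.
#' @export
region_id_of <- function(hier, acronym) {
  id <- hier$id[match(acronym, hier$acronym)]
  if (anyNA(id)) stop("unknown acronym: ", paste(acronym[is.na(id)], collapse = ", "))
  id
}

#' Ids of all regions within a named ancestor
#' @param hier a [region_hierarchy()].
#' @param ancestor_acronym acronym whose subtree to collect.
#' @return Integer vector of ids (the ancestor itself included).
#' @export
region_subtree <- function(hier, ancestor_acronym) {
  hier$id[is_within(hier, hier$id, ancestor_acronym)]
}
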