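#' Load a pipeline run configuration
#'
#' Reads YAML or JSON into the run-config list; see [run_pipeline()] for
#' the recognized fields. A list passed through is validated as-is.
#'
#' @param config path to a YAML/JSON file, or a config list.
#' @return Validated config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(
    min_object_px = 12, radius_factor = 1.5, nucleus_acronym = "VPM",
    parcellation = "ARA", denominator = "targeted", seed = 1,
    resume = TRUE, experiment_id = NULL, areas = NULL,
    morphology_dir = NULL, bulk_catalogue = NULL, flatmap = NULL
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("seg_dir", "anchoring_json", "out_dir")) {
    if (is.null(config[[nm]])) stop("run config is missing '", nm, "'")
  }
  for (nm in c("seg_dir", "anchoring_json", "morphology_dir", "bulk_catalogue")) {
    p <- config[[nm]]
    if (is.character(p) && !file.exists(p)) {
      stop("run config path does not exist: ", nm, " = ", p)
    }
  }
  if (config$min_object_px < 1) stop("min_object_px must be >= 1")
  if (config$radius_factor <= 0) stop("radius_factor must be > 0")
  config
}

resolve_space <- function(config) {
  if (!is.null(config$space)) return(config$space)
  at <- config$atlas
  if (is.null(at)) stop("run config needs either 'space' or 'atlas' paths")
  load_reference_space(at$annotation, at$template, at$hierarchy)
}

#' Run the full registration-and-quantification pipeline
#'
#' Orchestrates the post-registration stages for one experiment: validate
#' that every segmented section has anchoring (the interactive anchoring
#' tools are external producers, so their output files are a required input
#' — a deliberate pause point, not an invocation), recode and clean the raw
#' classifier images, voxelize through the per-section warp and anchoring,
#' curate the injection volume, split/mirror hemispheres, and compute
#' flatmap coverage and laminar distributions; optionally classify proximal
#' single-neuron morphologies and match a bulk-tracing catalogue. All
#' outputs are deterministic functions of the inputs and seed; cleaned
#' images are cached under the output directory and reused on resumed runs.
#'
#' Config fields: `seg_dir` (raw 3-label PNGs named `*_sNNN.png`),
#' `anchoring_json` (nonlinear dialect), `out_dir`, and either `space` (an
#' in-memory [reference_space()]) or `atlas` (paths `annotation`,
#' `template`, `hierarchy`); optional `flatmap` (lookup JSON), `areas`,
#' `morphology_dir`, `bulk_catalogue`, `experiment_id`, and the parameters
#' `min_object_px` (12), `nucleus_acronym` ("VPM"), `radius_factor` (1.5),
#' `denominator`, `parcellation`, `seed`, `resume`.
#'
#' @param config path to a YAML/JSON run config, or a config list
#'   ([load_run_config()]).
#' @return The run manifest (also written to `out_dir/run_manifest.json`),
#'   with the per-stage conservation ledger; the curated record and
#'   analytics tables are attached as attributes.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  space <- resolve_space(config)
  hier <- space$hierarchy
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cleaned_dir <- file.path(out_dir, "cleaned")
  dir.create(cleaned_dir, showWarnings = FALSE)

  # -- validate ------------------------------------------------------------
  seg_files <- sort(list.files(config$seg_dir, pattern = "_s[0-9]{3}\\.png$",
                               full.names = TRUE))
  if (length(seg_files) == 0) stop("stage validate: no segmented sections in ",
                                   config$seg_dir)
  stems <- sub("\\.png$", "", basename(seg_files))
  slices <- read_nonlinear_anchoring(config$anchoring_json)
  for (stem in stems) {
    if (is.null(slices[[stem]])) {
      stop("stage validate: anchoring missing for section ", stem)
    }
  }
  experiment_id <- config$experiment_id %||%
    sub("_s[0-9]{3}$", "", stems[1])

  # -- clean ---------------------------------------------------------------
  ledger <- list()
  increments <- list()
  raw_px <- 0; removed_px <- 0; cleaned_px <- 0
  for (i in seq_along(stems)) {
    stem <- stems[i]
    raw <- read_label_image(seg_files[i])
    seg <- recode_labels(raw)
    raw_px <- raw_px + sum(seg != 0)
    cache <- file.path(cleaned_dir, paste0(stem, ".png"))
    if (isTRUE(config$resume) && file.exists(cache)) {
      cleaned <- read_label_image(cache)
      removed_px <- removed_px + (sum(seg != 0) - sum(cleaned != 0))
    } else {
      cleaned <- clean_small_objects(seg, config$min_object_px)
      removed_px <- removed_px + sum(attr(cleaned, "report")$pixels_removed)
      write_label_image(cleaned, cache)
    }
    cleaned_px <- cleaned_px + sum(cleaned != 0)
    anchor <- slices[[stem]]$anchor
    warp <- build_warp(slices[[stem]]$markers, c(anchor$width_px, anchor$height_px))
    increments[[stem]] <- voxelize_section(cleaned, anchor, warp, space)
  }

  # -- assemble / curate / split ------------------------------------------
  colors <- assign_population_colors(experiment_id)
  record <- assemble_experiment(increments, experiment_id, colors[[1]])
  vox_report <- attr(record, "report")
  record <- curate_injection_volume(record, space, hier, config$nucleus_acronym)
  write_population_record(record, file.path(out_dir, "record_curated.json"))
  halves <- split_and_mirror(record, space)
  combined <- population_record(
    experiment_id,
    cloud_merge(halves$left$source, halves$right_mapped$source),
    cloud_merge(halves$left$target, halves$right_mapped$target),
    record$color
  )

  # -- analytics -----------------------------------------------------------
  lookup <- if (is.null(config$flatmap)) {
    make_flatmap_lookup(space)
  } else if (is.character(config$flatmap)) {
    read_flatmap_lookup(config$flatmap)
  } else {
    config$flatmap
  }
  flat <- flatmap_project(combined$target, lookup)
  coverage <- cortical_coverage(flat, lookup)
  areas <- config$areas
  if (is.null(areas)) {
    iso_kids <- hier$acronym[!is.na(hier$parent_id) &
                               hier$parent_id == region_id_of(hier, "Isocortex")]
    areas <- iso_kids
  }
  layer_tabs <- lapply(areas, function(a) {
    tab <- suppressWarnings(layer_distribution(combined, space, hier, a))
    tab$area <- a
    tab
  })
  layers <- do.call(rbind, layer_tabs)
  utils::write.csv(layers, file.path(out_dir, "layer_distribution.csv"),
                   row.names = FALSE)

  # -- integration (optional) ---------------------------------------------
  integration <- NULL
  if (!is.null(config$morphology_dir) || !is.null(config$bulk_catalogue)) {
    medoid <- population_medoid(record$source)
    radius <- membership_radius(record$source, medoid, config$radius_factor)
    integration <- list(medoid = medoid, radius = radius)
    if (!is.null(config$morphology_dir)) {
      morphs <- read_swc_dir(config$morphology_dir)
      cls <- classify_members(morphs, medoid, radius, space$dims)
      other_flat <- flatmap_project(cls$terminals, lookup)
      states <- overlap_states(flat, other_flat)
      fr <- lapply(areas, function(a) {
        mask <- flatmap_area_mask(lookup, hier, a)
        as.list(suppressWarnings(
          overlap_fractions(states, mask, config$denominator)))
      })
      names(fr) <- areas
      integration$members <- cls$members
      integration$overlap_fractions <- fr
    }
    if (!is.null(config$bulk_catalogue)) {
      catalogue <- read_bulk_catalogue(config$bulk_catalogue)
      integration$nearest_bulk <- nearest_bulk_experiment(record, catalogue)
    }
  }

  curated_report <- attr(record, "report")
  manifest <- list(
    experiment_id = experiment_id,
    parcellation = config$parcellation,
    n_sections = length(stems),
    stems = stems,
    ledger = list(
      raw_segmented_px = raw_px,
      removed_by_cleaning_px = removed_px,
      cleaned_px = cleaned_px,
      warp_clamped_px = vox_report$warp_clamped,
      out_of_space_px = vox_report$out_of_space,
      source_px = cloud_total(record$source),
      target_px = cloud_total(record$target),
      curated_pixels = curated_report$curated_pixels %||% 0,
      balance = cleaned_px -
        (cloud_total(record$source) + cloud_total(record$target) +
           vox_report$out_of_space)
    ),
    analytics = list(
      cortical_coverage = coverage,
      flat_skipped_px = attr(flat, "skipped")
    ),
    integration = integration,
    seed = config$seed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  attr(manifest, "record") <- record
  attr(manifest, "combined") <- combined
  attr(manifest, "layers") <- layers
  attr(manifest, "flat") <- flat
  invisible(manifest)
}
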