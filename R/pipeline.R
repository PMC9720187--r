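#' Pipeline configuration
#'
#' Collects every parameter of a full searchlight analysis. Defaults are the
#' method's standard settings: 1/35 rad cells, 11-cell grids, vertex-wise
#' threshold 3 (p < 0.001 one-tailed), FWE 0.01, 2,000 permutations.
#'
#' @param data_dir subjects directory ([write_dataset()] layout); ignored
#'   when `simulate` is a [sim_config()].
#' @param subject_prefix subject folder prefix.
#' @param cell_size,grid_size searchlight grid parameters ([grid_spec()]).
#' @param high_div,low_div template subdivision orders.
#' @param tr repetition-time override (default: file headers).
#' @param timepoint trial sampling latency after onset, seconds.
#' @param contrast contrast string ([parse_contrast()]).
#' @param classifier `"svm"` or `"cnn"`.
#' @param vertexwise,fwe_alpha,n_perm group-inference thresholds
#'   ([threshold_spec()]).
#' @param null_method `"tmap"` (flip per-vertex t signs) or `"subject"`
#'   (flip subject effects); see [signflip_null()].
#' @param hemi hemisphere tag used in output names.
#' @param workers per-subject worker processes (results are identical for
#'   any worker count).
#' @param seed master seed (permutations; simulation when `simulate` set).
#' @param simulate optional [sim_config()]: generate the dataset instead of
#'   reading `data_dir`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data_dir = NULL, subject_prefix = "Sub",
                            cell_size = 1 / 35, grid_size = 11L,
                            high_div = 16L, low_div = 4L, tr = NULL,
                            timepoint = 7, contrast = "1 vs 2",
                            classifier = "svm", vertexwise = 3,
                            fwe_alpha = 0.01, n_perm = 2000L,
                            null_method = "tmap", hemi = "lh", workers = 1L,
                            seed = 1L, simulate = NULL) {
  parse_contrast(contrast)                 # validate early
  structure(list(data_dir = data_dir, subject_prefix = subject_prefix,
                 cell_size = cell_size, grid_size = as.integer(grid_size),
                 high_div = as.integer(high_div), low_div = as.integer(low_div),
                 tr = tr, timepoint = timepoint, contrast = contrast,
                 classifier = classifier, vertexwise = vertexwise,
                 fwe_alpha = fwe_alpha, n_perm = as.integer(n_perm),
                 null_method = null_method, hemi = hemi,
                 workers = as.integer(workers), seed = as.integer(seed),
                 simulate = simulate),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config()] arguments; `simulate:` may hold a
#' mapping of [sim_config()] arguments. `overrides` (a named list) wins over
#' file values.
#'
#' @param path YAML file.
#' @param overrides named list of argument overrides.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$simulate) && is.list(vals$simulate))
    vals$simulate <- do.call(sim_config, vals$simulate)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full searchlight pipeline
#'
#' Chains template construction, searchlight layout (cached under
#' `out_dir`), trial extraction (or simulation), per-subject decoding, and
#' group inference, writing all results plus a manifest under `out_dir`.
#' Per-subject decoding can run on several workers; reductions happen in a
#' fixed subject order, so results are bit-identical for any worker count.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return List with `layout`, `maps`, `inference`, `report`, `manifest`
#'   (also written as files: per-subject accuracy maps, `tmap_*.txt`,
#'   `null_max_sizes_*.txt`, `clusters_*.tsv`, `manifest_*.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$simulate)) {
    if (is.null(config$data_dir) || !dir.exists(config$data_dir))
      sl_stop("data_dir does not exist (and no simulation requested)",
              "surflight_io_error")
    if (length(list.files(config$data_dir,
                          pattern = paste0("^", config$subject_prefix))) == 0L)
      sl_stop(sprintf("no '%s*' subject folders in '%s'",
                      config$subject_prefix, config$data_dir),
              "surflight_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  high <- subdivide(base_icosahedron(), config$high_div)
  low <- subdivide(base_icosahedron(), config$low_div)
  adjacency <- build_adjacency(low)
  spec <- grid_spec(config$cell_size, config$grid_size)
  layout_file <- file.path(out_dir, sprintf("%s_%s.rds", layout_stem(spec),
                                            config$hemi))
  layout <- if (file.exists(layout_file)) load_layout(layout_file)
  else {
    l <- build_layout(high, low, nearest_assignment(high, low), adjacency,
                      spec)
    save_layout(l, layout_file)
    l
  }

  input_digests <- NULL
  if (is.null(config$simulate)) {
    trialsets <- read_dataset(config$data_dir, config$subject_prefix,
                              timepoint = config$timepoint,
                              expected_vertices = nrow(high$vertices),
                              tr = config$tr)
    files <- sort(list.files(config$data_dir, recursive = TRUE,
                             full.names = TRUE))
    input_digests <- as.list(tools::md5sum(files))
    names(input_digests) <- substring(names(input_digests),
                                      nchar(config$data_dir) + 2L)
  } else {
    ds <- simulate_dataset(config$simulate, high, low)
    trialsets <- lapply(ds, function(sub)
      bind_trials(lapply(seq_along(sub$runs), function(r)
        extract_trials(sub$runs[[r]], sub$paradigms[[r]], config$timepoint))))
  }

  cspec <- classifier_spec(config$classifier, seed = config$seed)
  mask <- circular_mask(config$grid_size)
  decode_one <- function(s)
    subject_accuracy_map(trialsets[[s]], layout, contrast = config$contrast,
                         spec = cspec, mask = mask, subject_id = s)
  maps <- if (config$workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(trialsets), decode_one,
                       mc.cores = config$workers)
  } else {
    lapply(seq_along(trialsets), decode_one)
  }

  for (s in seq_along(maps))
    write.table(maps[[s]]$accuracy,
                file.path(out_dir, sprintf("accuracy_sub%02d_%s.txt", s,
                                           config$hemi)),
                row.names = FALSE, col.names = FALSE)

  tspec <- threshold_spec(config$vertexwise, config$fwe_alpha, config$n_perm,
                          seed = config$seed)
  inference <- group_inference(maps, adjacency, tspec,
                               method = config$null_method, template = low,
                               area_per_vertex = vertex_areas(low))
  write.table(inference$tmap$t,
              file.path(out_dir, sprintf("tmap_%s.txt", config$hemi)),
              row.names = FALSE, col.names = FALSE)
  write.table(inference$null$max_sizes,
              file.path(out_dir, sprintf("null_max_sizes_%s.txt", config$hemi)),
              row.names = FALSE, col.names = FALSE)
  report_file <- file.path(out_dir, sprintf("clusters_%s.tsv", config$hemi))
  write.table(inference$report, report_file, sep = "\t", row.names = FALSE,
              quote = FALSE)

  manifest <- list(
    package = "surflight",
    version = as.character(utils::packageVersion("surflight")),
    parameters = config[setdiff(names(config), "simulate")],
    simulate = if (!is.null(config$simulate)) unclass(config$simulate),
    seed = config$seed,
    n_subjects = length(maps),
    inputs = input_digests,
    outputs = sort(setdiff(list.files(out_dir),
                           sprintf("manifest_%s.json", config$hemi)))
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, sprintf("manifest_%s.json",
                                                  config$hemi)),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  list(layout = layout, maps = maps, inference = inference,
       report = inference$report, manifest = manifest)
}
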