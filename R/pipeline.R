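# End-to-end orchestration: synth -> segment -> describe -> stats -> search,
# with a config snapshot and reproducibility metadata in the run directory.

#' Default pipeline configuration
#'
#' @param counts Images per group (named integer vector).
#' @param canvas Canvas size `c(rows, cols)`.
#' @param profile_overrides Named list (per group) of profile field
#'   overrides, applied over the packaged defaults.
#' @param seg Segmentation parameter overrides (passed to [seg_params()]).
#' @param schemes Classifier schemes to run.
#' @param eval Accuracy protocol, `"resub"` or `"loocv"`.
#' @param subset3d Optional three predictor names for the 3-D separation
#'   output.
#' @return A `vq_run_config` list, YAML-serializable.
#' @export
run_config <- function(counts = c(CONTROL = 6L, TMG = 10L, CMG = 9L,
                                  CEG = 7L),
                       canvas = default_canvas(),
                       profile_overrides = list(),
                       seg = list(), schemes = VQ_SCHEMES,
                       eval = "resub", subset3d = NULL) {
  structure(list(counts = counts, canvas = canvas,
                 profile_overrides = profile_overrides, seg = seg,
                 schemes = schemes, eval = eval, subset3d = subset3d),
            class = "vq_run_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `vq_run_config`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$counts <- as.list(y$counts)       # keep group names as a YAML map
  y$canvas <- as.integer(y$canvas)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments; missing keys take
#' their defaults.
#'
#' @param path YAML file path.
#' @return A `vq_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (k in intersect(names(y), names(cfg))) cfg[[k]] <- y[[k]]
  if (!is.null(y$counts)) {
    counts <- unlist(y$counts)
    storage.mode(counts) <- "integer"
    cfg$counts <- counts
  }
  if (!is.null(y$canvas)) cfg$canvas <- as.integer(unlist(y$canvas))
  if (!is.null(y$schemes)) cfg$schemes <- unlist(y$schemes)
  cfg
}

#' Run the full pipeline into a run directory
#'
#' Executes all stages in order — synthetic dataset generation, segmentation,
#' shape description, group statistics, classifier search — and writes every
#' stage output plus a config snapshot and run metadata. The run is fully
#' reproducible: the same `(config, master_seed)` produces byte-identical
#' files.
#'
#' @param config A `vq_run_config` (or YAML path).
#' @param master_seed Integer master seed, fanned out to per-image child
#'   seeds by stable hashing.
#' @param out_dir Run directory (created; must be empty or nonexistent
#'   unless `overwrite = TRUE`).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with the in-memory stage outputs: `manifest`,
#'   `truth`, `regions`, `predictors`, `pooled`, `tests`, `search`.
#' @export
run_pipeline <- function(config = run_config(), master_seed = 1L,
                         out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "vq_run_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    stop("output directory ", out_dir,
         " is not empty (use overwrite = TRUE)", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  profiles <- lapply(names(config$counts), function(g)
    group_profile(g, overrides = config$profile_overrides[[g]] %||% list()))
  names(profiles) <- names(config$counts)
  ds_config <- dataset_config(counts = config$counts, canvas = config$canvas,
                              profiles = profiles)
  ds <- stage("synth", make_dataset(ds_config, master_seed, out_dir))

  params <- do.call(seg_params, config$seg)
  seg_dir <- file.path(out_dir, "segmentation")
  dir.create(seg_dir, showWarnings = FALSE)
  stage("segment", {
    for (id in names(ds$records)) {
      m <- segment(ds$records[[id]], params)
      png::writePNG(m$mask * 1.0,
                    file.path(seg_dir, paste0(id, "_lesions.png")))
      jsonlite::write_json(
        list(image_id = id,
             thresholds = round(unname(m$thresholds), 4),
             degenerate = unname(m$degenerate),
             n_components = m$n_components,
             params = unclass(params)),
        file.path(seg_dir, paste0(id, ".json")),
        auto_unbox = TRUE, null = "null", digits = NA)
    }
  })

  desc <- stage("describe", describe_dataset(ds$records, ds$manifest,
                                             params))
  utils::write.csv(desc$regions, file.path(out_dir, "regions.csv"),
                   row.names = FALSE)
  utils::write.csv(desc$predictors, file.path(out_dir, "predictors.csv"),
                   row.names = FALSE)

  stats_out <- stage("stats", {
    pooled <- pooled_group_estimators(desc$regions, ds$manifest)
    tests <- distribution_tests(desc$regions, ds$manifest)
    utils::write.csv(pooled, file.path(out_dir, "pooled_estimators.csv"),
                     row.names = FALSE)
    utils::write.csv(tests, file.path(out_dir, "distribution_tests.csv"),
                     row.names = FALSE)
    list(pooled = pooled, tests = tests)
  })

  search <- stage("search", run_all_schemes(
    desc$predictors, out_dir = file.path(out_dir, "search"),
    eval = config$eval, schemes = config$schemes,
    subset3d = config$subset3d))

  write_run_config(config, file.path(out_dir, "config_snapshot.yaml"))
  jsonlite::write_json(
    list(master_seed = master_seed,
         package = "vacuoquant",
         version = as.character(utils::packageVersion("vacuoquant")),
         n_images = nrow(ds$manifest)),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE)

  invisible(list(manifest = ds$manifest, truth = ds$truth,
                 regions = desc$regions, predictors = desc$predictors,
                 pooled = stats_out$pooled, tests = stats_out$tests,
                 search = search))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
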