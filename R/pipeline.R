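# Reproducible multi-stage workflows: a single config (list or YAML file)
# names the stages to run and their parameters; every run writes its
# outputs plus a manifest (parameters, seed, checksums, version) so that
# identical config + seed reproduces identical tables.

PIPELINE_STAGES <- c("simulate_spheroid", "simulate_tracks",
                     "simulate_expression", "features", "track_metrics",
                     "permde", "demo")

#' Run a multi-stage analysis pipeline
#'
#' Executes the requested stages in the given order and writes a JSON
#' manifest. Available stages:
#' \describe{
#'   \item{simulate_spheroid}{phantom stack -> `phantom.tif`,
#'     `phantom_truth.csv` (params: [spheroid_phantom_spec()] arguments).}
#'   \item{simulate_tracks}{chain tracks -> `tracks.csv` (+ YAML sidecar)
#'     (params: [track_sim_spec()] arguments).}
#'   \item{simulate_expression}{expression matrix -> `expression.tsv`,
#'     `design.csv`, `gene_truth.csv` (params: [expression_sim_spec()]
#'     arguments).}
#'   \item{features}{imaging pipeline on a stack TIFF (param `input`;
#'     defaults to the phantom written earlier in the same run) ->
#'     `features.csv`, `mask.tif` (params: [segmentation_params()]
#'     arguments).}
#'   \item{track_metrics}{[track_metrics()] on a tracks CSV (param
#'     `input`) -> `track_metrics.csv`; with an `event_table` CSV
#'     (`track_id,event_frame`), pre/post split metrics ->
#'     `track_splits.csv`.}
#'   \item{permde}{[run_de()] on an expression TSV + design CSV (params
#'     `matrix`, `design`, `B`, `alpha`, `welch`) -> `de_results.tsv`,
#'     `de_meta.json`.}
#'   \item{demo}{small phantom, quantified end to end; feature-vs-truth
#'     deltas are reported in the manifest.}
#' }
#'
#' The config is validated (unknown keys are rejected) and all declared
#' input files are checked *before* any stage runs.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Top-level keys: `stages` (character vector), `seed`, `out_dir`, plus
#'   one optional named section per stage.
#' @param seed,out_dir optional overrides of the config values.
#' @return the manifest (list), invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  allowed_top <- c("stages", "seed", "out_dir", PIPELINE_STAGES)
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stages <- config$stages
  if (is.null(stages) || !all(stages %in% PIPELINE_STAGES)) {
    stop("`stages` must be a vector of: ",
         paste(PIPELINE_STAGES, collapse = ", "), call. = FALSE)
  }
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("a `seed` is required", call. = FALSE)
  check_number(seed, "seed", integer = TRUE)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("an `out_dir` is required", call. = FALSE)

  # validate stage sections and input files before any computation
  for (st in stages) validate_stage_config(st, config[[st]], out_dir, stages)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- Sys.time()
  outputs <- character(0)
  notes <- list()

  for (st in stages) {
    res <- run_stage(st, config[[st]] %||% list(), seed, out_dir)
    outputs <- c(outputs, res$files)
    if (!is.null(res$note)) notes[[st]] <- res$note
  }

  manifest <- list(
    package = "sagakit",
    version = as.character(utils::packageVersion("sagakit")),
    seed = as.integer(seed),
    stages = as.list(stages),
    parameters = config[intersect(names(config), PIPELINE_STAGES)],
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    notes = notes,
    started = format(started, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_allowed_params <- function(stage) {
  switch(stage,
    simulate_spheroid = names(formals(spheroid_phantom_spec)),
    simulate_tracks = names(formals(track_sim_spec)),
    simulate_expression = names(formals(expression_sim_spec)),
    features = c("input", names(formals(segmentation_params)),
                 "pixel_size", "frame_interval"),
    track_metrics = c("input", "frame_interval", "pixel_size", "event_table"),
    permde = c("matrix", "design", "B", "alpha", "welch", "exhaustive",
               "exhaustive_cap"),
    demo = character(0))
}

validate_stage_config <- function(stage, params, out_dir, stages) {
  params <- params %||% list()
  allowed <- setdiff(stage_allowed_params(stage), "seed")
  unknown <- setdiff(names(params), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in `%s` config: %s", stage,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  # fail fast on missing inputs (unless produced by an earlier stage of
  # this same run)
  check_input <- function(key, default_file, producer) {
    f <- params[[key]]
    if (is.null(f)) {
      if (producer %in% stages) return(invisible())
      f <- file.path(out_dir, default_file)
    }
    if (!file.exists(f)) {
      stop(sprintf("input for stage `%s` not found: %s", stage, f),
           call. = FALSE)
    }
  }
  if (stage == "features") check_input("input", "phantom.tif", "simulate_spheroid")
  if (stage == "track_metrics") check_input("input", "tracks.csv", "simulate_tracks")
  if (stage == "permde") {
    check_input("matrix", "expression.tsv", "simulate_expression")
    check_input("design", "design.csv", "simulate_expression")
  }
  if (stage == "track_metrics" && !is.null(params$event_table) &&
      !file.exists(params$event_table)) {
    stop("event_table not found: ", params$event_table, call. = FALSE)
  }
  invisible()
}

run_stage <- function(stage, params, seed, out_dir) {
  p <- function(f) file.path(out_dir, f)
  switch(stage,
    simulate_spheroid = {
      spec <- do.call(spheroid_phantom_spec, c(params, list(seed = seed)))
      ph <- simulate_spheroid_stack(spec)
      write_stack_tiff(ph$stack, p("phantom.tif"))
      write.csv(ph$truth, p("phantom_truth.csv"), row.names = FALSE)
      list(files = c(p("phantom.tif"), p("phantom_truth.csv")))
    },
    simulate_tracks = {
      spec <- do.call(track_sim_spec, c(params, list(seed = seed)))
      trk <- simulate_tracks(spec)
      write_tracks_csv(trk, p("tracks.csv"), spec)
      list(files = c(p("tracks.csv"), p("tracks.csv.yaml")))
    },
    simulate_expression = {
      spec <- do.call(expression_sim_spec, c(params, list(seed = seed)))
      sim <- simulate_expression(spec)
      write_expression_tsv(sim$matrix, p("expression.tsv"))
      write.csv(sim$design, p("design.csv"), row.names = FALSE)
      write.csv(sim$truth, p("gene_truth.csv"), row.names = FALSE)
      list(files = c(p("expression.tsv"), p("design.csv"), p("gene_truth.csv")))
    },
    features = {
      input <- params$input %||% p("phantom.tif")
      stack <- read_stack_tiff(input)
      seg_args <- params[intersect(names(params),
                                   names(formals(segmentation_params)))]
      sp <- do.call(segmentation_params, seg_args)
      feats <- feature_timecourse(stack, sp,
                                  pixel_size = params$pixel_size,
                                  frame_interval = params$frame_interval)
      write.csv(as.data.frame(feats), p("features.csv"), row.names = FALSE)
      write_stack_tiff(unclass(attr(feats, "mask")), p("mask.tif"))
      list(files = c(p("features.csv"), p("mask.tif")))
    },
    track_metrics = {
      input <- params$input %||% p("tracks.csv")
      trk <- read_tracks_csv(input, frame_interval = params$frame_interval)
      met <- track_metrics(trk, frame_interval = params$frame_interval,
                           pixel_size = params$pixel_size)
      write.csv(met, p("track_metrics.csv"), row.names = FALSE)
      files <- p("track_metrics.csv")
      if (!is.null(params$event_table)) {
        ev <- read.csv(params$event_table)
        splits <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
          tr1 <- trk[trk$track_id == ev$track_id[i], , drop = FALSE]
          sp <- split_at_event(tr1, ev$event_frame[i],
                               frame_interval = params$frame_interval)
          rbind(cbind(track_id = ev$track_id[i], phase = "pre", sp$pre),
                cbind(track_id = ev$track_id[i], phase = "post", sp$post))
        }))
        write.csv(splits, p("track_splits.csv"), row.names = FALSE)
        files <- c(files, p("track_splits.csv"))
      }
      list(files = files)
    },
    permde = {
      mat <- read_expression_tsv(params$matrix %||% p("expression.tsv"))
      design <- read.csv(params$design %||% p("design.csv"))
      pp <- perm_params(B = params$B %||% 500,
                        alpha = params$alpha %||% 0.05,
                        seed = seed,
                        exhaustive = params$exhaustive %||% FALSE,
                        exhaustive_cap = params$exhaustive_cap %||% 2e5,
                        welch = params$welch %||% FALSE)
      res <- run_de(mat, design, pp)
      write.table(as.data.frame(res), p("de_results.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(attr(res, "meta"), p("de_meta.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      list(files = c(p("de_results.tsv"), p("de_meta.json")))
    },
    demo = {
      spec <- spheroid_phantom_spec(image_shape = c(4, 3, 128, 128),
                                    core_radius = 14, n_branches = 4,
                                    branch_growth_rate = 8, noise_sd = 3,
                                    seed = seed)
      ph <- simulate_spheroid_stack(spec)
      feats <- feature_timecourse(ph$stack)
      write.csv(as.data.frame(feats), p("demo_features.csv"),
                row.names = FALSE)
      note <- list(
        branch_count_delta = feats$branch_count - ph$truth$true_branch_count,
        invasive_radius_delta =
          round(feats$invasive_radius - ph$truth$true_invasive_radius, 2))
      list(files = p("demo_features.csv"), note = note)
    },
    stop("unknown stage: ", stage, call. = FALSE))
}
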