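#' The experiment-matching termination threshold preset
#'
#' The threshold used when simulating the search experiment itself. There is
#' no silent package default for `theta`: the optimal threshold depends on
#' the feature representation, so users either supply one, request the
#' optimizer, or use this named preset.
#' @export
THETA_EXPERIMENT <- 0.998

run_config_defaults <- function() {
  list(
    seed = 1L,
    log_level = "info",
    out_dir = "metasearch_out",
    params = list(theta = NULL, cost = 0.01, mask_scale = 3,
                  mask_sharpness = 200, prior_mean_sd = 0.01,
                  prior_precision = 0.01, fixation_budget = 22L),
    generator = list(n_objects = c(56L, 113L), n_features = 6L,
                     distractor_similarity = 0, cap_half_angle = pi / 3,
                     deadline_s = 8, max_objects = 113L),
    scenes = list(n = 20L),
    simulate = list(reps = 2L, policy = "fixate_map"),
    optimize = list(n_sims = 200L, grid_size = 15L),
    evaluate = NULL
  )
}

check_range <- function(value, field, lo, hi, open = c(TRUE, TRUE)) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      (if (open[1]) value <= lo else value < lo) ||
      (if (open[2]) value >= hi else value > hi))
    stop("config field '", field, "' out of range (", lo, ", ", hi, "): ",
         value)
  value
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML or JSON configuration, fills in the model's default
#' parameter values, rejects unknown keys, and range-checks every field.
#' `params$theta` is the one parameter with no default: it must be a number
#' in (0, 1), the string `"optimize"` (run the threshold optimizer first),
#' or the string `"experiment"` (the 0.998 preset).
#'
#' @param path YAML or JSON configuration file, or a list.
#' @return the normalized configuration (class `run_config`).
#' @export
validate_config <- function(path) {
  user <- if (is.list(path)) path else {
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  defaults <- run_config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  for (section in c("params", "generator", "scenes", "simulate", "optimize")) {
    bad <- setdiff(names(cfg[[section]]), names(defaults[[section]]))
    if (length(bad))
      stop("unknown config keys in '", section, "': ",
           paste(bad, collapse = ", "))
  }
  p <- cfg$params
  if (!is.null(p$theta) && is.character(p$theta)) {
    if (p$theta == "experiment") cfg$params$theta <- THETA_EXPERIMENT
    else if (p$theta != "optimize")
      stop("params.theta must be a number in (0, 1), 'optimize', or 'experiment'")
  } else if (!is.null(p$theta)) {
    check_range(p$theta, "params.theta", 0, 1)
  }
  check_range(p$cost, "params.cost", 0, Inf, open = c(FALSE, TRUE))
  check_range(p$mask_scale, "params.mask_scale", 0, Inf)
  check_range(p$mask_sharpness, "params.mask_sharpness", 0, Inf)
  check_range(p$prior_precision, "params.prior_precision", 0, Inf)
  if (!is_count(p$fixation_budget))
    stop("config field 'params.fixation_budget' must be a positive integer")
  if (!is_count(cfg$scenes$n)) stop("config field 'scenes.n' must be a positive integer")
  if (!is_count(cfg$simulate$reps))
    stop("config field 'simulate.reps' must be a positive integer")
  # constructs and validates the generator config
  do.call(scene_generator_config, cfg$generator)
  if (!cfg$log_level %in% c("debug", "info", "warning"))
    stop("log_level must be one of debug, info, warning")
  class(cfg) <- "run_config"
  cfg
}

ms_log <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warning = 3)
  if (levels[[level]] >= levels[[cfg$log_level]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

#' Run the generation -> simulation -> evaluation pipeline
#'
#' Executes the requested stages in dependency order with deterministic
#' per-stage child seeds, writes all artifacts under `config$out_dir`, and
#' records a manifest (inputs, outputs, seeds, parameter values, package
#' version) sufficient to reproduce the run bit-for-bit. A failing stage
#' leaves the artifacts of completed stages intact.
#'
#' @param config a validated `run_config` (or a path handed to
#'   [validate_config()]).
#' @param stages character vector among `"scenes"`, `"simulate"`,
#'   `"evaluate"`; `"optimize"` is inserted automatically when
#'   `params$theta == "optimize"`.
#' @return the manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, stages = c("scenes", "simulate", "evaluate")) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "metasearch",
                   version = as.character(utils::packageVersion("metasearch")),
                   seed = cfg$seed, params = cfg$params,
                   generator = cfg$generator, stages = list())
  gen <- do.call(scene_generator_config, cfg$generator)

  scenes <- NULL
  scene_dir <- file.path(cfg$out_dir, "scenes")
  if ("scenes" %in% stages) {
    seed_sc <- child_seed(cfg$seed, "scenes")
    ms_log(cfg, "info", "stage scenes: generating ", cfg$scenes$n,
           " scenes (seed ", seed_sc, ")")
    scenes <- generate_scenes(gen, cfg$scenes$n, seed = seed_sc)
    dir.create(scene_dir, showWarnings = FALSE)
    files <- vapply(seq_along(scenes), function(i) {
      f <- file.path(scene_dir, sprintf("scene%03d.json", i))
      write_scene(scenes[[i]], f)
      f
    }, character(1))
    manifest$stages$scenes <- list(seed = seed_sc, n = cfg$scenes$n,
                                   files = files)
  }

  load_scenes <- function() {
    if (!is.null(scenes)) return(scenes)
    files <- sort(list.files(scene_dir, pattern = "\\.json$", full.names = TRUE))
    if (!length(files))
      stop("stage requires scenes, but none were generated or found in ",
           scene_dir, " (run the 'scenes' stage first)")
    lapply(files, read_scene)
  }

  theta <- cfg$params$theta
  if (identical(theta, "optimize")) {
    scenes <- load_scenes()
    seed_opt <- child_seed(cfg$seed, "optimize")
    ms_log(cfg, "info", "stage optimize: grid search over (0.5, 0.999)")
    opt <- optimize_threshold(scenes, pipeline_params(cfg, 0.9),
                              n_sims = cfg$optimize$n_sims,
                              grid_size = cfg$optimize$grid_size,
                              seed = seed_opt)
    theta <- opt$theta
    manifest$stages$optimize <- list(seed = seed_opt, theta = theta,
                                     grid = opt$grid,
                                     mean_return = opt$mean_return)
  }

  traces_path <- file.path(cfg$out_dir, "traces.jsonl")
  traces <- NULL
  if ("simulate" %in% stages) {
    if (is.null(theta))
      stop("stage simulate requires params.theta (a number, 'optimize', ",
           "or 'experiment')")
    scenes <- load_scenes()
    seed_sim <- child_seed(cfg$seed, "simulate")
    ms_log(cfg, "info", "stage simulate: ", cfg$simulate$reps,
           " reps x ", length(scenes), " scenes at theta=", theta)
    pol <- switch(cfg$simulate$policy,
                  fixate_map = fixate_map_policy(theta),
                  random = random_policy(theta),
                  oracle = greedy_oracle_policy(theta),
                  stop("unknown policy: ", cfg$simulate$policy))
    traces <- simulate_policy(scenes, pol, pipeline_params(cfg, theta),
                              reps = cfg$simulate$reps, seed = seed_sim)
    write_traces(traces, traces_path,
                 scene_ids = sprintf("scene%03d", attr(traces, "scene_index")),
                 seeds = rep(seed_sim, length(traces)))
    manifest$stages$simulate <- list(seed = seed_sim, theta = theta,
                                     policy = cfg$simulate$policy,
                                     reps = cfg$simulate$reps,
                                     out = traces_path)
  }

  if ("evaluate" %in% stages) {
    if (is.null(traces)) {
      if (!file.exists(traces_path))
        stop("stage evaluate requires traces, but ", traces_path,
             " does not exist (run the 'simulate' stage first)")
      traces <- read_traces(traces_path)
    }
    ms_log(cfg, "info", "stage evaluate: summarizing ", length(traces),
           " traces")
    perf <- performance_summary(traces)
    eval_path <- file.path(cfg$out_dir, "evaluation.json")
    jsonlite::write_json(
      list(fractions = as.list(perf$fractions),
           mean_fixations = perf$mean_fixations,
           mean_return = perf$mean_return),
      eval_path, auto_unbox = TRUE, digits = NA)
    manifest$stages$evaluate <- list(out = eval_path)
  }

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  ms_log(cfg, "info", "manifest written to ", manifest_path)
  invisible(manifest)
}

pipeline_params <- function(cfg, theta) {
  p <- cfg$params
  meta_mdp_params(theta = theta, cost = p$cost, mask_scale = p$mask_scale,
                  mask_sharpness = p$mask_sharpness,
                  prior_mean_sd = p$prior_mean_sd,
                  prior_precision = p$prior_precision,
                  fixation_budget = p$fixation_budget)
}
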