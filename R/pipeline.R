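# Pipeline orchestration: runs the stages in order (ingest -> interpolate
# -> residence -> exposure -> fit/predict -> map), writing each stage's
# table under the output directory together with a machine-readable record
# count log. Any stage can be re-run standalone from prior artifacts.

#' Pipeline configuration
#'
#' @param logs_path Path to the raw log table (csv); ignored when
#'   `simulate = TRUE`.
#' @param landuse_path Path to the land-use table (csv); ignored when
#'   `simulate = TRUE`.
#' @param out_dir Output directory for stage artifacts.
#' @param simulate Generate a synthetic world instead of reading inputs.
#' @param world A [world_config()] used when `simulate = TRUE`.
#' @param max_accuracy_m,min_logs_per_day,min_valid_days,adjacency_mode,buffer_radius_m,min_users_per_grid
#'   Stage parameters (defaults 200, 24, 11, `"queen"`, 100, 5).
#' @param holidays Holiday dates; default [default_holidays()].
#' @param region Residence region restriction (see [restrict_region()]).
#' @param basis_dim,basis GAM spline basis dimension and class.
#' @param seed RNG seed for the simulate stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(logs_path = NULL, landuse_path = NULL,
                            out_dir = tempfile("stepscape_run_"),
                            simulate = FALSE, world = world_config(),
                            max_accuracy_m = 200, min_logs_per_day = 24,
                            min_valid_days = 11, adjacency_mode = "queen",
                            buffer_radius_m = 100, min_users_per_grid = 5,
                            holidays = default_holidays(), region = NULL,
                            basis_dim = 10, basis = "cr", seed = 1) {
  structure(
    list(logs_path = logs_path, landuse_path = landuse_path,
         out_dir = out_dir, simulate = simulate, world = world,
         max_accuracy_m = max_accuracy_m, min_logs_per_day = min_logs_per_day,
         min_valid_days = min_valid_days, adjacency_mode = adjacency_mode,
         buffer_radius_m = buffer_radius_m,
         min_users_per_grid = min_users_per_grid,
         holidays = holidays, region = region,
         basis_dim = basis_dim, basis = basis, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    rlang::abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
      class = "stepscape_config_error")
  }
  if (!is.null(raw$holidays)) raw$holidays <- as.Date(raw$holidays)
  if (!is.null(raw$world)) raw$world <- do.call(world_config, raw$world)
  do.call(pipeline_config, raw)
}

.artifact <- function(config, name) file.path(config$out_dir, name)

.need_artifact <- function(config, name, stage) {
  p <- .artifact(config, name)
  if (!file.exists(p)) {
    rlang::abort(paste0("stage '", stage, "' needs missing upstream artifact ", name),
      class = "stepscape_dependency_error")
  }
  p
}

.log_counts <- function(config, stage, counts) {
  path <- .artifact(config, "counts.json")
  all <- if (file.exists(path)) jsonlite::read_json(path) else list()
  all[[stage]] <- counts
  jsonlite::write_json(all, path, auto_unbox = TRUE, digits = NA)
  message(sprintf("[%s] %s", stage,
                  paste(names(counts), unlist(counts), sep = "=", collapse = " ")))
}

.read_points <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    uuid = readr::col_character(),
    timestamp = readr::col_datetime(),
    lat = readr::col_double(), lon = readr::col_double(),
    origin = readr::col_character()
  ), progress = FALSE)
}

.read_residences <- function(path) {
  res <- readr::read_csv(path, col_types = readr::cols(
    uuid = readr::col_character(), status = readr::col_character(),
    residential_grid_codes = readr::col_character(),
    residence_lat = readr::col_double(), residence_lon = readr::col_double()
  ), progress = FALSE)
  res$residential_grids <- strsplit(res$residential_grid_codes, ";", fixed = TRUE)
  res
}

.read_exposure <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    uuid = readr::col_character(), date = readr::col_date(),
    steps = readr::col_double(), sex = readr::col_character(),
    age_group = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `ingest`, `interpolate`, `residence`, `exposure`,
#' `fit`, `predict`, `map`. Each reads its upstream artifacts from the
#' output directory (a missing one is a dependency error naming the stage)
#' and writes its own.
#'
#' @param config A [pipeline_config()].
#' @param stage Stage name.
#' @return The main artifact of the stage, invisibly.
#' @export
run_stage <- function(config, stage) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    simulate = {
      world <- config$world
      world$seed <- config$seed
      sim <- simulate_world(world)
      write_gps_logs(sim$logs, .artifact(config, "logs.csv"))
      readr::write_csv(sim$landuse, .artifact(config, "landuse.csv"), progress = FALSE)
      readr::write_csv(
        dplyr::select(sim$users, -"beta0") |>
          dplyr::bind_cols(beta0 = sim$users$beta0),
        .artifact(config, "truth_users.csv"), progress = FALSE
      )
      .log_counts(config, "simulate",
                  list(users = nrow(sim$users), logs = nrow(sim$logs)))
      invisible(sim)
    },
    ingest = {
      logs_path <- if (config$simulate) {
        .need_artifact(config, "logs.csv", "ingest")
      } else config$logs_path
      logs <- read_gps_logs(logs_path)
      filtered <- filter_accuracy(logs, config$max_accuracy_m)
      index <- index_valid_days(filtered, config$min_logs_per_day, config$min_valid_days)
      active <- select_active(filtered, index)
      points <- dedupe_minute(active)
      readr::write_csv(filtered, .artifact(config, "logs_filtered.csv"), progress = FALSE)
      readr::write_csv(index, .artifact(config, "user_day_index.csv"), progress = FALSE)
      readr::write_csv(points, .artifact(config, "points_observed.csv"), progress = FALSE)
      .log_counts(config, "ingest", list(
        logs_in = nrow(logs), logs_accuracy_ok = nrow(filtered),
        active_users = dplyr::n_distinct(active$uuid),
        points_observed = nrow(points)
      ))
      invisible(points)
    },
    interpolate = {
      points <- .read_points(.need_artifact(config, "points_observed.csv", "interpolate"))
      index <- readr::read_csv(.need_artifact(config, "user_day_index.csv", "interpolate"),
                               col_types = readr::cols(uuid = readr::col_character(),
                                                       date = readr::col_date(),
                                                       n_logs = readr::col_integer(),
                                                       valid = readr::col_logical(),
                                                       active = readr::col_logical()),
                               progress = FALSE)
      traj <- interpolate_points(points, index)
      readr::write_csv(traj, .artifact(config, "trajectory.csv"), progress = FALSE)
      .log_counts(config, "interpolate", list(
        points_in = nrow(points), points_out = nrow(traj),
        interpolated = sum(traj$origin == "interpolated")
      ))
      invisible(traj)
    },
    residence = {
      traj <- .read_points(.need_artifact(config, "trajectory.csv", "residence"))
      res <- estimate_residences(traj, adjacency = config$adjacency_mode)
      res <- dplyr::bind_rows(
        restrict_region(dplyr::filter(res, .data$status == "valid"), config$region),
        dplyr::filter(res, .data$status == "undefinable")
      )
      out <- res |>
        dplyr::mutate(residential_grid_codes =
                        purrr::map_chr(.data$residential_grids, paste, collapse = ";")) |>
        dplyr::select("uuid", "status", "residential_grid_codes",
                      "residence_lat", "residence_lon")
      readr::write_csv(out, .artifact(config, "residences.csv"), progress = FALSE)
      .log_counts(config, "residence", list(
        users = nrow(res), valid = sum(res$status == "valid"),
        undefinable = sum(res$status == "undefinable")
      ))
      invisible(res)
    },
    exposure = {
      traj <- .read_points(.need_artifact(config, "trajectory.csv", "exposure"))
      res <- .read_residences(.need_artifact(config, "residences.csv", "exposure"))
      landuse_path <- if (config$simulate) {
        .need_artifact(config, "landuse.csv", "exposure")
      } else config$landuse_path
      logs <- readr::read_csv(.need_artifact(config, "logs_filtered.csv", "exposure"),
                              col_types = readr::cols(uuid = readr::col_character(),
                                                      timestamp = readr::col_datetime(),
                                                      sex = readr::col_character(),
                                                      age_group = readr::col_character(),
                                                      .default = readr::col_double()),
                              progress = FALSE)
      cells <- read_landuse(landuse_path)
      index <- build_cell_index(cells)
      valid <- dplyr::filter(res, .data$status == "valid")
      pts <- dplyr::semi_join(traj, valid, by = "uuid")
      pts <- filter_residential(pts, valid)
      counts <- compute_exposure(pts, index, config$buffer_radius_m)
      records <- exposure_records(counts, logs)
      readr::write_csv(records, .artifact(config, "exposure.csv"), progress = FALSE)
      .log_counts(config, "exposure", list(
        points_in = nrow(traj), points_after_residence_filter = nrow(pts),
        records = nrow(records)
      ))
      invisible(records)
    },
    fit = {
      records <- .read_exposure(.need_artifact(config, "exposure.csv", "fit"))
      model_data <- split_model_data(records)$with_steps
      fit <- fit_step_model(model_data, k = config$basis_dim, bs = config$basis)
      write_step_model(fit, .artifact(config, "model.rds"))
      readr::write_csv(glance(fit), .artifact(config, "model_glance.csv"), progress = FALSE)
      readr::write_csv(tidy(fit), .artifact(config, "model_terms.csv"), progress = FALSE)
      .log_counts(config, "fit", list(
        model_records = nrow(model_data),
        model_users = dplyr::n_distinct(model_data$uuid),
        deviance_explained = round(fit$deviance_explained, 4)
      ))
      invisible(fit)
    },
    predict = {
      fit <- read_step_model(.need_artifact(config, "model.rds", "predict"))
      records <- .read_exposure(.need_artifact(config, "exposure.csv", "predict"))
      target <- split_model_data(records)$without_steps
      preds <- predict_fixed(fit, target)
      readr::write_csv(preds, .artifact(config, "predictions.csv"), progress = FALSE)
      .log_counts(config, "predict", list(
        predictions = nrow(preds),
        mean_predicted_steps = round(mean(preds$predicted_steps), 2)
      ))
      invisible(preds)
    },
    map = {
      preds <- readr::read_csv(.need_artifact(config, "predictions.csv", "map"),
                               col_types = readr::cols(uuid = readr::col_character(),
                                                       date = readr::col_date(),
                                                       predicted_steps = readr::col_double()),
                               progress = FALSE)
      res <- .read_residences(.need_artifact(config, "residences.csv", "map"))
      means <- user_day_means(preds, holidays = config$holidays)
      summaries <- grid_summaries(means, res, min_users = config$min_users_per_grid)
      readr::write_csv(means, .artifact(config, "user_means.csv"), progress = FALSE)
      readr::write_csv(summaries, .artifact(config, "grid_summaries.csv"), progress = FALSE)
      write_grid_geojson(summaries, .artifact(config, "grid_summaries.geojson"))
      .log_counts(config, "map", list(
        user_means = nrow(means), grids = dplyr::n_distinct(summaries$grid_500m),
        rows = nrow(summaries)
      ))
      invisible(summaries)
    },
    rlang::abort(paste0("unknown stage: '", stage, "'"), class = "stepscape_config_error")
  )
}

#' Run the whole pipeline
#'
#' Executes simulate (when configured), ingest, interpolate, residence,
#' exposure, fit, predict, and map in order, writing each stage's artifact
#' and a per-stage record-count log (`counts.json`) under the output
#' directory.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stages <- c(if (config$simulate) "simulate",
              "ingest", "interpolate", "residence", "exposure",
              "fit", "predict", "map")
  for (stage in stages) run_stage(config, stage)
  invisible(config$out_dir)
}
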