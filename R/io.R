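#' Read a pumping raster CSV
#'
#' Expects columns `individual_id`, `time_h`, `pumping` (0/1), and
#' optionally `l4` (0/1) and `group`. Validates that pumping values are
#' binary (reporting offending line numbers) and that each individual's
#' observations lie on a fixed-interval grid.
#'
#' @param path CSV file path.
#' @return Validated raster data.frame.
#' @export
read_raster_csv <- function(path) {
  r <- read_checked_csv(path, c("individual_id", "time_h", "pumping"))
  bad <- which(!(r$pumping %in% c(0, 1)))
  if (length(bad) > 0L)
    stop(sprintf("non-binary pumping value at line %s of %s",
                 paste(bad + 1L, collapse = ", "), path))
  if ("l4" %in% names(r)) {
    bad <- which(!(r$l4 %in% c(0, 1)))
    if (length(bad) > 0L)
      stop(sprintf("non-binary l4 value at line %s of %s",
                   paste(bad + 1L, collapse = ", "), path))
  }
  for (id in unique(r$individual_id)) {
    tt <- sort(r$time_h[r$individual_id == id])
    dt <- diff(tt)
    if (length(dt) > 1L && any(abs(dt - dt[1L]) > 1e-8))
      stop(sprintf("fixed interval required (individual %s)", id))
  }
  r
}

#' @rdname read_raster_csv
#' @param raster Raster data.frame to write.
#' @export
write_raster_csv <- function(raster, path) {
  utils::write.csv(raster, path, row.names = FALSE)
  invisible(path)
}

#' Read activity traces and stage boundaries
#'
#' `read_traces_csv` expects columns `individual_id`, `time_h`, `activity`;
#' `read_boundaries_csv` expects `individual_id`, `stage`, `entry_h`,
#' `exit_h`.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_traces_csv <- function(path) {
  read_checked_csv(path, c("individual_id", "time_h", "activity"))
}

#' @rdname read_traces_csv
#' @export
read_boundaries_csv <- function(path) {
  b <- read_checked_csv(path, c("individual_id", "stage", "entry_h", "exit_h"))
  bad <- which(b$exit_h <= b$entry_h)
  if (length(bad) > 0L)
    stop(sprintf("exit_h <= entry_h at line %s of %s",
                 paste(bad + 1L, collapse = ", "), path))
  b
}

#' Read a morphometry CSV
#'
#' Expects columns `individual_id`, `time_h`, `group`, `length_um`,
#' `width_um`; validates positivity and width < length.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_morphometry_csv <- function(path) {
  m <- read_checked_csv(path, c("individual_id", "time_h", "group",
                                "length_um", "width_um"))
  bad <- which(m$length_um <= 0 | m$width_um <= 0 | m$width_um >= m$length_um)
  if (length(bad) > 0L)
    stop(sprintf("invalid length/width at line %s of %s",
                 paste(bad + 1L, collapse = ", "), path))
  m
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  x
}

#' Write a JSON run log
#'
#' Records the package version, timestamp, seed, parameters, and MD5 hashes
#' of the input files next to every pipeline output, so each artifact is
#' traceable to the configuration that produced it.
#'
#' @param path Output JSON path.
#' @param params Named list of parameters (including `seed`).
#' @param inputs Character vector of input file paths to hash.
#' @return The path, invisibly.
#' @export
write_run_log <- function(path, params, inputs = character(0)) {
  hashes <- if (length(inputs) > 0L) as.list(tools::md5sum(inputs)) else list()
  log <- list(package = "larvadev",
              version = as.character(utils::packageVersion("larvadev")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              params = params,
              input_md5 = hashes)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run a pipeline stage from a configuration list
#'
#' Dispatcher behind the command-line interface. Each subcommand reads its
#' inputs, runs the corresponding analysis, writes CSV outputs plus a JSON
#' run log into `out_dir`, and returns the result object invisibly. Outputs
#' are deterministic under a fixed `seed`.
#'
#' @param config Named list: `subcommand` (one of `"simulate"`,
#'   `"lineage-density"`, `"profile"`, `"lethargus"`, `"volume"`), `out_dir`,
#'   `seed`, and subcommand-specific fields (see the CLI script in
#'   `inst/cli/larvadev` for the full set).
#' @return The stage's result object, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$subcommand))
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  inputs <- character(0)
  res <- switch(
    config$subcommand,
    "simulate" = {
      params <- behavior_sim_params(
        n_individuals = config$n %||% 50L,
        fragmentation_prob = config$fragmentation_prob %||% 0.15)
      sim <- simulate_pumping_cohort(params, config$group %||% "control")
      write_raster_csv(sim$raster, file.path(out_dir, "raster.csv"))
      utils::write.csv(sim$truth, file.path(out_dir, "raster_truth.csv"),
                       row.names = FALSE)
      sim
    },
    "lineage-density" = {
      inputs <- config$image
      dd <- lineage_density(config$image, anchors = config$anchors,
                            half_width = config$half_width %||% 10L)
      utils::write.csv(dd$data, file.path(out_dir, "density.csv"),
                       row.names = FALSE)
      dd
    },
    "profile" = {
      inputs <- c(config$traces, config$boundaries)
      tr <- read_traces_csv(config$traces)
      bd <- read_boundaries_csv(config$boundaries)
      pr <- stage_activity_profile(tr, bd, config$stage %||% "L3",
                                   config$grid_step %||% 1)
      utils::write.csv(cbind(stage = config$stage %||% "L3",
                             as.data.frame(unclass(pr))[
                               c("percent", "mean", "sd", "sem", "n")]),
                       file.path(out_dir, "profile.csv"), row.names = FALSE)
      pr
    },
    "lethargus" = {
      inputs <- config$raster
      r <- read_raster_csv(config$raster)
      calls <- call_lethargus_cohort(r)
      utils::write.csv(as.data.frame(unclass(calls)),
                       file.path(out_dir, "lethargus_calls.csv"),
                       row.names = FALSE)
      summ <- NULL
      if (length(unique(calls$group)) >= 1L && !all(is.na(calls$group))) {
        summ <- cohort_lethargus_stats(
          calls, long_threshold_min = config$long_threshold %||% 100)
        jsonlite::write_json(
          list(by_group = summ$by_group,
               differences = as.list(summ$differences)),
          file.path(out_dir, "lethargus_summary.json"),
          auto_unbox = TRUE, pretty = TRUE, digits = NA)
      }
      if (!is.null(config$window)) {
        ff <- feeding_fraction(r, config$window)
        jsonlite::write_json(list(window = config$window,
                                  feeding_fraction = ff),
                             file.path(out_dir, "feeding_fraction.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      calls
    },
    "volume" = {
      inputs <- config$input
      m <- add_volume(read_morphometry_csv(config$input))
      utils::write.csv(m, file.path(out_dir, "volumes.csv"),
                       row.names = FALSE)
      res <- m
      if (isTRUE(config$divergence) && length(unique(m$group)) == 2L) {
        dv <- divergence_onset(m, alpha = config$alpha %||% 0.05)
        utils::write.csv(dv$table, file.path(out_dir, "divergence.csv"),
                         row.names = FALSE)
        res <- dv
      }
      res
    },
    stop(sprintf("unknown subcommand '%s'", config$subcommand))
  )
  write_run_log(file.path(out_dir, "run_log.json"),
                params = config[setdiff(names(config), "subcommand")],
                inputs = inputs[file.exists(inputs)])
  invisible(res)
}
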