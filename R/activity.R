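#' Crop an activity trace to one larval stage
#'
#' Restricts an individual's activity samples to the `[entry, exit]` window
#' of a larval stage and re-origins time to stage entry.
#'
#' @param trace Data frame with columns `time_h` and `activity` (one
#'   individual), times strictly increasing.
#' @param boundaries Data frame with columns `stage`, `entry_h`, `exit_h`
#'   (one individual), or a single row thereof.
#' @param stage Stage label to crop to (e.g. `"L3"`).
#' @return An object of class `stage_curve`: list with `time_h` (from 0),
#'   `activity`, `duration_h`, `stage`.
#' @export
crop_to_stage <- function(trace, boundaries, stage) {
  stopifnot(all(c("time_h", "activity") %in% names(trace)))
  b <- boundaries[boundaries$stage == stage, , drop = FALSE]
  if (nrow(b) == 0L) stop(sprintf("stage '%s' not found in boundaries", stage))
  if (nrow(b) > 1L) stop("multiple boundary rows for one stage")
  entry <- b$entry_h; exit <- b$exit_h
  if (exit <= entry) stop("stage exit must be after entry")
  keep <- trace$time_h >= entry & trace$time_h <= exit
  structure(list(time_h = trace$time_h[keep] - entry,
                 activity = trace$activity[keep],
                 duration_h = exit - entry,
                 stage = stage),
            class = "stage_curve")
}

#' Resample a stage curve onto the percent-completion axis
#'
#' Evaluates an individual's stage activity curve at fixed percentages of
#' stage completion: `P(i) = C(D * i / 100)` by linear interpolation between
#' the neighbouring samples, the endpoints taking the nearest sample. This
#' removes between-individual differences in stage duration so that profiles
#' can be averaged across a cohort.
#'
#' @param curve A [crop_to_stage()] result, or any list with `time_h`,
#'   `activity`, `duration_h`.
#' @param grid_step Grid spacing in percent (default 1, i.e. `i = 0..100`).
#' @return Numeric vector `P` named by percent completion.
#' @export
resample_percent <- function(curve, grid_step = 1) {
  stopifnot(grid_step > 0)
  if (length(curve$time_h) < 2L)
    stop("need at least 2 samples within the stage to interpolate")
  grid <- seq(0, 100, by = grid_step)
  p <- stats::approx(curve$time_h, curve$activity,
                     xout = curve$duration_h * grid / 100, rule = 2)$y
  stats::setNames(p, grid)
}

#' Average percent-stage profiles across a cohort
#'
#' Pointwise arithmetic mean (with SD and SEM) of individual profiles on a
#' shared percent-completion grid.
#'
#' @param profiles List of numeric vectors from [resample_percent()], all on
#'   the same grid, or a matrix with one row per individual.
#' @return Object of class `stage_profile`: data.frame with columns
#'   `percent`, `mean`, `sd`, `sem`, `n`, plus the individual matrix as
#'   attribute `"individuals"`.
#' @export
average_profiles <- function(profiles) {
  if (is.list(profiles)) {
    if (length(profiles) == 0L) stop("empty profile list")
    lens <- vapply(profiles, length, integer(1))
    if (length(unique(lens)) != 1L) stop("profiles must share one grid")
    mat <- do.call(rbind, profiles)
  } else mat <- as.matrix(profiles)
  if (nrow(mat) == 0L) stop("empty profile list")
  grid <- as.numeric(colnames(mat) %||% seq(0, 100, length.out = ncol(mat)))
  n <- colSums(!is.na(mat))
  m <- colMeans(mat, na.rm = TRUE)
  s <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  out <- data.frame(percent = grid, mean = m, sd = s,
                    sem = s / sqrt(pmax(n, 1L)), n = n)
  rownames(out) <- NULL
  attr(out, "individuals") <- mat
  class(out) <- c("stage_profile", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population activity profile for one larval stage
#'
#' Convenience wrapper: crops every individual's trace to the stage,
#' resamples onto the percent-completion grid, and averages across the
#' cohort.
#'
#' @param traces Data frame `individual_id`, `time_h`, `activity`.
#' @param boundaries Data frame `individual_id`, `stage`, `entry_h`,
#'   `exit_h`.
#' @param stage Stage label.
#' @param grid_step Percent grid spacing (default 1).
#' @return A `stage_profile` (see [average_profiles()]).
#' @export
stage_activity_profile <- function(traces, boundaries, stage, grid_step = 1) {
  ids <- unique(traces$individual_id)
  profs <- lapply(ids, function(id) {
    tr <- traces[traces$individual_id == id, , drop = FALSE]
    bd <- boundaries[boundaries$individual_id == id, , drop = FALSE]
    resample_percent(crop_to_stage(tr, bd, stage), grid_step)
  })
  out <- average_profiles(profs)
  attr(out, "stage") <- stage
  out
}

#' @export
print.stage_profile <- function(x, ...) {
  st <- attr(x, "stage")
  cat(sprintf("Percent-of-stage activity profile%s\n",
              if (!is.null(st)) paste0(" (", st, ")") else ""))
  cat(sprintf("  %d individuals, grid %g..%g%% (step %g)\n",
              max(x$n), min(x$percent), max(x$percent),
              if (nrow(x) > 1) x$percent[2] - x$percent[1] else NA))
  cat(sprintf("  mean activity %.3f (range %.3f..%.3f)\n",
              mean(x$mean), min(x$mean), max(x$mean)))
  invisible(x)
}

#' @export
plot.stage_profile <- function(x, show_individuals = TRUE, ...) {
  mat <- attr(x, "individuals")
  graphics::plot(x$percent, x$mean, type = "n",
                 xlab = "stage completion (%)", ylab = "activity",
                 ylim = range(if (show_individuals) mat else x$mean,
                              na.rm = TRUE), ...)
  if (show_individuals && !is.null(mat))
    for (i in seq_len(nrow(mat)))
      graphics::lines(x$percent, mat[i, ], col = "grey80", lty = 2)
  graphics::lines(x$percent, x$mean, lwd = 2)
  invisible(x)
}

#' Naive in-stage boundary suggestion from an activity minimum
#'
#' Flags the time of minimum smoothed activity inside a search window as a
#' candidate molt, for exploratory use when boundary annotations are missing.
#' This is a heuristic convenience only: stage boundaries are expected as
#' inputs, and all profile computations use the supplied annotations.
#'
#' @param trace Data frame `time_h`, `activity` for one individual.
#' @param window `c(start_h, end_h)` to search.
#' @param span Smoothing window in hours (default 0.5).
#' @return Time (h) of the smoothed activity minimum in the window.
#' @export
suggest_boundary <- function(trace, window, span = 0.5) {
  keep <- trace$time_h >= window[1L] & trace$time_h <= window[2L]
  if (!any(keep)) stop("no samples in the search window")
  tt <- trace$time_h[keep]; aa <- trace$activity[keep]
  sm <- vapply(tt, function(t0)
    mean(aa[abs(tt - t0) <= span / 2]), numeric(1))
  tt[which.min(sm)]
}
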