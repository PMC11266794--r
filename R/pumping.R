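#' Call a lethargus episode from one pumping raster row
#'
#' Scores one individual's binary pumping observations on a fixed time grid:
#' entry is the first observation without pumping, quiescent bouts are
#' maximal runs of non-pumping observations before L4 onset (or the end of
#' the window when no L4 flag is available), total duration is the number of
#' quiescent observations times the sampling interval, and the episode is
#' fragmented when pumping resumed between two quiescent bouts. Durations
#' are interval-censored: observations are snapshots, so the true bout
#' boundaries are only known to within one sampling interval.
#'
#' @param time_h Observation times in hours, fixed interval, increasing.
#' @param pumping 0/1 vector, same length.
#' @param l4 Optional 0/1 vector: 1 from the first observation with pumping
#'   and an invaginated vulva (L4 onset) onward.
#' @param longest_bout_only If `TRUE`, duration counts only the longest
#'   quiescent bout instead of summing all bouts (default `FALSE`).
#' @return Object of class `lethargus_call`: list with `entry_h`, `exit_h`
#'   (L4 onset time or `NA`), `duration_min`, `n_bouts`, `fragmented`,
#'   `censored`, `interval_min`.
#' @examples
#' t <- 32 + (0:6) / 3
#' call_lethargus(t, c(1, 1, 1, 0, 0, 0, 1), l4 = c(0, 0, 0, 0, 0, 0, 1))
#' @export
call_lethargus <- function(time_h, pumping, l4 = NULL,
                           longest_bout_only = FALSE) {
  stopifnot(length(time_h) >= 1L, length(pumping) == length(time_h))
  if (!all(pumping %in% c(0, 1))) stop("pumping must be 0/1")
  dt <- diff(time_h)
  if (length(dt) > 0L && any(abs(dt - dt[1L]) > 1e-8))
    stop("fixed interval required")
  # grids are often specified in fractional hours (20 min = 1/3 h); round
  # away that representation error so durations are exact interval multiples
  interval_min <- if (length(dt) > 0L) round(dt[1L] * 60, 9) else NA_real_
  l4_idx <- if (!is.null(l4)) which(l4 == 1)[1L] else NA_integer_
  # observations eligible for lethargus scoring: strictly before L4 onset
  last <- if (!is.na(l4_idx)) l4_idx - 1L else length(time_h)
  pre <- pumping[seq_len(last)]
  zero_idx <- which(pre == 0)
  if (length(zero_idx) == 0L) {
    out <- list(entry_h = NA_real_, exit_h = NA_real_, duration_min = 0,
                n_bouts = 0L, fragmented = FALSE, censored = TRUE,
                interval_min = interval_min)
  } else {
    r <- rle(pre == 0)
    n_bouts <- sum(r$values)
    bouts_len <- r$lengths[r$values]
    n_zero <- if (longest_bout_only) max(bouts_len) else sum(bouts_len)
    censored <- is.na(l4_idx)  # no L4 observed in window
    out <- list(entry_h = time_h[zero_idx[1L]],
                exit_h = if (!is.na(l4_idx)) time_h[l4_idx] else NA_real_,
                duration_min = n_zero * interval_min,
                n_bouts = as.integer(n_bouts),
                fragmented = n_bouts >= 2L,
                censored = censored,
                interval_min = interval_min)
  }
  structure(out, class = "lethargus_call")
}

#' @export
print.lethargus_call <- function(x, ...) {
  if (x$censored && x$n_bouts == 0L) {
    cat("Lethargus call: censored (no quiescent observation)\n")
  } else {
    cat(sprintf(
      "Lethargus call: entry %.2f h, duration %g min (%d bout%s)%s%s\n",
      x$entry_h, x$duration_min, x$n_bouts, if (x$n_bouts == 1L) "" else "s",
      if (x$fragmented) ", fragmented" else "",
      if (x$censored) ", censored (no L4 in window)" else ""))
  }
  invisible(x)
}

#' Call lethargus for every individual in a raster table
#'
#' @param raster Data frame `individual_id`, `time_h`, `pumping`, optional
#'   `l4` and `group`.
#' @param longest_bout_only Passed to [call_lethargus()].
#' @return Object of class `lethargus_calls`: data.frame with one row per
#'   individual (`individual_id`, `group`, `entry_h`, `exit_h`,
#'   `duration_min`, `n_bouts`, `fragmented`, `censored`), sorted by
#'   `entry_h` (the raster-sorting convention: first observation without
#'   pumping).
#' @export
call_lethargus_cohort <- function(raster, longest_bout_only = FALSE) {
  stopifnot(all(c("individual_id", "time_h", "pumping") %in% names(raster)))
  has_l4 <- "l4" %in% names(raster)
  has_grp <- "group" %in% names(raster)
  # animals are identified by id within group, so ids may repeat across groups
  key <- if (has_grp) interaction(raster$group, raster$individual_id, drop = TRUE)
         else raster$individual_id
  rows <- lapply(split(seq_len(nrow(raster)), key), function(idx) {
    r <- raster[idx, , drop = FALSE]
    id <- r$individual_id[1L]
    r <- r[order(r$time_h), , drop = FALSE]
    cl <- call_lethargus(r$time_h, r$pumping,
                         l4 = if (has_l4) r$l4 else NULL,
                         longest_bout_only = longest_bout_only)
    data.frame(individual_id = id,
               group = if (has_grp) r$group[1L] else NA_character_,
               entry_h = cl$entry_h, exit_h = cl$exit_h,
               duration_min = cl$duration_min, n_bouts = cl$n_bouts,
               fragmented = cl$fragmented, censored = cl$censored)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$entry_h, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lethargus_calls", class(out))
  out
}

#' Per-group lethargus summaries and differences
#'
#' Summarizes lethargus calls by group: entry and L4-onset distributions,
#' duration distribution, fragmentation fraction, and the fraction of long
#' episodes exceeding a threshold (default 100 min). With exactly two
#' groups, pairwise differences are reported.
#'
#' @param calls A [call_lethargus_cohort()] result (or compatible
#'   data.frame).
#' @param long_threshold_min Long-episode threshold in minutes (default
#'   100): an episode is long when its duration strictly exceeds this.
#' @return Object of class `lethargus_summary`: list with `by_group`
#'   (data.frame of per-group statistics over non-censored calls) and
#'   `differences` (named numeric vector, group2 minus group1, `NULL`
#'   unless exactly two groups).
#' @export
cohort_lethargus_stats <- function(calls, long_threshold_min = 100) {
  stopifnot(all(c("group", "entry_h", "duration_min", "fragmented",
                  "censored") %in% names(calls)))
  groups <- unique(calls$group)
  per <- lapply(groups, function(g) {
    cg <- calls[calls$group == g, , drop = FALSE]
    ok <- cg[!cg$censored, , drop = FALSE]
    if (nrow(ok) == 0L) stop(sprintf("all calls censored in group '%s'", g))
    data.frame(
      group = g, n = nrow(cg), n_censored = sum(cg$censored),
      entry_mean_h = mean(ok$entry_h), entry_median_h = stats::median(ok$entry_h),
      entry_sd_h = stats::sd(ok$entry_h),
      l4_median_h = stats::median(ok$exit_h, na.rm = TRUE),
      duration_mean_min = mean(ok$duration_min),
      duration_median_min = stats::median(ok$duration_min),
      fragmented_fraction = mean(ok$fragmented),
      long_fraction = mean(ok$duration_min > long_threshold_min)
    )
  })
  by_group <- do.call(rbind, per)
  rownames(by_group) <- NULL
  differences <- NULL
  if (length(groups) == 2L) {
    num <- vapply(by_group[, -1L], is.numeric, logical(1))
    differences <- unlist(by_group[2L, -1L][num]) - unlist(by_group[1L, -1L][num])
  }
  structure(list(by_group = by_group, differences = differences,
                 long_threshold_min = long_threshold_min),
            class = "lethargus_summary")
}

#' @export
print.lethargus_summary <- function(x, ...) {
  cat(sprintf("Lethargus cohort summary (long episode > %g min)\n",
              x$long_threshold_min))
  print(x$by_group, row.names = FALSE, digits = 4)
  if (!is.null(x$differences)) {
    cat(sprintf("\nDifferences (%s - %s):\n",
                x$by_group$group[2L], x$by_group$group[1L]))
    print(round(x$differences, 4))
  }
  invisible(x)
}

#' Pooled feeding fraction in a time window
#'
#' Number of pumping observations divided by the total number of
#' observations, pooled across all animals (not averaged per animal), over
#' observations with `window[1] <= time_h <= window[2]`.
#'
#' @param raster Data frame `individual_id`, `time_h`, `pumping`, optional
#'   `group`.
#' @param window `c(start_h, end_h)`.
#' @param group Optional: restrict to one group.
#' @return Fraction in `[0, 1]`.
#' @export
feeding_fraction <- function(raster, window, group = NULL) {
  stopifnot(length(window) == 2L, window[1L] < window[2L])
  r <- raster
  if (!is.null(group)) r <- r[r$group == group, , drop = FALSE]
  keep <- r$time_h >= window[1L] & r$time_h <= window[2L]
  if (!any(keep)) stop("no observations in the window")
  mean(r$pumping[keep] == 1)
}

#' Between-group feeding-fraction comparison
#'
#' Computes the pooled feeding fraction per group in a window and reports
#' the difference both ways the phrase "x% greater" can be read: relative
#' (ratio minus one) and absolute (percentage points).
#'
#' @inheritParams feeding_fraction
#' @param groups Two group labels, reference first.
#' @return List with `fractions` (named), `relative_increase`
#'   (`f2/f1 - 1`) and `absolute_increase` (`f2 - f1`).
#' @export
feeding_fraction_compare <- function(raster, window,
                                     groups = c("control", "MCP")) {
  stopifnot(length(groups) == 2L)
  f1 <- feeding_fraction(raster, window, group = groups[1L])
  f2 <- feeding_fraction(raster, window, group = groups[2L])
  list(fractions = stats::setNames(c(f1, f2), groups),
       relative_increase = f2 / f1 - 1,
       absolute_increase = f2 - f1)
}

#' Fractions of larvae past the L3 exit and L4 entry at a time
#'
#' The fraction of individuals whose first quiescent observation is at or
#' before `t` (exited L3) and whose L4 onset is at or before `t` (entered
#' L4), per group. Censored individuals stay in the denominator.
#'
#' @param calls A [call_lethargus_cohort()] result.
#' @param t Time in hours.
#' @return Data frame `group`, `n`, `exited_l3`, `entered_l4`.
#' @export
stage_transition_fractions <- function(calls, t) {
  groups <- unique(calls$group)
  out <- lapply(groups, function(g) {
    cg <- calls[calls$group == g, , drop = FALSE]
    data.frame(group = g, n = nrow(cg),
               exited_l3 = mean(!is.na(cg$entry_h) & cg$entry_h <= t),
               entered_l4 = mean(!is.na(cg$exit_h) & cg$exit_h <= t))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pharyngeal pumping rate with exclusion rules
#'
#' Rate = grinder movements per second of recording. Animals with no
#' observed grinder movements, or located off the bacterial lawn, are
#' excluded (with the reason recorded) rather than entered as zeros.
#'
#' @param counts Integer vector of grinder movements per recording.
#' @param duration_s Recording durations in seconds (recycled if length 1).
#' @param on_lawn Logical vector: was the animal on the lawn (recycled).
#' @return Data frame `rate` (movements/s, `NA` when excluded), `excluded`,
#'   `reason` (`""`, `"no_pumping"` or `"off_lawn"`).
#' @examples
#' pumping_rate(c(45, 0, 30), 10, c(TRUE, TRUE, FALSE))
#' @export
pumping_rate <- function(counts, duration_s, on_lawn = TRUE) {
  if (any(duration_s <= 0)) stop("duration_s must be positive")
  n <- length(counts)
  duration_s <- rep_len(duration_s, n)
  on_lawn <- rep_len(on_lawn, n)
  reason <- rep("", n)
  reason[counts == 0] <- "no_pumping"
  reason[!on_lawn] <- "off_lawn"
  excluded <- reason != ""
  rate <- ifelse(excluded, NA_real_, counts / duration_s)
  data.frame(rate = rate, excluded = excluded, reason = reason)
}

#' Two-group comparison (Welch t or Fisher exact)
#'
#' Standard two-group test used throughout the pipeline: Welch's t-test for
#' continuous measurements, Fisher's exact test on the 2x2 success table for
#' binary outcomes.
#'
#' @param a,b Numeric vectors (continuous) or 0/1 / logical vectors
#'   (binary).
#' @param kind `"continuous"` or `"binary"`.
#' @return List with `method`, `effect` (mean difference, or difference in
#'   proportions), `p_value`, `n` (per-group sizes).
#' @export
compare_groups <- function(a, b, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    if (length(a) < 2L || length(b) < 2L)
      stop("need >= 2 values per continuous group")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: constant groups; Welch statistic undefined
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      return(list(method = "welch_t (degenerate: zero variance)",
                  effect = mean(b) - mean(a), p_value = p,
                  n = c(length(a), length(b))))
    }
    tt <- stats::t.test(b, a)
    list(method = "welch_t", effect = mean(b) - mean(a),
         p_value = tt$p.value, n = c(length(a), length(b)))
  } else {
    a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
    tab <- rbind(c(sum(a == 1), sum(a == 0)),
                 c(sum(b == 1), sum(b == 0)))
    ft <- stats::fisher.test(tab)
    list(method = "fisher_exact", effect = mean(b) - mean(a),
         p_value = ft$p.value, n = c(length(a), length(b)))
  }
}
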