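#' Cylindrical body-volume estimate
#'
#' Volume of a larva modelled as a cylinder: `V = pi * length * (width/2)^2`,
#' with length measured along the skeletonized midline and width at the
#' vulva (or ~2/3 of body length).
#'
#' @param length_um Midline length in micrometres (vectorized).
#' @param width_um Body width in micrometres (vectorized).
#' @return Volume in cubic micrometres.
#' @examples
#' estimate_volume(1000, 80)  # ~5.03e6 um^3
#' @export
estimate_volume <- function(length_um, width_um) {
  if (any(length_um <= 0) || any(width_um <= 0))
    stop("length and width must be positive")
  pi * length_um * (width_um / 2)^2
}

#' Attach volume to a morphometry table
#'
#' @param records Data frame with `length_um` and `width_um` columns.
#' @return The same data frame with a `volume_um3` column added.
#' @export
add_volume <- function(records) {
  records$volume_um3 <- estimate_volume(records$length_um, records$width_um)
  records
}

#' Length of a hand-traced midline polyline
#'
#' Sum of segment lengths of a segmented-line midline trace, the way worm
#' length is measured from a skeletonized micrograph.
#'
#' @param x,y Vertex coordinates (same units, e.g. um).
#' @return Total polyline length.
#' @export
polyline_length <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

shared_times <- function(records, groups) {
  t1 <- unique(records$time_h[records$group == groups[1L]])
  t2 <- unique(records$time_h[records$group == groups[2L]])
  sort(intersect(t1, t2))
}

#' Test isomorphy of growth between two groups
#'
#' Growth is isomorphic when body proportions are preserved, i.e. the
#' width/length ratio does not differ between groups at any shared time
#' point. Per time point the ratios are compared with Welch's t-test;
#' p-values are Holm-adjusted across time points, and the verdict is
#' isomorphic when no adjusted p-value falls below `alpha`.
#'
#' @param records Morphometry data frame (`time_h`, `group`, `length_um`,
#'   `width_um`) with exactly two groups.
#' @param alpha Significance level after adjustment (default 0.05).
#' @return Object of class `isomorphy_test`: list with `table` (per-time
#'   ratio means, p, adjusted p) and `isomorphic` (logical verdict).
#' @export
isomorphy_test <- function(records, alpha = 0.05) {
  groups <- unique(records$group)
  stopifnot(length(groups) == 2L)
  times <- shared_times(records, groups)
  if (length(times) == 0L) stop("no shared timepoints between groups")
  rows <- lapply(times, function(t) {
    rt <- records[records$time_h == t, , drop = FALSE]
    r1 <- with(rt[rt$group == groups[1L], ], width_um / length_um)
    r2 <- with(rt[rt$group == groups[2L], ], width_um / length_um)
    cmp <- compare_groups(r1, r2, "continuous")
    data.frame(time_h = t, ratio_mean_1 = mean(r1), ratio_mean_2 = mean(r2),
               diff = cmp$effect, p = cmp$p_value)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = "holm")
  structure(list(table = tab, groups = groups, alpha = alpha,
                 isomorphic = all(tab$p_adj >= alpha)),
            class = "isomorphy_test")
}

#' @export
print.isomorphy_test <- function(x, ...) {
  cat(sprintf("Isomorphy test (%s vs %s), Holm-adjusted alpha = %g\n",
              x$groups[1L], x$groups[2L], x$alpha))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Verdict: growth %s\n",
              if (x$isomorphic) "isomorphic (no ratio difference at any time)"
              else "NOT isomorphic"))
  invisible(x)
}

#' Earliest sustained divergence in body volume between groups
#'
#' Per shared time point, compares volumes between the two groups (Welch's
#' t-test, Holm adjustment across time points). The divergence onset is the
#' earliest time at which the difference is significant and stays
#' significant at every later measured time — a sustained-significance rule
#' that operationalizes divergence "becoming evident".
#'
#' @param records Morphometry data frame with two groups (volume added
#'   automatically if absent).
#' @param alpha Significance level after adjustment (default 0.05).
#' @return Object of class `divergence_onset`: list with `table` (per-time
#'   mean volumes, p, adjusted p, significance) and `onset_h` (`NA` when no
#'   sustained divergence).
#' @export
divergence_onset <- function(records, alpha = 0.05) {
  groups <- unique(records$group)
  stopifnot(length(groups) == 2L)
  if (!"volume_um3" %in% names(records)) records <- add_volume(records)
  times <- shared_times(records, groups)
  if (length(times) < 2L) stop("need >= 2 shared timepoints")
  rows <- lapply(times, function(t) {
    rt <- records[records$time_h == t, , drop = FALSE]
    v1 <- rt$volume_um3[rt$group == groups[1L]]
    v2 <- rt$volume_um3[rt$group == groups[2L]]
    cmp <- compare_groups(v1, v2, "continuous")
    data.frame(time_h = t, mean_1 = mean(v1), mean_2 = mean(v2),
               p = cmp$p_value)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = "holm")
  tab$significant <- tab$p_adj < alpha
  # earliest time significant at itself and at every later time
  sustained <- rev(cumprod(rev(tab$significant))) == 1
  onset <- if (any(sustained)) tab$time_h[which(sustained)[1L]] else NA_real_
  structure(list(table = tab, groups = groups, alpha = alpha,
                 onset_h = onset),
            class = "divergence_onset")
}

#' @export
print.divergence_onset <- function(x, ...) {
  cat(sprintf("Volume divergence (%s vs %s), Holm-adjusted alpha = %g\n",
              x$groups[1L], x$groups[2L], x$alpha))
  print(x$table, row.names = FALSE, digits = 4)
  if (is.na(x$onset_h)) cat("No sustained divergence detected.\n")
  else cat(sprintf("Divergence onset: %g h\n", x$onset_h))
  invisible(x)
}

#' Percent difference of mean volumes between groups at a time point
#'
#' `100 * (mean_2 - mean_1) / mean_1` for the two groups' volumes at time
#' `t` (`group_pair[1]` is the reference).
#'
#' @param records Morphometry data frame (volume added if absent).
#' @param t Time point in hours.
#' @param group_pair Two group labels, reference first.
#' @return Percent difference (positive when group 2 is larger).
#' @export
relative_size <- function(records, t, group_pair = c("control", "MCP")) {
  stopifnot(length(group_pair) == 2L)
  if (!"volume_um3" %in% names(records)) records <- add_volume(records)
  rt <- records[records$time_h == t, , drop = FALSE]
  v1 <- rt$volume_um3[rt$group == group_pair[1L]]
  v2 <- rt$volume_um3[rt$group == group_pair[2L]]
  if (length(v1) == 0L || length(v2) == 0L)
    stop("both groups must be measured at t")
  100 * (mean(v2) - mean(v1)) / mean(v1)
}
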