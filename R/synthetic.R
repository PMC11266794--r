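#' Specify a synthetic lineage diagram
#'
#' Describes a lineage-diagram fixture in the standard diagram dialect:
#' horizontal division bars (height `bar_height`, width > 2 px), vertical
#' connector lines (width `line_width`), and optional 'X' death markers
#' drawn from five blocks of at most 2x2 px.
#'
#' @param divisions Data frame or list with columns/fields `row_index`
#'   (0-based top row of the bar band) and `n_bars` (number of bars drawn in
#'   that band).
#' @param image_height,image_width Image size in px.
#' @param bar_height Bar band height in px (default 2).
#' @param line_width Connector line width in px (default 2).
#' @param n_deaths Number of 'X' death markers to place (default 0).
#' @return A validated `lineage_spec` object.
#' @export
lineage_spec <- function(divisions, image_height, image_width,
                         bar_height = 2L, line_width = 2L, n_deaths = 0L) {
  divisions <- as.data.frame(divisions)
  stopifnot(all(c("row_index", "n_bars") %in% names(divisions)),
            image_height >= 1L, image_width >= 1L,
            bar_height >= 1L, line_width >= 1L, n_deaths >= 0L)
  if (any(divisions$n_bars < 1L))
    stop("n_bars must be >= 1 for every division")
  if (any(divisions$row_index < 0L) ||
      any(divisions$row_index + bar_height > image_height))
    stop("division bands must fit inside the image height")
  # bands of different divisions may not share rows: merged bars in one row
  # would break the per-row ground truth
  if (nrow(divisions) > 1L) {
    o <- order(divisions$row_index)
    d <- divisions[o, ]
    if (any(diff(d$row_index) < bar_height))
      stop("division bands overlap in rows; merged bars are not allowed")
  }
  # each bar needs width >= 3 px (wider than the 2 px deletion rule) and
  # >= 1 px white gap between bars
  min_needed <- divisions$n_bars * 3L + (divisions$n_bars - 1L)
  if (any(min_needed > image_width))
    stop("too many bars to fit the image width with 1 px gaps")
  structure(list(divisions = divisions, image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 bar_height = as.integer(bar_height),
                 line_width = as.integer(line_width),
                 n_deaths = as.integer(n_deaths)),
            class = "lineage_spec")
}

#' Render a synthetic lineage diagram with known ground truth
#'
#' Draws a binary image in the lineage-diagram pixel dialect: per division
#' band, evenly spaced horizontal bars wider than 2 px; vertical connector
#' lines of width `line_width` descending into and out of each bar; and
#' optional 'X' death markers built from five blocks each at most 2x2 px.
#' Connector and marker ink is only placed where it cannot horizontally touch
#' other ink, so every non-bar element remains at most `line_width` px wide
#' in every row and the row-scan deletion rule removes it exactly.
#'
#' @param spec A [lineage_spec()].
#' @param seed Optional integer seed for death-marker placement.
#' @return A list with `image` (binary matrix, class `lineage_image`),
#'   `truth` (integer vector: exact bar count per image row, 1-indexed
#'   vector over 0-based rows), and `spec`.
#' @export
render_lineage_diagram <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "lineage_spec"))
  if (!is.null(seed)) set.seed(seed)
  h <- spec$image_height; w <- spec$image_width
  img <- matrix(0L, h, w)
  truth <- integer(h)
  # all bar rows known upfront so connectors from any band avoid every band
  bar_rows <- unlist(lapply(seq_len(nrow(spec$divisions)), function(b)
    (spec$divisions$row_index[b] + 1L):(spec$divisions$row_index[b] + spec$bar_height)))
  for (b in seq_len(nrow(spec$divisions))) {
    r0 <- spec$divisions$row_index[b]          # 0-based
    nb <- spec$divisions$n_bars[b]
    rows <- (r0 + 1L):(r0 + spec$bar_height)   # 1-based matrix rows
    # bars of equal width >= 3 px separated by exactly 1 px white gaps
    bw <- (w - (nb - 1L)) %/% nb
    for (k in seq_len(nb)) {
      c1 <- (k - 1L) * (bw + 1L) + 1L
      c2 <- c1 + bw - 1L
      img[rows, c1:c2] <- 1L
      # connectors: parent line entering from above at the bar centre,
      # child line leaving from the bar's left end
      cc <- (c1 + c2) %/% 2L
      img <- draw_vstroke(img, r0 - 20L, r0 - 1L, cc, spec$line_width, bar_rows)
      img <- draw_vstroke(img, r0 + spec$bar_height, r0 + spec$bar_height + 14L,
                          c1, spec$line_width, bar_rows)
    }
    truth[rows] <- nb
  }
  if (spec$n_deaths > 0L) img <- place_death_markers(img, spec$n_deaths, bar_rows)
  class(img) <- c("lineage_image", class(img))
  list(image = img, truth = truth, spec = spec)
}

# Draw a vertical stroke of width `width` at 0-based rows r0..r1, left column
# `col0` (1-based), skipping rows where the stroke would fall outside the
# image, land on a bar row, or horizontally touch existing ink.
draw_vstroke <- function(img, r0, r1, col0, width, bar_rows) {
  h <- nrow(img); w <- ncol(img)
  cols <- col0:(col0 + width - 1L)
  if (any(cols < 1L) || any(cols > w)) return(img)
  guard <- max(1L, col0 - 1L):min(w, col0 + width)
  for (r in (r0 + 1L):(r1 + 1L)) {          # to 1-based
    if (r < 1L || r > h || r %in% bar_rows) next
    if (any(img[r, guard] > 0L)) next
    img[r, cols] <- 1L
  }
  img
}

# An 'X' marker: five 2x2 blocks in a cross/X arrangement (centre plus four
# diagonal neighbours), each stroke <= 2 px wide in every row.
place_death_markers <- function(img, n, bar_rows) {
  h <- nrow(img); w <- ncol(img)
  placed <- 0L; tries <- 0L
  while (placed < n && tries < 200L) {
    tries <- tries + 1L
    r <- sample.int(max(1L, h - 8L), 1L)   # top-left of an 8x8 free zone
    c <- sample.int(max(1L, w - 8L), 1L)
    zone_r <- r:min(h, r + 7L); zone_c <- c:min(w, c + 7L)
    if (length(zone_r) < 8L || length(zone_c) < 8L) next
    if (any(zone_r %in% bar_rows)) next
    if (any(img[zone_r, zone_c] > 0L)) next
    blocks <- list(c(2L, 2L), c(0L, 0L), c(0L, 4L), c(4L, 0L), c(4L, 4L))
    for (bk in blocks) {
      rr <- r + 1L + bk[1L] + 0:1; cc <- c + 1L + bk[2L] + 0:1
      img[rr, cc] <- 1L
    }
    placed <- placed + 1L
  }
  img
}

#' Draw a random lineage spec
#'
#' Convenience generator for round-trip testing: random division bands at
#' non-overlapping rows with random bar counts.
#'
#' @param image_height,image_width Image size in px.
#' @param n_divisions Number of division bands.
#' @param max_bars Maximum bars per band.
#' @param n_deaths Number of death markers.
#' @return A `lineage_spec`.
#' @export
random_lineage_spec <- function(image_height = 300L, image_width = 200L,
                                n_divisions = 6L, max_bars = 8L,
                                n_deaths = 2L) {
  max_bars <- min(max_bars, (image_width + 1L) %/% 4L)
  # candidate band top rows spaced >= 3 apart, away from the image border
  cand <- seq(25L, image_height - 25L, by = 3L)
  rows <- sort(sample(cand, n_divisions))
  lineage_spec(
    divisions = data.frame(row_index = rows,
                           n_bars = sample.int(max_bars, n_divisions, replace = TRUE)),
    image_height = image_height, image_width = image_width,
    n_deaths = n_deaths
  )
}

#' Simulate a cohort of larval activity traces
#'
#' Generates per-individual activity curves that share a common template on
#' the percent-of-stage-completion axis but differ in stage duration:
#' individual `i` has duration `D_i` drawn from a normal distribution and
#' activity `C_i(t) = template(100 t / D_i) + noise`. This emulates
#' displacement-per-10-s locomotion traces of larvae with variable
#' developmental tempo.
#'
#' @param template Function of percent completion in `[0, 100]` giving the
#'   noiseless activity level.
#' @param n Number of individuals.
#' @param duration_mean Mean stage duration in hours (default 8).
#' @param duration_cv Coefficient of variation of duration (default 0.15).
#' @param noise_sd SD of additive Gaussian noise (activity units).
#' @param sampling_interval_s Sampling interval in seconds (default 10).
#' @param stage Stage label for the boundaries table (default "L3").
#' @param seed Optional integer seed.
#' @return A list of class `activity_cohort`: `traces` (data.frame
#'   `individual_id`, `time_h`, `activity`), `boundaries` (data.frame
#'   `individual_id`, `stage`, `entry_h`, `exit_h`), `durations_h`,
#'   `template`.
#' @export
simulate_activity_cohort <- function(template, n, duration_mean = 8,
                                     duration_cv = 0.15, noise_sd = 0.1,
                                     sampling_interval_s = 10,
                                     stage = "L3", seed = NULL) {
  stopifnot(is.function(template), n >= 1L, duration_cv >= 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  dt <- sampling_interval_s / 3600
  durations <- numeric(n)
  for (i in seq_len(n)) {
    d <- stats::rnorm(1, duration_mean, duration_cv * duration_mean)
    tries <- 0L
    while (d <= 0 && tries < 50L) {
      d <- stats::rnorm(1, duration_mean, duration_cv * duration_mean)
      tries <- tries + 1L
    }
    if (d <= 0) stop("could not draw a positive stage duration")
    durations[i] <- d
  }
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- seq(0, durations[i], by = dt)
    act <- template(100 * tt / durations[i]) + stats::rnorm(length(tt), 0, noise_sd)
    traces[[i]] <- data.frame(individual_id = i, time_h = tt, activity = act)
  }
  structure(list(
    traces = do.call(rbind, traces),
    boundaries = data.frame(individual_id = seq_len(n), stage = stage,
                            entry_h = 0, exit_h = durations),
    durations_h = durations,
    template = template
  ), class = "activity_cohort")
}

#' Parameters for the pumping-raster simulator
#'
#' Bundles and validates the knobs of [simulate_pumping_cohort()]. Defaults
#' reflect the standard scoring design: 10-s pumping observations every
#' 20 min between 32 and 39 h post hatching, lethargus onset centred at 34 h
#' (so about half the cohort has exited L3 by 34 h), and a two-component
#' duration mixture whose long mode produces episodes above 100 min.
#'
#' @param n_individuals Cohort size.
#' @param sampling_interval Minutes between observations (default 20).
#' @param observation_window `c(start, end)` in hours (default `c(32, 39)`).
#' @param onset_mean,onset_sd Lethargus onset distribution (hours).
#' @param dur_short_mean,dur_short_sd Short-mode duration (minutes).
#' @param dur_long_mean,dur_long_sd Long-mode duration (minutes).
#' @param long_weight Mixture weight of the long mode in `[0, 1]`.
#' @param fragmentation_prob Probability that a quiescent period is
#'   interrupted by one interior pumping bout.
#' @param seed Optional integer seed stored with the parameters.
#' @return A validated `behavior_sim_params` object.
#' @export
behavior_sim_params <- function(n_individuals = 50L, sampling_interval = 20,
                                observation_window = c(32, 39),
                                onset_mean = 34, onset_sd = 0.75,
                                dur_short_mean = 70, dur_short_sd = 15,
                                dur_long_mean = 130, dur_long_sd = 20,
                                long_weight = 0.2, fragmentation_prob = 0.15,
                                seed = NULL) {
  stopifnot(n_individuals >= 1L, sampling_interval > 0,
            length(observation_window) == 2L,
            observation_window[1L] < observation_window[2L],
            onset_sd >= 0, dur_short_sd >= 0, dur_long_sd >= 0,
            long_weight >= 0, long_weight <= 1,
            fragmentation_prob >= 0, fragmentation_prob <= 1)
  structure(as.list(environment()), class = "behavior_sim_params")
}

#' Probability that a simulated lethargus episode exceeds a threshold
#'
#' Closed-form tail mass of the two-component normal duration mixture used
#' by [simulate_pumping_cohort()]; useful as the reference value when
#' checking recovered long-episode fractions.
#'
#' @param params A [behavior_sim_params()].
#' @param threshold_min Episode length threshold in minutes (default 100).
#' @return Probability in `[0, 1]`.
#' @export
long_episode_prob <- function(params, threshold_min = 100) {
  stopifnot(inherits(params, "behavior_sim_params"))
  with(params,
       long_weight * stats::pnorm(threshold_min, dur_long_mean, dur_long_sd,
                                  lower.tail = FALSE) +
       (1 - long_weight) * stats::pnorm(threshold_min, dur_short_mean,
                                        dur_short_sd, lower.tail = FALSE))
}

#' Simulate a cohort of pumping rasters around the L3-to-L4 transition
#'
#' Each individual pumps until its drawn lethargus onset, is quiescent for
#' its drawn duration (possibly interrupted by one interior pumping bout if
#' fragmented), and then resumes pumping as an L4 (invaginated vulva). All
#' times are discretized to the observation grid. Individuals whose
#' quiescence never starts, or never ends, inside the observation window are
#' marked censored in the ground truth rather than dropped.
#'
#' @param params A [behavior_sim_params()].
#' @param group_label Group name stored in the output (e.g. `"control"`,
#'   `"MCP"`).
#' @param seed Optional integer seed (overrides `params$seed`).
#' @return A list of class `pumping_cohort`: `raster` (data.frame
#'   `individual_id`, `time_h`, `pumping`, `l4`, `group`) and `truth`
#'   (data.frame `individual_id`, `group`, `onset_h`, `duration_min`,
#'   `fragmented`, `bout_h`, `censored`).
#' @export
simulate_pumping_cohort <- function(params, group_label = "control",
                                    seed = NULL) {
  stopifnot(inherits(params, "behavior_sim_params"))
  seed <- if (!is.null(seed)) seed else params$seed
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(params$observation_window[1L], params$observation_window[2L],
              by = params$sampling_interval / 60)
  n <- params$n_individuals
  rasters <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    onset <- stats::rnorm(1, params$onset_mean, params$onset_sd)
    is_long <- stats::runif(1) < params$long_weight
    dur <- -1
    tries <- 0L
    while (dur <= 0 && tries < 50L) {
      dur <- if (is_long) stats::rnorm(1, params$dur_long_mean, params$dur_long_sd)
             else stats::rnorm(1, params$dur_short_mean, params$dur_short_sd)
      tries <- tries + 1L
    }
    if (dur <= 0) stop("could not draw a positive lethargus duration")
    exit <- onset + dur / 60
    quiescent <- grid >= onset & grid < exit
    pumping <- as.integer(!quiescent)
    l4 <- integer(length(grid))
    first_l4 <- which(grid >= exit & pumping == 1L)[1L]
    if (!is.na(first_l4)) l4[first_l4:length(grid)] <- 1L
    # fragmentation: flip one interior quiescent observation back to pumping
    frag_drawn <- stats::runif(1) < params$fragmentation_prob
    qi <- which(quiescent)
    fragmented <- FALSE; bout_h <- NA_real_
    if (frag_drawn && length(qi) >= 3L) {
      interior <- qi[-c(1L, length(qi))]
      bi <- if (length(interior) == 1L) interior else sample(interior, 1L)
      pumping[bi] <- 1L
      fragmented <- TRUE
      bout_h <- grid[bi]
    }
    censored <- length(qi) == 0L || is.na(first_l4)
    rasters[[i]] <- data.frame(individual_id = i, time_h = grid,
                               pumping = pumping, l4 = l4,
                               group = group_label)
    truth[[i]] <- data.frame(individual_id = i, group = group_label,
                             onset_h = onset, duration_min = dur,
                             fragmented = fragmented, bout_h = bout_h,
                             censored = censored)
  }
  structure(list(raster = do.call(rbind, rasters),
                 truth = do.call(rbind, truth),
                 params = params),
            class = "pumping_cohort")
}

#' Simulate an isomorphic larval growth timecourse
#'
#' Length grows exponentially, width is a fixed fraction of length
#' (isomorphic growth), and measurement noise is multiplicative with a given
#' CV. A second group follows the same trajectory advanced by
#' `group_offset_h` hours; with `divergence_h` set, the advance applies only
#' from that time point on, so the groups coincide earlier and diverge there.
#'
#' @param timepoints Hours at which both groups are measured.
#' @param n_per_group Animals per group per time point.
#' @param length0_um Length scale at time 0 (default 250 um).
#' @param growth_rate Exponential length growth rate per hour (default
#'   0.031, about a 100-fold volume increase over 50 h).
#' @param width_to_length_ratio Width as a fraction of length (default 0.08).
#' @param noise_cv Multiplicative measurement noise CV (default 0.05).
#' @param group_offset_h Developmental advance of the second group in hours.
#' @param divergence_h Time from which the advance applies; `-Inf` (default)
#'   shifts the whole trajectory.
#' @param groups Two group labels, unshifted first.
#' @param allometry_ratio_factor Multiplier on the width/length ratio of the
#'   second group (1 = isomorphic; e.g. 1.2 simulates allometric growth).
#' @param seed Optional integer seed.
#' @return A data.frame (`morphometry` layout): `individual_id`, `time_h`,
#'   `group`, `length_um`, `width_um`.
#' @export
simulate_morphometry <- function(timepoints = seq(26, 46, by = 2),
                                 n_per_group = 30L, length0_um = 250,
                                 growth_rate = 0.031,
                                 width_to_length_ratio = 0.08,
                                 noise_cv = 0.05, group_offset_h = 0,
                                 divergence_h = -Inf,
                                 groups = c("control", "MCP"),
                                 allometry_ratio_factor = 1,
                                 seed = NULL) {
  stopifnot(width_to_length_ratio > 0, noise_cv >= 0, length(groups) == 2L,
            allometry_ratio_factor > 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", 2L * length(timepoints)); b <- 0L; id0 <- 0L
  for (g in seq_along(groups)) {
    offset <- if (g == 2L) group_offset_h else 0
    ratio <- width_to_length_ratio * if (g == 2L) allometry_ratio_factor else 1
    for (t in timepoints) {
      t_eff <- t + offset * (t >= divergence_h)
      base_len <- length0_um * exp(growth_rate * t_eff)
      n <- n_per_group
      b <- b + 1L
      rows[[b]] <- data.frame(
        individual_id = id0 + seq_len(n), time_h = t, group = groups[g],
        length_um = base_len * (1 + stats::rnorm(n, 0, noise_cv)),
        width_um = ratio * base_len * (1 + stats::rnorm(n, 0, noise_cv)))
      id0 <- id0 + n
    }
  }
  do.call(rbind, rows)
}
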