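test_that("renderer ground truth follows the spec by construction", {
  spec <- lineage_spec(data.frame(row_index = 10L, n_bars = 1L),
                       image_height = 40L, image_width = 30L)
  ren <- render_lineage_diagram(spec)
  expect_equal(ren$truth[11:12], c(1L, 1L))  # 0-based rows 10 and 11
  expect_equal(sum(ren$truth), 2L)
})

test_that("overlapping division bands are rejected", {
  expect_error(
    lineage_spec(data.frame(row_index = c(50L, 51L), n_bars = c(3L, 2L)),
                 image_height = 100L, image_width = 80L),
    "overlap")
  expect_error(
    lineage_spec(data.frame(row_index = 5L, n_bars = 30L),
                 image_height = 50L, image_width = 40L),
    "width")
})

test_that("renderer/parser round trip is exact on random specs", {
  set.seed(2024)
  for (k in 1:20) {
    spec <- random_lineage_spec(sample(150:400, 1), sample(80:250, 1),
                                sample(2:8, 1), 8, sample(0:3, 1))
    ren <- render_lineage_diagram(spec, seed = k)
    v <- count_bars_per_row(strip_narrow_elements(ren$image))
    expect_identical(v, ren$truth)
  }
})

test_that("simulators are reproducible under a fixed seed", {
  set.seed(5); spec_a <- random_lineage_spec(n_deaths = 2)
  set.seed(5); spec_b <- random_lineage_spec(n_deaths = 2)
  a <- render_lineage_diagram(spec_a, seed = 5)
  set.seed(0)  # perturb global RNG state in between
  b <- render_lineage_diagram(spec_b, seed = 5)
  expect_identical(a$image, b$image)

  p <- behavior_sim_params(n_individuals = 10)
  expect_identical(simulate_pumping_cohort(p, seed = 3),
                   simulate_pumping_cohort(p, seed = 3))
  tpl <- function(i) i / 100
  expect_identical(simulate_activity_cohort(tpl, 5, seed = 3)$traces,
                   simulate_activity_cohort(tpl, 5, seed = 3)$traces)
  expect_identical(simulate_morphometry(seed = 3), simulate_morphometry(seed = 3))
})

test_that("activity cohort honours its template and duration scaling", {
  flat <- simulate_activity_cohort(function(i) rep(5, length(i)), n = 3,
                                   noise_sd = 0, seed = 1)
  expect_true(all(flat$traces$activity == 5))
  # linear template: value at the stage midpoint is 0.5 whatever the duration
  lin <- simulate_activity_cohort(function(i) i / 100, n = 2,
                                  duration_mean = 6, duration_cv = 0.4,
                                  noise_sd = 0, seed = 8)
  for (id in 1:2) {
    tr <- lin$traces[lin$traces$individual_id == id, ]
    D <- lin$durations_h[id]
    mid <- which.min(abs(tr$time_h - D / 2))
    expect_equal(tr$activity[mid], 0.5, tolerance = 1e-3)
  }
})

test_that("mean recovered activity profile tracks the template", {
  tpl <- function(i) 1 + sin(i / 15)
  co <- simulate_activity_cohort(tpl, n = 50, noise_sd = 0.1, seed = 77)
  pr <- stage_activity_profile(co$traces, co$boundaries, "L3")
  se <- 0.1 / sqrt(50)
  expect_lt(max(abs(pr$mean - tpl(pr$percent))), 3 * se * 2)
})

test_that("unfragmented pumping rows never show an interior pumping bout", {
  p <- behavior_sim_params(n_individuals = 40, fragmentation_prob = 0)
  sim <- simulate_pumping_cohort(p, seed = 12)
  calls <- call_lethargus_cohort(sim$raster)
  expect_true(all(!calls$fragmented))
  expect_true(all(calls$n_bouts <= 1L))
})

test_that("degenerate 60-min durations give exactly 3 quiescent observations", {
  p <- behavior_sim_params(n_individuals = 30, onset_sd = 0.4,
                           dur_short_mean = 60, dur_short_sd = 0,
                           dur_long_mean = 60, dur_long_sd = 0,
                           long_weight = 0, fragmentation_prob = 0)
  sim <- simulate_pumping_cohort(p, seed = 21)
  calls <- call_lethargus_cohort(sim$raster)
  ok <- !calls$censored
  expect_true(any(ok))
  expect_true(all(calls$duration_min[ok] == 60))
})

test_that("heavy-tail mixture puts the stated mass above 100 min", {
  p <- behavior_sim_params(n_individuals = 200, long_weight = 0.2)
  expect_equal(long_episode_prob(p), 0.2048, tolerance = 1e-3)
  sim <- simulate_pumping_cohort(p, seed = 31)
  frac <- mean(sim$truth$duration_min > 100)
  ci <- frac + c(-1, 1) * 1.96 * sqrt(frac * (1 - frac) / 200)
  expect_true(long_episode_prob(p) >= ci[1] && long_episode_prob(p) <= ci[2])
})

test_that("censoring is flagged, not silently dropped", {
  p <- behavior_sim_params(n_individuals = 50, onset_mean = 38.8,
                           onset_sd = 0.5)
  sim <- simulate_pumping_cohort(p, seed = 4)
  expect_equal(nrow(sim$truth), 50L)
  expect_true(any(sim$truth$censored))
})

test_that("morphometry simulator is isomorphic and shift-consistent", {
  m0 <- simulate_morphometry(noise_cv = 0, group_offset_h = 0, n_per_group = 2)
  ctrl <- m0[m0$group == "control", c("time_h", "length_um", "width_um")]
  mcp <- m0[m0$group == "MCP", c("time_h", "length_um", "width_um")]
  expect_equal(ctrl, mcp, ignore_attr = TRUE)
  expect_true(all(abs(m0$width_um / m0$length_um - 0.08) < 1e-12))
  # 2 h shift: shifted group at t equals unshifted group at t + 2
  m2 <- simulate_morphometry(timepoints = seq(26, 44, 2), noise_cv = 0,
                             group_offset_h = 2, n_per_group = 1)
  m2 <- add_volume(m2)
  v_mcp_30 <- m2$volume_um3[m2$group == "MCP" & m2$time_h == 30][1]
  v_ctl_32 <- m2$volume_um3[m2$group == "control" & m2$time_h == 32][1]
  expect_equal(v_mcp_30, v_ctl_32)
  # length grows monotonically
  lens <- tapply(m2$length_um[m2$group == "control"],
                 m2$time_h[m2$group == "control"], mean)
  expect_true(all(diff(lens) > 0))
})
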