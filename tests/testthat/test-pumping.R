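test_that("call_lethargus scores entry, duration and fragmentation", {
  t7 <- 32 + (0:6) / 3
  cl <- call_lethargus(t7, c(1, 1, 1, 0, 0, 0, 1),
                       l4 = c(0, 0, 0, 0, 0, 0, 1))
  expect_equal(cl$entry_h, 33)
  expect_equal(cl$duration_min, 60)
  expect_equal(cl$n_bouts, 1L)
  expect_false(cl$fragmented)
  expect_false(cl$censored)
  expect_equal(cl$exit_h, 34)

  t5 <- 32 + (0:4) / 3
  fr <- call_lethargus(t5, c(1, 0, 1, 0, 1), l4 = c(0, 0, 0, 0, 1))
  expect_true(fr$fragmented)
  expect_equal(fr$n_bouts, 2L)
  expect_equal(fr$duration_min, 40)
  # longest-bout variant counts only the longest run
  lb <- call_lethargus(t7, c(1, 0, 1, 0, 0, 0, 1), l4 = c(0, 0, 0, 0, 0, 0, 1),
                       longest_bout_only = TRUE)
  expect_equal(lb$duration_min, 60)
})

test_that("call_lethargus flags censoring instead of erroring", {
  tt <- 32 + (0:5) / 3
  all_pump <- call_lethargus(tt, rep(1, 6), l4 = rep(0, 6))
  expect_true(all_pump$censored)
  expect_equal(all_pump$n_bouts, 0L)
  no_l4 <- call_lethargus(tt, c(1, 1, 0, 0, 0, 0), l4 = rep(0, 6))
  expect_true(no_l4$censored)
  expect_equal(no_l4$duration_min, 80)  # still measured, just censored
  expect_error(call_lethargus(c(32, 32.2, 32.5), c(1, 0, 1)), "fixed interval")
})

test_that("duration equals interval times quiescent observations, exactly", {
  p <- behavior_sim_params(n_individuals = 60)
  sim <- simulate_pumping_cohort(p, seed = 63)
  calls <- call_lethargus_cohort(sim$raster)
  for (i in seq_len(nrow(calls))) {
    id <- calls$individual_id[i]
    r <- sim$raster[sim$raster$individual_id == id, ]
    pre <- r$pumping[r$l4 == 0]
    expect_equal(calls$duration_min[i], sum(pre == 0) * 20)
  }
  # sorting convention: calls come back ordered by first quiescent observation
  expect_true(!is.unsorted(calls$entry_h, na.rm = TRUE))
})

test_that("onset/duration/fragmentation recovery matches ground truth", {
  p <- behavior_sim_params(n_individuals = 120)
  sim <- simulate_pumping_cohort(p, seed = 15)
  cj <- join_truth(call_lethargus_cohort(sim$raster), sim$truth)
  ok <- !cj$censored_gt
  expect_identical(cj$censored, cj$censored_gt)
  expect_true(all(abs(cj$entry_h[ok] - cj$onset_h[ok]) <= 20 / 60 + 1e-9))
  expect_true(all(abs(cj$duration_min[ok] - expected_duration_min(cj[ok, ])) <=
                    20 + 1e-9))
  expect_identical(cj$fragmented[ok], cj$fragmented_gt[ok])
})

test_that("cohort stats summarize durations, fragmentation and long episodes", {
  calls <- data.frame(individual_id = 1:4, group = rep(c("a", "b"), each = 2),
                      entry_h = c(33, 34, 33, 34), exit_h = c(35, 36, 35, 36),
                      duration_min = c(60, 120, 60, 120), n_bouts = 1L,
                      fragmented = FALSE, censored = FALSE)
  s <- cohort_lethargus_stats(calls)
  expect_equal(s$by_group$long_fraction, c(0.5, 0.5))
  # identical groups: every difference is zero
  expect_true(all(s$differences == 0))
  all_cens <- calls; all_cens$censored <- TRUE
  expect_error(cohort_lethargus_stats(all_cens), "censored")
})

test_that("group contrast in long episodes is recovered from simulation", {
  ctl <- simulate_pumping_cohort(
    behavior_sim_params(n_individuals = 150, long_weight = 0.25), "control",
    seed = 71)
  mcp <- simulate_pumping_cohort(
    behavior_sim_params(n_individuals = 150, long_weight = 0.05), "MCP",
    seed = 72)
  raster <- rbind(ctl$raster, mcp$raster)
  s <- cohort_lethargus_stats(call_lethargus_cohort(raster))
  est_diff <- s$differences[["long_fraction"]]
  true_diff <- mean(mcp$truth$duration_min > 100) -
    mean(ctl$truth$duration_min > 100)
  # binomial sampling scale for a difference of proportions at n = 150
  expect_lt(abs(est_diff - true_diff), 1.96 * sqrt(2 * 0.25 / 150) + 0.05)
  # MCP should show the shorter durations the lower long-mode weight implies
  expect_lt(s$differences[["duration_mean_min"]], 0)
})

test_that("feeding fraction pools observations across animals", {
  r <- data.frame(individual_id = rep(1:2, each = 6),
                  time_h = rep(34 + (0:5) / 3, 2),
                  pumping = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0))
  expect_equal(feeding_fraction(r, c(34, 36)), 0.75)
  r$pumping <- 1
  expect_equal(feeding_fraction(r, c(34, 36)), 1)
  expect_error(feeding_fraction(r, c(50, 52)), "no observations")
})

test_that("feeding fraction is monotone under flipping observations to pumping", {
  set.seed(88)
  r <- data.frame(individual_id = rep(1:5, each = 10),
                  time_h = rep(32 + (0:9) / 3, 5),
                  pumping = rbinom(50, 1, 0.6))
  f0 <- feeding_fraction(r, c(32, 35))
  expect_gte(f0, 0); expect_lte(f0, 1)
  zeros <- which(r$pumping == 0 & r$time_h <= 35)
  r$pumping[zeros[1]] <- 1
  expect_gt(feeding_fraction(r, c(32, 35)), f0)
})

test_that("feeding comparison reports both readings of 'greater'", {
  r <- data.frame(individual_id = rep(1:2, each = 4),
                  time_h = rep(34 + (0:3) / 3, 2),
                  pumping = c(1, 1, 0, 0, 1, 1, 1, 0),
                  group = rep(c("control", "MCP"), each = 4))
  fc <- feeding_fraction_compare(r, c(34, 36))
  expect_equal(unname(fc$fractions), c(0.5, 0.75))
  expect_equal(fc$relative_increase, 0.5)
  expect_equal(fc$absolute_increase, 0.25)
})

test_that("stage-transition fractions count censored animals in denominators", {
  calls <- data.frame(individual_id = 1:4, group = "control",
                      entry_h = c(33, 33, 33, NA), exit_h = c(35, 35, NA, NA),
                      duration_min = c(60, 60, 60, 0), n_bouts = 1L,
                      fragmented = FALSE, censored = c(FALSE, FALSE, TRUE, TRUE))
  tf <- stage_transition_fractions(calls, 34)
  expect_equal(tf$exited_l3, 0.75)
  expect_equal(tf$entered_l4, 0)
  tf36 <- stage_transition_fractions(calls, 36)
  expect_equal(tf36$entered_l4, 0.5)
})

test_that("simulated cohort crosses 50% L3 exit near the onset median", {
  p <- behavior_sim_params(n_individuals = 200)
  sim <- simulate_pumping_cohort(p, seed = 123)
  calls <- call_lethargus_cohort(sim$raster)
  f34 <- stage_transition_fractions(calls, 34)$exited_l3
  expect_lt(abs(f34 - 0.5), 1.96 * sqrt(0.25 / 200) + 0.01)
})

test_that("pumping rate normalizes by duration and applies exclusions", {
  pr <- pumping_rate(c(45, 0, 30), 10, c(TRUE, TRUE, FALSE))
  expect_equal(pr$rate[1], 4.5)
  expect_true(is.na(pr$rate[2]) && pr$reason[2] == "no_pumping")
  expect_true(is.na(pr$rate[3]) && pr$reason[3] == "off_lawn")
  expect_error(pumping_rate(10, 0), "positive")
})

test_that("compare_groups handles identical, separated and shifted samples", {
  idb <- compare_groups(rep(c(0, 1), 5), rep(c(0, 1), 5), "binary")
  expect_equal(idb$p_value, 1)
  expect_equal(idb$effect, 0)
  sep <- compare_groups(rep(1, 10), rep(0, 10), "binary")
  expect_lt(sep$p_value, 0.001)
  expect_equal(sep$method, "fisher_exact")
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), "continuous")
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(1, c(1, 2), "continuous"), ">= 2 values")
})

test_that("the Welch test has adequate power at a 1 SD shift, n = 50", {
  set.seed(2718)
  rej <- 0L
  for (k in 1:1000) {
    a <- rnorm(50)
    b <- rnorm(50, 1)
    if (compare_groups(a, b, "continuous")$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 1000, 0.8)
})
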