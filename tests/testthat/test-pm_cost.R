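test_that("the anticipation filter drops RTs strictly below 300 ms", {
  d <- data.frame(rt = c(0.25, 0.30, 0.80))
  out <- filter_responses(d)
  expect_equal(out$rt, c(0.30, 0.80))
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(nrow(filter_responses(d[d$rt >= 0.3, , drop = FALSE])), 2L)
  expect_equal(nrow(filter_responses(d[0, , drop = FALSE])), 0L)
  expect_error(filter_responses(data.frame(x = 1)), "rt")
})

test_that("baselines are difficulty-by-practice cell means of correct non-PM RTs", {
  probes <- toy_probes(levels = c(3, 2, 1), rt_non = c(0.7, 0.8, 0.9),
                       rt_pm = c(0.9, 0.9, 0.9), blocks = 2)
  # block 1 = early, block 2 = late under the default split
  bl <- compute_baselines(probes)
  expect_equal(nrow(bl), 6L)  # 3 levels x 2 bins
  cell <- bl[bl$difficulty_level == 3 & bl$bin == "early", ]
  expect_equal(cell$mean_rt, 0.7)
  expect_equal(cell$n_obs, 1L)

  # two observations in one cell average
  p2 <- probes
  p2$block <- 1L  # single block -> all late under floor(1/2)=0 early blocks
  p2$difficulty_level <- 3L
  bl2 <- compute_baselines(p2)
  expect_equal(bl2$mean_rt[bl2$bin == "late"], mean(c(0.7, 0.8, 0.9)))

  # incorrect responses are excluded by default, kept when asked
  p3 <- probes
  p3$og_correct[p3$pm_type == "none" & p3$probe == 1] <- FALSE
  bl3 <- compute_baselines(p3)
  empty <- bl3[bl3$difficulty_level == 3 & bl3$bin == "early", ]
  expect_equal(empty$n_obs, 0L)
  expect_true(is.na(empty$mean_rt))
  bl3all <- compute_baselines(p3, correct_only = FALSE)
  expect_gt(bl3all$n_obs[bl3all$difficulty_level == 3 &
                           bl3all$bin == "early"], 0L)

  expect_error(compute_baselines(probes[probes$pm_type != "none", ]),
               "non-PM")
})

test_that("a complete synthetic session populates all 30 baseline cells", {
  co <- test_cohort(n = 2, blocks = 6, seed = 19)
  bl <- compute_baselines(suppressMessages(filter_responses(co$probes)))
  expect_equal(sum(bl$participant == 1), 30L)
  expect_setequal(unique(bl$difficulty_level), 1:15)
  expect_setequal(unique(bl$bin), c("early", "late"))
})

test_that("per-probe cost is RT minus the matched baseline", {
  probes <- toy_probes(levels = c(5, 4, 3), rt_non = c(0.8, 0.8, 0.8),
                       rt_pm = c(0.9, 0.8, 1.0), blocks = 2)
  bl <- compute_baselines(probes)
  cc <- probe_costs(probes, bl)
  expect_equal(nrow(cc), 6L)  # PM probes only
  expect_equal(cc$cost[cc$block == 1], c(0.1, 0.0, 0.2))
  # constant shift of PM RTs shifts costs exactly, slopes not at all
  shifted <- probes
  shifted$rt[shifted$pm_type != "none"] <-
    shifted$rt[shifted$pm_type != "none"] + 0.05
  cs <- probe_costs(shifted, compute_baselines(shifted))
  expect_equal(cs$cost, cc$cost + 0.05)
})

test_that("empty baseline cells fall back to the other practice bin", {
  probes <- toy_probes(levels = c(3, 2, 1), rt_non = c(0.7, 0.8, 0.9),
                       rt_pm = c(0.9, 0.9, 0.9), blocks = 2)
  # remove all early non-PM rows: early PM probes must use the late bin
  probes <- probes[!(probes$block == 1 & probes$pm_type == "none"), ]
  bl <- compute_baselines(probes)
  cc <- probe_costs(probes, bl)
  early <- cc[cc$block == 1, ]
  expect_true(all(early$baseline_fallback))
  expect_equal(early$cost, c(0.9 - 0.7, 0.9 - 0.8, 0.9 - 0.9))
})

test_that("cost slope follows the window formula in ms/s", {
  # 100 ms window difference on a 10-probe trial -> 5 ms/s
  cost <- c(0.05, 0.05, 0.05, 0.2, 0.2, 0.2, 0.15, 0.15, 0.15, 0.4)
  expect_equal(cost_slope(cost, 1:10, 10), 1000 * ((0.15 - 0.05) / 10) / 2)
  expect_equal(cost_slope(cost, 1:10, 10), 5)
  # constant costs -> slope 0; additive invariance; linear scaling
  expect_equal(cost_slope(rep(0.1, 10), 1:10, 10), 0)
  expect_equal(cost_slope(cost + 0.3, 1:10, 10), cost_slope(cost, 1:10, 10))
  expect_equal(cost_slope(cost * 2, 1:10, 10),
               2 * cost_slope(cost, 1:10, 10))
  # short trials have overlapping windows
  s <- cost_slope(rep(0.1, 6), 1:6, 6)
  expect_true(is.na(s))
  expect_match(attr(s, "reason"), "overlap")
  # missing costs: available costs used, min_window_n enforced
  cost_na <- cost
  cost_na[c(1, 2)] <- NA
  expect_false(is.na(cost_slope(cost_na, 1:10, 10)))
  expect_true(is.na(cost_slope(cost_na, 1:10, 10, min_window_n = 3)))
})

test_that("trial summaries apply the 50% accuracy exclusion monotonically", {
  co <- test_cohort(n = 6, blocks = 4, seed = 23)
  bh <- memo("bh_6_4_23", pm_cost_pipeline(co))
  tr <- bh$trials
  expect_true(all(tr$excluded[!is.na(tr$og_accuracy) & tr$og_accuracy < 0.5]))
  expect_true(all(!tr$excluded[tr$og_accuracy >= 0.5]))
  # non-PM trials never get a cost slope
  expect_true(all(is.na(tr$cost_slope[tr$pm_type == "none"])))
  # lowering the threshold never excludes more trials
  probes <- bh$costed_probes
  lower <- summarize_trials(probes, co$trials, accuracy_threshold = 0.3)
  expect_lte(sum(lower$trials$excluded), sum(tr$excluded))
})

test_that("mean cost declines with difficulty when the decay is positive", {
  bh <- test_behavior(n = 16, blocks = 4, seed = 42)
  lc <- aggregate(mean_cost ~ difficulty_level, data = bh$level_costs,
                  FUN = mean)
  expect_gt(lc$mean_cost[lc$difficulty_level == 1],
            lc$mean_cost[lc$difficulty_level == 15])
  expect_lt(cor(lc$difficulty_level, lc$mean_cost), 0)
  expect_lt(bh$cost_trend, 0)
})

test_that("null generator yields near-zero costs and condition slopes", {
  p <- synth_params(cost_amplitude = 0, drift_inc = 0, drift_dec = 0,
                    drift_fix = 0, pm_slope_gain = 0,
                    n_participants = 10, n_blocks = 4, seed = 31)
  bh <- pm_cost_pipeline(simulate_cohort(p))
  expect_lt(max(abs(bh$condition_slopes$mean_slope)), 3)
  lc <- aggregate(mean_cost ~ difficulty_level, data = bh$level_costs,
                  FUN = mean)
  expect_lt(max(abs(lc$mean_cost)), 0.06)
  expect_lt(abs(mean(lc$mean_cost)), 0.01)
})
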