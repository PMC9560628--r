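base_policy <- solve_policy(small_sim_cfg())

test_that("degenerate policies produce the expected trial outcomes", {
  # decide everywhere at t = 0: immediate choice, uniform tie-break
  p_stop <- stub_policy(base_policy, gap_value = 1)
  set.seed(1)
  tr <- simulate_trial(p_stop, c(1, 1, 1))
  expect_identical(tr$rt, 0)
  expect_false(tr$censored)
  expect_identical(tr$trajectory_len, 0L)
  expect_true(tr$choice %in% 1:3)

  # never deciding: censored forced choice at the horizon
  p_wait <- stub_policy(base_policy, gap_value = -1)
  set.seed(1)
  tr2 <- simulate_trial(p_wait, c(1, 1, 1))
  expect_identical(tr2$rt, small_sim_cfg()$horizon)
  expect_true(tr2$censored)
})

test_that("batches are seed-reproducible and summarized correctly", {
  set.seed(9)
  s1 <- simulate_batch(base_policy, c(0, 0, 0), 50)
  set.seed(9)
  s2 <- simulate_batch(base_policy, c(0, 0, 0), 50)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$mean_rt, s2$mean_rt)

  expect_equal(sum(s1$choice_freq), 1)
  expect_true(all(s1$trials$rt >= 0))
  expect_true(s1$ci95[1L] <= s1$mean_rt && s1$mean_rt <= s1$ci95[2L])
  expect_equal(s1$mean_rt, mean(s1$trials$rt))

  # n = 1: degenerate interval at the single observation
  set.seed(2)
  s3 <- simulate_batch(base_policy, c(1, 1, 1), 1)
  expect_identical(s3$ci95, c(s3$mean_rt, s3$mean_rt))
  expect_error(simulate_batch(base_policy, c(1, 1, 1), 0), "n must be")
  expect_error(simulate_batch(base_policy, c(1, 1), 10), "length 3")
  expect_error(simulate_batch(base_policy, c(1, 1, 1), 10, sim_dt = 0),
               "sim_dt")
})

test_that("equal-value choices are symmetric across options", {
  set.seed(31)
  s <- simulate_batch(base_policy, c(1, 1, 1), 3000)
  # 99% binomial band around 1/3
  band <- 2.576 * sqrt(1 / 3 * 2 / 3 / 3000)
  expect_true(all(abs(s$choice_freq - 1 / 3) < band))

  # permuting true values permutes choice frequencies (statistically):
  # with unequal values, the best option dominates wherever it is placed
  set.seed(32)
  sA <- simulate_batch(base_policy, c(2.5, 0, 0), 400)
  set.seed(33)
  sB <- simulate_batch(base_policy, c(0, 0, 2.5), 400)
  expect_identical(which.max(sA$choice_freq), 1L)
  expect_identical(which.max(sB$choice_freq), 3L)
  expect_lt(abs(sA$choice_freq[1L] - sB$choice_freq[3L]), 0.1)
  # and the RT distribution is unchanged in distribution
  expect_lt(abs(sA$mean_rt - sB$mean_rt),
            4 * sqrt(sA$se^2 + sB$se^2) + 1e-9)
})

test_that("magnitude sweep produces a decreasing curve under discounting", {
  set.seed(5)
  curve <- magnitude_sweep(small_sim_cfg(), c(-4, -2, 0, 2, 4),
                           n_per_value = 300, policy = base_policy)
  expect_s3_class(curve, "rt_curve")
  expect_identical(nrow(curve), 5L)
  # decisions postponed for low equal-value option sets
  expect_true(all(diff(curve$mean_rt) < 0))
  sl <- magnitude_slope(curve)
  expect_lt(sl, 0)
  expect_lt(sl + 2.576 * attr(sl, "se"), 0)

  # dry run returns the solved policy and no summaries
  dry <- magnitude_sweep(small_sim_cfg(), c(0, 1), n_per_value = 0,
                         policy = base_policy)
  expect_identical(nrow(dry), 0L)
  expect_s3_class(attr(dry, "policy"), "policy_grid")
  expect_error(magnitude_sweep(small_sim_cfg(), c(1, 0), 10,
                               policy = base_policy), "sorted")
})

test_that("magnitude_slope is the OLS slope of mean RT on value", {
  flat <- data.frame(v = c(-1, 0, 1), mean_rt = c(2, 2, 2))
  expect_equal(as.numeric(magnitude_slope(flat)), 0)
  two <- data.frame(v = c(0, 1), mean_rt = c(2, 1))
  expect_equal(as.numeric(magnitude_slope(two)), -1)
  expect_error(magnitude_slope(flat[1L, ]), "2 sweep points")
  # pooled SE from per-point standard errors
  cur <- data.frame(v = c(-1, 0, 1), mean_rt = c(3, 2, 1),
                    se = c(0.1, 0.1, 0.1))
  w <- c(-1, 0, 1) / 2
  expect_equal(attr(magnitude_slope(cur), "se"),
               sqrt(sum(w^2 * 0.01)), tolerance = 1e-12)
})

test_that("censoring is rare for high-value sets under strong discounting", {
  set.seed(77)
  s <- simulate_batch(base_policy, c(3, 3, 3), 300)
  expect_lt(s$censored_frac, 0.01)
  expect_true(all(s$trials$rt <= small_sim_cfg()$horizon))
  # censored implies the horizon was reached
  expect_true(all(s$trials$rt[s$trials$censored] ==
                    small_sim_cfg()$horizon))
})
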