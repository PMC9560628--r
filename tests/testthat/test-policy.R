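test_that("terminal values implement the forced argmax choice", {
  cfg <- tiny_lin_cfg(rho = 0)
  cfg$utility <- utility_linear()
  term <- terminal_values(cfg)
  g <- valuedp:::config_grid(cfg)
  # linear utility: value is the largest coordinate
  i <- which(g == 1.5); j <- which(g == 0); k <- which(g == -1.5)
  expect_equal(term$V[i, j, k], 1.5)
  expect_identical(term$A[i, j, k], 1L)
  expect_identical(term$A[j, i, k], 2L)
  # equal triple: value U(v), tie broken to the lowest index
  expect_equal(term$V[j, j, j], 0)
  expect_identical(term$A[j, j, j], 1L)

  # logistic utility at the example point
  cfg2 <- tiny_geo_cfg()
  cfg2$utility <- utility_logistic(4, 3.5)
  term2 <- terminal_values(cfg2)
  expect_equal(term2$V[which(g == 1.5), which(g == 0), which(g == 0)],
               3.9582392, tolerance = 1e-6)

  # linear regime subtracts rho * t_w at the horizon
  cfg3 <- tiny_lin_cfg(rho = 0.4)
  cfg3$utility <- utility_linear()
  term3 <- terminal_values(cfg3)
  expect_equal(term3$V[i, j, k], 1.5 - 0.4 * 1)
})

test_that("expected continuation is a proper separable smoothing", {
  cfg <- tiny_geo_cfg()
  n <- cfg$grid_n
  # constant field is preserved exactly (kernel renormalization)
  V0 <- array(2.7, rep(n, 3L))
  expect_equal(expected_continuation(V0, 1, cfg), V0, tolerance = 1e-12)
  # zero std is the identity
  set.seed(3)
  V <- array(rnorm(n^3), rep(n, 3L))
  expect_identical(expected_continuation(V, 0, cfg), V)
  expect_error(expected_continuation(V, NaN, cfg), "finite")

  # matches the direct 3-D quadrature oracle at one grid spacing
  g <- valuedp:::config_grid(cfg)
  s <- g[2L] - g[1L]
  expect_equal(expected_continuation(V, s, cfg),
               oracle_continuation(V, g, s), tolerance = 1e-6)
})

test_that("bellman step obeys the two cost regimes", {
  # geometric with continuation annihilated: decide everywhere (the stop
  # value must be strictly positive, hence a positive utility)
  cfg <- tiny_geo_cfg()
  cfg$gamma <- 1e-12
  cfg$utility <- utility_custom(exp, "exp")
  term <- terminal_values(cfg)
  stp <- bellman_step(term$V, 1.0, cfg)
  expect_true(all(stp$A != 0L))
  expect_true(all(stp$gap >= 0))

  # linear regime with free waiting: waiting never hurts
  cfg2 <- tiny_lin_cfg(rho = 0)
  cfg2$c <- 0
  term2 <- terminal_values(cfg2)
  stp2 <- bellman_step(term2$V, 1.0, cfg2)
  expect_true(all(stp2$V >= term2$V - 1e-12))

  # config errors
  cfg3 <- tiny_geo_cfg(); cfg3$gamma <- NULL
  expect_error(bellman_step(term$V, 1.0, cfg3), "gamma")
  cfg4 <- tiny_lin_cfg(); cfg4$rho <- NULL
  expect_error(bellman_step(term2$V, 1.0, cfg4), "rho")
})

test_that("solve_policy matches the plain-loop small-instance oracle", {
  for (cfg in list(tiny_geo_cfg(), tiny_lin_cfg(rho = 0.5))) {
    p <- solve_policy(cfg)
    orc <- oracle_policy_values(cfg)
    expect_equal(p$V[[1L]], orc$V0, tolerance = 1e-6)
    expect_identical(p$A[[1L]] == 0L, orc$wait[[1L]])
  }
})

test_that("solved policies satisfy structural invariants", {
  cfg <- small_sim_cfg()
  p <- solve_policy(cfg)
  nt <- length(p$times)
  # no waiting at the horizon
  expect_true(all(p$A[[nt]] != 0L))
  # V >= stop value, equality exactly on the decide region
  sr <- valuedp:::stop_rewards(cfg, 0)
  expect_true(all(p$V[[1L]] >= sr$maxr - 1e-12))
  decide <- p$A[[1L]] != 0L
  expect_equal(p$V[[1L]][decide], sr$maxr[decide], tolerance = 1e-12)
  expect_true(all(p$V[[1L]][!decide] > sr$maxr[!decide]))
  # V nondecreasing in each coordinate (utility increasing)
  for (a in 1:3) {
    d <- apply(p$V[[1L]], setdiff(1:3, a), diff)
    expect_true(all(d >= -1e-10))
  }
})

test_that("policies are permutation-equivariant", {
  p <- solve_policy(tiny_geo_cfg())
  V <- p$V[[1L]]; A <- p$A[[1L]]
  g <- p$grid
  xs <- as.matrix(expand.grid(g, g, g))
  u <- matrix(evaluate_utility(tiny_geo_cfg()$utility, as.vector(xs)),
              ncol = 3L)
  tied <- apply(u, 1L, function(r) sum(r == max(r)) > 1L)
  # self-inverse label swaps: relabeling options permutes actions and
  # leaves values unchanged (ties excluded: broken to the lowest index)
  for (pr in list(c(2L, 1L, 3L), c(3L, 2L, 1L), c(1L, 3L, 2L))) {
    expect_equal(aperm(V, pr), V, tolerance = 1e-12)
    relabel <- c(0L, pr)[aperm(A, pr) + 1L]
    expect_identical(relabel[!tied], A[!tied])
  }
})

test_that("reward-rate calibration finds the self-consistent fixed point", {
  cfg <- bellman_config(cost_regime = "linear", c = 0, t_w = 1,
                        utility = utility_logistic(4, 0.25),
                        grid_n = 21L, horizon = 2, dt = 0.1)
  rho <- calibrate_reward_rate(cfg)
  expect_gt(rho, 0)
  expect_lt(rho, 4 / 1)  # below max utility / t_w
  cfg$rho <- rho
  p <- solve_policy(cfg)
  resid <- valuedp:::interp_grid(p$V[[1L]], p$grid, matrix(1.5, 1, 3))
  expect_lt(abs(resid), 1e-3)

  # degenerate utility earns nothing: rho* = 0
  cfg0 <- tiny_lin_cfg(rho = NULL)
  cfg0$utility <- utility_custom(function(x) 0 * x, "zero")
  expect_identical(calibrate_reward_rate(cfg0), 0)

  expect_error(calibrate_reward_rate(tiny_geo_cfg()), "linear")
})

test_that("geometric boundaries collapse and are magnitude-sensitive", {
  cfg <- small_sim_cfg(gamma = 0.2, s = 3.5)
  p <- solve_policy(cfg)
  # wait region shrinks along the sweep of v at fixed t
  wf_v <- vapply(c(-2, 0, 1), function(v)
    wait_fraction(project_boundary_slice(p, 0, v)), numeric(1))
  expect_true(all(diff(wf_v) <= 0))
  expect_lt(wf_v[3L], wf_v[1L])
  # and shrinks with t at fixed v (boundary collapse; the horizon slice
  # forces a choice, so the final wait area is zero)
  wf_t <- vapply(c(0, 0.5, 1, 1.5, 2), function(t)
    wait_fraction(project_boundary_slice(p, t, -2)), numeric(1))
  expect_true(all(diff(wf_t) <= 1e-12))
  expect_gt(wf_t[1L], 0)
  expect_identical(wf_t[5L], 0)
})

test_that("boundary slices live on the stated plane with orthonormal axes", {
  p <- solve_policy(tiny_geo_cfg())
  g <- p$grid
  h <- g[2L] - g[1L]
  sl <- project_boundary_slice(p, 0, 1)
  expect_s3_class(sl, "boundary_slice")
  expect_true(all(c("u", "w", "v", "t", "action") %in% names(sl)))
  # planar coordinates must come from grid points: u*sqrt(2) = x1 - x2 and
  # w*sqrt(6) = x1 + x2 - 2*x3 are integer multiples of the spacing
  expect_true(all(abs(sl$u * sqrt(2) / h -
                        round(sl$u * sqrt(2) / h)) < 1e-9))
  expect_true(all(abs(sl$w * sqrt(6) / h -
                        round(sl$w * sqrt(6) / h)) < 1e-9))
  # membership: exactly the grid points within half a spacing of the plane
  pts <- expand.grid(g, g, g)
  expect_identical(nrow(sl),
                   sum(abs(rowSums(pts) - 3 * 1) / sqrt(3) <= h / 2))
  expect_error(project_boundary_slice(p, 0.123, 1), "time slices")
  expect_error(project_boundary_slice(p, 0, 99), "outside the grid")

  # decide-everywhere slice has no wait labels
  p0 <- stub_policy(p, gap_value = 1)
  expect_identical(wait_fraction(project_boundary_slice(p0, 0, 0)), 0)

  # symmetric policy: slice labels invariant under the 3-fold rotation
  sl0 <- project_boundary_slice(p, 0, 0)
  waits <- sl0[sl0$action == "wait", c("u", "w")]
  if (nrow(waits) > 0L) {
    # rotate by 120 degrees in the (u, w) plane: permutes the options
    rot <- cbind(-0.5 * waits$u - sqrt(3) / 2 * waits$w,
                 sqrt(3) / 2 * waits$u - 0.5 * waits$w)
    key <- function(m) paste(round(m[, 1L], 6), round(m[, 2L], 6))
    expect_setequal(key(rot), key(as.matrix(waits)))
  }
})

test_that("two-option configurations solve as a degenerate case", {
  cfg <- bellman_config(n_options = 2L, cost_regime = "geometric",
                        gamma = 0.3, utility = utility_logistic(4, 0.5),
                        grid_n = 9L, dt = 0.25, horizon = 1)
  p <- solve_policy(cfg)
  expect_identical(dim(p$V[[1L]]), c(9L, 9L))
  expect_equal(t(p$V[[1L]]), p$V[[1L]], tolerance = 1e-12)
  expect_true(all(p$A[[length(p$times)]] != 0L))
})

test_that("config validation rejects inconsistent regimes", {
  expect_error(bellman_config(cost_regime = "geometric", gamma = 1.5),
               "gamma")
  expect_error(bellman_config(cost_regime = "geometric"), "gamma")
  expect_error(bellman_config(cost_regime = "linear", gamma = 0.5),
               "geometric")
  expect_error(bellman_config(grid_n = 2L), "grid_n")
  expect_error(bellman_config(grid_lo = 2, grid_hi = -2), "grid_lo")
  expect_error(bellman_config(dt = 0.07, horizon = 1), "multiple")
  expect_error(bellman_config(n_options = 4L), "n_options")
})
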