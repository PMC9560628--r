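# Independent oracles used to freeze expected values: brute-force numerical
# Bayes rule on a fine grid, direct tensor quadrature for the continuation
# expectation, and a plain-loop backward recursion for small policy
# instances. These deliberately share no code with the package internals.

# Discretized Bayes rule for the posterior over the value rate given the
# sufficient statistic sum(evidence) ~ N(x * t, obs_var * t).
oracle_posterior <- function(prior_mean, prior_var, obs_var, t, sum_evidence,
                             n_grid = 40001L, span = 15) {
  sd0 <- sqrt(prior_var)
  x <- seq(prior_mean - span * sd0, prior_mean + span * sd0,
           length.out = n_grid)
  lp <- dnorm(x, prior_mean, sd0, log = TRUE)
  if (t > 0)
    lp <- lp + dnorm(sum_evidence, x * t, sqrt(obs_var * t), log = TRUE)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  m <- sum(w * x)
  list(mean = m, var = sum(w * (x - m)^2))
}

# Direct 3-D quadrature of the continuation expectation with per-axis
# renormalized Gaussian weights (hexuple loop; small grids only).
oracle_continuation <- function(V, grid, s) {
  n <- length(grid)
  W <- outer(grid, grid, function(a, b) dnorm(b - a, sd = s))
  W <- W / rowSums(W)
  out <- array(0, dim(V))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    acc <- 0
    for (a in 1:n) for (b in 1:n) for (cc in 1:n)
      acc <- acc + W[i, a] * W[j, b] * W[k, cc] * V[a, b, cc]
    out[i, j, k] <- acc
  }
  out
}

# Plain-loop backward recursion over the stop/continue tree on a small grid,
# using the joint-quadrature continuation above. Returns the t = 0 value
# array and per-slice stop/wait labels.
oracle_policy_values <- function(cfg) {
  grid <- seq(cfg$grid_lo, cfg$grid_hi, length.out = cfg$grid_n)
  n <- cfg$grid_n
  times <- seq(0, cfg$horizon, by = cfg$dt)
  pv <- function(t) 1 / (1 / cfg$prior_var + t / cfg$obs_var)
  ug <- function(t) {
    if (cfg$utility_mode == "expected")
      expected_utility(cfg$utility, grid, pv(t))
    else
      evaluate_utility(cfg$utility, grid)
  }
  stop_value <- function(t) {
    u <- ug(t)
    S <- array(0, rep(n, 3L))
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      S[i, j, k] <- max(u[i], u[j], u[k])
    if (cfg$cost_regime == "linear") S - cfg$rho * cfg$t_w else S
  }
  V <- stop_value(cfg$horizon)
  A <- vector("list", length(times))
  for (kk in seq(length(times) - 1L, 1L)) {
    t <- times[kk]
    s_t <- sqrt(pv(t) - pv(t + cfg$dt))
    C <- oracle_continuation(V, grid, s_t)
    C <- if (cfg$cost_regime == "linear")
      C - (cfg$c + cfg$rho) * cfg$dt
    else
      C * cfg$gamma^cfg$dt
    S <- stop_value(t)
    V <- pmax(S, C)
    A[[kk]] <- C > S  # TRUE = wait
  }
  list(V0 = V, wait = A)
}

# Small, fast configurations reused across tests.
tiny_geo_cfg <- function(...) {
  bellman_config(cost_regime = "geometric", gamma = 0.3,
                 utility = utility_logistic(4, 0.5),
                 grid_n = 5L, grid_lo = -3, grid_hi = 3,
                 dt = 0.5, horizon = 1.5, ...)
}

tiny_lin_cfg <- function(rho = 0.5, ...) {
  bellman_config(cost_regime = "linear", c = 0.1, rho = rho, t_w = 1,
                 utility = utility_logistic(4, 0.5),
                 grid_n = 5L, grid_lo = -3, grid_hi = 3,
                 dt = 0.5, horizon = 1.5, ...)
}

# Moderate grid for simulation-based tests: solving stays under a second.
small_sim_cfg <- function(gamma = 0.1, s = 0.5, ...) {
  bellman_config(cost_regime = "geometric", gamma = gamma,
                 utility = utility_logistic(4, s),
                 grid_n = 21L, horizon = 2, dt = 0.05, ...)
}

# Hand-built policy stubs for the simulator contract tests.
stub_policy <- function(base, gap_value) {
  stopifnot(inherits(base, "policy_grid"))
  for (k in seq_along(base$gap)) {
    base$gap[[k]] <- array(gap_value, dim(base$gap[[k]]))
    base$A[[k]] <- array(if (gap_value >= 0) 1L else 0L,
                         dim(base$A[[k]]))
  }
  base
}
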