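# Backward-induction dynamic programming on a grid of posterior-mean
# estimates, for linear (Bayes-Risk) and geometric time costs.
#
# State: the vector of posterior means, one per option, on a regular grid.
# Under the conjugate belief the posterior mean evolves as a martingale with
# one-step std transition_std(t, dt), independently per option, so the
# expectation over next estimates is a separable Gaussian smoothing whose
# kernel mass is renormalized at grid edges.

#' Dynamic-programming configuration
#'
#' Collects every input of the backward induction: the cost regime, the
#' utility function, the belief parameters, and the estimate-space grid.
#'
#' Two cost regimes are supported. In the `"linear"` (Bayes-Risk) regime the
#' Bellman recursion is
#' \deqn{V(t, \hat{x}) = \max\{\max_i r_i(\hat{x}) - \rho t_w,\;
#'       \langle V(t+\delta t)\rangle - (c + \rho)\,\delta t\},}
#' with linear time cost `c`, reward rate `rho` (calibrated to the
#' self-consistent fixed point when not supplied) and inter-trial wait `t_w`.
#' In the `"geometric"` regime future reward is discounted multiplicatively:
#' \deqn{V(t, \hat{x}) = \max\{\max_i r_i(\hat{x}),\;
#'       \langle V(t+\delta t)\rangle\, \gamma^{\delta t}\},}
#' with per-unit-time discount factor `0 < gamma < 1`.
#'
#' @param n_options Number of options (2 or 3; default 3).
#' @param cost_regime `"linear"` or `"geometric"`.
#' @param c Linear cost per unit time (linear regime; default 0).
#' @param rho Reward rate per unit time (linear regime). `NULL` requests
#'   calibration by [calibrate_reward_rate()] when the policy is solved.
#' @param t_w Inter-trial waiting time (linear regime; default 1).
#' @param gamma Per-unit-time discount factor in (0, 1) (geometric regime).
#' @param dt Dynamic-programming time step (default 0.05).
#' @param horizon Decision horizon; must be an integer multiple of `dt`
#'   (default 3). The transition std plateaus in `t`, so results are
#'   insensitive to the horizon beyond roughly 2 time units for the default
#'   belief parameters.
#' @param grid_lo,grid_hi Estimate-space bounds per axis (defaults -5, 5).
#' @param grid_n Grid points per axis (>= 3; default 41).
#' @param utility A [utility_fn][utility_logistic] (default linear).
#' @param prior_mean,prior_var,obs_var Belief parameters (defaults 1.5, 5, 2).
#' @param utility_mode `"point"` applies the utility to the posterior mean
#'   estimate (default); `"expected"` uses the expected utility under the
#'   full Gaussian posterior at each time slice.
#' @return An object of class `bellman_config`.
#' @examples
#' cfg <- bellman_config(cost_regime = "geometric", gamma = 0.1,
#'                       utility = utility_logistic(4, 3.5), grid_n = 15)
#' @export
bellman_config <- function(n_options = 3L,
                           cost_regime = c("linear", "geometric"),
                           c = 0, rho = NULL, t_w = 1,
                           gamma = NULL,
                           dt = 0.05, horizon = 3,
                           grid_lo = -5, grid_hi = 5, grid_n = 41L,
                           utility = utility_linear(),
                           prior_mean = 1.5, prior_var = 5, obs_var = 2,
                           utility_mode = c("point", "expected")) {
  cost_regime <- match.arg(cost_regime)
  utility_mode <- match.arg(utility_mode)
  n_options <- as.integer(n_options)
  if (!n_options %in% c(2L, 3L))
    stop("n_options must be 2 or 3", call. = FALSE)
  if (!inherits(utility, "utility_fn"))
    stop("utility must be a utility_fn", call. = FALSE)
  if (grid_lo >= grid_hi) stop("grid_lo must be < grid_hi", call. = FALSE)
  grid_n <- as.integer(grid_n)
  if (grid_n < 3L) stop("grid_n must be >= 3", call. = FALSE)
  if (dt <= 0 || horizon <= 0) stop("dt and horizon must be > 0", call. = FALSE)
  n_steps <- horizon / dt
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stop("horizon must be an integer multiple of dt", call. = FALSE)
  if (cost_regime == "geometric") {
    if (is.null(gamma) || !is.numeric(gamma) || length(gamma) != 1L ||
        gamma <= 0 || gamma >= 1)
      stop("geometric regime requires gamma in (0, 1)", call. = FALSE)
  } else {
    if (!is.null(gamma))
      stop("gamma is only valid in the geometric regime", call. = FALSE)
    if (c < 0) stop("c must be >= 0", call. = FALSE)
    if (t_w < 0) stop("t_w must be >= 0", call. = FALSE)
    if (!is.null(rho) && (!is.numeric(rho) || rho < 0))
      stop("rho must be NULL or >= 0", call. = FALSE)
  }
  # belief validation delegated to the constructor
  gaussian_belief(prior_mean, prior_var, obs_var)
  structure(list(n_options = n_options, cost_regime = cost_regime,
                 c = c, rho = rho, t_w = t_w, gamma = gamma,
                 dt = dt, horizon = horizon,
                 grid_lo = grid_lo, grid_hi = grid_hi, grid_n = grid_n,
                 utility = utility,
                 prior_mean = prior_mean, prior_var = prior_var,
                 obs_var = obs_var, utility_mode = utility_mode),
            class = "bellman_config")
}

#' @export
print.bellman_config <- function(x, ...) {
  cat(sprintf("bellman config: %d options, %s time cost\n",
              x$n_options, x$cost_regime))
  if (x$cost_regime == "linear")
    cat(sprintf("  c = %g, rho = %s, t_w = %g\n", x$c,
                if (is.null(x$rho)) "(to calibrate)" else format(x$rho), x$t_w))
  else
    cat(sprintf("  gamma = %g\n", x$gamma))
  cat(sprintf("  grid [%g, %g] x %d per axis; dt = %g, horizon = %g\n",
              x$grid_lo, x$grid_hi, x$grid_n, x$dt, x$horizon))
  print(x$utility)
  cat(sprintf("  belief: prior N(%g, %g), obs_var %g; reward mode: %s\n",
              x$prior_mean, x$prior_var, x$obs_var, x$utility_mode))
  invisible(x)
}

config_grid <- function(cfg) {
  seq(cfg$grid_lo, cfg$grid_hi, length.out = cfg$grid_n)
}

config_belief <- function(cfg, t = 0) {
  gaussian_belief(cfg$prior_mean, cfg$prior_var, cfg$obs_var, t = t)
}

# Per-axis utility values at time t (time enters only in "expected" mode).
axis_rewards <- function(cfg, t) {
  g <- config_grid(cfg)
  if (cfg$utility_mode == "expected")
    expected_utility(cfg$utility, g, posterior_var(config_belief(cfg, t)))
  else
    evaluate_utility(cfg$utility, g)
}

# Stop values max_i r_i and argmax option (lowest index on ties) as d-dim
# arrays on the grid.
stop_rewards <- function(cfg, t) {
  ug <- axis_rewards(cfg, t)
  n <- cfg$grid_n
  d <- cfg$n_options
  dims <- rep(n, d)
  axes <- lapply(seq_len(d), function(a)
    array(rep(ug, each = n^(a - 1L)), dims))
  maxr <- Reduce(pmax, axes)
  arg <- array(1L, dims)
  for (a in seq(2L, d)) {
    better <- axes[[a]] > Reduce(pmax, axes[seq_len(a - 1L)])
    arg[better] <- a
  }
  list(maxr = maxr, argmax = arg)
}

#' Terminal values of the backward induction
#'
#' Seeds the recursion at the horizon with a forced choice: the value is the
#' best immediate reward (minus `rho * t_w` in the linear regime) and the
#' action is the corresponding option.
#'
#' @param cfg A [bellman_config()] (with `rho` resolved in the linear regime).
#' @return A list with d-dimensional arrays `V` (values) and `A` (actions:
#'   integer option index; 0 codes "wait" and never occurs here).
#' @export
terminal_values <- function(cfg) {
  sr <- stop_rewards(cfg, cfg$horizon)
  V <- sr$maxr
  if (cfg$cost_regime == "linear") {
    rho <- cfg$rho
    if (is.null(rho)) stop("rho must be supplied or calibrated", call. = FALSE)
    V <- V - rho * cfg$t_w
  }
  list(V = V, A = sr$argmax)
}

# Row-stochastic transition kernel along one axis for std s; rows are
# renormalized so no probability mass leaks at grid edges.
transition_kernel <- function(grid, s) {
  h <- grid[2L] - grid[1L]
  if (s < 1e-9 * h) return(NULL)  # identity
  K <- outer(grid, grid, function(a, b) stats::dnorm(b - a, sd = s))
  K / rowSums(K)
}

apply_axis <- function(V, K, axis) {
  d <- dim(V)
  if (axis > 1L) {
    perm <- seq_along(d)
    perm[c(1L, axis)] <- c(axis, 1L)
    V <- aperm(V, perm)
    d <- dim(V)
  }
  V <- array(K %*% matrix(V, d[1L], prod(d[-1L])), d)
  if (axis > 1L) V <- aperm(V, perm)
  V
}

#' Expectation of the next-slice value function
#'
#' Computes \eqn{\langle V(t + \delta t, \hat{x}(t+\delta t)) \rangle} by
#' separable Gaussian smoothing of the next slice along each option axis with
#' the transition std `s_t`; options carry independent evidence streams, so
#' the kernel factorizes. Edge rows are renormalized to unit mass.
#'
#' @param V_next Value array from slice `t + dt`.
#' @param s_t Transition standard deviation (>= 0, finite).
#' @param cfg The [bellman_config()].
#' @return Array of the same shape as `V_next`.
#' @export
expected_continuation <- function(V_next, s_t, cfg) {
  if (!is.numeric(s_t) || length(s_t) != 1L || !is.finite(s_t) || s_t < 0)
    stop("s_t must be finite and >= 0", call. = FALSE)
  K <- transition_kernel(config_grid(cfg), s_t)
  if (is.null(K)) return(V_next)
  for (a in seq_len(cfg$n_options)) V_next <- apply_axis(V_next, K, a)
  V_next
}

#' One backward Bellman step
#'
#' Given the value function at slice `t + dt`, computes values, actions and
#' the signed stop-continue gap at slice `t` under the configured cost
#' regime.
#'
#' @param V_next Value array from slice `t + dt`.
#' @param t Time of the slice being computed.
#' @param cfg The [bellman_config()] (with `rho` resolved if linear).
#' @return A list with arrays `V` (slice values), `A` (actions; 0 = wait,
#'   i = choose option i) and `gap` (stop value minus continuation value;
#'   >= 0 exactly on the decide region).
#' @export
bellman_step <- function(V_next, t, cfg) {
  s_t <- transition_std(config_belief(cfg, t), cfg$dt)
  C <- expected_continuation(V_next, s_t, cfg)
  if (cfg$cost_regime == "linear") {
    rho <- cfg$rho
    if (is.null(rho))
      stop("linear regime requires rho (supply or calibrate)", call. = FALSE)
    C <- C - (cfg$c + rho) * cfg$dt
    sr <- stop_rewards(cfg, t)
    S <- sr$maxr - rho * cfg$t_w
  } else {
    if (is.null(cfg$gamma))
      stop("geometric regime requires gamma", call. = FALSE)
    C <- C * cfg$gamma^cfg$dt
    sr <- stop_rewards(cfg, t)
    S <- sr$maxr
  }
  V <- pmax(S, C)
  A <- sr$argmax
  A[C > S] <- 0L
  list(V = V, A = A, gap = S - C)
}

#' Solve the optimal policy by backward induction
#'
#' Runs the full recursion from the horizon back to t = 0 and returns every
#' time slice. In the linear regime with `rho = NULL` the reward rate is
#' first calibrated with [calibrate_reward_rate()].
#'
#' @param cfg A [bellman_config()].
#' @param verbose Print progress (grid size, calibrated rho).
#' @return An object of class `policy_grid`: list with `times` (ascending),
#'   `V`, `A`, `gap` (lists of arrays, one per slice), `grid` (axis
#'   coordinates) and the resolved `config`.
#' @examples
#' cfg <- bellman_config(cost_regime = "geometric", gamma = 0.2,
#'                       utility = utility_logistic(4, 3.5),
#'                       grid_n = 11, horizon = 1, dt = 0.1)
#' p <- solve_policy(cfg)
#' @export
solve_policy <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "bellman_config"))
  if (cfg$cost_regime == "linear" && is.null(cfg$rho)) {
    cfg$rho <- calibrate_reward_rate(cfg)
    if (verbose)
      message(sprintf("calibrated reward rate rho = %.6g", cfg$rho))
  }
  sol <- backward_induction(cfg, store = TRUE)
  if (verbose)
    message(sprintf("solved %d slices on a %d^%d grid",
                    length(sol$times), cfg$grid_n, cfg$n_options))
  sol
}

backward_induction <- function(cfg, store = TRUE) {
  times <- seq(0, cfg$horizon, by = cfg$dt)
  nt <- length(times)
  term <- terminal_values(cfg)
  if (store) {
    Vs <- vector("list", nt); As <- vector("list", nt)
    gaps <- vector("list", nt)
    Vs[[nt]] <- term$V; As[[nt]] <- term$A
    gaps[[nt]] <- array(1, dim(term$V))  # forced stop at the horizon
  }
  V <- term$V
  for (k in seq(nt - 1L, 1L)) {
    step <- bellman_step(V, times[k], cfg)
    if (any(!is.finite(step$V)))
      stop(sprintf("non-finite values in backward induction at t = %g",
                   times[k]), call. = FALSE)
    V <- step$V
    if (store) {
      Vs[[k]] <- step$V; As[[k]] <- step$A; gaps[[k]] <- step$gap
    }
  }
  if (!store)
    return(V)
  structure(list(times = times, V = Vs, A = As, gap = gaps,
                 grid = config_grid(cfg), config = cfg),
            class = "policy_grid")
}

#' @export
print.policy_grid <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("policy grid: %d slices (t in [0, %g], dt = %g), %d^%d points\n",
              length(x$times), cfg$horizon, cfg$dt, cfg$grid_n,
              cfg$n_options))
  cat(sprintf("  regime: %s%s\n", cfg$cost_regime,
              if (cfg$cost_regime == "linear")
                sprintf(" (c = %g, rho = %g, t_w = %g)", cfg$c, cfg$rho,
                        cfg$t_w)
              else sprintf(" (gamma = %g)", cfg$gamma)))
  wait0 <- mean(x$A[[1L]] == 0L)
  cat(sprintf("  wait fraction at t = 0: %.3f\n", wait0))
  invisible(x)
}

# Multilinear interpolation of a d-dim grid array at points (rows of pts).
interp_grid <- function(arr, grid, pts) {
  n <- length(grid)
  h <- grid[2L] - grid[1L]
  d <- length(dim(arr))
  pts <- pmin(pmax(pts, grid[1L]), grid[n])
  i0 <- pmin(pmax(floor((pts - grid[1L]) / h) + 1L, 1L), n - 1L)
  fr <- (pts - grid[i0]) / h
  fr <- pmin(pmax(fr, 0), 1)
  out <- numeric(nrow(pts))
  corners <- as.matrix(expand.grid(rep(list(0:1), d)))
  stride <- n^(seq_len(d) - 1L)
  for (r in seq_len(nrow(corners))) {
    idx <- i0 + matrix(corners[r, ], nrow(pts), d, byrow = TRUE)
    w <- rep(1, nrow(pts))
    for (a in seq_len(d))
      w <- w * if (corners[r, a] == 1L) fr[, a] else 1 - fr[, a]
    lin <- 1 + (idx - 1L) %*% stride
    out <- out + w * arr[lin]
  }
  out
}

#' Calibrate the reward rate of the linear (Bayes-Risk) regime
#'
#' Finds the self-consistent reward rate: the `rho` at which the value of
#' the decision problem at its starting state — t = 0, all posterior means at
#' the prior mean — is zero, so that on average each trial earns exactly
#' `rho` per unit of (decision + waiting) time. Solved by bisection of
#' `V_rho(0, prior point)` on the bracket `(1e-6, max U / t_w)`.
#'
#' @param cfg A [bellman_config()] with `cost_regime = "linear"`.
#' @param tol Residual tolerance on `|V(0, prior point)|` (default 1e-3).
#' @param max_iter Bisection iteration cap.
#' @return The calibrated reward rate `rho*`.
#' @export
calibrate_reward_rate <- function(cfg, tol = 1e-3, max_iter = 100L) {
  stopifnot(inherits(cfg, "bellman_config"))
  if (cfg$cost_regime != "linear")
    stop("reward-rate calibration applies to the linear regime only",
         call. = FALSE)
  grid <- config_grid(cfg)
  u_max <- max(axis_rewards(cfg, 0))
  if (u_max <= tol * 1e-3) return(0)  # degenerate utility: nothing to earn
  prior_pt <- matrix(cfg$prior_mean, 1L, cfg$n_options)
  value_at_prior <- function(rho) {
    cfg$rho <- rho
    V0 <- backward_induction(cfg, store = FALSE)
    interp_grid(V0, grid, prior_pt)
  }
  lo <- 1e-6
  hi <- u_max / max(cfg$t_w, cfg$dt)
  f_lo <- value_at_prior(lo)
  f_hi <- value_at_prior(hi)
  if (f_lo < 0 || f_hi > 0)
    stop(sprintf(
      "reward-rate bracket has no sign change: V(rho=%g) = %g, V(rho=%g) = %g",
      lo, f_lo, hi, f_hi), call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- value_at_prior(mid)
    if (abs(f_mid) < tol) return(mid)
    if (f_mid > 0) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "reward-rate calibration did not converge: bracket [%g, %g]", lo, hi),
    call. = FALSE)
}

#' Project a policy slice onto the plane orthogonal to the equal-value line
#'
#' Extracts the grid points lying within half a grid spacing of the plane
#' \eqn{\hat{x}_1 + \hat{x}_2 + \hat{x}_3 = 3v} at policy time `t` and maps
#' them to planar coordinates via the orthonormal basis
#' \eqn{u = (1,-1,0)/\sqrt{2}}, \eqn{w = (1,1,-2)/\sqrt{6}}. These are the
#' triangular boundary sections conventionally drawn along the equal-value
#' diagonal.
#'
#' @param p A `policy_grid` with 3 options.
#' @param t A time among the policy slices.
#' @param v Common value of the slice plane.
#' @return A `data.frame` of class `boundary_slice` with columns `u`, `w`,
#'   `v`, `t` and `action` (`"wait"` or `"choose_i"`).
#' @export
project_boundary_slice <- function(p, t, v) {
  stopifnot(inherits(p, "policy_grid"))
  if (p$config$n_options != 3L)
    stop("boundary projection is defined for 3 options", call. = FALSE)
  k <- which.min(abs(p$times - t))
  if (abs(p$times[k] - t) > 1e-8 + 1e-8 * abs(t))
    stop(sprintf("t = %g is not among the policy time slices", t),
         call. = FALSE)
  g <- p$grid
  h <- g[2L] - g[1L]
  if (3 * v < 3 * g[1L] - sqrt(3) * h / 2 ||
      3 * v > 3 * g[length(g)] + sqrt(3) * h / 2)
    stop(sprintf("plane v = %g lies outside the grid support", v),
         call. = FALSE)
  pts <- expand.grid(x1 = g, x2 = g, x3 = g)
  dist <- abs(pts$x1 + pts$x2 + pts$x3 - 3 * v) / sqrt(3)
  keep <- dist <= h / 2
  if (!any(keep))
    stop(sprintf("plane v = %g intersects no grid points", v), call. = FALSE)
  pts <- pts[keep, , drop = FALSE]
  a <- as.vector(p$A[[k]])[keep]
  out <- data.frame(
    u = (pts$x1 - pts$x2) / sqrt(2),
    w = (pts$x1 + pts$x2 - 2 * pts$x3) / sqrt(6),
    v = v, t = p$times[k],
    action = ifelse(a == 0L, "wait", paste0("choose_", a)),
    stringsAsFactors = FALSE)
  class(out) <- c("boundary_slice", "data.frame")
  out
}

#' Fraction of a boundary slice occupied by the "wait" region
#'
#' @param slice A [project_boundary_slice()] result.
#' @return Fraction in `[0, 1]`.
#' @export
wait_fraction <- function(slice) {
  stopifnot(inherits(slice, "boundary_slice"))
  mean(slice$action == "wait")
}

#' @export
plot.boundary_slice <- function(x, ...) {
  cols <- c(wait = "grey70", choose_1 = "#D55E00", choose_2 = "#0072B2",
            choose_3 = "#009E73")
  plot(x$u, x$w, col = cols[x$action], pch = 15, asp = 1,
       xlab = "u = (x1 - x2)/sqrt(2)", ylab = "w = (x1 + x2 - 2 x3)/sqrt(6)",
       main = sprintf("t = %g, v = %g", x$t[1L], x$v[1L]), ...)
  legend("topright", legend = names(cols), col = cols, pch = 15, bty = "n",
         cex = 0.8)
  invisible(x)
}
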