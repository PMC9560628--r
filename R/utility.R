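# Subjective utility functions mapping raw option value to reward.

#' Subjective utility functions
#'
#' Constructors for the utility families used throughout the package. The
#' logistic family
#' \deqn{U(x) = m \left( \frac{2}{1 + e^{-sx}} - 1 \right)}
#' spans near-linear shapes (small `s`, where \eqn{U(x) \approx (ms/2)\,x})
#' to near-stepwise shapes (large `s`, where \eqn{U(x) \to m\,\mathrm{sign}(x)}).
#' The linear family is the identity \eqn{U(x) = x}. `utility_custom()`
#' wraps an arbitrary increasing function, mainly for degenerate test modes.
#'
#' @param m Utility half-range: logistic output lies strictly inside
#'   (-m, m). Must be positive.
#' @param s Slope parameter (per value unit). Must be strictly positive;
#'   `s = 0` is rejected rather than silently treated as linear.
#' @param fn A vectorized function of one numeric argument.
#' @param label Short label for printing a custom utility.
#' @return An object of class `utility_fn`.
#' @examples
#' u <- utility_logistic(m = 4, s = 3.5)
#' evaluate_utility(u, c(-1.5, 0, 1.5))
#' @seealso [evaluate_utility()], [shape_profile()]
#' @export
utility_logistic <- function(m, s) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("logistic utility requires a single finite m > 0", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("logistic utility requires a single finite s > 0", call. = FALSE)
  structure(list(family = "logistic", m = m, s = s), class = "utility_fn")
}

#' @rdname utility_logistic
#' @export
utility_linear <- function() {
  structure(list(family = "linear"), class = "utility_fn")
}

#' @rdname utility_logistic
#' @export
utility_custom <- function(fn, label = "custom") {
  stopifnot(is.function(fn))
  structure(list(family = "custom", fn = fn, label = label),
            class = "utility_fn")
}

#' Evaluate a utility function
#'
#' Applies a utility function elementwise to raw values.
#'
#' @param u A `utility_fn` object.
#' @param x Numeric vector of raw values; must be finite.
#' @return Numeric vector of subjective utilities, same length as `x`.
#' @export
evaluate_utility <- function(u, x) {
  stopifnot(inherits(u, "utility_fn"))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("x must be finite numeric", call. = FALSE)
  switch(u$family,
    linear   = x,
    logistic = u$m * (2 / (1 + exp(-u$s * x)) - 1),
    custom   = u$fn(x),
    stop("unknown utility family: ", u$family, call. = FALSE)
  )
}

#' Expected utility under a Gaussian posterior
#'
#' Computes \eqn{E[U(X)]} for \eqn{X \sim N(\mu, \sigma^2)} by Gauss-Hermite
#' quadrature. This is the optional "expected" reward mode of the dynamic
#' program; the default mode applies `u` directly to the posterior mean.
#'
#' @param u A `utility_fn`.
#' @param mean Numeric vector of posterior means.
#' @param var Posterior variance (scalar, >= 0).
#' @param nodes Number of Gauss-Hermite nodes.
#' @return Numeric vector of expected utilities.
#' @export
expected_utility <- function(u, mean, var, nodes = 31L) {
  stopifnot(inherits(u, "utility_fn"), is.numeric(var), length(var) == 1L,
            var >= 0)
  if (var == 0) return(evaluate_utility(u, mean))
  gh <- gauss_hermite(nodes)
  sd <- sqrt(var)
  out <- numeric(length(mean))
  for (k in seq_along(gh$nodes))
    out <- out + gh$weights[k] * evaluate_utility(u, mean + sd * gh$nodes[k])
  out
}

# Probabilists' Gauss-Hermite rule (weights sum to 1, nodes in standard
# normal scale) via Golub-Welsch on the Jacobi matrix.
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1L))
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1L, ]^2)
}

#' Tabulate a utility profile
#'
#' Evaluates a utility function on a grid of raw values, for diagnostics of
#' the shape spanned between near-linear and near-stepwise regimes.
#'
#' @param u A `utility_fn`.
#' @param xs Nonempty, sorted numeric grid.
#' @return A `data.frame` with columns `x` and `utility`.
#' @export
shape_profile <- function(u, xs) {
  if (length(xs) == 0L) stop("xs must be nonempty", call. = FALSE)
  if (is.unsorted(xs)) stop("xs must be sorted increasing", call. = FALSE)
  data.frame(x = xs, utility = evaluate_utility(u, xs))
}

#' @export
print.utility_fn <- function(x, ...) {
  switch(x$family,
    linear   = cat("utility: linear (identity)\n"),
    logistic = cat(sprintf("utility: logistic, m = %g, s = %g\n", x$m, x$s)),
    cat(sprintf("utility: %s\n", x$label %||% x$family))
  )
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
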