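#' Fast-manifold equilibrium of the local pair frequency
#'
#' Under weak selection the local (pair) frequencies equilibrate much faster
#' than the global frequency. Ignoring selection-dependent terms, the
#' conditional neighbor frequency `q_A|A` relaxes to
#' `p_A + (1 - p_A) / (k - 1)`: a resident type is over-represented among its
#' own neighbors by the local assortment excess `1/(k-1)` that the
#' death-birth update builds up. In the well-mixed limit `k -> Inf` this
#' reduces to `p_A`.
#'
#' @param p_A global type-A frequency in `[0, 1]` (vectorized).
#' @param k vertex degree (>= 2).
#' @return `q_A|A` values in `[1/(k-1), 1]`.
#' @export
qAA_fast_equilibrium <- function(p_A, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop("degree k must be an integer >= 2")
  if (any(p_A < 0 | p_A > 1)) stop("p_A must lie in [0, 1]")
  p_A + (1 - p_A) / (k - 1)
}

#' Slow-manifold rate of change of the global type-A frequency
#'
#' Returns `rate_scale * omega * p (1 - p) * g(p)` with
#' `g(p) = c0 + c1 p + c2 p^2` from [stability_coefficients()]. The overall
#' positive prefactor of the slow manifold is not determined by the sign
#' analysis, so `rate_scale` sets an arbitrary timescale (default 1);
#' equilibria, signs and stability are unaffected by it. The rate vanishes
#' identically at `p = 0` and `p = 1`.
#'
#' @param p_A global type-A frequency (vectorized).
#' @param payoff an [interaction_matrix()] (or equivalent).
#' @param k vertex degree.
#' @param omega selection intensity.
#' @param rate_scale positive timescale constant.
#' @return Rate values (same length as `p_A`).
#' @export
pA_rate <- function(p_A, payoff, k, omega = 0.01, rate_scale = 1) {
  if (rate_scale <= 0) stop("rate_scale must be positive")
  co <- stability_coefficients(payoff, k)
  rate_scale * omega * p_A * (1 - p_A) * sign_polynomial(p_A, co)
}

#' Integrate the slow-manifold dynamics
#'
#' Solves `dp/dt = pA_rate(p)` with the local frequency `q_A|A` slaved to its
#' fast equilibrium, using an explicit adaptive Runge-Kutta pair (relative
#' tolerance 1e-8). Excursions of `p` outside `[0, 1]` at machine-epsilon
#' scale are clipped.
#'
#' @param payoff an [interaction_matrix()] (or equivalent).
#' @param k vertex degree (k = 2 is supported as the degenerate linear case).
#' @param omega selection intensity.
#' @param p0 initial global type-A frequency in `[0, 1]`.
#' @param t_max integration horizon (arbitrary slow-manifold time units).
#' @param n_out number of output points (default 201).
#' @param rate_scale positive timescale constant (see [pA_rate()]).
#' @return An `ee_ode` data frame with columns `t`, `p_A`, `q_A_given_A`.
#' @export
integrate_pair_approx <- function(payoff, k, omega = 0.01, p0, t_max,
                                  n_out = 201, rate_scale = 1) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 < 0 || p0 > 1)
    stop("p0 must lie in [0, 1]")
  if (t_max <= 0) stop("t_max must be positive")
  co <- stability_coefficients(payoff, k)
  deriv <- function(t, y, parms) {
    p <- min(max(y[1], 0), 1)
    list(rate_scale * omega * p * (1 - p) * sign_polynomial(p, co))
  }
  times <- seq(0, t_max, length.out = n_out)
  sol <- deSolve::ode(y = c(p = p0), times = times, func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = 1e-8, atol = 1e-10)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; see deSolve diagnostics")
  p <- pmin(pmax(sol[, "p"], 0), 1)
  structure(data.frame(t = sol[, "time"], p_A = p,
                       q_A_given_A = qAA_fast_equilibrium(p, k)),
            class = c("ee_ode", "data.frame"),
            config = list(payoff = as_payoff(payoff), k = k, omega = omega,
                          p0 = p0, t_max = t_max, rate_scale = rate_scale))
}

#' Long-time limit of the slow-manifold dynamics
#'
#' Integrates with an internally normalized timescale until the trajectory is
#' stationary, and returns the final value of `p_A`. Used to cross-check the
#' analytic classifier against the numerical integrator.
#'
#' @inheritParams integrate_pair_approx
#' @param tol stationarity tolerance on the rate (default 1e-10).
#' @return The limiting value of `p_A`.
#' @export
ode_limit <- function(payoff, k, omega = 0.01, p0, tol = 1e-10) {
  co <- stability_coefficients(payoff, k)
  scale <- max(abs(co))
  if (scale == 0 || omega == 0) return(p0)  # neutral: no deterministic motion
  rs <- 1 / (omega * scale)                 # normalize the timescale
  p <- p0
  t_max <- 50
  for (i in 1:12) {
    sol <- integrate_pair_approx(payoff, k, omega, p, t_max,
                                 n_out = 11, rate_scale = rs)
    p_new <- sol$p_A[nrow(sol)]
    rate <- omega * p_new * (1 - p_new) * sign_polynomial(p_new, co) * rs
    if (abs(rate) < tol && abs(p_new - p) < 1e-8) return(p_new)
    p <- p_new
    t_max <- t_max * 2
  }
  p
}

#' Phase line of the slow dynamics
#'
#' Samples the slow-manifold rate on a uniform grid over `[0, 1]` and
#' annotates the analytic equilibria from [stability_equilibria()].
#'
#' @inheritParams pA_rate
#' @param n_grid number of grid points (>= 3).
#' @return A `phase_line` data frame with columns `p`, `rate`; the analytic
#'   equilibria (with stability labels) are attached as attribute `roots`.
#' @export
phase_line <- function(payoff, k, omega = 0.01, n_grid = 201, rate_scale = 1) {
  if (n_grid < 3) stop("n_grid must be >= 3")
  p <- seq(0, 1, length.out = n_grid)
  structure(data.frame(p = p,
                       rate = pA_rate(p, payoff, k, omega, rate_scale)),
            class = c("phase_line", "data.frame"),
            roots = stability_equilibria(payoff, k),
            config = list(payoff = as_payoff(payoff), k = k, omega = omega,
                          rate_scale = rate_scale))
}
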