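#' Exit-entry competition model of two cell populations
#'
#' The central constructor. Bundles the interaction matrix, network degree,
#' selection intensity, population size and initial composition into a model
#' object, validates the configuration, and attaches the analytic stability
#' classification. Methods: [print.exit_entry_model()], `summary`, `coef`
#' (the sign-polynomial coefficients), `predict` (the limiting type-A
#' frequency, optionally for new starting frequencies), `plot` (the phase
#' line with equilibria) and `simulate` (stochastic trajectories of the
#' agent-based process).
#'
#' @param payoff an [interaction_matrix()], 2x2 matrix, or length-4 numeric
#'   `(a, b, c, d)`.
#' @param k vertex degree (default 4).
#' @param omega selection intensity in `[0, 1)` (default 0.01, weak
#'   selection).
#' @param p0 initial type-A frequency (default 0.99).
#' @param N population size for simulation (default 10000).
#' @param topology network topology for simulation (see [regular_network()]).
#' @param count_vacated_link payoff-tally convention (see [neighbor_tally()]).
#' @return An object of class `exit_entry_model`.
#' @examples
#' m <- exit_entry_model(interaction_matrix(0, 1, 1, 0), k = 4, p0 = 0.99)
#' coef(m)
#' predict(m)
#' @export
exit_entry_model <- function(payoff, k = 4, omega = 0.01, p0 = 0.99,
                             N = 10000, topology = "random-regular",
                             count_vacated_link = TRUE) {
  payoff <- do.call(interaction_matrix, as_payoff(payoff))
  validate_selection(payoff, k, omega)
  if (!is.numeric(p0) || p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (round(N * p0) != N * p0)
    p0 <- round(N * p0) / N  # align to an integer initial count
  structure(list(payoff = payoff, k = as.integer(k), omega = omega,
                 p0 = p0, N = as.integer(N), topology = topology,
                 count_vacated_link = count_vacated_link,
                 report = classify_dynamics(payoff, k, p0)),
            class = "exit_entry_model")
}

#' @export
print.exit_entry_model <- function(x, ...) {
  cat("Exit-entry competition model\n")
  cat(sprintf("  payoff [%g %g; %g %g], k = %d, omega = %g\n",
              x$payoff[1, 1], x$payoff[1, 2], x$payoff[2, 1], x$payoff[2, 2],
              x$k, x$omega))
  cat(sprintf("  N = %d, p0 = %g, topology = %s\n", x$N, x$p0, x$topology))
  cat(sprintf("  classification: %s; predicted limit of P_A: %s\n",
              x$report$case_label,
              if (is.na(x$report$predicted_limit)) "undecided"
              else format(x$report$predicted_limit, digits = 6)))
  invisible(x)
}

#' @export
summary.exit_entry_model <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$report)
  invisible(object$report)
}

#' @export
coef.exit_entry_model <- function(object, ...) object$report$coefficients

#' Predicted limiting type-A frequency
#'
#' @param object an [exit_entry_model()].
#' @param p0 optional vector of starting frequencies; defaults to the model's.
#' @param ... unused.
#' @return Numeric vector of predicted limits (NA where undecided).
#' @export
predict.exit_entry_model <- function(object, p0 = NULL, ...) {
  if (is.null(p0)) p0 <- object$p0
  vapply(p0, function(q)
    classify_dynamics(object$payoff, object$k, q)$predicted_limit,
    numeric(1))
}

#' Simulate stochastic trajectories from a model
#'
#' Runs `nsim` independent agent-based replicates (fresh network and initial
#' assignment per replicate, seeds `seed + 0:(nsim-1)`).
#'
#' @param object an [exit_entry_model()].
#' @param nsim number of replicates.
#' @param seed base seed.
#' @param generations number of generations (default 200).
#' @param unit generation unit (default `"sweep"`).
#' @param record_every recording stride (default 1).
#' @param ... unused.
#' @return A single `ee_trajectory` when `nsim = 1`, otherwise an
#'   `ee_ensemble`.
#' @export
simulate.exit_entry_model <- function(object, nsim = 1, seed = 1,
                                      generations = 200, unit = "sweep",
                                      record_every = 1, ...) {
  ens <- ensemble_ee(object$payoff, N = object$N, k = object$k,
                     n_A_initial = round(object$p0 * object$N),
                     omega = object$omega, generations = generations,
                     unit = unit, record_every = record_every,
                     topology = object$topology,
                     count_vacated_link = object$count_vacated_link,
                     n_runs = nsim, base_seed = seed)
  if (nsim == 1) {
    set.seed(seed)
    net <- regular_network(object$N, object$k, topology = object$topology)
    st <- assign_types(net, round(object$p0 * object$N))
    return(run_ee(st, object$payoff, object$omega, generations, unit = unit,
                  record_every = record_every,
                  count_vacated_link = object$count_vacated_link))
  }
  ens
}

#' Phase-line plot of the slow dynamics
#'
#' Plots the slow-manifold rate of change of `P_A` against `P_A`, marking the
#' analytic equilibria (filled points: stable; open: unstable) and the
#' model's initial frequency.
#'
#' @param x an [exit_entry_model()].
#' @param n_grid grid resolution.
#' @param ... passed to [graphics::plot()].
#' @export
plot.exit_entry_model <- function(x, n_grid = 201, ...) {
  pl <- phase_line(x$payoff, x$k, x$omega, n_grid = n_grid)
  graphics::plot(pl$p, pl$rate, type = "l",
                 xlab = expression(P[A]),
                 ylab = expression(dot(P)[A]), ...)
  graphics::abline(h = 0, col = "grey")
  eq <- attr(pl, "roots")
  graphics::points(eq$location, rep(0, nrow(eq)),
                   pch = ifelse(eq$stability == "stable", 19, 1), cex = 1.3)
  graphics::points(x$p0, 0, pch = 8, col = "red")
  invisible(pl)
}
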