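#' One exit-entry event (pure-R reference implementation)
#'
#' Performs a single stochastic exit-entry event: a vertex chosen uniformly at
#' random exits, and its vacated vertex is refilled by a type-A cell with
#' probability `F_A / (F_A + F_C)` computed from the neighbor group fitnesses,
#' else by a type-C cell. Exactly two RNG draws are made, in the fixed order
#' (exiting vertex, replacement Bernoulli), so this function is
#' bit-equivalent to one iteration of the compiled loop used by [run_ee()].
#'
#' This is the reference implementation used to pin down the semantics; the
#' compiled loop is proven equivalent by test. It refuses to run on an
#' absorbed state (all-A or all-C), which the dynamics cannot leave.
#'
#' @param state a `graph_state`.
#' @param payoff an [interaction_matrix()] (or equivalent).
#' @param omega selection intensity in `[0, 1)`.
#' @param count_vacated_link logical; see [neighbor_tally()].
#' @return A list with `state` (updated) and `record` (exited vertex, exited
#'   type, entered type, and the replacement probability used).
#' @export
ee_step <- function(state, payoff, omega, count_vacated_link = TRUE) {
  stopifnot(inherits(state, "graph_state"))
  N <- state$network$N
  n_A <- sum(state$types == 1L)
  if (n_A == 0L || n_A == N)
    stop("state is absorbed (single-type population); exit-entry cannot proceed")
  v <- as.integer(stats::runif(1) * N) + 1L
  if (v > N) v <- N
  exited <- state$types[v]
  tal <- neighbor_tally(state, v, count_vacated_link)
  fit <- group_fitness(tal, payoff, omega)
  pA <- replacement_probability(fit)
  entered <- if (stats::runif(1) < pA) 1L else 0L
  state$types[v] <- entered
  list(state = state,
       record = list(exited_vertex = v,
                     exited_type = if (exited == 1L) "A" else "C",
                     entered_type = if (entered == 1L) "A" else "C",
                     prob_A = pA))
}

events_per_generation <- function(unit, N) {
  switch(unit, sweep = N, event = 1L,
         stop("generation unit must be 'sweep' or 'event'"))
}

#' Run the stochastic exit-entry simulation
#'
#' Iterates exit-entry events on a network state until absorption (the type-A
#' count reaches 0 or N) or until `generations` generations have elapsed.
#' One generation is either a single event (`unit = "event"`, matching the
#' elementary definition of the update step) or a sweep of N events
#' (`unit = "sweep"`, the default, matching the timescale on which
#' population-level change is visible).
#'
#' @param state a `graph_state` giving the network and initial types.
#' @param payoff an [interaction_matrix()] (or equivalent).
#' @param omega selection intensity in `[0, 1)`; default 0.01 (weak selection).
#' @param generations maximum number of generations (>= 1).
#' @param unit generation unit, `"sweep"` or `"event"`.
#' @param record_every recording stride in generations.
#' @param seed optional integer seed (applied with `set.seed` before the run).
#' @param count_vacated_link logical; see [neighbor_tally()].
#' @param validate run [validate_selection()] first (default TRUE).
#' @return An `ee_trajectory`: a data frame with columns `generation`, `n_A`,
#'   `P_A`, `P_AA`, `P_AC`, `P_CA`, `P_CC`, `q_A_given_A`, with attributes
#'   `absorbed`, `absorption_generation`, `config`, `final_types`.
#' @examples
#' net <- regular_network(100, 4, seed = 1)
#' st <- assign_types(net, 30, seed = 2)
#' tr <- run_ee(st, interaction_matrix(0, 1, 1, 0), omega = 0.01,
#'              generations = 20, seed = 3)
#' @export
run_ee <- function(state, payoff, omega = 0.01, generations,
                   unit = c("sweep", "event"), record_every = 1,
                   seed = NULL, count_vacated_link = TRUE, validate = TRUE) {
  stopifnot(inherits(state, "graph_state"))
  unit <- match.arg(unit)
  if (!is.numeric(generations) || generations < 1)
    stop("generations must be >= 1")
  p <- as_payoff(payoff)
  N <- state$network$N; k <- state$network$k
  if (validate) validate_selection(payoff, k, omega)
  if (!is.null(seed)) set.seed(seed)
  epg <- events_per_generation(unit, N)
  res <- run_abm_cpp(state$network$neighbors - 1L, state$types,
                     p$a, p$b, p$c, p$d, omega,
                     max_events = generations * epg,
                     record_every = record_every * epg,
                     count_vacated = count_vacated_link)
  rec <- res$records
  dAA <- 2 * rec[, 3]; dAC <- rec[, 4]; dCC <- 2 * rec[, 5]
  M <- N * k
  n_A <- rec[, 2]
  traj <- data.frame(
    generation = rec[, 1] / epg,
    n_A = n_A,
    P_A = n_A / N,
    P_AA = dAA / M, P_AC = dAC / M, P_CA = dAC / M, P_CC = dCC / M,
    q_A_given_A = ifelse(n_A > 0, dAA / (k * n_A), 0))
  structure(traj,
            class = c("ee_trajectory", "data.frame"),
            absorbed = res$absorbed,
            absorption_generation =
              if (is.na(res$absorption_event)) NA_real_
              else res$absorption_event / epg,
            config = list(N = N, k = k, topology = state$network$topology,
                          payoff = p, omega = omega,
                          generations = generations, unit = unit,
                          record_every = record_every, seed = seed,
                          count_vacated_link = count_vacated_link,
                          n_events = res$n_events),
            final_types = res$final_types)
}

#' @export
print.ee_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("exit-entry trajectory: N = %d, k = %d, omega = %g, unit = %s\n",
              cfg$N, cfg$k, cfg$omega, cfg$unit))
  cat(sprintf("  %d records over %g generations; ", nrow(x),
              max(x$generation)))
  if (isTRUE(attr(x, "absorbed")))
    cat(sprintf("absorbed at n_A = %d (generation %g)\n",
                x$n_A[nrow(x)], attr(x, "absorption_generation")))
  else cat(sprintf("not absorbed; final n_A = %d\n", x$n_A[nrow(x)]))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns: `generation,n_A,P_A,P_AA,P_AC,P_CC,q_A_given_A`.
#' @param traj an `ee_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(
    traj[, c("generation", "n_A", "P_A", "P_AA", "P_AC", "P_CC", "q_A_given_A")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ensemble of independent exit-entry runs
#'
#' Runs `n_runs` independent replicates with seeds `base_seed + 0:(n_runs-1)`.
#' Each replicate builds a fresh network and initial assignment from its own
#' seed, then simulates. Absorbed runs are extended with their absorbing value
#' when averaging across replicates (constant extension).
#'
#' @param payoff an [interaction_matrix()] (or equivalent).
#' @param N,k,topology network settings (see [regular_network()]).
#' @param n_A_initial initial number of type-A cells.
#' @param omega selection intensity.
#' @param generations maximum generations per run.
#' @param unit,record_every,count_vacated_link as in [run_ee()].
#' @param n_runs number of replicates (>= 1).
#' @param base_seed integer; replicate i uses seed `base_seed + i - 1`.
#' @return An `ee_ensemble`: list with `times` (recorded generations), `n_A`
#'   (runs x times matrix, constant-extended), `mean_n_A`, `sd_n_A`,
#'   `final_n_A`, `absorption_generation`, `fixation_fraction` (named, A and
#'   C), `q_A_given_A` (runs x times), and the config echo.
#' @export
ensemble_ee <- function(payoff, N, k, n_A_initial, omega = 0.01,
                        generations, unit = c("sweep", "event"),
                        record_every = 1, topology = "random-regular",
                        count_vacated_link = TRUE,
                        n_runs, base_seed = 1) {
  unit <- match.arg(unit)
  if (n_runs < 1) stop("n_runs must be >= 1")
  validate_selection(payoff, k, omega)
  times <- seq(0, generations, by = record_every)
  nAmat <- matrix(NA_real_, n_runs, length(times))
  qmat <- matrix(NA_real_, n_runs, length(times))
  final_n_A <- numeric(n_runs)
  absg <- rep(NA_real_, n_runs)
  for (i in seq_len(n_runs)) {
    seed_i <- base_seed + i - 1L
    set.seed(seed_i)
    net <- regular_network(N, k, topology = topology)
    st <- assign_types(net, n_A_initial)
    tr <- run_ee(st, payoff, omega, generations, unit = unit,
                 record_every = record_every, count_vacated_link =
                   count_vacated_link, validate = FALSE)
    idx <- match(round(tr$generation / record_every),
                 round(times / record_every))
    nAmat[i, idx] <- tr$n_A
    qmat[i, idx] <- tr$q_A_given_A
    # constant extension past absorption / early stop
    last <- max(which(!is.na(nAmat[i, ])))
    if (last < length(times)) {
      nAmat[i, (last + 1):length(times)] <- nAmat[i, last]
      qmat[i, (last + 1):length(times)] <- qmat[i, last]
    }
    final_n_A[i] <- tr$n_A[nrow(tr)]
    absg[i] <- attr(tr, "absorption_generation")
  }
  structure(list(
    times = times, n_A = nAmat, q_A_given_A = qmat,
    mean_n_A = colMeans(nAmat), sd_n_A = apply(nAmat, 2, stats::sd),
    final_n_A = final_n_A, absorption_generation = absg,
    fixation_fraction = c(A = mean(final_n_A == N, na.rm = TRUE),
                          C = mean(final_n_A == 0, na.rm = TRUE)),
    n_runs = n_runs, base_seed = base_seed,
    config = list(N = N, k = k, topology = topology, payoff = as_payoff(payoff),
                  omega = omega, generations = generations, unit = unit,
                  record_every = record_every,
                  count_vacated_link = count_vacated_link)),
    class = "ee_ensemble")
}

#' @export
print.ee_ensemble <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("exit-entry ensemble: %d runs, N = %d, k = %d, omega = %g\n",
              x$n_runs, cfg$N, cfg$k, cfg$omega))
  cat(sprintf("  fixation fractions: A = %.3f, C = %.3f\n",
              x$fixation_fraction["A"], x$fixation_fraction["C"]))
  cat(sprintf("  mean final n_A = %.1f (sd %.1f)\n",
              mean(x$final_n_A), stats::sd(x$final_n_A)))
  invisible(x)
}

#' Parameter sweep over one payoff entry and the degree
#'
#' Reproduces the grid experiment: the mean type-C population at a fixed
#' readout generation as one payoff entry (`b` in the matrix `[0 b; 1 0]`, or
#' `d` in `[1 0; 0 d]`) and the degree `k` vary.
#'
#' @param param `"b"` or `"d"`.
#' @param values numeric grid for the swept entry.
#' @param k_values degrees to sweep (default `c(4, 5, 6)`).
#' @param N population size; `n_C_initial` initial type-C count.
#' @param omega selection intensity.
#' @param readout_generation generation (in `unit`s) at which the type-C
#'   population is read out.
#' @param unit generation unit (default `"sweep"`).
#' @param n_runs replicates per grid point.
#' @param base_seed seed base; each grid point advances it by `n_runs`.
#' @return A data frame with columns `param`, `value`, `k`, `mean_n_C`,
#'   `se_n_C`, `n_runs`.
#' @export
sweep_ee <- function(param = c("b", "d"), values, k_values = c(4, 5, 6),
                     N = 10000, n_C_initial = 100, omega = 0.01,
                     readout_generation = 5, unit = "sweep",
                     n_runs = 10, base_seed = 1) {
  param <- match.arg(param)
  out <- NULL
  seed0 <- base_seed
  for (k in k_values) {
    for (val in values) {
      payoff <- if (param == "b") interaction_matrix(0, val, 1, 0)
                else interaction_matrix(1, 0, 0, val)
      ens <- ensemble_ee(payoff, N = N, k = k,
                         n_A_initial = N - n_C_initial, omega = omega,
                         generations = readout_generation, unit = unit,
                         record_every = readout_generation,
                         n_runs = n_runs, base_seed = seed0)
      n_C <- N - ens$n_A[, ncol(ens$n_A)]
      out <- rbind(out, data.frame(
        param = param, value = val, k = k,
        mean_n_C = mean(n_C),
        se_n_C = stats::sd(n_C) / sqrt(n_runs),
        n_runs = n_runs))
      seed0 <- seed0 + n_runs
    }
  }
  out
}
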