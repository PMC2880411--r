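#' Preset experiments
#'
#' The six single-run experiments (`fig2` ... `fig7`) share N = 10000 cells,
#' degree k = 4 and selection intensity omega = 0.01 and differ in the
#' interaction matrix and the initial composition; `fig8` is the grid sweep
#' over one payoff entry (`b` in `[0 b; 1 0]` or `d` in `[1 0; 0 d]`) and the
#' degree, read out as the mean type-C population at a fixed generation.
#'
#' @param name one of `"fig2"` ... `"fig8"`.
#' @return A list describing the preset: payoff, `k`, `N`, `omega`,
#'   `n_A_initial` (or sweep settings for `fig8`) and the expected
#'   qualitative outcome.
#' @export
figure_preset <- function(name) {
  presets <- list(
    fig2 = list(payoff = interaction_matrix(1, 0, 0, 1), n_A_initial = 9900,
                outcome = "type A dominates (P_A -> 1)"),
    fig3 = list(payoff = interaction_matrix(0, -0.5, 1, 0), n_A_initial = 9900,
                outcome = "type A exits (P_A -> 0)"),
    fig4 = list(payoff = interaction_matrix(0, 1, 1, 0), n_A_initial = 9900,
                outcome = "coexistence at the interior root 0.5 (n_A ~ 5000)"),
    fig5 = list(payoff = interaction_matrix(0, 1, 1, 0), n_A_initial = 4000,
                outcome = "coexistence at the interior root 0.5 (n_A ~ 5000)"),
    fig6 = list(payoff = interaction_matrix(0, -1, -2, 0), n_A_initial = 9900,
                outcome = "bistable, starts above the 0.3 threshold: P_A -> 1"),
    fig7 = list(payoff = interaction_matrix(0, -1, -2, 0), n_A_initial = 2000,
                outcome = "bistable, starts below the 0.3 threshold: P_A -> 0"),
    fig8 = list(sweep_params = c("b", "d"), k_values = c(4, 5, 6),
                n_C_initial = 100, readout_generation = 5,
                outcome = "type-C population at the readout generation shifts with b, d and k"))
  if (!name %in% names(presets))
    stop("unknown preset; use one of ", paste(names(presets), collapse = ", "))
  out <- presets[[name]]
  out$name <- name
  out$N <- 10000L; out$k <- 4L; out$omega <- 0.01
  out
}

#' Run a preset end-to-end and compare prediction with simulation
#'
#' For `fig2`-`fig7`: classifies the configuration analytically, runs an
#' ensemble of agent-based replicates, and reports the predicted and the
#' observed limit. For `fig8`: runs the payoff/degree sweep.
#'
#' @param name preset name (`"fig2"` ... `"fig8"`).
#' @param seed base seed for the ensemble.
#' @param n_runs replicates (default 10).
#' @param generations maximum generations per run (sweep unit; default 2000,
#'   long enough for the absorbing presets to absorb and the coexistence
#'   presets to plateau).
#' @param sweep_values grid for the swept entry (`fig8` only).
#' @return A list report (class `preset_report`): the preset, the stability
#'   report, ensemble summaries, and for `fig2`-`fig7` the observed limit and
#'   whether it matches the prediction.
#' @export
reproduce_preset <- function(name, seed = 1, n_runs = 10, generations = 2000,
                             sweep_values = c(-0.5, 0, 0.5, 1)) {
  ps <- figure_preset(name)
  if (name == "fig8") {
    res <- lapply(ps$sweep_params, function(prm)
      sweep_ee(prm, values = sweep_values, k_values = ps$k_values,
               N = ps$N, n_C_initial = ps$n_C_initial, omega = ps$omega,
               readout_generation = ps$readout_generation,
               n_runs = n_runs, base_seed = seed))
    names(res) <- ps$sweep_params
    return(structure(list(preset = ps, sweep = res), class = "preset_report"))
  }
  p0 <- ps$n_A_initial / ps$N
  report <- classify_dynamics(ps$payoff, ps$k, p0)
  ens <- ensemble_ee(ps$payoff, N = ps$N, k = ps$k,
                     n_A_initial = ps$n_A_initial, omega = ps$omega,
                     generations = generations, unit = "sweep",
                     record_every = max(1, generations %/% 200),
                     n_runs = n_runs, base_seed = seed)
  observed <- observed_limit(ens)
  predicted <- report$predicted_limit
  structure(list(preset = ps, report = report, ensemble = ens,
                 predicted_limit = predicted,
                 observed_limit = observed,
                 match = !is.na(predicted) &&
                   abs(observed - predicted) < 0.05),
            class = "preset_report")
}

# Per-ensemble observed limit of P_A: mean over runs of each run's final
# quarter-trajectory mean (absorbed runs contribute their absorbing value).
observed_limit <- function(ens) {
  nt <- ncol(ens$n_A)
  tail_idx <- seq(max(1L, floor(0.75 * nt)), nt)
  mean(rowMeans(ens$n_A[, tail_idx, drop = FALSE])) / ens$config$N
}

#' @export
print.preset_report <- function(x, ...) {
  cat(sprintf("preset %s: %s\n", x$preset$name, x$preset$outcome))
  if (!is.null(x$sweep)) {
    for (nm in names(x$sweep)) {
      cat(sprintf("sweep over %s:\n", nm))
      print(x$sweep[[nm]])
    }
    return(invisible(x))
  }
  cat(sprintf("  predicted limit of P_A: %s; observed: %.4f; %s\n",
              format(x$predicted_limit, digits = 4), x$observed_limit,
              if (isTRUE(x$match)) "MATCH" else "MISMATCH"))
  invisible(x)
}
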