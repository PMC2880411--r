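#' Interaction matrix between two cell types
#'
#' Constructs the 2x2 matrix of interaction strengths between the two modelled
#' cell types, labelled `A` (e.g. alternatively activated, pro-repair
#' macrophages) and `C` (classically activated, pro-inflammatory macrophages).
#' Entry conventions: `a` is the energy a type-A cell gives a linked type-A
#' cell, `b` the energy a type-A cell gives a linked type-C cell, `c` the
#' energy a type-C cell gives a linked type-A cell, and `d` the energy a
#' type-C cell gives a linked type-C cell. Negative entries (inhibitory
#' interactions) are permitted.
#'
#' @param a,b,c,d finite numeric interaction strengths.
#' @return An object of class `interaction_matrix`: a 2x2 numeric matrix with
#'   dimnames `c("A","C")` (rows index the cell type providing the energy).
#' @examples
#' interaction_matrix(0, 1, 1, 0)   # mutual cross-support, coexistence game
#' interaction_matrix(0, -1, -2, 0) # mutual inhibition, bistable game
#' @export
interaction_matrix <- function(a, b, c, d) {
  vals <- c(a = a, b = b, c = c, d = d)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals)))
    stop("all four interaction strengths must be finite numbers")
  m <- matrix(as.numeric(vals), 2L, 2L, byrow = TRUE,
              dimnames = list(provider = c("A", "C"), receiver = c("A", "C")))
  class(m) <- c("interaction_matrix", class(m))
  m
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Interaction matrix (row = providing type):\n")
  print(unclass(x), ...)
  invisible(x)
}

# Coerce payoff input (interaction_matrix, plain 2x2 matrix, or length-4
# vector a,b,c,d) to a named list.
as_payoff <- function(payoff) {
  if (inherits(payoff, "interaction_matrix")) {
    list(a = payoff[1, 1], b = payoff[1, 2], c = payoff[2, 1], d = payoff[2, 2])
  } else if (is.matrix(payoff) && all(dim(payoff) == 2L)) {
    list(a = payoff[1, 1], b = payoff[1, 2], c = payoff[2, 1], d = payoff[2, 2])
  } else if (is.numeric(payoff) && length(payoff) == 4L) {
    list(a = payoff[[1]], b = payoff[[2]], c = payoff[[3]], d = payoff[[4]])
  } else {
    stop("payoff must be an interaction_matrix, a 2x2 matrix, or a length-4 numeric (a, b, c, d)")
  }
}

check_omega <- function(omega) {
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) ||
      omega < 0 || omega >= 1)
    stop("selection intensity omega must lie in [0, 1)")
  invisible(omega)
}

#' Tally the neighborhood of a vacated vertex
#'
#' Counts, among the `k` cells linked to vertex `v`, how many are of each type
#' (`K_A`, `K_C`) and how many links those neighbors themselves hold to type-A
#' and type-C cells. These link tallies carry each neighbor's per-cell energy:
#' the group payoff in [group_fitness()] is the sum of every neighbor's energy.
#'
#' The link from a neighbor back to `v` is counted with the exiting cell's own
#' (current) type when `count_vacated_link = TRUE` (the default), and skipped
#' when `FALSE`.
#'
#' @param state a `graph_state` (see [assign_types()]).
#' @param v vertex index (1-based).
#' @param count_vacated_link logical; see Details.
#' @return A list of class `neighbor_tally` with elements `K_A`, `K_C`,
#'   `edges_A_to_A`, `edges_A_to_C`, `edges_C_to_A`, `edges_C_to_C`.
#' @export
neighbor_tally <- function(state, v, count_vacated_link = TRUE) {
  nbrs <- state$network$neighbors[v, ]
  types <- state$types
  K_A <- 0L; K_C <- 0L
  eAA <- 0L; eAC <- 0L; eCA <- 0L; eCC <- 0L
  for (u in nbrs) {
    links <- state$network$neighbors[u, ]
    if (!count_vacated_link) links <- links[links != v]
    lA <- sum(types[links] == 1L)
    lC <- length(links) - lA
    if (types[u] == 1L) { K_A <- K_A + 1L; eAA <- eAA + lA; eAC <- eAC + lC }
    else                { K_C <- K_C + 1L; eCA <- eCA + lA; eCC <- eCC + lC }
  }
  structure(list(K_A = K_A, K_C = K_C,
                 edges_A_to_A = eAA, edges_A_to_C = eAC,
                 edges_C_to_A = eCA, edges_C_to_C = eCC),
            class = "neighbor_tally")
}

#' Aggregate fitness of the two neighbor groups
#'
#' Fitness of a single cell is `F = 1 - omega + omega * eps`, where `eps` is
#' the energy the cell confers on its linked neighbors under the interaction
#' matrix and `omega` is the selection intensity. The group fitness of the
#' type-A neighbors of a vacated vertex is the sum over those `K_A` cells:
#' `F_A = K_A (1 - omega) + omega (a * edges_A_to_A + b * edges_A_to_C)`,
#' and symmetrically
#' `F_C = K_C (1 - omega) + omega (c * edges_C_to_A + d * edges_C_to_C)`.
#' At `omega = 0` this reduces to the bare counts `(K_A, K_C)` (neutral drift).
#'
#' @param tally a [neighbor_tally()].
#' @param payoff an [interaction_matrix()] (or equivalent).
#' @param omega selection intensity in `[0, 1)`.
#' @return A list of class `fitness_pair` with elements `F_A`, `F_C`.
#' @export
group_fitness <- function(tally, payoff, omega) {
  p <- as_payoff(payoff)
  check_omega(omega)
  F_A <- tally$K_A * (1 - omega) +
    omega * (tally$edges_A_to_A * p$a + tally$edges_A_to_C * p$b)
  F_C <- tally$K_C * (1 - omega) +
    omega * (tally$edges_C_to_A * p$c + tally$edges_C_to_C * p$d)
  structure(list(F_A = F_A, F_C = F_C), class = "fitness_pair")
}

#' Probability that the vacated vertex is refilled by a type-A cell
#'
#' The exit-entry rule: a vacated vertex is filled by a new type-A cell with
#' probability `F_A / (F_A + F_C)`, the relative aggregate fitness of its
#' type-A neighbor group.
#'
#' @param fitness a `fitness_pair` from [group_fitness()], or a numeric `F_A`.
#' @param F_C numeric; required when `fitness` is given as a bare number.
#' @return Probability in `[0, 1]`.
#' @export
replacement_probability <- function(fitness, F_C = NULL) {
  if (inherits(fitness, "fitness_pair")) {
    F_A <- fitness$F_A; F_C <- fitness$F_C
  } else {
    F_A <- fitness
    if (is.null(F_C)) stop("F_C must be supplied")
  }
  if (F_A < 0 || F_C < 0)
    stop("group fitnesses must be non-negative; run validate_selection() on the configuration")
  tot <- F_A + F_C
  if (tot <= 0)
    stop("degenerate fitness configuration: F_A + F_C = 0")
  F_A / tot
}

#' Validate that a selection configuration keeps fitness positive
#'
#' With negative interaction strengths the linear fitness `1 - omega + omega *
#' eps` can turn negative, which breaks the probabilistic exit-entry rule.
#' This guard computes, for each type, the minimal attainable group fitness
#' `min over K in 1..k of K (1 - omega) + omega * K * k * min(row entries)`
#' and rejects the configuration unless both minima are strictly positive.
#'
#' @param payoff an [interaction_matrix()] (or equivalent).
#' @param k vertex degree (>= 2).
#' @param omega selection intensity in `[0, 1)`.
#' @param warn_threshold omega above which a weak-selection warning is issued
#'   (the pair-approximation reduction assumes `omega << 1`); default 0.1.
#' @return `TRUE` invisibly, or an error naming the offending bound.
#' @export
validate_selection <- function(payoff, k, omega, warn_threshold = 0.1) {
  p <- as_payoff(payoff)
  check_omega(omega)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop("degree k must be an integer >= 2")
  worst <- function(mn) min(vapply(seq_len(k), function(K)
    K * (1 - omega) + omega * K * k * mn, numeric(1)))
  wA <- worst(min(p$a, p$b))
  wC <- worst(min(p$c, p$d))
  if (wA <= 0)
    stop(sprintf("type-A group fitness can reach %.4g <= 0; reduce omega or the magnitude of negative payoffs", wA))
  if (wC <= 0)
    stop(sprintf("type-C group fitness can reach %.4g <= 0; reduce omega or the magnitude of negative payoffs", wC))
  if (omega > warn_threshold)
    warning(sprintf("omega = %g exceeds the weak-selection threshold %g; the pair-approximation reduction may be inaccurate", omega, warn_threshold))
  invisible(TRUE)
}
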