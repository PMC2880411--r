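# Small fixtures and independent oracles shared across tests.

# A cycle graph (ring, k = 2) with explicit type labels ("A"/"C" characters).
cycle_state <- function(labels) {
  n <- length(labels)
  net <- regular_network(n, 2, topology = "ring")
  st <- assign_types(net, 0)
  st$types <- as.integer(labels == "A")
  st
}

# Brute-force frequency oracle: loop over every directed edge explicitly.
oracle_summary <- function(state) {
  nbrs <- state$network$neighbors
  types <- state$types
  N <- state$network$N; k <- state$network$k
  d <- c(AA = 0, AC = 0, CA = 0, CC = 0)
  for (v in seq_len(N)) for (u in nbrs[v, ]) {
    key <- paste0(if (types[v] == 1L) "A" else "C",
                  if (types[u] == 1L) "A" else "C")
    d[key] <- d[key] + 1
  }
  M <- N * k
  n_A <- sum(types == 1L)
  list(P_A = n_A / N, P_C = 1 - n_A / N,
       P_AA = d[["AA"]] / M, P_AC = d[["AC"]] / M,
       P_CA = d[["CA"]] / M, P_CC = d[["CC"]] / M,
       q_A_given_A = if (n_A > 0) d[["AA"]] / (k * n_A) else 0,
       q_A_given_C = if (n_A < N) d[["AC"]] / (k * (N - n_A)) else 0)
}

# The six single-run study configurations (N = 10000, k = 4, omega = 0.01).
study_configs <- function() {
  list(
    fig2 = list(I = interaction_matrix(1, 0, 0, 1),    n_A = 9900),
    fig3 = list(I = interaction_matrix(0, -0.5, 1, 0), n_A = 9900),
    fig4 = list(I = interaction_matrix(0, 1, 1, 0),    n_A = 9900),
    fig5 = list(I = interaction_matrix(0, 1, 1, 0),    n_A = 4000),
    fig6 = list(I = interaction_matrix(0, -1, -2, 0),  n_A = 9900),
    fig7 = list(I = interaction_matrix(0, -1, -2, 0),  n_A = 2000))
}

# Random neighbor tally on a degree-k vertex (valid edge-total convention).
random_tally <- function(k) {
  K_A <- sample(0:k, 1)
  K_C <- k - K_A
  eAA <- if (K_A > 0) sample(0:(K_A * k), 1) else 0L
  eCA <- if (K_C > 0) sample(0:(K_C * k), 1) else 0L
  structure(list(K_A = K_A, K_C = K_C,
                 edges_A_to_A = eAA, edges_A_to_C = K_A * k - eAA,
                 edges_C_to_A = eCA, edges_C_to_C = K_C * k - eCA),
            class = "neighbor_tally")
}
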