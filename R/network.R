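#' Build a seeded k-regular interaction network
#'
#' Every cell occupies a vertex and links to exactly `k` adjacent cells.
#' Three topologies are provided: `"random-regular"` (the default; a uniform
#' random simple k-regular graph with a connectivity retry loop), `"ring"`
#' (each vertex linked to its k/2 nearest neighbors on each side; requires
#' even `k`), and `"torus"` (periodic square lattice; requires `k = 4` and
#' `N` a perfect square).
#'
#' @param N number of vertices (cells).
#' @param k vertex degree, `2 <= k < N`; `N * k` must be even.
#' @param topology one of `"random-regular"`, `"ring"`, `"torus"`.
#' @param seed optional integer seed; when supplied the construction is
#'   deterministic.
#' @param max_retries retries allowed for the random-regular topology to
#'   produce a connected graph (default 100).
#' @return An object of class `ee_network`: a list with `neighbors` (an
#'   `N x k` integer matrix of 1-based neighbor ids), `N`, `k`, `topology`
#'   and `seed`.
#' @examples
#' net <- regular_network(100, 4, seed = 1)
#' @export
regular_network <- function(N, k,
                            topology = c("random-regular", "ring", "torus"),
                            seed = NULL, max_retries = 100L) {
  topology <- match.arg(topology)
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 3)
    stop("N must be an integer >= 3")
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2 || k >= N)
    stop("k must be an integer with 2 <= k < N")
  if ((N * k) %% 2 != 0)
    stop("N * k must be even (handshake lemma): no k-regular graph exists")
  N <- as.integer(N); k <- as.integer(k)
  if (!is.null(seed)) set.seed(seed)

  if (topology == "ring") {
    if (k %% 2 != 0) stop("ring topology requires even k")
    half <- k %/% 2
    offs <- c(seq_len(half), N - seq_len(half))
    nbrs <- outer(seq_len(N) - 1L, offs, function(i, o) (i + o) %% N) + 1L
    storage.mode(nbrs) <- "integer"
  } else if (topology == "torus") {
    m <- sqrt(N)
    if (k != 4L) stop("torus topology requires k = 4")
    if (m != round(m)) stop("torus topology requires N to be a perfect square")
    g <- igraph::make_lattice(length = as.integer(m), dim = 2, circular = TRUE)
    nbrs <- neighbors_matrix(g, N, k)
  } else {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      g <- igraph::sample_k_regular(N, k, multiple = FALSE)
      if (igraph::is_connected(g)) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("failed to generate a connected %d-regular graph in %d tries", k, max_retries))
    nbrs <- neighbors_matrix(g, N, k)
  }
  structure(list(neighbors = nbrs, N = N, k = k,
                 topology = topology, seed = seed),
            class = "ee_network")
}

neighbors_matrix <- function(g, N, k) {
  adj <- igraph::as_adj_list(g)
  nbrs <- matrix(0L, N, k)
  for (i in seq_len(N)) {
    ids <- as.integer(adj[[i]])
    if (length(ids) != k)
      stop(sprintf("vertex %d has degree %d, expected %d", i, length(ids), k))
    nbrs[i, ] <- ids
  }
  nbrs
}

#' @export
print.ee_network <- function(x, ...) {
  cat(sprintf("%d-regular network: N = %d vertices, topology %s%s\n",
              x$k, x$N, x$topology,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Assign initial cell types to a network
#'
#' Labels exactly `n_A` vertices as type A, chosen uniformly at random without
#' replacement (or clustered by breadth-first growth from a random root when
#' `placement = "clustered"`, for robustness checks), and the rest as type C.
#'
#' @param network an [regular_network()] object.
#' @param n_A number of type-A cells, `0 <= n_A <= N`.
#' @param seed optional integer seed for the assignment.
#' @param placement `"random"` (default) or `"clustered"`.
#' @return An object of class `graph_state`: list with `network` and `types`
#'   (an integer vector, 1 = type A, 0 = type C).
#' @export
assign_types <- function(network, n_A, seed = NULL,
                         placement = c("random", "clustered")) {
  placement <- match.arg(placement)
  stopifnot(inherits(network, "ee_network"))
  N <- network$N
  if (!is.numeric(n_A) || length(n_A) != 1L || n_A != round(n_A) ||
      n_A < 0 || n_A > N)
    stop(sprintf("n_A must be an integer in [0, %d]", N))
  if (!is.null(seed)) set.seed(seed)
  types <- integer(N)
  if (placement == "random") {
    types[sample.int(N, n_A)] <- 1L
  } else if (n_A > 0) {
    root <- sample.int(N, 1L)
    chosen <- logical(N)
    queue <- root; chosen[root] <- TRUE; taken <- 1L
    while (taken < n_A && length(queue) > 0) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in network$neighbors[v, ]) {
        if (!chosen[u] && taken < n_A) {
          chosen[u] <- TRUE; taken <- taken + 1L; queue <- c(queue, u)
        }
      }
    }
    # top up from the remainder if the component was exhausted
    if (taken < n_A) {
      rest <- which(!chosen)
      chosen[rest[seq_len(n_A - taken)]] <- TRUE
    }
    types[chosen] <- 1L
  }
  structure(list(network = network, types = types), class = "graph_state")
}

#' @export
print.graph_state <- function(x, ...) {
  cat(sprintf("graph_state: N = %d (A: %d, C: %d), k = %d, topology %s\n",
              x$network$N, sum(x$types == 1L), sum(x$types == 0L),
              x$network$k, x$network$topology))
  invisible(x)
}

#' Global, pair and conditional frequency summary of a network state
#'
#' Computes the population fractions `P_A`, `P_C`, the ordered-pair edge
#' frequencies `P_AA`, `P_AC`, `P_CA`, `P_CC` (every undirected edge counted
#' once in each direction, which makes `P_AC = P_CA` an exact identity), and
#' the conditional neighbor frequencies `q_X|Y = P_XY / P_Y` (defined as 0,
#' and flagged, when type Y is absent). The identities
#' `P_A + P_C = 1`, `sum of pair frequencies = 1`, `q_A|Y + q_C|Y = 1` and
#' `P_XY = q_X|Y P_Y` hold exactly up to floating point.
#'
#' @param state a `graph_state`.
#' @return A list of class `state_summary` with fields `P_A`, `P_C`, `P_AA`,
#'   `P_AC`, `P_CA`, `P_CC`, `q_A_given_A`, `q_C_given_A`, `q_A_given_C`,
#'   `q_C_given_C`, plus `absent` naming any type with zero population.
#' @export
summarize_state <- function(state) {
  stopifnot(inherits(state, "graph_state"))
  types <- state$types
  nbrs <- state$network$neighbors
  N <- state$network$N; k <- state$network$k
  n_A <- sum(types == 1L)
  # directed edge tallies: source type x target type
  src <- rep(types, times = k)
  tgt <- types[as.vector(nbrs)]
  M <- N * k  # number of directed edges
  dAA <- sum(src == 1L & tgt == 1L)
  dAC <- sum(src == 1L & tgt == 0L)  # source A, target C
  dCA <- sum(src == 0L & tgt == 1L)
  dCC <- sum(src == 0L & tgt == 0L)
  summary_from_tallies(N, k, n_A, dAA, dAC, dCA, dCC)
}

summary_from_tallies <- function(N, k, n_A, dAA, dAC, dCA, dCC) {
  M <- N * k
  P_A <- n_A / N; P_C <- 1 - P_A
  P_AA <- dAA / M; P_AC <- dAC / M; P_CA <- dCA / M; P_CC <- dCC / M
  q_A_given_A <- if (n_A > 0) dAA / (k * n_A) else 0
  q_C_given_A <- if (n_A > 0) dCA / (k * n_A) else 0
  q_A_given_C <- if (n_A < N) dAC / (k * (N - n_A)) else 0
  q_C_given_C <- if (n_A < N) dCC / (k * (N - n_A)) else 0
  absent <- c(if (n_A == 0) "A", if (n_A == N) "C")
  structure(list(P_A = P_A, P_C = P_C,
                 P_AA = P_AA, P_AC = P_AC, P_CA = P_CA, P_CC = P_CC,
                 q_A_given_A = q_A_given_A, q_C_given_A = q_C_given_A,
                 q_A_given_C = q_A_given_C, q_C_given_C = q_C_given_C,
                 absent = absent),
            class = "state_summary")
}

#' @export
print.state_summary <- function(x, digits = 4, ...) {
  cat(sprintf("P_A = %.*f, P_C = %.*f\n", digits, x$P_A, digits, x$P_C))
  cat(sprintf("pair frequencies: P_AA = %.*f, P_AC = P_CA = %.*f, P_CC = %.*f\n",
              digits, x$P_AA, digits, x$P_AC, digits, x$P_CC))
  cat(sprintf("conditionals: q_A|A = %.*f, q_A|C = %.*f\n",
              digits, x$q_A_given_A, digits, x$q_A_given_C))
  if (length(x$absent))
    cat("absent type(s):", paste(x$absent, collapse = ", "),
        "(their conditionals are reported as 0)\n")
  invisible(x)
}

#' Export / import a network state as plain-text fixtures
#'
#' Writes the edge list as one `"u v"` pair per line (0-based vertex ids,
#' each undirected edge once) and the type labels as a `vertex_id,type` CSV.
#'
#' @param state a `graph_state`.
#' @param edge_file,label_file file paths.
#' @return `write_graph_fixture` returns the paths invisibly;
#'   `read_graph_fixture` returns the reconstructed `graph_state`.
#' @export
write_graph_fixture <- function(state, edge_file, label_file) {
  stopifnot(inherits(state, "graph_state"))
  nbrs <- state$network$neighbors
  N <- state$network$N; k <- state$network$k
  us <- rep(seq_len(N), times = k); vs <- as.vector(nbrs)
  keep <- us < vs
  writeLines(paste(us[keep] - 1L, vs[keep] - 1L), edge_file)
  utils::write.csv(
    data.frame(vertex_id = seq_len(N) - 1L,
               type = ifelse(state$types == 1L, "A", "C")),
    label_file, row.names = FALSE, quote = FALSE)
  invisible(c(edge_file, label_file))
}

#' @rdname write_graph_fixture
#' @export
read_graph_fixture <- function(edge_file, label_file) {
  el <- utils::read.table(edge_file, col.names = c("u", "v"))
  labs <- utils::read.csv(label_file)
  N <- nrow(labs)
  deg <- tabulate(c(el$u, el$v) + 1L, nbins = N)
  k <- deg[1L]
  if (any(deg != k)) stop("edge list is not regular")
  nbrs <- matrix(0L, N, k)
  fill <- integer(N)
  for (i in seq_len(nrow(el))) {
    u <- el$u[i] + 1L; v <- el$v[i] + 1L
    fill[u] <- fill[u] + 1L; nbrs[u, fill[u]] <- v
    fill[v] <- fill[v] + 1L; nbrs[v, fill[v]] <- u
  }
  net <- structure(list(neighbors = nbrs, N = N, k = k,
                        topology = "imported", seed = NULL),
                   class = "ee_network")
  types <- integer(N)
  types[labs$vertex_id + 1L] <- as.integer(labs$type == "A")
  structure(list(network = net, types = types), class = "graph_state")
}
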