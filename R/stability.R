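#' Coefficients of the sign polynomial of the slow dynamics
#'
#' Under weak selection the global type-A frequency `p = P_A` evolves on the
#' slow manifold with rate proportional to `p (1 - p) g(p)` where
#' `g(p) = c0 + c1 p + c2 p^2` and
#' \deqn{c_0 = (k+1)a + (k^2-k-1)b - c + (k^2-1)d}
#' \deqn{c_1 = (k+1)(k-3)a - (2k^2-2k-3)b - (k^2-k-3)c - (k+1)d}
#' \deqn{c_2 = -(k+1)(k-2)(a-b-c+d).}
#' The identity `c0 + c1 + c2 = 0` holds for every payoff and degree, so
#' `g(1) = 0` and `g` factors as `c2 (p - 1)(p - c0/c2)` whenever `c2 != 0`.
#'
#' @param payoff an [interaction_matrix()] (or equivalent).
#' @param k vertex degree (>= 2).
#' @return Named numeric vector `c(c0, c1, c2)`.
#' @examples
#' stability_coefficients(interaction_matrix(0, 1, 1, 0), k = 4) # 10 -30 20
#' @export
stability_coefficients <- function(payoff, k) {
  p <- as_payoff(payoff)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop("degree k must be an integer >= 2")
  a <- p$a; b <- p$b; cc <- p$c; d <- p$d
  c0 <- (k + 1) * a + (k^2 - k - 1) * b - cc + (k^2 - 1) * d
  c1 <- (k + 1) * (k - 3) * a - (2 * k^2 - 2 * k - 3) * b -
    (k^2 - k - 3) * cc - (k + 1) * d
  c2 <- -(k + 1) * (k - 2) * (a - b - cc + d)
  c(c0 = c0, c1 = c1, c2 = c2)
}

# Evaluate g(p) = c0 + c1 p + c2 p^2 (vectorized in p).
sign_polynomial <- function(p, coefs) {
  coefs[["c0"]] + coefs[["c1"]] * p + coefs[["c2"]] * p^2
}

# TRUE when the dynamics are payoff-indifferent: every cell's energy is
# identical whatever the configuration, so selection cannot distinguish the
# types and the process is exactly neutral drift. (The printed polynomial
# coefficients do not vanish on this diagonal -- a normalization artifact of
# the closure -- so the neutral case is recognised from the payoff itself.)
is_neutral_payoff <- function(payoff) {
  p <- as_payoff(payoff)
  isTRUE(all.equal(c(p$a, p$a, p$a), c(p$b, p$c, p$d)))
}

#' Equilibria of the slow dynamics and their stability
#'
#' The boundary states `p = 0` and `p = 1` are always equilibria (absorbing
#' for the stochastic process). When `c2 != 0` and the interior root
#' `p* = c0/c2` lies in (0, 1) it is a third equilibrium: stable (attracting
#' coexistence) when `c2 > 0`, unstable (a bistable threshold) when `c2 < 0`.
#' Boundary equilibria are labelled from the adjacent sign of `g`.
#'
#' @inheritParams stability_coefficients
#' @return A data frame with columns `location` and `stability`
#'   (`"stable"`, `"unstable"`, `"semi-stable"`, or `"degenerate"`).
#' @export
stability_equilibria <- function(payoff, k) {
  co <- stability_coefficients(payoff, k)
  if (is_neutral_payoff(payoff))
    return(data.frame(location = c(0, 1),
                      stability = c("degenerate", "degenerate")))
  c0 <- co[["c0"]]; c2 <- co[["c2"]]
  root <- if (c2 != 0) c0 / c2 else NA_real_
  interior <- !is.na(root) && root > 0 && root < 1
  eps <- 1e-9
  g_near0 <- sign_polynomial(eps, co)       # sign of g just above 0
  g_near1 <- sign_polynomial(1 - eps, co)   # sign of g just below 1
  lab0 <- if (g_near0 < 0) "stable" else if (g_near0 > 0) "unstable" else "degenerate"
  lab1 <- if (g_near1 > 0) "stable" else if (g_near1 < 0) "unstable" else "degenerate"
  out <- data.frame(location = c(0, 1), stability = c(lab0, lab1))
  if (interior) {
    labr <- if (c2 > 0) "stable" else "unstable"
    out <- rbind(out, data.frame(location = root, stability = labr))
    out <- out[order(out$location), ]
    rownames(out) <- NULL
  }
  out
}

#' Classify the evolutionary profile of the network
#'
#' Predicts, from the interaction matrix, the degree and the initial type-A
#' frequency `p0`, which population the exit-entry dynamics approach:
#' * `A_dominates` (Case 1): `g > 0` throughout `(p0, 1)`; the limit is 1.
#' * `C_dominates` (Case 2): `g < 0` throughout `(0, p0)`; the limit is 0.
#' * `stable_coexistence` (Case 3): `c2 > 0` with `c0/c2` in (0, 1); the
#'   limit is the interior root from any interior start.
#' * `bistable_threshold`: `c2 < 0` with `c0/c2` in (0, 1); the limit is 1
#'   when `p0` lies above the threshold, 0 below it, and is reported as
#'   undecided when `p0` sits exactly on it.
#' * `neutral`: payoff-indifferent dynamics (`a = b = c = d`); no
#'   deterministic prediction.
#' Starts at `p0 = 0` or `p0 = 1` are already absorbed and return that value.
#'
#' @inheritParams stability_coefficients
#' @param p0 initial type-A frequency in `[0, 1]`.
#' @return An object of class `stability_report`: list with `payoff`, `k`,
#'   `p0`, `coefficients`, `equilibria`, `interior_root` (NA when none),
#'   `case_label`, `predicted_limit` (NA when undecided), `basin_boundary`
#'   (the threshold, when bistable) and `note`.
#' @examples
#' classify_dynamics(interaction_matrix(0, 1, 1, 0), k = 4, p0 = 0.99)
#' @export
classify_dynamics <- function(payoff, k, p0) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 < 0 || p0 > 1)
    stop("p0 must lie in [0, 1]")
  co <- stability_coefficients(payoff, k)
  eq <- stability_equilibria(payoff, k)
  c0 <- co[["c0"]]; c2 <- co[["c2"]]
  root <- if (c2 != 0) c0 / c2 else NA_real_
  interior <- !is.na(root) && root > 0 && root < 1
  note <- NULL

  if (is_neutral_payoff(payoff)) {
    case <- "neutral"; limit <- NA_real_; basin <- NA_real_
    note <- "payoff-indifferent dynamics: pure neutral drift, no deterministic limit"
  } else if (p0 == 0 || p0 == 1) {
    limit <- p0; basin <- if (interior && c2 < 0) root else NA_real_
    case <- classify_case(co, root, interior)
    note <- "initial state is already absorbing"
  } else {
    case <- classify_case(co, root, interior)
    basin <- NA_real_
    if (case == "A_dominates") limit <- 1
    else if (case == "C_dominates") limit <- 0
    else if (case == "stable_coexistence") limit <- root
    else { # bistable_threshold
      basin <- root
      if (p0 > root) limit <- 1
      else if (p0 < root) limit <- 0
      else { limit <- NA_real_; note <- "p0 sits exactly on the unstable threshold: undecided" }
    }
  }
  structure(list(payoff = as_payoff(payoff), k = k, p0 = p0,
                 coefficients = co, equilibria = eq,
                 interior_root = if (interior) root else NA_real_,
                 case_label = case, predicted_limit = limit,
                 basin_boundary = basin, note = note),
            class = "stability_report")
}

# Case from the sign of g on (0,1), using the factorization
# g(p) = c2 (p - 1)(p - c0/c2) forced by c0 + c1 + c2 = 0.
classify_case <- function(co, root, interior) {
  c2 <- co[["c2"]]
  if (c2 == 0) {
    # g(p) = c0 (1 - p): single sign on (0,1)
    if (co[["c0"]] > 0) "A_dominates"
    else if (co[["c0"]] < 0) "C_dominates"
    else "neutral"
  } else if (interior) {
    if (c2 > 0) "stable_coexistence" else "bistable_threshold"
  } else {
    # no interior root: g keeps one sign on (0,1); sample the midpoint
    if (sign_polynomial(0.5, co) > 0) "A_dominates" else "C_dominates"
  }
}

#' @export
print.stability_report <- function(x, ...) {
  p <- x$payoff
  cat(sprintf("stability report: payoff [%g %g; %g %g], k = %d, p0 = %g\n",
              p$a, p$b, p$c, p$d, x$k, x$p0))
  cat(sprintf("  c0 = %g, c1 = %g, c2 = %g\n",
              x$coefficients[["c0"]], x$coefficients[["c1"]],
              x$coefficients[["c2"]]))
  cat("  equilibria:\n")
  for (i in seq_len(nrow(x$equilibria)))
    cat(sprintf("    p* = %-8.4g %s\n", x$equilibria$location[i],
                x$equilibria$stability[i]))
  cat(sprintf("  case: %s; predicted limit of P_A: %s\n", x$case_label,
              if (is.na(x$predicted_limit)) "undecided"
              else format(x$predicted_limit, digits = 6)))
  if (!is.na(x$basin_boundary))
    cat(sprintf("  basin boundary at p* = %g\n", x$basin_boundary))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Serialize a stability report to JSON
#'
#' @param report a `stability_report`.
#' @param path optional output file; when NULL the JSON string is returned.
#' @export
stability_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "stability_report"))
  obj <- list(
    payoff = report$payoff, k = report$k, p0 = report$p0,
    coefficients = as.list(report$coefficients),
    equilibria = report$equilibria,
    interior_root = report$interior_root,
    case_label = report$case_label,
    predicted_limit = report$predicted_limit,
    basin_boundary = report$basin_boundary,
    note = report$note)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
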