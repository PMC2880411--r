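test_that("coefficient formulas reproduce the hand-derived study values", {
  expect_equal(stability_coefficients(interaction_matrix(1, 0, 0, 1), 4),
               c(c0 = 20, c1 = 0, c2 = -20))
  expect_equal(stability_coefficients(interaction_matrix(0, 1, 1, 0), 4),
               c(c0 = 10, c1 = -30, c2 = 20))
  expect_equal(stability_coefficients(interaction_matrix(0, -1, -2, 0), 4),
               c(c0 = -9, c1 = 39, c2 = -30))
  expect_error(stability_coefficients(interaction_matrix(0, 1, 1, 0), 1),
               "k must")
})

test_that("c0 + c1 + c2 vanishes identically", {
  set.seed(61)
  rel <- vapply(1:10000, function(i) {
    co <- stability_coefficients(runif(4, -100, 100), sample(2:30, 1))
    abs(sum(co)) / max(1, max(abs(co)))
  }, numeric(1))
  expect_lt(max(rel), 1e-9)
})

test_that("equilibria carry the right locations and stability labels", {
  eq <- stability_equilibria(interaction_matrix(0, 1, 1, 0), 4)
  expect_equal(eq$location, c(0, 0.5, 1))
  expect_equal(eq$stability, c("unstable", "stable", "unstable"))
  eq2 <- stability_equilibria(interaction_matrix(0, -1, -2, 0), 4)
  expect_equal(eq2$location, c(0, 0.3, 1))
  expect_equal(eq2$stability, c("stable", "unstable", "stable"))
  # payoff-indifferent diagonal: degenerate
  eq3 <- stability_equilibria(interaction_matrix(1, 1, 1, 1), 4)
  expect_true(all(eq3$stability == "degenerate"))
  # c2 = 0 (a - b - c + d = 0): g is linear with the sign of c0
  eq4 <- stability_equilibria(interaction_matrix(1, 1, 0, 0), 4)
  expect_equal(eq4$location, c(0, 1))
  expect_equal(eq4$stability, c("unstable", "stable"))
})

test_that("the classifier reproduces every study configuration", {
  cases <- list(
    list(I = interaction_matrix(1, 0, 0, 1), p0 = 0.99,
         case = "A_dominates", limit = 1),
    list(I = interaction_matrix(0, -0.5, 1, 0), p0 = 0.99,
         case = "C_dominates", limit = 0),
    list(I = interaction_matrix(0, 1, 1, 0), p0 = 0.99,
         case = "stable_coexistence", limit = 0.5),
    list(I = interaction_matrix(0, 1, 1, 0), p0 = 0.40,
         case = "stable_coexistence", limit = 0.5),
    list(I = interaction_matrix(0, -1, -2, 0), p0 = 0.99,
         case = "bistable_threshold", limit = 1),
    list(I = interaction_matrix(0, -1, -2, 0), p0 = 0.20,
         case = "bistable_threshold", limit = 0))
  for (cs in cases) {
    rep <- classify_dynamics(cs$I, 4, cs$p0)
    expect_equal(rep$case_label, cs$case)
    expect_equal(rep$predicted_limit, cs$limit)
  }
  # bistable basin boundary is the interior root
  rep <- classify_dynamics(interaction_matrix(0, -1, -2, 0), 4, 0.99)
  expect_equal(rep$basin_boundary, 0.3)
})

test_that("boundary and tie cases are reported explicitly, never guessed", {
  I <- interaction_matrix(0, -1, -2, 0)
  tie <- classify_dynamics(I, 4, 0.3)  # exactly on the unstable threshold
  expect_true(is.na(tie$predicted_limit))
  expect_match(tie$note, "threshold")
  at0 <- classify_dynamics(I, 4, 0)
  expect_equal(at0$predicted_limit, 0)
  at1 <- classify_dynamics(I, 4, 1)
  expect_equal(at1$predicted_limit, 1)
  neu <- classify_dynamics(interaction_matrix(2, 2, 2, 2), 4, 0.4)
  expect_equal(neu$case_label, "neutral")
  expect_true(is.na(neu$predicted_limit))
})

test_that("cross-interaction payoffs mirror under A/C relabeling", {
  # for matrices [0 b; c 0] the swapped matrix is [0 c; b 0] and the interior
  # root maps to its mirror image: r + r' = 1 exactly
  set.seed(67)
  for (i in 1:200) {
    b <- runif(1, -2, 2); cc <- runif(1, -2, 2)
    if (abs(b + cc) < 1e-6) next
    k <- sample(3:8, 1)
    p0 <- runif(1, 0.05, 0.95)
    f <- classify_dynamics(interaction_matrix(0, b, cc, 0), k, p0)
    g <- classify_dynamics(interaction_matrix(0, cc, b, 0), k, 1 - p0)
    if (!is.na(f$interior_root))
      expect_equal(f$interior_root + g$interior_root, 1, tolerance = 1e-9)
    if (!is.na(f$predicted_limit) && !is.na(g$predicted_limit))
      expect_equal(f$predicted_limit + g$predicted_limit, 1, tolerance = 1e-9)
  }
})

test_that("stability reports serialize to JSON with the classification", {
  rep <- classify_dynamics(interaction_matrix(0, 1, 1, 0), 4, 0.99)
  js <- jsonlite::fromJSON(stability_report_json(rep))
  expect_equal(js$interior_root, 0.5)
  expect_equal(js$case_label, "stable_coexistence")
  expect_equal(js$predicted_limit, 0.5)
  expect_equal(js$coefficients$c2, 20)
})
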