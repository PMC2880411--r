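test_that("regular graphs have the requested degree and are deterministic", {
  net <- regular_network(10, 3, seed = 1)
  expect_true(all(apply(net$neighbors, 1, function(r) length(unique(r))) == 3))
  expect_error(regular_network(5, 3), "even")
  n1 <- regular_network(500, 4, seed = 11)
  n2 <- regular_network(500, 4, seed = 11)
  expect_identical(n1$neighbors, n2$neighbors)
  # no self loops, symmetry of adjacency
  expect_false(any(n1$neighbors == row(n1$neighbors)))
  for (v in sample(500, 20))
    for (u in n1$neighbors[v, ]) expect_true(v %in% n1$neighbors[u, ])
})

test_that("ring and torus topologies have the expected structure", {
  ring <- regular_network(8, 4, topology = "ring")
  expect_equal(sort(ring$neighbors[1, ]), c(2, 3, 7, 8))
  expect_error(regular_network(8, 3, topology = "ring"), "even k")
  torus <- regular_network(16, 4, topology = "torus")
  expect_true(all(rowSums(torus$neighbors > 0) == 4))
  expect_error(regular_network(15, 4, topology = "torus"),
               "N.*k must be even|perfect square")
  expect_error(regular_network(16, 6, topology = "torus"), "k = 4")
})

test_that("type assignment places exactly n_A cells, reproducibly", {
  net <- regular_network(100, 4, seed = 5)
  st <- assign_types(net, 100)
  expect_true(all(st$types == 1L))
  expect_error(assign_types(net, 101), "n_A")
  s1 <- assign_types(net, 30, seed = 9)
  s2 <- assign_types(net, 30, seed = 9)
  expect_identical(s1$types, s2$types)
  expect_equal(sum(s1$types), 30)
  cl <- assign_types(net, 30, seed = 9, placement = "clustered")
  expect_equal(sum(cl$types), 30)
})

test_that("state summary matches the hand-enumerated 4-cycle", {
  st <- cycle_state(c("A", "A", "C", "C"))
  sm <- summarize_state(st)
  expect_equal(sm$P_A, 0.5)
  expect_equal(sm$P_AA, 0.25); expect_equal(sm$P_CC, 0.25)
  expect_equal(sm$P_AC, 0.25); expect_equal(sm$P_CA, 0.25)
  expect_equal(sm$q_A_given_A, 0.5)
  # all-A state
  stA <- cycle_state(rep("A", 6))
  smA <- summarize_state(stA)
  expect_equal(smA$P_A, 1); expect_equal(smA$P_AA, 1)
  expect_equal(smA$q_A_given_A, 1)
  expect_equal(smA$P_CC + smA$P_AC + smA$q_A_given_C, 0)
  expect_equal(smA$absent, "C")
})

test_that("frequency identities hold and match the brute-force oracle", {
  set.seed(17)
  for (i in 1:10) {
    N <- sample(seq(10, 50, by = 2), 1)
    net <- regular_network(N, sample(c(3, 4, 6), 1), seed = i)
    st <- assign_types(net, sample(0:N, 1))
    sm <- summarize_state(st)
    orc <- oracle_summary(st)
    expect_equal(sm$P_AA, orc$P_AA); expect_equal(sm$P_AC, orc$P_AC)
    expect_equal(sm$P_CA, orc$P_CA); expect_equal(sm$P_CC, orc$P_CC)
    expect_equal(sm$q_A_given_A, orc$q_A_given_A)
    expect_equal(sm$q_A_given_C, orc$q_A_given_C)
    # exact identities
    expect_equal(sm$P_A + sm$P_C, 1, tolerance = 1e-12)
    expect_equal(sm$P_AA + sm$P_AC + sm$P_CA + sm$P_CC, 1, tolerance = 1e-12)
    expect_identical(sm$P_AC, sm$P_CA)
    if (sm$P_A > 0) {
      expect_equal(sm$q_A_given_A + sm$q_C_given_A, 1, tolerance = 1e-12)
      expect_equal(sm$P_AA, sm$q_A_given_A * sm$P_A, tolerance = 1e-12)
      expect_equal(sm$P_CA, sm$q_C_given_A * sm$P_A, tolerance = 1e-12)
    }
  }
})

test_that("complement relabeling swaps the A and C summaries", {
  set.seed(23)
  net <- regular_network(40, 4, seed = 3)
  st <- assign_types(net, 15)
  flip <- st; flip$types <- 1L - st$types
  a <- summarize_state(st); b <- summarize_state(flip)
  expect_equal(a$P_AA, b$P_CC); expect_equal(a$P_CC, b$P_AA)
  expect_equal(a$P_AC, b$P_CA)
  expect_equal(a$q_A_given_A, b$q_C_given_C)
  expect_equal(a$q_A_given_C, b$q_C_given_A)
})

test_that("graph fixtures round-trip through plain-text files", {
  net <- regular_network(20, 4, seed = 2)
  st <- assign_types(net, 7, seed = 3)
  ef <- tempfile(fileext = ".txt"); lf <- tempfile(fileext = ".csv")
  write_graph_fixture(st, ef, lf)
  back <- read_graph_fixture(ef, lf)
  expect_identical(back$types, st$types)
  expect_equal(back$network$k, 4)
  # same adjacency as sets
  for (v in seq_len(20))
    expect_setequal(back$network$neighbors[v, ], st$network$neighbors[v, ])
  expect_equal(summarize_state(back), summarize_state(st))
  unlink(c(ef, lf))
})
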