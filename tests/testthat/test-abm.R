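test_that("a step changes at most one label and conserves the population", {
  set.seed(31)
  net <- regular_network(50, 4, seed = 1)
  st <- assign_types(net, 20, seed = 2)
  I <- interaction_matrix(0, 1, 1, 0)
  for (i in 1:50) {
    out <- ee_step(st, I, 0.05)
    expect_lte(sum(out$state$types != st$types), 1)
    expect_equal(length(out$state$types), 50)
    st <- out$state
    n_A <- sum(st$types)
    expect_true(n_A >= 0 && n_A <= 50)
    if (n_A == 0 || n_A == 50) break
  }
})

test_that("stepping an absorbed state is refused and run() halts there", {
  net <- regular_network(20, 4, seed = 1)
  all_A <- assign_types(net, 20)
  expect_error(ee_step(all_A, interaction_matrix(1, 0, 0, 1), 0.01),
               "absorbed")
  tr <- run_ee(all_A, interaction_matrix(1, 0, 0, 1), 0.01, generations = 5)
  expect_true(attr(tr, "absorbed"))
  expect_equal(nrow(tr), 1)
  expect_equal(attr(tr, "absorption_generation"), 0)
})

test_that("compiled loop is bit-identical to the pure-R reference step", {
  net <- regular_network(30, 4, seed = 7)
  st0 <- assign_types(net, 12, seed = 8)
  I <- interaction_matrix(0, -0.5, 1, 0)
  for (cvl in c(TRUE, FALSE)) {
    tr <- run_ee(st0, I, 0.05, generations = 25, unit = "event",
                 record_every = 1, seed = 99, count_vacated_link = cvl)
    set.seed(99)
    st <- st0
    nA <- numeric(25)
    for (i in 1:25) {
      out <- ee_step(st, I, 0.05, count_vacated_link = cvl)
      st <- out$state
      nA[i] <- sum(st$types)
    }
    expect_identical(tr$n_A[-1], nA)
    expect_identical(attr(tr, "final_types"), st$types)
  }
})

test_that("at omega = 0 the replacement probability equals the local A share", {
  net <- regular_network(60, 4, seed = 4)
  st <- assign_types(net, 25, seed = 5)
  I <- interaction_matrix(2, -1, 3, 0.5)  # payoffs must not matter at omega 0
  set.seed(6)
  for (i in 1:100) {
    out <- ee_step(st, I, 0)
    tal <- neighbor_tally(st, out$record$exited_vertex)
    expect_equal(out$record$prob_A, tal$K_A / 4)
    st <- out$state
  }
})

test_that("neutral drift fixes type A at its initial frequency", {
  fix <- vapply(1:300, function(s) {
    set.seed(s)
    net <- regular_network(100, 4)
    st <- assign_types(net, 30)
    tr <- run_ee(st, interaction_matrix(1, 1, 1, 1), 0, generations = 2e5,
                 unit = "event", record_every = 2e5)
    tr$n_A[nrow(tr)]
  }, numeric(1))
  expect_true(all(fix %in% c(0, 100)))  # all runs absorbed
  phat <- mean(fix == 100)
  se <- sqrt(0.3 * 0.7 / 300)
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("trajectories are reproducible and the event budget is respected", {
  net <- regular_network(100, 4, seed = 1)
  st <- assign_types(net, 50, seed = 2)
  I <- interaction_matrix(0, 1, 1, 0)
  t1 <- run_ee(st, I, 0.01, generations = 10, seed = 42)
  t2 <- run_ee(st, I, 0.01, generations = 10, seed = 42)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  e1 <- run_ee(st, I, 0.01, generations = 1, unit = "event", seed = 1)
  expect_equal(attr(e1, "config")$n_events, 1)
  expect_error(run_ee(st, I, 0.01, generations = 0), "generations")
})

test_that("ensembles aggregate runs, extend absorbed runs, and reduce at n_runs = 1", {
  I <- interaction_matrix(0, 1, 1, 0)
  ens <- ensemble_ee(I, N = 60, k = 4, n_A_initial = 30, omega = 0.01,
                     generations = 50, n_runs = 8, base_seed = 3)
  expect_false(anyNA(ens$n_A))
  expect_equal(dim(ens$n_A), c(8, 51))
  expect_equal(ens$mean_n_A, colMeans(ens$n_A))
  expect_equal(unname(ens$fixation_fraction["A"] + ens$fixation_fraction["C"]),
               mean(ens$final_n_A %in% c(0, 60)))
  # absorbed runs carry their absorbing value to the end
  ab <- which(!is.na(ens$absorption_generation))
  for (i in ab) expect_true(all(ens$n_A[i, ncol(ens$n_A)] == ens$final_n_A[i]))
  # n_runs = 1 reduces to the single trajectory
  one <- ensemble_ee(I, N = 60, k = 4, n_A_initial = 30, omega = 0.01,
                     generations = 20, n_runs = 1, base_seed = 7)
  set.seed(7)
  net <- regular_network(60, 4)
  st <- assign_types(net, 30)
  tr <- run_ee(st, I, 0.01, generations = 20)
  expect_equal(one$final_n_A, tr$n_A[nrow(tr)])
  expect_equal(one$n_A[1, as.integer(tr$generation) + 1L], tr$n_A)
})

test_that("relabeling types, payoffs and the start frequency mirrors the dynamics", {
  # fixation fraction of A under (I, p0) should match fixation fraction of C
  # under the swapped matrix at 1 - p0, within Monte-Carlo error
  I <- interaction_matrix(0.5, -0.2, 0.8, 0.1)
  Isw <- interaction_matrix(0.1, 0.8, -0.2, 0.5)  # a<->d, b<->c
  runs <- 150
  fixA <- mean(vapply(seq_len(runs), function(s) {
    set.seed(s)
    st <- assign_types(regular_network(40, 4), 16)
    tr <- run_ee(st, I, 0.05, generations = 1e5, unit = "event",
                 record_every = 1e5, validate = TRUE)
    as.numeric(tr$n_A[nrow(tr)] == 40)
  }, numeric(1)))
  fixC <- mean(vapply(seq_len(runs), function(s) {
    set.seed(s + runs)
    st <- assign_types(regular_network(40, 4), 24)
    tr <- run_ee(st, Isw, 0.05, generations = 1e5, unit = "event",
                 record_every = 1e5, validate = TRUE)
    as.numeric(tr$n_A[nrow(tr)] == 0)
  }, numeric(1)))
  se <- sqrt(fixA * (1 - fixA) / runs + fixC * (1 - fixC) / runs + 1e-6)
  expect_lt(abs(fixA - fixC), 4 * se + 0.02)
})

test_that("measured q_A|A tracks the fast-manifold equilibrium at weak selection", {
  I <- interaction_matrix(0, 1, 1, 0)
  for (k in c(4, 5, 6)) {
    set.seed(100 + k)
    st <- assign_types(regular_network(2000, k), 1000)
    tr <- run_ee(st, I, 0.01, generations = 400, record_every = 2)
    late <- tr[tr$generation > 150, ]
    dev <- late$q_A_given_A - qAA_fast_equilibrium(late$P_A, k)
    expect_lt(abs(mean(dev)), 0.03)
  }
})

test_that("trajectory CSV has the documented columns", {
  st <- assign_types(regular_network(40, 4, seed = 1), 20, seed = 2)
  tr <- run_ee(st, interaction_matrix(0, 1, 1, 0), 0.01, generations = 5,
               seed = 3)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  got <- utils::read.csv(f)
  expect_identical(names(got),
    c("generation", "n_A", "P_A", "P_AA", "P_AC", "P_CC", "q_A_given_A"))
  expect_equal(got$n_A, tr$n_A)
  unlink(f)
})
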