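dm1 <- death_matrix(rps_payoff(1))

test_that("init_state places the requested composition", {
  st <- init_state(fully_connected(9), "equal", 1)
  expect_equal(unname(st$counts), c(3, 3, 3))
  st10 <- init_state(fully_connected(10), "equal", 5)
  expect_equal(sort(unname(st10$counts)), c(3, 3, 4))
  expect_identical(init_state(fully_connected(30), "equal", 7)$species,
                   init_state(fully_connected(30), "equal", 7)$species)
  expect_error(init_state(fully_connected(9), c(3, 3, 4)), "summing to N")
})

test_that("monomorphic states are absorbing up to relabelling", {
  net <- fully_connected(12)
  st <- init_state(net, c(12, 0, 0), 1)
  out <- rgb_update(st, dm1, seed = 3, n = 500)
  expect_equal(unname(out$counts), c(12, 0, 0))
  expect_equal(out$updates, 500)
})

test_that("one-step oracle is exact on symmetric and monomorphic states", {
  net <- fully_connected(3)
  or <- one_step_distribution_oracle(init_state(net, c(1, 1, 1), 1), dm1)
  expect_equal(or$expected_dN, c(0, 0, 0), tolerance = 1e-14)
  expect_equal(sum(or$outcomes$prob), 1, tolerance = 1e-14)
  mono <- one_step_distribution_oracle(
    init_state(fully_connected(8), c(8, 0, 0), 1), dm1)
  expect_equal(nrow(mono$outcomes), 1L)
  expect_equal(mono$outcomes$prob, 1)
  expect_error(
    one_step_distribution_oracle(init_state(fully_connected(200), "equal", 1),
                                 dm1),
    "too large")
})

test_that("oracle expectation approaches the mean-field formula as 1/N", {
  # E[dN_i] -> sum_jk (D_kj - D_ij) x_i x_j x_k with O(1/N) corrections
  # from neighbour exclusion on the fully-connected network
  D <- dm1$entries
  mean_field <- function(x) {
    vapply(1:3, function(i) {
      tot <- 0
      for (j in 1:3) for (k in 1:3)
        tot <- tot + (D[k, j] - D[i, j]) * x[i] * x[j] * x[k]
      tot
    }, 0)
  }
  err <- vapply(c(30, 60, 99), function(N) {
    comp <- round(N * c(0.5, 0.3, 0.2))
    comp[1] <- N - sum(comp[-1])
    st <- init_state(fully_connected(N), comp, 1)
    x <- comp / N
    max(abs(one_step_distribution_oracle(st, dm1)$expected_dN -
              mean_field(x)))
  }, 0)
  expect_true(all(diff(err) < 0))                 # shrinking with N
  expect_lt(err[3] / err[1], 30 / 99 * 1.5)       # roughly 1/N decay
})

test_that("simulator one-step distribution matches the enumeration oracle", {
  for (spec in list(list(net = fully_connected(6), comp = c(2, 2, 2)),
                    list(net = grid2d(3), comp = c(3, 3, 3)))) {
    st <- init_state(spec$net, spec$comp, 11)
    or <- one_step_distribution_oracle(st, dm1)
    tal <- one_step_tally(st, dm1, seed = 17, K = 1e5)
    Dm <- tal$deaths
    obs <- c(tal$n - sum(Dm[row(Dm) != col(Dm)]))
    probs <- c(or$outcomes$prob[or$outcomes$dA == 0 & or$outcomes$dB == 0 &
                                  or$outcomes$dC == 0])
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      obs <- c(obs, Dm[i, j])
      probs <- c(probs, or$pair[i, j])
    }
    keep <- probs > 0
    gof <- suppressWarnings(
      stats::chisq.test(obs[keep], p = probs[keep] / sum(probs[keep])))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("extinction records behave at the boundaries and deterministically", {
  net <- fully_connected(20)
  st <- init_state(net, c(20, 0, 0), 1)
  rec <- run_to_extinction(st, dm1, seed = 1)
  expect_equal(rec$t_ex, 0)
  expect_equal(rec$first_extinct, "B")  # tie broken by species order
  expect_false(rec$censored)
  st2 <- init_state(net, "equal", 2)
  r1 <- run_to_extinction(st2, dm1, seed = 99)
  r2 <- run_to_extinction(st2, dm1, seed = 99)
  expect_identical(r1, r2)
  expect_gt(r1$t_ex, 0)
  # censoring is flagged, not raised
  rc <- run_to_extinction(st2, dm1, seed = 5, max_updates = 10)
  expect_true(rc$censored)
})

test_that("critical-point extinction time is of order N generations", {
  net <- fully_connected(30)
  ens <- run_ensemble(net, dm1, 300, seed = 4)
  expect_true(all(!ens$censored))
  expect_gt(mean(ens$t_ex) / 30, 0.02)
  expect_lt(mean(ens$t_ex) / 30, 5)
})

test_that("population size is conserved along trajectories and snapshots", {
  net <- grid2d(6)
  run <- sample_snapshots(net, dm1, burn_in = 1, interval = 0.5, count = 5,
                          seed = 8, traj_every = 0.25)
  for (sn in run$snapshots)
    expect_equal(length(sn) - sum(tabulate(as.vector(sn) + 1L, 3)), 0L)
  expect_true(all(rowSums(run$trajectory[, c("A", "B", "C")]) == 36))
  expect_equal(run$times, 1 + 0.5 * (seq_along(run$snapshots) - 1))
})

test_that("snapshot sampling truncates on extinction", {
  net <- grid2d(3)
  run <- sample_snapshots(net, dm1, burn_in = 50, interval = 50,
                          count = 50, seed = 2)
  expect_true(run$truncated)
  expect_lt(length(run$snapshots), 50)
})

test_that("cyclic relabelling leaves the extinction-time law unchanged", {
  net <- fully_connected(30)
  t1 <- run_ensemble(net, dm1, 500, seed = 31, composition = c(15, 10, 5))$t_ex
  # relabel A->B->C->A: composition rotates, death matrix is invariant
  t2 <- run_ensemble(net, dm1, 500, seed = 87, composition = c(5, 15, 10))$t_ex
  ks <- suppressWarnings(stats::ks.test(t1, t2))
  expect_gt(ks$p.value, 0.01)
})

test_that("rescaled times are invariant to the rescaling factor s", {
  net <- fully_connected(60)
  dm_min <- death_matrix(rps_payoff(1))             # s = 2
  dm_2x <- death_matrix(rps_payoff(1), s = 4)       # twice the minimum
  ta <- run_ensemble(net, dm_min, 500, seed = 13)$t_ex
  tb <- run_ensemble(net, dm_2x, 500, seed = 14)$t_ex
  expect_equal(mean(ta) / mean(tb), 1, tolerance = 0.1)
  ks <- suppressWarnings(stats::ks.test(ta, tb))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensemble mean path on a large FC network tracks the replicator", {
  g <- 1.5
  P <- rps_payoff(g)
  dm <- death_matrix(P)
  net <- fully_connected(3000)
  times <- seq(0, 4, by = 0.5)
  reps <- 60
  seeds <- withr::with_seed(21L, sample.int(1e6, reps))
  acc <- 0
  for (r in seq_len(reps)) {
    st <- init_state(net, c(1500, 900, 600), seeds[r])
    tr <- count_trajectory(st, dm, t_max = 4, sample_every = 0.5,
                           seed = seeds[r] + 1L)
    acc <- acc + as.matrix(tr[, c("A", "B", "C")]) / 3000
  }
  emp <- acc / reps
  det <- replicator_integrate(c(0.5, 0.3, 0.2), times, P = P)
  expect_lt(max(abs(emp - as.matrix(det[, c("a", "b", "c")]))), 0.015)
})
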