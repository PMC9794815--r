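random_snapshots <- function(n, L, probs = c(1, 1, 1) / 3, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(k) {
    matrix(sample(0:2, L * L, replace = TRUE, prob = probs), L, L)
  }))
}

test_that("spatial estimator obeys its exact identities", {
  L <- 20
  mono <- list(matrix(0L, L, L))
  cm <- spatial_correlation(mono, r_max = 5)
  expect_equal(cm$C, rep(0, 6))
  # iid equal composition: C(0) = 2/3, C(r >= 1) ~ 0
  snaps <- random_snapshots(60, 30, seed = 4)
  est <- spatial_correlation(snaps, r_max = 8)
  xb <- est$means
  expect_equal(est$C[1], 1 - sum(xb^2), tolerance = 1e-12) # exact identity
  expect_equal(est$C[1], 2 / 3, tolerance = 0.01)
  expect_lt(max(abs(est$C[-1])), 0.005)
  # identity also holds for arbitrary (unequal) compositions
  est2 <- spatial_correlation(random_snapshots(10, 15, c(5, 3, 2) / 10,
                                               seed = 9), r_max = 4)
  expect_equal(est2$C[1], 1 - sum(est2$means^2), tolerance = 1e-12)
  expect_error(spatial_correlation(snaps, r_max = 15), "L/2")
})

test_that("correlations are invariant under cyclic species relabelling", {
  snaps <- random_snapshots(8, 12, c(5, 3, 2) / 10, seed = 2)
  rel <- lapply(snaps, function(m) (m + 1L) %% 3L)
  e1 <- spatial_correlation(snaps, 4)
  e2 <- spatial_correlation(rel, 4)
  expect_equal(e1$C, e2$C, tolerance = 1e-12)
  ser <- vapply(snaps, function(m) as.integer(m), integer(144))
  ser_rel <- (ser + 1L) %% 3L
  t1 <- temporal_correlation(ser, dt = 1, lag_max = 5)
  t2 <- temporal_correlation(ser_rel, dt = 1, lag_max = 5)
  expect_equal(t1$C, t2$C, tolerance = 1e-12)
})

test_that("temporal estimator handles frozen and shuffled series", {
  withr::with_seed(3, {
    col <- sample(0:2, 400, replace = TRUE)
    frozen <- matrix(col, 400, 30) # constant in time
  })
  ef <- temporal_correlation(frozen, dt = 0.5, lag_max = 10)
  expect_equal(ef$C, rep(ef$C[1], length(ef$C)), tolerance = 1e-12)
  expect_equal(ef$t, seq(0, 10, by = 0.5))
  withr::with_seed(5, {
    iid <- matrix(sample(0:2, 400 * 50, replace = TRUE), 400, 50)
  })
  ei <- temporal_correlation(iid, dt = 1, lag_max = 10)
  expect_lt(max(abs(ei$C[-1])), 0.01)
  expect_gt(ei$C[1], 0.6)
})

test_that("spatial fit recovers exponential decays", {
  r <- 0:20
  exact <- list(r = r, C = 0.6 * exp(-r / 3.3))
  f0 <- fit_spatial(exact)
  expect_equal(f0$A_s, 0.6, tolerance = 1e-6)
  expect_equal(f0$xi, 3.3, tolerance = 1e-6)
  withr::with_seed(6, {
    noisy <- list(r = r, C = 0.6 * exp(-r / 3.3) + rnorm(21, 0, 0.005))
  })
  fn <- fit_spatial(noisy)
  expect_equal(fn$A_s, 0.6, tolerance = 0.02)
  expect_equal(fn$xi, 3.3, tolerance = 0.15)
  expect_error(fit_spatial(list(r = 0:2, C = c(1, 0.5, 0.2))), ">= 4")
})

test_that("temporal fit recovers damped cosines and degenerate limits", {
  tt <- seq(0, 150, by = 0.5)
  truth <- list(A = 0.2, omega = 0.18, phi = 0.2, tau = 38)
  withr::with_seed(7, {
    C <- truth$A * cos(truth$omega * tt + truth$phi) * exp(-tt / truth$tau) +
      rnorm(length(tt), 0, 0.003)
  })
  f <- fit_temporal(list(t = tt, C = C))
  expect_equal(f$A_t, truth$A, tolerance = 0.1 * truth$A)
  expect_equal(f$omega, truth$omega, tolerance = 0.1 * truth$omega)
  expect_equal(f$phi, truth$phi, tolerance = 0.1)
  expect_equal(f$tau, truth$tau, tolerance = 0.1 * truth$tau)
  expect_false(f$flat_phase)
  # pure exponential: omega ~ 0 with the flat-phase flag
  fe <- fit_temporal(list(t = tt, C = 0.5 * exp(-tt / 20)))
  expect_true(fe$flat_phase)
  expect_lt(fe$omega * 150, pi / 8)
  expect_error(fit_temporal(list(t = 0:5, C = rep(1, 6))), ">= 8")
})

test_that("measured lattice frequency does not track the replicator one", {
  # omega_0 = (g+1)/(2 sqrt(3)) grows 67% from g = 0.5 to g = 1.5.  The
  # comparison must be made in a g-independent time unit: the rescaled
  # unit itself carries a factor s = g + 1, which would mimic exactly
  # the omega_0 trend.  Per generation (N updates) the steady-state
  # lattice oscillation stays put while omega_0 does not.
  om_gen <- vapply(c(0.5, 1.5), function(g) {
    res <- correlation_analysis(L = 40, g = g, seed = 3, burn_in = 200,
                                n_gen = 500, r_max = 10,
                                lag_max_gen = 300)
    res$fit_t$omega / res$s # rad per rescaled unit -> rad per generation
  }, 0)
  ratio_measured <- om_gen[2] / om_gen[1]
  ratio_intrinsic <- intrinsic_frequency(1.5) / intrinsic_frequency(0.5)
  expect_lt(abs(ratio_measured - 1), (ratio_intrinsic - 1) / 2)
})
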