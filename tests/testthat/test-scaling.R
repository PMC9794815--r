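test_that("measure_table reports SEs, censoring and reproduces itself", {
  cells <- sweep_cells("fc", c(12, 24), 1)
  one <- measure_table(cells[1, ], reps = 1, seed = 2)
  expect_true(is.na(one$se_t))
  ta <- measure_table(cells, reps = 40, seed = 9)
  tb <- measure_table(cells, reps = 40, seed = 9)
  expect_equal(ta$mean_t, tb$mean_t)
  # a hopeless cap censors every run and flags the cell unusable
  cen <- measure_table(cells[2, ], reps = 5, seed = 3, max_updates = 5)
  expect_equal(cen$censored_frac, 1)
  expect_false(cen$usable)
})

test_that("critical column means grow with N", {
  tb <- measure_table(sweep_cells("fc", c(30, 60, 120), 1), reps = 150,
                      seed = 21)
  expect_true(all(diff(tb$mean_t) > 0))
})

test_that("fit_alpha is exact on noiseless power laws", {
  Ns <- c(30, 60, 120, 240)
  expect_equal(fit_alpha(synthetic_table(Ns, 1, 2 * Ns)), 1,
               tolerance = 1e-12)
  expect_equal(fit_alpha(synthetic_table(Ns, 1, 0.5 * Ns^2)), 2,
               tolerance = 1e-12)
  set.seed(10)
  for (a in runif(5, 0.3, 2.5))
    expect_equal(fit_alpha(synthetic_table(Ns, 1, 3 * Ns^a)), a,
                 tolerance = 1e-10)
  expect_error(fit_alpha(synthetic_table(c(30, 60), 1, c(1, 2))),
               "3 distinct N")
})

test_that("collapse applies the definitional mapping", {
  tb <- synthetic_table(c(10, 20, 30), c(1.2, 1.2, 0.9), c(5, 10, 15))
  cl <- collapse(tb, 1, 1)
  expect_equal(cl$x, c(10, 20, 30) * abs(c(1.2, 1.2, 0.9) - 1))
  expect_equal(cl$y, c(5, 10, 15) / c(10, 20, 30))
  expect_equal(cl$branch, c("stable", "stable", "unstable"))
  # critical rows land on x = 0 at one shared level when t = cN
  tcrit <- synthetic_table(c(10, 20, 40), 1, 3 * c(10, 20, 40))
  clc <- collapse(tcrit, 1, 1)
  expect_true(all(clc$x == 0))
  expect_equal(clc$y, rep(3, 3))
  expect_equal(unique(clc$branch), "critical")
})

test_that("scaling-form data collapse exactly at the generating exponents", {
  syn <- scaling_form_table(A = 0.7)
  expect_lt(rgbgame:::collapse_objective(syn, 1, 1), 1e-20)
  expect_gt(rgbgame:::collapse_objective(syn, 1, 0.5), 1e-3)
  fb <- fit_beta(syn, 1)
  expect_equal(fb$beta, 1, tolerance = 0.02)
  # objective profile has its global scan minimum at the truth
  prof <- fb$profile
  expect_equal(prof$beta[which.min(prof$objective)], 1, tolerance = 0.051)
})

test_that("branch fits recover synthetic laws exactly", {
  Ns <- c(50, 100, 200, 400)
  st <- fit_stable_branch(synthetic_table(Ns, 1.3, Ns * exp(Ns / 50)))
  expect_equal(st$branch, "stable")
  expect_equal(st$N_plus, 50, tolerance = 1e-9)
  expect_equal(st$A, 1 / (50 * 0.3), tolerance = 1e-9)
  lg <- fit_unstable_branch(synthetic_table(Ns, 0.7, 3 * log(Ns) + 1))
  expect_equal(lg$slope, 3, tolerance = 1e-9)
  expect_equal(lg$intercept, 1, tolerance = 1e-9)
  # a log-law table is not the stable branch
  notst <- fit_stable_branch(synthetic_table(Ns, 1.3, 3 * log(Ns) + 1))
  expect_equal(notst$branch, "not_stable_branch")
  # and exponential data make a demonstrably poor log fit
  cmp <- classify_branch(synthetic_table(Ns, 1.3, Ns * exp(Ns / 50)))
  expect_equal(cmp$class, "exponential")
  expect_gt(cmp$ratio, 10)
})

test_that("branch classification ignores the time unit", {
  Ns <- c(50, 100, 200, 400)
  tb <- synthetic_table(Ns, 1.2, Ns * exp(Ns / 80))
  tb7 <- tb
  tb7$mean_t <- tb$mean_t * 7
  c1 <- classify_branch(tb)
  c2 <- classify_branch(tb7)
  expect_equal(c1$class, c2$class)
  expect_equal(c1$ratio, c2$ratio, tolerance = 1e-9)
})

test_that("critical gain is bracketed on a constructed sweep", {
  gs <- seq(0.8, 1.2, by = 0.05)
  Ns <- c(60, 120, 240)
  rows <- lapply(gs, function(g) {
    t <- if (g > 1) Ns * exp(Ns * (g - 1) / 40) else 20 * log(Ns) / (g + 1)
    synthetic_table(Ns, g, t)
  })
  tb <- do.call(rbind, rows)
  est <- estimate_critical_gain(tb)
  expect_gte(est$g_c, 0.95)
  expect_lte(est$g_c, 1.05)
  expect_lte(diff(est$ci), 0.1 + 1e-12)
  expect_error(estimate_critical_gain(synthetic_table(Ns, 1.2,
                                                      Ns * exp(Ns / 50))),
               "sweep")
})
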