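# shared fixture builders (everything generated in code; no stored data)

# minimal extinction-table skeleton for fit-level tests
synthetic_table <- function(N, g, mean_t, s = 2, kind = "fc") {
  data.frame(kind = kind, N = N, L = NA_integer_, g = g, s = s,
             n_reps = 1000L, n_used = 1000L, mean_t = mean_t,
             se_t = 0, censored_frac = 0, usable = TRUE)
}

# dataset drawn exactly from the scaling form t = N^alpha * F(N^beta dg),
# F(x) = exp(a x) on both sides
scaling_form_table <- function(A = 0.7, alpha = 1, beta = 1,
                               Ns = c(60, 120, 240),
                               gs = c(0.85, 0.9, 0.95, 1.05, 1.1, 1.15)) {
  cells <- expand.grid(N = Ns, g = gs)
  synthetic_table(cells$N, cells$g,
                  cells$N^alpha * exp(A * cells$N^beta * abs(cells$g - 1)))
}

# cyclic relabelling A -> B -> C -> A applied to a species vector
relabel_cyclic <- function(species) (species + 1L) %% 3L

expect_simplex <- function(x, tol = 1e-9) {
  expect_lt(abs(sum(x) - 1), tol)
  expect_true(all(x >= -tol))
}
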