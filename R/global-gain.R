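#' Characteristic constant of the exponential extinction trend
#'
#' Measures fresh extinction data on one network kind at a fixed local
#' gain across several sizes, checks that the exponential (stable) trend
#' beats the logarithmic one, and returns the characteristic constant
#' `N_plus` of `T_ex ~ N exp(N / N_plus)` with a bootstrap standard
#' error (cells resampled from their per-replicate times).
#'
#' @param kind `"fc"` or `"grid"`.
#' @param g local gain.
#' @param sizes N values (fc) or L values (grid), at least 3.
#' @param reps replicates per cell.
#' @param seed master seed.
#' @param n_boot bootstrap resamples for the SE.
#' @param max_updates per-run cap.
#' @param censor_max maximum tolerated censored fraction per cell.
#' @return list with `N_plus`, `se`, `fit` (the `branch_fit`), `table`,
#'   `comparison`; or, when the branch test fails, a list with
#'   `stable = FALSE` and the comparison diagnostics.
#' @export
characteristic_constant <- function(kind, g, sizes, reps, seed = 1L,
                                    n_boot = 200, max_updates = 1e9,
                                    censor_max = 0.05) {
  tb <- measure_table(sweep_cells(kind, sizes, g), reps, seed, max_updates)
  cmp <- classify_branch(tb, censor_max)
  if (cmp$class != "exponential")
    return(list(stable = FALSE, comparison = cmp, table = tb))
  fit <- fit_stable_branch(tb, censor_max = censor_max)
  if (fit$branch != "stable")
    return(list(stable = FALSE, comparison = cmp, table = tb))
  boots <- withr::with_seed(as.integer(seed) %% 1000003L + 7L, {
    vapply(seq_len(n_boot), function(b) {
      tb2 <- tb
      tb2$mean_t <- vapply(tb$raw, function(v) {
        mean(v[sample.int(length(v), replace = TRUE)])
      }, 0)
      f <- stats::lm(log(mean_t / N) ~ N, data = tb2[tb2$usable, ])
      sl <- unname(stats::coef(f)[2])
      if (sl > 0) 1 / sl else NA_real_
    }, 0)
  })
  list(stable = TRUE, N_plus = fit$N_plus,
       se = stats::sd(boots, na.rm = TRUE), fit = fit, table = tb,
       comparison = cmp)
}

#' Reference curve N_plus(G) on the fully-connected network
#'
#' Tabulates the characteristic constant on the fully-connected network
#' over a grid of gains G > 1 and equips it with a monotone interpolant,
#' so a characteristic constant measured on any other network can be
#' inverted into a global gain.  `N_plus = 1/(A dG)` shrinks as G moves
#' away from the critical gain; a non-monotone tabulation (noise) is
#' refused rather than inverted.
#'
#' @param G_grid gains, all > 1, increasing.
#' @param sizes N values for the stable-branch fits.
#' @param reps replicates per cell.
#' @param seed master seed.
#' @param ... passed to [characteristic_constant()].
#' @return a `reference_curve`: data.frame (G, N_plus, se) plus
#'   interpolants in attributes.
#' @export
build_reference_curve <- function(G_grid, sizes, reps, seed = 1L, ...) {
  stopifnot(all(G_grid > 1), !is.unsorted(G_grid))
  seeds <- derive_seeds(seed, length(G_grid))
  rows <- lapply(seq_along(G_grid), function(k) {
    cc <- characteristic_constant("fc", G_grid[k], sizes, reps, seeds[k],
                                  ...)
    if (!isTRUE(cc$stable))
      stop(sprintf("G = %g not in the stable regime on FC", G_grid[k]),
           call. = FALSE)
    data.frame(G = G_grid[k], N_plus = cc$N_plus, se = cc$se)
  })
  curve <- do.call(rbind, rows)
  if (is.unsorted(rev(curve$N_plus), strictly = TRUE))
    stop("tabulated N_plus(G) is not strictly decreasing; refuse to invert",
         call. = FALSE)
  structure(curve, class = c("reference_curve", "data.frame"))
}

# monotone piecewise-cubic inverse interpolation N_plus -> G
ref_invert <- function(ref, n_plus) {
  # work in log N_plus: the curve is close to 1/(A dG)
  f <- stats::splinefun(rev(log(ref$N_plus)), rev(ref$G), method = "hyman")
  f(log(n_plus))
}

#' Map a local gain to the global gain
#'
#' Matches the characteristic constant measured on a network at local
#' gain g with the fully-connected reference curve: the global gain G
#' solves `N_plus(network, g) = N_plus^FC(G)`.  By construction G = g on
#' the fully-connected network itself.  Values of N_plus outside the
#' tabulated reference range are refused (no extrapolation).
#'
#' @param cc result of [characteristic_constant()] on the target
#'   network, or a list with `N_plus` and `se`.
#' @param ref a `reference_curve`.
#' @return list with `G`, `ci` (from propagating the N_plus SEs in
#'   quadrature through the inverse interpolant) and `N_plus`.
#' @export
map_global_gain <- function(cc, ref) {
  if (!isTRUE(cc$stable %||% TRUE))
    stop("characteristic constant not available: not in stable regime",
         call. = FALSE)
  np <- cc$N_plus
  if (np < min(ref$N_plus) || np > max(ref$N_plus))
    stop(sprintf(
      "N_plus = %.3g outside reference range [%.3g, %.3g]; extrapolation refused",
      np, min(ref$N_plus), max(ref$N_plus)), call. = FALSE)
  G <- ref_invert(ref, np)
  # SE of the target in quadrature with the local reference SE
  se_ref <- stats::approx(ref$G, ref$se, xout = G, rule = 2)$y
  se_np <- sqrt((cc$se %||% 0)^2 + se_ref^2)
  # 95% interval, clipped to the invertible range
  lo <- max(np - 1.96 * se_np, min(ref$N_plus))
  hi <- min(np + 1.96 * se_np, max(ref$N_plus))
  ci <- sort(c(ref_invert(ref, hi), ref_invert(ref, lo)))
  list(G = G, ci = ci, N_plus = np)
}
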