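#' Replicator right-hand side
#'
#' Frequency dynamics `dx_i/dt = (f_i - phi) x_i / s` with fitness
#' `f_i = sum_j P_ij x_j` and average fitness `phi = sum_i f_i x_i`.
#' For the cyclic payoff matrix this reduces to
#' `da/dt = (g c - b) a - phi a` (and cyclic permutations) with
#' `phi = (g - 1)(ab + bc + ca)`.  The slowdown `s` matches the
#' death-matrix rescaling so the deterministic RGB limit can be compared
#' directly.
#'
#' @param x frequency vector (a, b, c) on the simplex.
#' @param P 3x3 payoff matrix.
#' @param s slowdown factor (>= 0), default 1 (bare replicator).
#' @param tol simplex tolerance.
#' @return tangent vector summing to zero.
#' @export
replicator_rhs <- function(x, P, s = 1, tol = 1e-8) {
  check_simplex(x, tol)
  f <- as.vector(unclass(P) %*% x)
  phi <- sum(f * x)
  (f - phi) * x / s
}

check_simplex <- function(x, tol = 1e-8) {
  if (length(x) != 3L || any(!is.finite(x)))
    stop("x must be three finite frequencies", call. = FALSE)
  if (any(x < -tol) || abs(sum(x) - 1) > tol)
    stop("x is not on the simplex", call. = FALSE)
  invisible(x)
}

#' Death-version replicator right-hand side
#'
#' `dx_i/dt = -d_i x_i + phi_d x_i` with frequency-dependent death
#' probability `d_i = sum_j D_ij x_j` and population average
#' `phi_d = sum_i d_i x_i`.  For a death matrix built from payoff `P`
#' with factor `s` this is identically `replicator_rhs(x, P, s)` -- the
#' deterministic content of the time rescaling `T_ex = T_RGB / s`.
#'
#' @param x frequency vector on the simplex.
#' @param death a `death_matrix`.
#' @inheritParams replicator_rhs
#' @export
death_rhs <- function(x, death, tol = 1e-8) {
  check_simplex(x, tol)
  d <- as.vector(death$entries %*% x)
  phi_d <- sum(d * x)
  (-d + phi_d) * x
}

# ---- adaptive Dormand-Prince 5(4) -------------------------------------
# No ODE-solver package ships with the target library, so a compact
# textbook RK45 with PI step control lives here.  The systems integrated
# are 3-dimensional polynomial flows; this is more than adequate.
dopri5 <- function(f, y0, times, rtol = 1e-10, atol = 1e-12, h0 = 1e-3,
                   project = identity) {
  A <- list(c(1 / 5),
            c(3 / 40, 9 / 40),
            c(44 / 45, -56 / 15, 32 / 9),
            c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
            c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176,
              -5103 / 18656),
            c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  y <- y0
  t <- times[1]
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y0
  h <- h0
  k1 <- f(y)
  for (m in 2:length(times)) {
    t_target <- times[m]
    while (t < t_target - 1e-14) {
      h <- min(h, t_target - t)
      k <- matrix(0, 7, length(y))
      k[1, ] <- k1
      for (i in 1:6) {
        yi <- y + h * as.vector(A[[i]] %*% k[seq_along(A[[i]]), ,
                                             drop = FALSE])
        k[i + 1, ] <- f(yi)
      }
      y5 <- y + h * as.vector(b5 %*% k)
      y4 <- y + h * as.vector(b4 %*% k)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (err <= 1 || h < 1e-12) {
        t <- t + h
        # re-project onto the invariant manifold: the simplex normal is
        # linearly unstable for strongly shifted payoffs, so untreated
        # round-off drift would grow exponentially
        y <- project(y5)
        k1 <- if (identical(project, identity)) k[7, ] else f(y)
      } else {
        k1 <- k[1, ]
      }
      h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-16))^(1 / 5)))
      if (!all(is.finite(y))) stop("integrator diverged", call. = FALSE)
    }
    out[m, ] <- y
  }
  out
}

#' Integrate replicator dynamics
#'
#' Adaptive Runge-Kutta integration of the replicator flow (or its
#' death-matrix twin when `death` is supplied instead of `P`).
#'
#' @param x0 initial frequencies on the simplex.
#' @param times strictly increasing output times (first = start).
#' @param P payoff matrix (used with slowdown `s`).
#' @param death optional `death_matrix`; overrides `P`.
#' @inheritParams replicator_rhs
#' @param rtol,atol integrator tolerances.
#' @return data.frame `time`, `a`, `b`, `c`; the trajectory stays on the
#'   simplex to within 1e-9.
#' @export
replicator_integrate <- function(x0, times, P = NULL, s = 1, death = NULL,
                                 rtol = 1e-10, atol = 1e-12) {
  check_simplex(x0)
  f <- if (!is.null(death)) {
    De <- death$entries
    function(x) {
      d <- as.vector(De %*% x)
      (-d + sum(d * x)) * x
    }
  } else {
    Pm <- unclass(P)
    function(x) {
      fi <- as.vector(Pm %*% x)
      (fi - sum(fi * x)) * x / s
    }
  }
  tr <- dopri5(f, x0, times, rtol, atol,
               project = function(y) pmax(y, 0) / sum(pmax(y, 0)))
  drift <- max(abs(rowSums(tr) - 1))
  if (drift > 1e-9)
    stop(sprintf("simplex drift %.3g exceeds 1e-9", drift), call. = FALSE)
  data.frame(time = times, a = tr[, 1], b = tr[, 2], c = tr[, 3])
}

# Reduced 2-D flow (c eliminated); accepts complex input so the Jacobian
# can be taken by complex-step differentiation at machine precision.
reduced_rhs <- function(ab, g) {
  a <- ab[1]
  b <- ab[2]
  cc <- 1 - a - b
  phi <- (g - 1) * (a * b + b * cc + cc * a)
  c((g * cc - b) * a - phi * a,
    (g * a - cc) * b - phi * b)
}

#' Linear stability of the interior fixed point
#'
#' Computes the Jacobian of the reduced two-dimensional replicator flow
#' (c = 1 - a - b eliminated, avoiding the spurious eigenvalue along the
#' simplex normal) at (1/3, 1/3, 1/3) and classifies the fixed point by
#' the sign of the eigenvalue real part.  The flow is neutral (purely
#' imaginary eigenvalues) exactly at the critical gain g = 1; the
#' imaginary part is the intrinsic oscillation frequency
#' `(g + 1) / (2 sqrt(3))`.
#'
#' @param g gain, > 0.
#' @param tol neutrality tolerance on the real part (default 1e-9).
#' @return list with `class` ("stable", "neutral" or "unstable"),
#'   `eigenvalues` (complex pair) and `g`.
#' @export
stability <- function(g, tol = 1e-9) {
  stopifnot(is.numeric(g), length(g) == 1L, g >= 0)
  x0 <- c(1 / 3, 1 / 3)
  h <- 1e-30
  J <- vapply(1:2, function(j) {
    dx <- c(0, 0)
    dx[j] <- h
    Im(reduced_rhs(x0 + 1i * dx, g)) / h
  }, numeric(2))
  ev <- eigen(J, only.values = TRUE)$values
  re <- max(Re(ev))
  cls <- if (abs(re) <= tol) "neutral" else if (re < 0) "stable"
         else "unstable"
  list(class = cls, eigenvalues = ev, g = g)
}

#' Intrinsic oscillation frequency near the fixed point
#'
#' `omega_0 = (g + 1) / (2 sqrt(3))`, the angular frequency of the
#' linearised replicator flow around (1/3, 1/3, 1/3).
#'
#' @param g gain, > 0.
#' @export
intrinsic_frequency <- function(g) {
  stopifnot(all(g >= 0))
  (g + 1) / (2 * sqrt(3))
}

#' Drift rate of the biodiversity indicator
#'
#' The indicator `chi = a b c` vanishes iff some species is extinct.
#' Along the replicator flow `dchi/dt = (g - 1) Gamma(a,b,c) chi` with
#' `Gamma = 1 - 3(ab + bc + ca) >= 0`; the drift pushes toward
#' extinction for g < 1, stabilises for g > 1, and vanishes in the
#' zero-sum game g = 1, where chi is conserved.
#'
#' @param x frequencies on the simplex.
#' @param g gain.
#' @return the instantaneous rate `dchi/dt`.
#' @export
chi_rate <- function(x, g) {
  check_simplex(x)
  a <- x[1]; b <- x[2]; cc <- x[3]
  (g - 1) * (1 - 3 * (a * b + b * cc + cc * a)) * a * b * cc
}

#' Locate the stability boundary in g
#'
#' Bisection on the real part of the leading eigenvalue of the reduced
#' Jacobian at the interior fixed point.
#'
#' @param lower,upper bracket for g.
#' @param tol bisection tolerance on g.
#' @return the critical gain.
#' @export
critical_gain_replicator <- function(lower = 0.5, upper = 2, tol = 1e-12) {
  re_at <- function(g) max(Re(stability(g, tol = 0)$eigenvalues))
  f_lo <- re_at(lower)
  f_hi <- re_at(upper)
  if (f_lo * f_hi > 0) stop("bracket does not straddle the boundary",
                            call. = FALSE)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (re_at(mid) * f_lo <= 0) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}
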