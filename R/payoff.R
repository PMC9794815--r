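#' Rock-paper-scissors payoff matrix
#'
#' Builds the symmetric cyclic payoff matrix for three species (A, B, C)
#' in which every species loses 1 against its predator and gains `g`
#' against its prey: diagonal 0, entry (i, i+1 mod 3) equal to -1 and
#' entry (i, i-1 mod 3) equal to `g`.  Rows index the focal species,
#' columns the opponent.
#'
#' @param g finite non-negative gain of the cyclic competition.
#'   `g = 1` is the zero-sum game; `g > 1` stabilises the interior fixed
#'   point of the replicator flow and `g < 1` destabilises it.  The
#'   extreme case `g = 0` (no reward from the prey at all) is admitted
#'   because the grid dynamics is studied there.
#' @return a `payoff_matrix`: a 3x3 numeric matrix with dimnames
#'   `c("A","B","C")` and attribute `gain = g`.
#' @examples
#' rps_payoff(1)
#' @export
rps_payoff <- function(g) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 0)
    stop("`g` must be a single finite value >= 0", call. = FALSE)
  P <- matrix(c(0, -1, g,
                g, 0, -1,
                -1, g, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  structure(P, gain = g, class = c("payoff_matrix", "matrix", "array"))
}

#' Gauge shift of a payoff matrix
#'
#' Adds a constant to every payoff entry.  Replicator dynamics is
#' invariant under this shift (gauge redundancy), which is what allows
#' an all-non-positive representative of the game to be chosen before
#' converting payoffs into death probabilities.
#'
#' @param P a 3x3 payoff matrix.
#' @param c constant added to every entry.
#' @return the shifted matrix, preserving class and `gain` attribute.
#' @export
gauge_shift <- function(P, c) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c))
  P[] <- unclass(P) + c
  P
}

#' Minimal rescaling factor of a non-positive payoff matrix
#'
#' For a payoff matrix with all entries <= 0, the smallest factor `s`
#' for which `-P/s` has entries in `[0, 1]` is `s_m = max(|P_ij|)`.
#'
#' @param P_neg payoff matrix, all entries <= 0.
#' @return `s_m`, the lower bound for the rescaling factor.
#' @export
min_rescale <- function(P_neg) {
  m <- unclass(P_neg)
  if (any(m > 0)) stop("matrix has positive entries; gauge-shift it first",
                       call. = FALSE)
  max(abs(m))
}

#' Death matrix of a payoff matrix
#'
#' Converts payoffs into per-encounter death probabilities
#' `D_ij = -(P_ij + shift) / s`.  The shift makes the matrix
#' non-positive (gauge redundancy keeps the dynamics unchanged) and the
#' rescaling factor `s >= s_m = max|P_ij + shift|` maps it into
#' `[0, 1]`.  Rescaling slows the deterministic limit uniformly by the
#' factor `s`, so all simulated times must be divided by `s`; `s` is
#' therefore carried alongside the entries.
#'
#' @param P a 3x3 payoff matrix.
#' @param shift `"auto"` (default) subtracts the maximum entry -- the
#'   smallest shift producing a non-positive matrix, hence the smallest
#'   `s_m` and fastest simulated dynamics -- or an explicit constant.
#' @param s `"min"` (default) uses `s_m`; or an explicit value `>= s_m`.
#' @return a `death_matrix`: list with `entries` (3x3, in `[0,1]`), `s`,
#'   `shift` and `gain` (the originating gain if known, else `NA`).
#' @examples
#' death_matrix(rps_payoff(1))
#' @export
death_matrix <- function(P, shift = "auto", s = "min") {
  m <- unclass(P)
  if (identical(shift, "auto")) shift <- -max(m)
  stopifnot(is.numeric(shift), length(shift) == 1L, is.finite(shift))
  ms <- m + shift
  if (any(ms > 1e-12))
    stop("shifted payoff matrix has positive entries", call. = FALSE)
  ms[ms > 0] <- 0
  s_m <- max(abs(ms))
  if (identical(s, "min")) s <- s_m
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s))
  if (s <= 0) stop("rescaling factor s must be > 0 (degenerate game)",
                   call. = FALSE)
  if (s < s_m - 1e-12)
    stop(sprintf("s = %g below lower bound s_m = %g", s, s_m), call. = FALSE)
  D <- matrix(-as.vector(ms) / s, 3, 3, dimnames = dimnames(ms))
  structure(list(entries = D, s = s, shift = shift,
                 gain = attr(P, "gain") %||% NA_real_),
            class = "death_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.death_matrix <- function(x, ...) {
  cat(sprintf("death matrix (shift = %g, s = %g)\n", x$shift, x$s))
  print(x$entries)
  invisible(x)
}

# JSON-serialisable description embedded in every result file
payoff_meta <- function(dm) {
  list(entries = dm$entries, gain = dm$gain, shift = dm$shift, s = dm$s)
}
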