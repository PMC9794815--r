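#' @useDynLib rgbgame, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SPECIES <- c("A", "B", "C")

#' Initial population state
#'
#' Places the requested species composition on the network in uniformly
#' random positions.  With `composition = "equal"` each species gets
#' `floor(N/3)` individuals and the (at most two) remainders are
#' assigned to distinct species chosen uniformly at random.
#'
#' @param net an `rgb_network`.
#' @param composition `"equal"` or an integer vector of three counts
#'   summing to `net$N`.
#' @param seed integer seed; the same seed always yields the same label
#'   arrangement.
#' @return an `rgb_state`: list with `species` (0/1/2 per node, integer),
#'   `counts` (named, summing to N), `updates = 0` and the network.
#' @export
init_state <- function(net, composition = "equal", seed = 1L) {
  stopifnot(inherits(net, "rgb_network"))
  N <- net$N
  withr::with_seed(as.integer(seed), {
    if (identical(composition, "equal")) {
      comp <- rep(N %/% 3L, 3L)
      rem <- N - sum(comp)
      if (rem > 0) {
        lucky <- sample.int(3L, rem)
        comp[lucky] <- comp[lucky] + 1L
      }
    } else {
      comp <- as.integer(composition)
      if (length(comp) != 3L || any(comp < 0) || sum(comp) != N)
        stop("composition must be three non-negative counts summing to N",
             call. = FALSE)
    }
    species <- sample(rep.int(0:2, comp))
  })
  new_state(species, net)
}

new_state <- function(species, net, updates = 0) {
  counts <- tabulate(species + 1L, nbins = 3L)
  names(counts) <- SPECIES
  structure(list(species = as.integer(species), counts = counts,
                 updates = updates, net = net),
            class = "rgb_state")
}

#' @export
print.rgb_state <- function(x, ...) {
  cat(sprintf("rgb_state: N = %d (%s), updates = %g, counts: %s\n",
              x$net$N, x$net$kind, x$updates,
              paste(SPECIES, x$counts, sep = "=", collapse = " ")))
  invisible(x)
}

#' Apply RGB updates to a state
#'
#' Runs `n` elementary Reference-Gamble-Birth updates (default 1) and
#' returns the new state.  Monomorphic states are legal and absorbing up
#' to relabelling; updates always advance the clock.
#'
#' @param state an `rgb_state`.
#' @param death a `death_matrix`.
#' @param seed integer seed for this update sequence.
#' @param n number of updates.
#' @return the updated `rgb_state`.
#' @export
rgb_update <- function(state, death, seed = 1L, n = 1L) {
  stopifnot(inherits(state, "rgb_state"), inherits(death, "death_matrix"))
  a <- net_cpp_args(state$net)
  res <- cpp_simulate(state$species, death$entries, a$kind, a$L, a$degree,
                      a$adj, a$ptr, as.numeric(seed), as.numeric(n),
                      FALSE, 0, numeric(0), TRUE)
  new_state(res$species, state$net, state$updates + res$updates)
}

#' Exact one-step transition distribution
#'
#' Enumerates every (Gamble, Reference, Birth) triple with its
#' probability and returns the exact distribution of the population
#' change vector after a single RGB update.  Serves as the independent
#' oracle for the stochastic engine.  The mean-field formula
#' `E[dN_i] = sum_jk (D_kj - D_ij) x_i x_j x_k` is its infinite-N limit;
#' at finite N neighbour exclusion (Reference and Birth are never the
#' Gamble itself) gives O(1/N) corrections.
#'
#' @param state an `rgb_state`.
#' @param death a `death_matrix`.
#' @return list with `outcomes` (data.frame: dA, dB, dC, prob) and
#'   `expected_dN` (length-3 numeric).
#' @export
one_step_distribution_oracle <- function(state, death) {
  net <- state$net
  N <- net$N
  nb <- lapply(seq_len(N), function(i) neighbors(net, i))
  if (N * max(lengths(nb))^2 > 1e6)
    stop("state too large to enumerate (N * degree^2 > 1e6)", call. = FALSE)
  D <- death$entries
  sp <- state$species
  # the change vector is determined by (Gamble species, Birth species)
  # alone, so accumulate a 3x3 matrix of pair probabilities
  pair <- matrix(0, 3, 3)
  p_none <- 0
  for (g in seq_len(N)) {
    ns <- nb[[g]]
    sg1 <- sp[g] + 1L
    frac <- tabulate(sp[ns] + 1L, nbins = 3L) / length(ns)
    # Reference and Birth are iid uniform over the neighbourhood, so
    # only the neighbourhood species fractions enter
    p_death <- sum(D[sg1, ] * frac)
    p_none <- p_none + (1 - p_death) / N
    pair[sg1, ] <- pair[sg1, ] + (p_death / N) * frac
  }
  p_none <- p_none + sum(diag(pair))
  res <- data.frame(dA = 0L, dB = 0L, dC = 0L, prob = p_none)
  for (i in 1:3) {
    for (j in 1:3) {
      if (i == j || pair[i, j] == 0) next
      dN <- integer(3)
      dN[i] <- -1L
      dN[j] <- 1L
      res <- rbind(res, data.frame(dA = dN[1], dB = dN[2], dC = dN[3],
                                   prob = pair[i, j]))
    }
  }
  res <- res[order(res$dA, res$dB, res$dC), ]
  rownames(res) <- NULL
  list(outcomes = res, pair = pair,
       expected_dN = c(sum(res$dA * res$prob), sum(res$dB * res$prob),
                       sum(res$dC * res$prob)))
}

#' Empirical one-step tally
#'
#' Draws `K` independent single updates from the same initial state and
#' tallies death events by (Gamble species, Birth species); companion to
#' [one_step_distribution_oracle()] for goodness-of-fit testing.
#'
#' @inheritParams rgb_update
#' @param K number of independent one-step draws.
#' @return list with `deaths` (3x3 integer tally) and `n = K`.
#' @export
one_step_tally <- function(state, death, seed = 1L, K = 1e5) {
  a <- net_cpp_args(state$net)
  cpp_one_step_tally(state$species, death$entries, a$kind, a$L, a$degree,
                     a$adj, a$ptr, as.numeric(seed), as.integer(K))
}

#' Run one realisation to extinction
#'
#' Simulates RGB updates until some species' count reaches zero or
#' `max_updates` is exhausted (then the record is censored, not an
#' error).  The extinction time is reported in rescaled units
#' `t_ex = updates / (N * s)`: one generation is N elementary updates,
#' and the death-matrix rescaling factor `s` slows the dynamics
#' uniformly, so simulated times are divided by `s` to recover
#' replicator-equation time.
#'
#' @param state initial `rgb_state`.
#' @param death a `death_matrix`.
#' @param seed integer seed.
#' @param max_updates cap on elementary updates (default 1e9).
#' @return an `extinction_record`: list with `t_ex`, `censored`,
#'   `first_extinct` ("A"/"B"/"C", ties at the initial state broken by
#'   species order), `updates`, `seed`, `s`.
#' @export
run_to_extinction <- function(state, death, seed = 1L, max_updates = 1e9) {
  stopifnot(inherits(state, "rgb_state"), inherits(death, "death_matrix"))
  a <- net_cpp_args(state$net)
  res <- cpp_simulate(state$species, death$entries, a$kind, a$L, a$degree,
                      a$adj, a$ptr, as.numeric(seed),
                      as.numeric(max_updates), TRUE, 0, numeric(0), FALSE)
  structure(list(t_ex = res$updates / (state$net$N * death$s),
                 censored = res$censored,
                 first_extinct = if (res$first_extinct >= 0)
                   SPECIES[res$first_extinct + 1L] else NA_character_,
                 updates = res$updates, seed = as.integer(seed),
                 s = death$s),
            class = "extinction_record")
}

# Deterministic per-replicate seeds from one master seed.
derive_seeds <- function(master, n) {
  withr::with_seed(as.integer(master),
                   sample.int(.Machine$integer.max - 1L, n))
}

#' Ensemble of extinction runs
#'
#' Runs `reps` independent realisations from fresh random equal-composition
#' initial states (unless `composition` says otherwise), with per-replicate
#' seeds derived deterministically from `seed`.
#'
#' @param net an `rgb_network`.
#' @param death a `death_matrix`.
#' @param reps number of replicates.
#' @param seed master seed.
#' @param max_updates per-run cap (censoring, not error).
#' @param composition passed to [init_state()].
#' @return data.frame with one row per replicate: `seed`, `t_ex`,
#'   `censored`, `first_extinct`; attribute `s`.
#' @export
run_ensemble <- function(net, death, reps, seed = 1L, max_updates = 1e9,
                         composition = "equal") {
  seeds <- derive_seeds(seed, 2L * reps)
  init_seeds <- seeds[seq_len(reps)]
  run_seeds <- seeds[reps + seq_len(reps)]
  recs <- lapply(seq_len(reps), function(r) {
    st <- init_state(net, composition, init_seeds[r])
    run_to_extinction(st, death, run_seeds[r], max_updates)
  })
  out <- data.frame(seed = run_seeds,
                    t_ex = vapply(recs, `[[`, 0, "t_ex"),
                    censored = vapply(recs, `[[`, TRUE, "censored"),
                    first_extinct = vapply(recs, `[[`, "", "first_extinct"))
  attr(out, "s") <- death$s
  out
}

#' Steady-state snapshots and trajectory
#'
#' Runs the RGB dynamics on a grid and records full lattice snapshots at
#' rescaled times `burn_in + k * interval`, `k = 0 .. count-1`, together
#' with a species-count trajectory.  If extinction occurs first the
#' snapshots collected so far are returned with `truncated = TRUE`.
#'
#' @param net a grid `rgb_network`.
#' @param death a `death_matrix`.
#' @param init initial `rgb_state` (default: equal random from `seed`).
#' @param burn_in,interval,count snapshot schedule in rescaled time
#'   units (`updates / (N * s)`); `interval > 0`.
#' @param seed integer seed.
#' @param traj_every record counts every this many rescaled time units
#'   (0 = no trajectory).
#' @return list with `snapshots` (list of L x L integer matrices, values
#'   0/1/2), `times` (rescaled), `truncated`, `trajectory` (data.frame
#'   time, A, B, C or NULL), `s`, `net`.
#' @export
sample_snapshots <- function(net, death, init = NULL, burn_in, interval,
                             count, seed = 1L, traj_every = 0) {
  stopifnot(inherits(net, "rgb_network"), net$kind == "grid2d",
            interval > 0, count >= 1)
  if (is.null(init)) init <- init_state(net, "equal", seed)
  unit <- net$N * death$s # updates per rescaled time unit
  snap_at <- round((burn_in + (seq_len(count) - 1) * interval) * unit)
  a <- net_cpp_args(net)
  res <- cpp_simulate(init$species, death$entries, a$kind, a$L, a$degree,
                      a$adj, a$ptr, as.numeric(seed),
                      max(snap_at) + 1, TRUE,
                      if (traj_every > 0) round(traj_every * unit) else 0,
                      as.numeric(snap_at), FALSE)
  taken <- res$snap_taken
  snaps <- lapply(seq_len(taken), function(k) {
    matrix(res$snapshots[k, ], nrow = net$L, byrow = TRUE)
  })
  traj <- NULL
  if (traj_every > 0 && !is.null(res$trajectory)) {
    tr <- res$trajectory
    traj <- data.frame(time = tr[, 1] / unit, A = tr[, 2], B = tr[, 3],
                       C = tr[, 4])
  }
  list(snapshots = snaps, times = snap_at[seq_len(taken)] / unit,
       truncated = taken < count, trajectory = traj, s = death$s, net = net)
}

#' Species-count trajectory of one realisation
#'
#' @inheritParams run_to_extinction
#' @param t_max run length in rescaled time units.
#' @param sample_every sampling interval in rescaled time units.
#' @return data.frame `time`, `A`, `B`, `C` (counts).
#' @export
count_trajectory <- function(state, death, t_max, sample_every, seed = 1L) {
  unit <- state$net$N * death$s
  a <- net_cpp_args(state$net)
  res <- cpp_simulate(state$species, death$entries, a$kind, a$L, a$degree,
                      a$adj, a$ptr, as.numeric(seed),
                      round(t_max * unit), FALSE,
                      round(sample_every * unit), numeric(0), FALSE)
  tr <- res$trajectory
  data.frame(time = tr[, 1] / unit, A = tr[, 2], B = tr[, 3], C = tr[, 4])
}
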