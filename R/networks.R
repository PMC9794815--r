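#' Fully-connected network
#'
#' Population structure in which every individual is a neighbour of
#' every other (the well-mixed reference).
#'
#' @param N population size, at least 3 (three species cannot coexist on
#'   fewer nodes).
#' @return an `rgb_network` of kind `"fully_connected"`.
#' @export
fully_connected <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 3)
    stop("`N` must be an integer >= 3", call. = FALSE)
  structure(list(kind = "fully_connected", N = as.integer(N)),
            class = "rgb_network")
}

#' Two-dimensional grid network
#'
#' L x L lattice with one individual per node.  Node (r, c) -- rows and
#' columns counted from 0 -- has id `r*L + c + 1` (ids are 1-based on
#' the R side).  The default von Neumann scheme with periodic boundaries
#' makes every site statistically equivalent, which translation-invariant
#' correlation estimates rely on.
#'
#' @param L side length, at least 3.
#' @param scheme `"von_neumann"` (4 axis neighbours, default) or
#'   `"moore"` (8 neighbours).
#' @param periodic logical; wrap boundaries (default `TRUE`).
#' @return an `rgb_network` of kind `"grid2d"` with `N = L^2`.
#' @export
grid2d <- function(L, scheme = c("von_neumann", "moore"), periodic = TRUE) {
  if (!is.numeric(L) || length(L) != 1L || L != round(L) || L < 3)
    stop("`L` must be an integer >= 3", call. = FALSE)
  scheme <- match.arg(scheme)
  structure(list(kind = "grid2d", N = as.integer(L)^2, L = as.integer(L),
                 scheme = scheme, periodic = isTRUE(periodic)),
            class = "rgb_network")
}

#' Neighbours of a node
#'
#' @param net an `rgb_network`.
#' @param i node id in `1:net$N`.
#' @return integer vector of neighbour ids (1-based), never containing
#'   `i`, stable and duplicate-free.
#' @export
neighbors <- function(net, i) {
  stopifnot(inherits(net, "rgb_network"))
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > net$N)
    stop("node id out of range", call. = FALSE)
  i <- as.integer(i)
  if (net$kind == "fully_connected") return(setdiff(seq_len(net$N), i))
  L <- net$L
  r <- (i - 1L) %/% L
  c <- (i - 1L) %% L
  d <- if (net$scheme == "von_neumann") {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  }
  rr <- r + d[, 1L]
  cc <- c + d[, 2L]
  if (net$periodic) {
    rr <- rr %% L
    cc <- cc %% L
  } else {
    keep <- rr >= 0L & rr < L & cc >= 0L & cc < L
    rr <- rr[keep]
    cc <- cc[keep]
  }
  sort(unique(rr * L + cc + 1L))
}

#' @export
print.rgb_network <- function(x, ...) {
  if (x$kind == "fully_connected") {
    cat(sprintf("fully-connected network, N = %d\n", x$N))
  } else {
    cat(sprintf("%d x %d grid (%s, %s), N = %d\n", x$L, x$L, x$scheme,
                if (x$periodic) "periodic" else "open", x$N))
  }
  invisible(x)
}

# Metadata block for result headers
network_meta <- function(net) {
  list(kind = net$kind, N = net$N, L = net$L %||% NA_integer_,
       scheme = net$scheme %||% NA_character_,
       periodic = net$periodic %||% NA)
}

# Arguments for the compiled loop.  Fully-connected and periodic grids
# are sampled arithmetically in C++; anything else goes through a CSR
# adjacency built here (0-based).
net_cpp_args <- function(net) {
  if (net$kind == "fully_connected") {
    return(list(kind = 0L, L = 0L, degree = 0L,
                adj = integer(0), ptr = integer(0)))
  }
  if (net$periodic) {
    deg <- if (net$scheme == "von_neumann") 4L else 8L
    return(list(kind = 1L, L = net$L, degree = deg,
                adj = integer(0), ptr = integer(0)))
  }
  nb <- lapply(seq_len(net$N), function(i) neighbors(net, i) - 1L)
  lens <- lengths(nb)
  list(kind = 2L, L = net$L, degree = 0L,
       adj = as.integer(unlist(nb)),
       ptr = as.integer(c(0L, cumsum(lens))))
}
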