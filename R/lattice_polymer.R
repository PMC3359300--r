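#' Lattice configuration
#'
#' The simulation lattice is a simple cubic lattice of linear size `L` with
#' periodic boundaries. The allowed bond vectors are every displacement with
#' components in {-1, 0, +1} except the null vector (bond lengths 1, sqrt(2),
#' sqrt(3)), a single-site variant of the bond-fluctuation model; the
#' loop-formation cutoff equals the maximum bond length sqrt(3), so two
#' non-adjacent monomers must be at least as close as backbone neighbours can
#' be to form a loop. `L` must be much larger than the chain's radius of
#' gyration to avoid interactions through the periodic boundary.
#'
#' @param L Linear lattice size (default 600).
#' @return A `lattice_config` object.
#' @export
lattice_config <- function(L = 600L) {
  L <- as.integer(L)
  if (is.na(L) || L < 2) stop("L must be an integer >= 2")
  bv <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  bv <- bv[rowSums(abs(bv)) > 0, , drop = FALSE]
  structure(list(L = L, cutoff = sqrt(3), bond_vectors = bv),
            class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat("cubic lattice: L =", x$L, "(periodic), cutoff =", format(x$cutoff),
      ",", nrow(x$bond_vectors), "bond vectors\n")
  invisible(x)
}

new_polymer_state <- function(positions, loops = NULL, mcs_clock = 0) {
  storage.mode(positions) <- "integer"
  if (is.null(loops))
    loops <- data.frame(i = integer(0), j = integer(0), expiry = numeric(0))
  structure(list(positions = positions, loops = loops,
                 mcs_clock = as.numeric(mcs_clock), N = nrow(positions)),
            class = "polymer_state")
}

#' @export
print.polymer_state <- function(x, ...) {
  cat("polymer state: N =", x$N, ", mcs =", x$mcs_clock,
      ",", nrow(x$loops), "active loop bonds\n")
  invisible(x)
}

loops_i <- function(state) as.integer(state$loops$i)
loops_j <- function(state) as.integer(state$loops$j)
loops_e <- function(state) as.numeric(state$loops$expiry)

#' Initialise a self-avoiding chain
#'
#' Grows the backbone by biased self-avoiding placement over the allowed bond
#' vectors, restarting on dead ends. The residual growth bias is removed by
#' the loop-free equilibration phase of [equilibrate()].
#'
#' @param N Chain length (>= 2).
#' @param config A [lattice_config()].
#' @param seed Optional integer seed (positions are deterministic given it).
#' @return A `polymer_state` with no loop bonds and `mcs_clock = 0`.
#' @export
init_random_chain <- function(N, config = lattice_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- cpp_init_chain(as.integer(N), config$L)
  new_polymer_state(pos)
}

#' Check every state invariant
#'
#' Reports each violated invariant: site overlaps (excluded volume), illegal
#' backbone or loop bond vectors, loop bonds past expiry, monomers holding
#' more than one loop bond.
#'
#' @param state A `polymer_state`.
#' @param config A [lattice_config()].
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_state <- function(state, config = lattice_config()) {
  cpp_validate_state(state$positions, loops_i(state), loops_j(state),
                     loops_e(state), state$mcs_clock, config$L)
}

#' Propose and apply one elementary trial move
#'
#' A monomer is chosen uniformly and, with uniform probability, one of the 6
#' nearest-neighbour displacements is attempted. The move is accepted iff the
#' target site is free (excluded volume on the wrapped lattice) and every
#' bond of the monomer -- backbone and loop -- remains an allowed bond
#' vector; the state is unchanged on rejection.
#'
#' @param state A `polymer_state`.
#' @param config A [lattice_config()].
#' @param monomer,direction Optional forced choices for testing (1-based
#'   monomer index; direction in 1..6 for +x,-x,+y,-y,+z,-z). When `NULL`
#'   they are drawn from R's RNG.
#' @return List with `state`, `accepted`, `moved_index`.
#' @export
propose_and_apply_move <- function(state, config = lattice_config(),
                                   monomer = NULL, direction = NULL) {
  res <- cpp_try_move(state$positions, loops_i(state), loops_j(state),
                      loops_e(state), state$mcs_clock, config$L,
                      if (is.null(monomer)) 0L else as.integer(monomer),
                      if (is.null(direction)) 0L else as.integer(direction))
  state$positions <- res$positions
  list(state = state, accepted = res$accepted, moved_index = res$moved_index)
}

#' Spatial neighbours within the loop-formation cutoff
#'
#' All monomers within Euclidean distance sqrt(3) of monomer `i` (equivalent
#' to Chebyshev distance 1 on this lattice), excluding `i` itself and its
#' backbone neighbours `i - 1`, `i + 1`. The lookup scans the O(1)
#' surrounding lattice sites through the occupancy map; periodic images are
#' rejected on the unwrapped coordinates.
#'
#' @param state A `polymer_state`.
#' @param i Monomer index (1-based).
#' @param config A [lattice_config()].
#' @return Sorted integer vector of monomer indices.
#' @export
neighbors_within_cutoff <- function(state, i, config = lattice_config()) {
  cpp_neighbors_within_cutoff(state$positions, as.integer(i), config$L)
}
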