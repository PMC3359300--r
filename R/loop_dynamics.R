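#' Loop-dynamics parameters
#'
#' @param affinities An [affinity_profile()] or numeric affinity vector.
#' @param mean_lifetime Mean of the Poisson bond-lifetime distribution, in
#'   MCS (default 8000).
#' @param loops_enabled Disable to simulate a pure self-avoiding chain.
#' @return A `loop_params` object.
#' @export
loop_params <- function(affinities, mean_lifetime = 8000, loops_enabled = TRUE) {
  if (mean_lifetime < 0) stop("mean_lifetime must be >= 0")
  structure(list(affinities = as_affinities(affinities),
                 mean_lifetime = mean_lifetime,
                 loops_enabled = isTRUE(loops_enabled)),
            class = "loop_params")
}

#' Looping probability of a monomer pair
#'
#' Symmetric combination of the two interaction affinities,
#' `p_ij = sqrt(a_i * a_j)` (the geometric mean). For a homogeneous fibre
#' (`a_i = a_j = a`) the looping probability equals the affinity itself, and
#' the probability vanishes whenever either affinity is zero. The combiner is
#' pluggable through `combiner` (e.g. `prod`-based or `min`).
#'
#' @param a_i,a_j Affinities in `[0, 1]` (vectorised).
#' @param combiner Optional replacement function `(a_i, a_j) -> p`.
#' @return Probabilities in `[0, 1]`.
#' @export
looping_probability <- function(a_i, a_j, combiner = NULL) {
  if (any(a_i < 0 | a_i > 1) || any(a_j < 0 | a_j > 1))
    stop("affinities must lie in [0, 1]")
  p <- if (is.null(combiner)) sqrt(a_i * a_j) else combiner(a_i, a_j)
  if (any(p < 0 | p > 1)) stop("combiner produced probabilities outside [0, 1]")
  p
}

#' Draw loop-bond lifetimes
#'
#' Lifetimes are Poisson-distributed (in MCS) with the configured mean.
#'
#' @param mean Mean lifetime in MCS (>= 0).
#' @param n Number of draws.
#' @return Integer-valued lifetimes.
#' @export
sample_lifetime <- function(mean, n = 1) {
  if (mean < 0) stop("mean lifetime must be >= 0")
  rpois(n, mean)
}

#' Attempt loop formation for a just-moved monomer
#'
#' Event-driven formation: after an accepted move of monomer `moved_index`
#' (itself loop-free), its unbonded spatial neighbours within the cutoff are
#' the candidates; one is chosen uniformly and a bond forms with probability
#' [looping_probability()]. On formation the bond expiry is
#' `mcs_clock + sample_lifetime(mean_lifetime)`.
#'
#' @param state A `polymer_state`.
#' @param moved_index Monomer that just moved (must be loop-free).
#' @param params A [loop_params()].
#' @param config A [lattice_config()].
#' @return List with `state` and `bond` (one-row data frame, or `NULL` when
#'   no bond formed).
#' @export
attempt_loop_formation <- function(state, moved_index, params,
                                   config = lattice_config()) {
  if (!params$loops_enabled) return(list(state = state, bond = NULL))
  bonded <- c(loops_i(state), loops_j(state))
  if (moved_index %in% bonded)
    stop("monomer ", moved_index, " already holds a loop bond")
  cand <- neighbors_within_cutoff(state, moved_index, config)
  cand <- setdiff(cand, bonded)
  if (length(cand) == 0) return(list(state = state, bond = NULL))
  j <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
  a <- params$affinities
  p <- looping_probability(a[moved_index], a[j])
  if (runif(1) >= p) return(list(state = state, bond = NULL))
  expiry <- state$mcs_clock + sample_lifetime(params$mean_lifetime)
  bond <- data.frame(i = min(moved_index, j), j = max(moved_index, j),
                     expiry = expiry)
  state$loops <- rbind(state$loops, bond)
  list(state = state, bond = bond)
}

#' Dissociate expired loop bonds
#'
#' Removes every loop bond whose expiry time has been reached
#' (`expiry <= mcs_clock`, inclusive); survivors are untouched. Run once per
#' MCS by the engine, after the N trial moves.
#'
#' @param state A `polymer_state`.
#' @return List with `state` and `removed` (data frame of dissolved bonds).
#' @export
expire_bonds <- function(state) {
  gone <- state$loops$expiry <= state$mcs_clock
  removed <- state$loops[gone, , drop = FALSE]
  state$loops <- state$loops[!gone, , drop = FALSE]
  list(state = state, removed = removed)
}

#' Realised lifetimes from a frozen two-monomer contact
#'
#' Test harness: two loop-eligible monomers are held at unit distance and the
#' engine's formation path (uniform candidate pick, Bernoulli coin with
#' probability `p`, Poisson lifetime) is exercised until `n_bonds` bonds have
#' formed; the realised lifetime of each is returned.
#'
#' @param n_bonds Number of bonds to realise.
#' @param mean_lifetime Configured mean lifetime (MCS).
#' @param p Formation probability per attempt.
#' @return Numeric vector of `n_bonds` realised lifetimes.
#' @export
frozen_contact_lifetimes <- function(n_bonds, mean_lifetime = 8000, p = 1) {
  cpp_lifetime_harness(as.integer(n_bonds), mean_lifetime, p)
}
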