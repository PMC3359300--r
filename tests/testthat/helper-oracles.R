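# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately use naive double loops, never the package's own
# vectorised/compiled code paths.

# squared-distance MSD by explicit double loop over monomer pairs
brute_msd <- function(conformations) {
  N <- nrow(conformations[[1]])
  out <- numeric(N)
  for (n in 1:(N - 1)) {
    acc <- 0; cnt <- 0
    for (P in conformations) {
      for (i in 1:(N - n)) {
        acc <- acc + sum((P[i + n, ] - P[i, ])^2)
        cnt <- cnt + 1
      }
    }
    out[n + 1] <- acc / cnt
  }
  data.frame(separation = 0:(N - 1), msd = out)
}

# all-pairs scan for spatial neighbours within Euclidean cutoff sqrt(3)
brute_neighbors <- function(positions, i, cutoff = sqrt(3)) {
  N <- nrow(positions)
  hits <- integer(0)
  for (j in seq_len(N)) {
    if (j == i || abs(j - i) == 1) next
    d <- sqrt(sum((positions[j, ] - positions[i, ])^2))
    if (d > 0 && d <= cutoff + 1e-12) hits <- c(hits, j)
  }
  hits
}

# direct kernel sum for the 3-D Gaussian product-kernel density
brute_gkde <- function(coords) {
  n <- nrow(coords)
  bw <- apply(coords, 2, sd) * n^(-1 / 7)
  dens <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_len(n)) {
      z <- (coords[i, ] - coords[k, ]) / bw
      s <- s + exp(-0.5 * sum(z^2))
    }
    dens[i] <- s / (n * (2 * pi)^1.5 * prod(bw))
  }
  dens
}

# Spearman rho by the exhaustive rank formula (no ties assumed)
brute_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# a short valid chain laid out by hand: hairpin bringing monomers 1 and 6
# to unit distance
hairpin_state <- function() {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
               c(2, 1, 0), c(1, 1, 0), c(0, 1, 0))
  dynloop:::new_polymer_state(pos)
}

# chain of 4 whose only loop candidate for monomer 1 is monomer 4
single_candidate_state <- function() {
  pos <- rbind(c(0, 0, 0), c(1, 0, 1), c(0, 0, 2), c(0, 0, 1))
  dynloop:::new_polymer_state(pos)
}

# random valid small chains, relaxed briefly so geometries vary
random_states <- function(n_states, N = 20, L = 40, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_states), function(k) {
    st <- init_random_chain(N, lattice_config(L))
    run_mcs(st, 0, lattice_config(L), loops_enabled = FALSE, n_mcs = 20)
  })
}

make_ensemble <- function(conformations, loops = NULL) {
  as_dl_ensemble(conformations, loops)
}
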