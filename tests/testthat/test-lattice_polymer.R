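test_that("chain initialisation produces valid, seed-deterministic states", {
  cfg <- lattice_config(600)
  st <- init_random_chain(10, cfg, seed = 1)
  expect_length(validate_state(st, cfg), 0)
  expect_equal(nrow(st$loops), 0)

  dimer <- init_random_chain(2, cfg, seed = 3)
  d <- dimer$positions[2, ] - dimer$positions[1, ]
  expect_true(all(abs(d) <= 1) && any(d != 0))

  a <- init_random_chain(50, cfg, seed = 7)
  b <- init_random_chain(50, cfg, seed = 7)
  expect_identical(a$positions, b$positions)
})

test_that("validate_state reports each violated invariant", {
  cfg <- lattice_config(50)
  pos <- cbind(0:4, 0L, 0L)
  st <- dynloop:::new_polymer_state(pos)
  expect_length(validate_state(st, cfg), 0)

  ov <- st
  ov$positions[2, ] <- ov$positions[1, ]   # two monomers on one site
  msgs <- validate_state(ov, cfg)
  expect_true(any(grepl("overlap", msgs)))

  stretched <- st
  stretched$loops <- data.frame(i = 1L, j = 5L, expiry = 100)  # distance 4
  msgs <- validate_state(stretched, cfg)
  expect_true(any(grepl("stretched beyond the cutoff", msgs)))

  near <- st
  near$loops <- data.frame(i = 1L, j = 2L, expiry = 100)   # backbone pair
  expect_true(any(grepl("backbone", validate_state(near, cfg))))

  # wrapped-site overlap through the periodic boundary is still an overlap
  wrapped <- dynloop:::new_polymer_state(rbind(c(0, 0, 0), c(50, 0, 1),
                                               c(50, 0, 0)))
  expect_true(any(grepl("overlap", validate_state(wrapped, cfg))))
})

test_that("trial moves obey excluded volume and bond constraints", {
  cfg <- lattice_config(100)
  # dimer with a slack diagonal-free geometry: monomer 1 at origin, 2 at +x
  dimer <- dynloop:::new_polymer_state(rbind(c(0, 0, 0), c(1, 0, 0)))

  # +y keeps the bond an allowed vector -> accepted
  r <- propose_and_apply_move(dimer, cfg, monomer = 1, direction = 3)
  expect_true(r$accepted)
  expect_equal(r$state$positions[1, ], c(0, 1, 0))

  # -x stretches the backbone bond to length 2 -> rejected, state unchanged
  r <- propose_and_apply_move(dimer, cfg, monomer = 1, direction = 2)
  expect_false(r$accepted)
  expect_identical(r$state$positions, dimer$positions)

  # +x onto the occupied site of monomer 2 -> rejected
  r <- propose_and_apply_move(dimer, cfg, monomer = 1, direction = 1)
  expect_false(r$accepted)
  expect_identical(r$state$positions, dimer$positions)

  # an active loop bond constrains moves exactly like a backbone bond
  looped <- hairpin_state()
  looped$loops <- data.frame(i = 1L, j = 6L, expiry = 1e6)
  # monomer 1 at (0,0,0), partner 6 at (0,1,0); -y move puts them 2 apart
  r <- propose_and_apply_move(looped, cfg, monomer = 1, direction = 4)
  expect_false(r$accepted)
})

test_that("accepted directions of an unconstrained axis pair are uniform", {
  # with the bond along +x, four of the six directions are acceptable for
  # monomer 1, each proposed with probability 1/6
  cfg <- lattice_config(100)
  dimer <- dynloop:::new_polymer_state(rbind(c(0, 0, 0), c(1, 0, 0)))
  set.seed(20)
  n <- 12000
  disp <- matrix(0L, n, 3)
  acc <- logical(n)
  for (k in seq_len(n)) {
    r <- propose_and_apply_move(dimer, cfg, monomer = 1)
    acc[k] <- r$accepted
    if (r$accepted) disp[k, ] <- r$state$positions[1, ] - dimer$positions[1, ]
  }
  expect_lt(abs(mean(acc) - 4 / 6), 3 * sqrt((4 / 6) * (2 / 6) / n))
  keys <- paste(disp[acc, 1], disp[acc, 2], disp[acc, 3])
  counts <- table(keys)
  expect_length(counts, 4)   # +y, -y, +z, -z
  p <- 1 / 6
  tol <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) < tol))
})

test_that("spatial neighbour lookup matches a brute-force all-pairs scan", {
  cfg <- lattice_config(40)
  # straight chain: interior monomers have no non-backbone neighbours
  straight <- dynloop:::new_polymer_state(cbind(0:9, 0L, 0L))
  expect_length(neighbors_within_cutoff(straight, 5, cfg), 0)

  # hairpin: ends meet across the fold
  hp <- hairpin_state()
  expect_true(6 %in% neighbors_within_cutoff(hp, 1, cfg))
  expect_true(1 %in% neighbors_within_cutoff(hp, 6, cfg))

  for (st in random_states(50, N = 20, L = 40, seed = 4)) {
    for (i in c(1, 7, 20)) {
      expect_equal(neighbors_within_cutoff(st, i, cfg),
                   brute_neighbors(st$positions, i))
    }
  }
})

test_that("state invariants survive 1e5 elementary moves with loops active", {
  cfg <- lattice_config(30)
  set.seed(15)
  st <- init_random_chain(50, cfg)
  total_trials <- 0
  for (chunk in 1:20) {
    st <- run_mcs(st, 0.3, cfg, mean_lifetime = 500, loops_enabled = TRUE,
                  n_mcs = 100)
    total_trials <- total_trials + attr(st, "trials")
    expect_length(validate_state(st, cfg), 0)
  }
  expect_gte(total_trials, 1e5)
})
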