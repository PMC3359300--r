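test_that("whole-fibre MSD matches geometry and the brute-force oracle", {
  rod <- cbind(1:20, 0, 0)
  ens <- make_ensemble(list(rod, rod))
  m <- msd_total(ens)
  expect_equal(m$msd[1], 0)                       # zero separation
  expect_equal(m$msd, (0:19)^2)                   # straight rod: n^2
  expect_equal(m$separation_mb, (0:19) * 0.15)

  set.seed(21)
  confs <- lapply(1:10, function(k)
    apply(matrix(sample(c(-1, 0, 1), 20 * 3, TRUE), 20, 3), 2, cumsum))
  ens2 <- make_ensemble(confs)
  expect_equal(msd_total(ens2)$msd, brute_msd(confs)$msd, tolerance = 1e-12)
})

test_that("loci-specific MSD averages only the marked pairs", {
  rod <- cbind(1:10, 0, 0)
  ens <- make_ensemble(list(rod, rod))
  out <- msd_loci(ens, rbind(c(3, 3), c(2, 5)))
  expect_equal(out$msd, c(0, 9))

  # averaging all pairs at fixed separation reproduces the total MSD
  set.seed(22)
  confs <- lapply(1:5, function(k)
    apply(matrix(sample(c(-1, 0, 1), 12 * 3, TRUE), 12, 3), 2, cumsum))
  ens2 <- make_ensemble(confs)
  n <- 4
  pairs <- cbind(1:(12 - n), (1 + n):12)
  expect_equal(mean(msd_loci(ens2, pairs)$msd),
               msd_total(ens2)$msd[n + 1], tolerance = 1e-12)
})

test_that("loop-size distribution counts bond lengths with the (N - g) factor", {
  # N = 5: three distinct pairs can form a loop of length 2
  bonds <- data.frame(i = c(1, 2), j = c(3, 4), expiry = c(1, 1))
  d <- loop_size_distribution(bonds, N = 5)
  expect_equal(d$dist$g, 2)
  expect_equal(d$dist$p, 1)
  expect_equal(d$dist$n_pairs, 3)

  ens <- make_ensemble(list(cbind(1:6, 0, 0), cbind(1:6, 0, 0)),
                       loops = list(data.frame(i = 1L, j = 4L, expiry = 1),
                                    data.frame(i = 2L, j = 4L, expiry = 2)))
  d2 <- loop_size_distribution(ens)
  expect_equal(d2$dist$g, c(2, 3))
  expect_equal(d2$dist$p, c(0.5, 0.5))
  expect_error(loop_size_distribution(
    make_ensemble(list(cbind(1:6, 0, 0)))), "no loop bonds")
})

test_that("loop exponent fit recovers constructed power laws", {
  N <- 100
  g <- 2:80
  make_dist <- function(alpha) {
    counts <- round(1e7 * (N - g) * g^alpha / sum((N - g) * g^alpha))
    bonds <- data.frame(i = rep(1, length(g)), j = 1 + g)
    # expand counts into a bond table via direct construction
    tab <- data.frame(i = rep(bonds$i, counts), j = rep(bonds$j, counts))
    loop_size_distribution(tab, N = N)
  }
  expect_lt(abs(fit_loop_exponent(make_dist(-1.5)) + 1.5), 0.02)
  expect_lt(abs(fit_loop_exponent(make_dist(0))), 0.02)
  a <- fit_loop_exponent(make_dist(-1.18))
  expect_lt(abs(a + 1.18), 0.02)
  expect_gte(attr(a, "n_points"), 4)
})

test_that("GKDE density is a true kernel sum with expected structure", {
  set.seed(30)
  toy <- matrix(rnorm(30), 10, 3)
  expect_equal(local_density_gkde(toy)$density, brute_gkde(toy),
               tolerance = 1e-12)

  # tight cluster is denser than the same points spread out
  tight <- matrix(rnorm(60, sd = 0.5), 20, 3)
  spread <- tight * 10
  expect_true(all(local_density_gkde(tight)$density >
                  local_density_gkde(spread)$density))

  # two well-separated congruent clusters have equal within-cluster density
  cl <- matrix(rnorm(30, sd = 0.3), 10, 3)
  both <- rbind(cl, cl + 100)
  dens <- local_density_gkde(both)$density
  expect_equal(dens[1:10], dens[11:20], tolerance = 0.01)
})

test_that("volume ratio is the inverse density ratio and inverts on swap", {
  regions <- data.frame(label = c("high", "low"), start = c(1L, 11L),
                        end = c(10L, 20L))
  df <- structure(list(density = c(rep(2, 10), rep(2, 10)),
                       bandwidth = c(1, 1, 1), n_conformations = 1L),
                  class = "density_field")
  expect_equal(volume_ratio(df, regions), 1)

  df$density <- c(rep(1, 10), rep(2, 10))   # rho_low = 2 rho_high
  expect_equal(volume_ratio(df, regions), 2)

  swapped <- regions
  swapped$label <- rev(swapped$label)
  expect_equal(volume_ratio(df, swapped), 1 / volume_ratio(df, regions))
  expect_error(volume_ratio(df, regions[1, ]), "required")
})

test_that("gyration tensor is the centred second moment with trace Rg^2", {
  expect_equal(gyration_tensor(matrix(c(5, 2, 1), 1, 3)),
               matrix(0, 3, 3))
  two <- rbind(c(-2, 0, 0), c(2, 0, 0))         # d = 4: Q_xx = d^2/4
  Q <- gyration_tensor(two)
  expect_equal(Q[1, 1], 4)
  expect_equal(sum(abs(Q)) - Q[1, 1], 0)

  set.seed(33)
  for (rep in 1:20) {
    pts <- matrix(rnorm(3 * sample(5:50, 1)), ncol = 3)
    M <- nrow(pts)
    # Lagrange identity: Rg^2 = (1 / 2M^2) sum_ij |r_i - r_j|^2
    pair_sum <- 0
    for (i in 1:M) for (j in 1:M)
      pair_sum <- pair_sum + sum((pts[i, ] - pts[j, ])^2)
    expect_equal(sum(diag(gyration_tensor(pts))), pair_sum / (2 * M^2),
                 tolerance = 1e-10)
  }
})

test_that("asphericity interpolates between sphere and rod and is scale-free", {
  expect_equal(asphericity(c(2, 1, 1)), 0.0625)
  expect_equal(asphericity(c(3, 3, 3)), 0)
  expect_equal(asphericity(c(5, 0, 0)), 1)
  set.seed(34)
  for (rep in 1:50) {
    l <- runif(3, 0, 10)
    expect_equal(asphericity(l * runif(1, 0.1, 100)), asphericity(l))
  }
  expect_error(asphericity(c(0, 0, 0)), "zero")
  expect_error(asphericity(c(-1, 1, 1)), "non-negative")
})

test_that("radial metrics identify the territory centre and surface", {
  # cube corners around an interior point at the centre-of-mass
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  pts <- rbind(corners, c(0, 0, 0))
  r <- radial_metrics(pts)
  expect_equal(r$center_sq[9], 0)               # centre point
  expect_equal(r$surface_sq[1:8], rep(0, 8))    # hull vertices
  expect_equal(r$surface_sq[9], 1)              # unit distance to each face

  # dense sphere: centre point sits ~R from the surface
  set.seed(35)
  u <- matrix(rnorm(1500), ncol = 3)
  u <- rbind(u, -u)                     # point-symmetric: com exactly 0
  sph <- 5 * u / sqrt(rowSums(u^2))
  rs <- radial_metrics(rbind(sph, c(0, 0, 0)))
  expect_equal(sqrt(rs$surface_sq[1001]), 5, tolerance = 0.02)
  expect_equal(rs$center_sq[1:1000], rep(25, 1000), tolerance = 1e-10)
})

test_that("MSMD is measured in the territory frame and detects diffusion", {
  frozen <- array(rep(cbind(1:10, 0, 0), 5), dim = c(10, 3, 5))
  traj <- dynloop:::build_trajectory(
    lapply(1:5, function(k) cbind(1:10, 0L, 0L)), 1:5, 1L)
  expect_true(all(msmd(traj, max_lag_frames = 3)$msmd == 0))

  # rigid translation of the whole chain is invisible in the com frame
  moving <- lapply(1:6, function(k) cbind(1:10 + 3L * k, 0L, k))
  traj2 <- dynloop:::build_trajectory(moving, 1:6, 1L)
  expect_true(all(msmd(traj2, max_lag_frames = 4)$msmd == 0))

  # independent unconfined walkers: MSMD grows linearly in lag time
  set.seed(36)
  nw <- 40; nt <- 2000
  dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  walks <- array(0L, dim = c(nw, 3, nt))
  for (t in 2:nt)
    walks[, , t] <- walks[, , t - 1] + dirs[sample.int(6, nw, TRUE), ]
  traj3 <- dynloop:::build_trajectory(
    lapply(seq_len(nt), function(t) walks[, , t]), seq_len(nt), 1L)
  curves <- msmd(traj3, edge_exclusion = 0, max_lag_frames = 20)
  ratio <- curves$msmd_over_t
  expect_lt(max(abs(ratio - mean(ratio))) / mean(ratio), 0.10)
})

test_that("expression correlations agree with closed forms and rank oracle", {
  e <- c(1, 4, 2, 8, 5)
  up <- correlate_with_expression(2 * e + 1, e)
  expect_equal(up$estimate, c(1, 1))
  down <- correlate_with_expression(-e, e)
  expect_equal(down$estimate, c(-1, -1))

  set.seed(37)
  x <- rnorm(5); y <- rnorm(5)
  out <- correlate_with_expression(x, y)
  expect_equal(out$estimate[out$method == "spearman"], brute_spearman(x, y))
  expect_error(correlate_with_expression(rep(1, 5), e), "constant")
})

test_that("lattice scaling solves the least-squares match of MSD curves", {
  sim <- data.frame(separation_mb = seq(0.5, 10, by = 0.5),
                    msd = seq(0.5, 10, by = 0.5)^1.2)
  exp4 <- data.frame(mb = sim$separation_mb, um2 = 4 * sim$msd)
  expect_equal(lattice_scaling(sim, exp4), 2)
  exp1 <- data.frame(mb = sim$separation_mb, um2 = sim$msd)
  expect_equal(lattice_scaling(sim, exp1), 1)
  expect_error(lattice_scaling(sim, data.frame(mb = c(100, 200), um2 = c(1, 2))),
               "overlap")
})
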