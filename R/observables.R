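#' Mean square spatial distance of the whole fibre
#'
#' For every contour separation `n` the squared Euclidean distance between
#' monomers `i` and `i + n` is averaged over all positions `i` and all
#' conformations of the ensemble (unwrapped lattice coordinates, so the
#' result is in lattice units squared). The large-`n` plateau of this curve
#' is the "leveling-off" characteristic of looped chromatin.
#'
#' @param ensemble A `dl_ensemble`.
#' @param monomer_mb Genomic content of one monomer in Mb (for the
#'   `separation_mb` column).
#' @return Data frame with columns `separation` (monomers), `separation_mb`,
#'   `msd` (lattice units squared). `msd[separation == 0]` is 0.
#' @export
msd_total <- function(ensemble, monomer_mb = 0.15) {
  P <- ensemble$positions
  N <- dim(P)[1]; nc <- dim(P)[3]
  if (nc < 2) stop("need at least two conformations")
  msd <- numeric(N)
  for (n in seq_len(N - 1)) {
    D <- P[(1 + n):N, , , drop = FALSE] - P[1:(N - n), , , drop = FALSE]
    msd[n + 1] <- sum(as.numeric(D)^2) / ((N - n) * nc)
  }
  data.frame(separation = 0:(N - 1),
             separation_mb = (0:(N - 1)) * monomer_mb,
             msd = msd)
}

#' Loci-specific mean square distance
#'
#' Ensemble-averaged squared distance for selected monomer pairs, mirroring
#' what FISH probes measure: only the marked loci enter the average.
#'
#' @param ensemble A `dl_ensemble`.
#' @param loci_pairs Two-column matrix or data frame of monomer index pairs
#'   `(i, k)`.
#' @return Data frame with columns `i`, `k`, `msd`.
#' @export
msd_loci <- function(ensemble, loci_pairs) {
  loci_pairs <- as.matrix(loci_pairs)
  if (ncol(loci_pairs) != 2) stop("loci_pairs needs two columns")
  P <- ensemble$positions
  N <- dim(P)[1]
  if (any(loci_pairs < 1) || any(loci_pairs > N))
    stop("locus index outside the chain")
  msd <- vapply(seq_len(nrow(loci_pairs)), function(r) {
    D <- P[loci_pairs[r, 2], , , drop = FALSE] - P[loci_pairs[r, 1], , , drop = FALSE]
    mean(colSums(matrix(as.numeric(D), nrow = 3)^2))
  }, numeric(1))
  data.frame(i = loci_pairs[, 1], k = loci_pairs[, 2], msd = msd)
}

#' Loop-size distribution
#'
#' Histogram of loop lengths `g = j - i` (contour monomers) over the active
#' loop bonds of every snapshot, normalised to an empirical probability. The
#' combinatorial factor `N - g` -- the number of distinct monomer pairs at
#' separation `g`, i.e. the maximum number of loops of that length -- is
#' returned alongside for the exponent fit.
#'
#' @param x A `dl_ensemble`, or a data frame of bonds with columns `i`, `j`
#'   (a bond-event log).
#' @param N Chain length; required when `x` is a bare bond table.
#' @return A `loop_distribution` object: data frame `dist` with columns `g`,
#'   `count`, `p`, `n_pairs`, plus `N` and the total bond count.
#' @export
loop_size_distribution <- function(x, N = NULL) {
  if (inherits(x, "dl_ensemble")) {
    bonds <- do.call(rbind, x$loops)
    N <- x$N
  } else {
    bonds <- as.data.frame(x)
    if (is.null(N)) stop("supply the chain length N with a bare bond table")
  }
  if (is.null(bonds) || nrow(bonds) == 0)
    stop("no loop bonds observed")
  g <- abs(bonds$j - bonds$i)
  tab <- table(g)
  gs <- as.integer(names(tab))
  counts <- as.integer(tab)
  structure(list(dist = data.frame(g = gs, count = counts,
                                   p = counts / sum(counts),
                                   n_pairs = N - gs),
                 N = N, total = sum(counts)),
            class = "loop_distribution")
}

#' @export
print.loop_distribution <- function(x, ...) {
  cat("loop distribution:", x$total, "bonds, g in [",
      min(x$dist$g), ",", max(x$dist$g), "] on N =", x$N, "\n")
  invisible(x)
}

#' Fit the short-loop exponent alpha
#'
#' Over short genomic loops (0.5-7 Mb by default) the loop probability
#' behaves as `P(g) ~ (N - g) * g^alpha`. Dividing out the combinatorial
#' factor, `alpha` is the least-squares slope of `log(P(g) / (N - g))`
#' against `log(g)` over the fit range.
#'
#' @param dist A [loop_size_distribution()].
#' @param fit_range_mb Genomic fit window in Mb.
#' @param monomer_mb Genomic content of one monomer in Mb.
#' @return The fitted exponent `alpha`, with the number of fitted points and
#'   the range as attributes.
#' @export
fit_loop_exponent <- function(dist, fit_range_mb = c(0.5, 7),
                              monomer_mb = 0.15) {
  stopifnot(inherits(dist, "loop_distribution"))
  d <- dist$dist
  g_mb <- d$g * monomer_mb
  keep <- g_mb >= fit_range_mb[1] & g_mb <= fit_range_mb[2] &
    d$count > 0 & d$n_pairs > 0
  if (sum(keep) < 4)
    stop("fewer than 4 loop lengths in the fit range; widen the range or ",
         "sample more bonds")
  x <- log(d$g[keep])
  y <- log(d$p[keep] / d$n_pairs[keep])
  alpha <- unname(coef(lm(y ~ x))[2])
  attr(alpha, "n_points") <- sum(keep)
  attr(alpha, "fit_range_mb") <- fit_range_mb
  alpha
}

# 3-D Gaussian product-kernel density of one conformation, evaluated at the
# monomer positions themselves; Scott's rule bandwidth per dimension.
gkde_at_monomers <- function(coords) {
  n <- nrow(coords)
  bw <- apply(coords, 2, sd) * n^(-1 / 7)
  if (any(bw <= 0)) stop("degenerate conformation: zero spread in a dimension")
  Z <- sweep(coords, 2, bw, "/")
  sq <- rowSums(Z^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Z)
  dens <- rowSums(exp(-0.5 * pmax(D2, 0))) / (n * (2 * pi)^1.5 * prod(bw))
  list(density = dens, bandwidth = bw)
}

#' Local chromatin density by 3-D Gaussian kernel density estimation
#'
#' For each conformation a Gaussian kernel density estimate is fitted to the
#' N monomer positions (product kernel, Scott's-rule bandwidth per
#' dimension, recorded in the output) and evaluated at each monomer's own
#' position; the per-monomer densities are then averaged over the ensemble.
#' High local density marks compact (lowly expressed) chromatin.
#'
#' @param ensemble A `dl_ensemble`, or a single N x 3 coordinate matrix.
#' @return A `density_field` object: list with `density` (ensemble-averaged
#'   per-monomer density), `bandwidth` (mean Scott bandwidth per dimension)
#'   and `n_conformations`.
#' @export
local_density_gkde <- function(ensemble) {
  if (is.matrix(ensemble)) {
    one <- gkde_at_monomers(ensemble)
    return(structure(list(density = one$density, bandwidth = one$bandwidth,
                          n_conformations = 1L), class = "density_field"))
  }
  P <- ensemble$positions
  nc <- dim(P)[3]
  dens <- matrix(0, dim(P)[1], nc)
  bw <- matrix(0, 3, nc)
  for (k in seq_len(nc)) {
    one <- gkde_at_monomers(P[, , k])
    dens[, k] <- one$density
    bw[, k] <- one$bandwidth
  }
  structure(list(density = rowMeans(dens), bandwidth = rowMeans(bw),
                 n_conformations = nc), class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat("local density field:", length(x$density), "monomers over",
      x$n_conformations, "conformations; mean Scott bandwidth",
      format(mean(x$bandwidth), digits = 3), "\n")
  invisible(x)
}

#' Volume ratio of highly to lowly expressed chromatin
#'
#' The volume a region occupies is inversely proportional to its mean local
#' density, so `V_high / V_low = rho_low / rho_high` with `rho` the mean
#' [local_density_gkde()] density over the monomers of each region. Values
#' above 1 mean the highly expressed chromatin is decondensed relative to
#' the lowly expressed chromatin.
#'
#' @param density A `density_field`.
#' @param regions Region data frame (`label` in `high`/`low`, `start`,
#'   `end`, monomer indices 1-based inclusive).
#' @return The ratio `V_high / V_low`.
#' @export
volume_ratio <- function(density, regions) {
  stopifnot(inherits(density, "density_field"))
  n <- length(density$density)
  validate_regions(regions, n)
  hi <- region_members(regions, "high", n)
  lo <- region_members(regions, "low", n)
  if (length(hi) == 0 || length(lo) == 0)
    stop("both 'high' and 'low' regions are required")
  mean(density$density[lo]) / mean(density$density[hi])
}

#' Gyration tensor of a point set
#'
#' Centered second-moment tensor
#' `Q_ab = (1/M) * sum_k (r_ka - rbar_a) (r_kb - rbar_b)`; symmetric positive
#' semidefinite with `trace(Q) = Rg^2`.
#'
#' @param coords M x 3 coordinate matrix.
#' @return 3 x 3 gyration tensor.
#' @export
gyration_tensor <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be M x 3")
  centered <- sweep(coords, 2, colMeans(coords))
  crossprod(centered) / nrow(coords)
}

#' Asphericity from gyration-tensor eigenvalues
#'
#' Normalised eigenvalue dispersion
#' \deqn{A = \frac{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
#'   (\lambda_3-\lambda_1)^2}{2(\lambda_1+\lambda_2+\lambda_3)^2}}
#' which is 0 for a perfectly spherical monomer distribution (all
#' eigenvalues equal) and 1 for a rod (a single nonzero eigenvalue), and is
#' invariant under rescaling of the eigenvalues.
#'
#' @param eigenvalues Three non-negative gyration-tensor eigenvalues (tiny
#'   negative values from numerical eigen-decomposition are clamped).
#' @return Asphericity in `[0, 1]`.
#' @export
asphericity <- function(eigenvalues) {
  l <- as.numeric(eigenvalues)
  if (length(l) != 3) stop("need exactly three eigenvalues")
  if (any(l < -1e-8 * max(abs(l), 1))) stop("eigenvalues must be non-negative")
  l <- pmax(l, 0)
  s <- sum(l)
  if (s == 0) stop("all eigenvalues zero: shape undefined")
  ((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) / (2 * s^2)
}

#' Shape of a conformation or ensemble
#'
#' Gyration tensor, its eigenvalues, `Rg^2 = trace(Q)` and the asphericity.
#' For an ensemble the per-conformation shape measures are averaged
#' (asphericity per conformation, then the ensemble mean, as for all other
#' observables); pass `monomers` to restrict to a genomic region.
#'
#' @param x An N x 3 coordinate matrix or a `dl_ensemble`.
#' @param monomers Optional monomer subset (indices).
#' @return For a matrix: list with `Q`, `eigenvalues` (decreasing), `rg2`,
#'   `asphericity`. For an ensemble: data frame of per-conformation `rg2`
#'   and `asphericity` with ensemble means as attributes.
#' @export
shape_metrics <- function(x, monomers = NULL) {
  if (is.matrix(x)) {
    if (!is.null(monomers)) x <- x[monomers, , drop = FALSE]
    Q <- gyration_tensor(x)
    ev <- sort(eigen(Q, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    return(list(Q = Q, eigenvalues = ev, rg2 = sum(diag(Q)),
                asphericity = asphericity(ev)))
  }
  stopifnot(inherits(x, "dl_ensemble"))
  P <- x$positions
  nc <- dim(P)[3]
  res <- vapply(seq_len(nc), function(k) {
    s <- shape_metrics(P[, , k], monomers)
    c(s$rg2, s$asphericity)
  }, numeric(2))
  out <- data.frame(conformation = seq_len(nc), rg2 = res[1, ],
                    asphericity = res[2, ])
  attr(out, "mean_rg2") <- mean(out$rg2)
  attr(out, "mean_asphericity") <- mean(out$asphericity)
  out
}

#' Radial positioning inside the chromosome territory
#'
#' Per conformation, the territory centre is the monomer centre-of-mass and
#' the territory surface is the convex hull of the monomer positions. For
#' each monomer the squared distance to the centre and the squared distance
#' to the nearest hull facet are computed and then ensemble-averaged. Highly
#' expressed chromatin is expected close to the surface (large centre
#' distance, small surface distance).
#'
#' @param ensemble A `dl_ensemble` (or single N x 3 coordinate matrix).
#' @return Data frame with columns `monomer`, `center_sq`, `surface_sq`
#'   (lattice units squared).
#' @export
radial_metrics <- function(ensemble) {
  one <- function(coords) {
    com <- colMeans(coords)
    d2c <- rowSums(sweep(coords, 2, com)^2)
    hull <- cpp_hull_planes(coords)
    ds <- cpp_dist_to_hull(coords, hull$normals, hull$offsets)
    cbind(d2c, ds^2)
  }
  if (is.matrix(ensemble)) {
    m <- one(ensemble)
    return(data.frame(monomer = seq_len(nrow(m)),
                      center_sq = m[, 1], surface_sq = m[, 2]))
  }
  stopifnot(inherits(ensemble, "dl_ensemble"))
  P <- ensemble$positions
  nc <- dim(P)[3]
  acc <- matrix(0, dim(P)[1], 2)
  for (k in seq_len(nc)) acc <- acc + one(P[, , k] * 1.0)
  acc <- acc / nc
  data.frame(monomer = seq_len(dim(P)[1]),
             center_sq = acc[, 1], surface_sq = acc[, 2])
}

#' Mean square monomer displacement inside the territory
#'
#' Mobility of the fibre relative to its own territory: with
#' `delta_i(t0, t) = [r_i(t0 + t) - r_cm(t0 + t)] - [r_i(t0) - r_cm(t0)]`,
#' the MSMD at lag `t` is the mean of `|delta|^2` over time origins and over
#' the monomers of each region. A fraction `edge_exclusion` of monomers at
#' each chain end is excluded (chain ends diffuse differently). The
#' diagnostic column `msmd_over_t` is constant for normal diffusion;
#' a decreasing curve reveals the anomalous, confined diffusion of
#' territory-bound chromatin.
#'
#' @param trajectory A `dl_trajectory` (dense, equally spaced frames).
#' @param regions Optional region data frame; curves are computed for each
#'   label and for `total`.
#' @param edge_exclusion Fraction of monomers excluded at each chain end.
#' @param max_lag_frames Largest lag, in frames.
#' @return Data frame with columns `region`, `t_mcs`, `msmd`, `msmd_over_t`.
#' @export
msmd <- function(trajectory, regions = NULL, edge_exclusion = 0.05,
                 max_lag_frames = 100) {
  stopifnot(inherits(trajectory, "dl_trajectory"))
  P <- trajectory$positions * 1.0
  N <- dim(P)[1]; nt <- dim(P)[3]
  if (nt < 2) stop("trajectory too short")
  com <- apply(P, c(2, 3), mean)
  rel <- P - rep(1, N) %o% com           # N x 3 x T relative coordinates
  edge <- floor(edge_exclusion * N)
  interior <- setdiff(seq_len(N), c(seq_len(edge), N - seq_len(edge) + 1))
  groups <- list(total = interior)
  if (!is.null(regions)) {
    validate_regions(regions, N)
    for (lab in unique(regions$label))
      groups[[lab]] <- intersect(region_members(regions, lab, N), interior)
  }
  lags <- seq_len(min(max_lag_frames, nt - 1))
  out <- lapply(names(groups), function(lab) {
    idx <- groups[[lab]]
    if (length(idx) == 0) return(NULL)
    m <- vapply(lags, function(l) {
      D <- rel[idx, , (1 + l):nt, drop = FALSE] -
        rel[idx, , 1:(nt - l), drop = FALSE]
      sum(D^2) / (length(idx) * (nt - l))
    }, numeric(1))
    t_mcs <- lags * trajectory$every
    data.frame(region = lab, t_mcs = t_mcs, msmd = m,
               msmd_over_t = m / t_mcs)
  })
  do.call(rbind, out)
}

#' Correlate a per-monomer observable with expression
#'
#' Pearson and Spearman correlation (with two-sided p-values) between a
#' per-monomer metric -- local density, squared distance to centre or
#' surface -- and the expression profile.
#'
#' @param metric Numeric per-monomer vector.
#' @param expression A `binned_expression` or numeric level vector of the
#'   same length.
#' @return Data frame with columns `method`, `estimate`, `p_value`.
#' @export
correlate_with_expression <- function(metric, expression) {
  e <- if (inherits(expression, "binned_expression")) expression$levels
       else as.numeric(expression)
  metric <- as.numeric(metric)
  if (length(metric) != length(e)) stop("metric and expression lengths differ")
  if (length(e) < 3) stop("need at least 3 monomers")
  if (sd(metric) == 0 || sd(e) == 0) stop("constant input: correlation undefined")
  pe <- cor.test(metric, e, method = "pearson")
  sp <- suppressWarnings(cor.test(metric, e, method = "spearman",
                                  exact = FALSE))
  data.frame(method = c("pearson", "spearman"),
             estimate = c(unname(pe$estimate), unname(sp$estimate)),
             p_value = c(pe$p.value, sp$p.value))
}

#' Lattice-to-physical scaling factor
#'
#' Least-squares match of the simulated MSD curve (lattice units squared) to
#' an experimental MSD table (micrometres squared vs genomic separation in
#' Mb): the factor `s` (micrometres per lattice unit) minimises
#' `sum(s^2 * MSD_lattice - MSD_um)^2` after interpolating the simulated
#' curve to the experimental abscissae.
#'
#' @param sim_msd Data frame from [msd_total()] (columns `separation_mb`,
#'   `msd`).
#' @param exp_msd Data frame or matrix with genomic separation in Mb (column
#'   1) and MSD in micrometres squared (column 2).
#' @return Scaling factor `s` in micrometres per lattice unit.
#' @export
lattice_scaling <- function(sim_msd, exp_msd) {
  exp_msd <- as.data.frame(exp_msd)
  mb <- exp_msd[[1]]; um2 <- exp_msd[[2]]
  sim <- approx(sim_msd$separation_mb, sim_msd$msd, xout = mb)$y
  keep <- is.finite(sim) & is.finite(um2) & sim > 0
  if (sum(keep) < 2)
    stop("no overlap between simulated and experimental separations")
  s2 <- sum(sim[keep] * um2[keep]) / sum(sim[keep]^2)
  if (s2 <= 0) stop("non-positive scaling; check the input curves")
  sqrt(s2)
}
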