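#' Simulation parameters
#'
#' Bundles every knob of a Dynamic Loop run. Defaults follow the calibrated
#' chromosome setup: one monomer per 150 kb, lattice size `L = 600`, minimum
#' affinity 0.01, maximum affinity 0.065, mean bond lifetime 8000 MCS, two
#' equilibration phases of `equilibration_mcs` MCS each and at least 1000
#' decorrelated conformations sampled every `2*tau` MCS.
#'
#' @param N Chain length.
#' @param L Linear lattice size.
#' @param a_min,a_max Affinity bounds.
#' @param mean_lifetime Mean Poisson bond lifetime (MCS).
#' @param equilibration_mcs MCS per equilibration phase.
#' @param n_conformations Ensemble size to generate.
#' @param sample_interval `"auto"` (every `ceiling(2*tau)` MCS, with `tau`
#'   estimated from a pilot segment) or a fixed positive integer interval.
#' @param pilot_mcs Length of the pilot segment used to estimate `tau` under
#'   the auto policy.
#' @param trajectory_every Dense-stream recording interval in MCS (0 = off);
#'   needed for the MSMD observable.
#' @param trajectory_frames Cap on dense-stream frames.
#' @param seed Integer seed for the single RNG stream of the run.
#' @return A `sim_params` object.
#' @export
sim_params <- function(N, L = 600L, a_min = 0.01, a_max = 0.065,
                       mean_lifetime = 8000, equilibration_mcs = 200000,
                       n_conformations = 1000, sample_interval = "auto",
                       pilot_mcs = 4000, trajectory_every = 0,
                       trajectory_frames = 1000, seed = 1L) {
  if (N < 2) stop("N must be >= 2")
  if (equilibration_mcs <= 0) stop("equilibration_mcs must be positive")
  if (n_conformations < 1) stop("n_conformations must be >= 1")
  if (!(identical(sample_interval, "auto") ||
        (is.numeric(sample_interval) && sample_interval >= 1)))
    stop("sample_interval must be \"auto\" or a positive integer")
  structure(list(N = as.integer(N), L = as.integer(L), a_min = a_min,
                 a_max = a_max, mean_lifetime = mean_lifetime,
                 equilibration_mcs = equilibration_mcs,
                 n_conformations = as.integer(n_conformations),
                 sample_interval = sample_interval,
                 pilot_mcs = pilot_mcs,
                 trajectory_every = as.integer(trajectory_every),
                 trajectory_frames = as.integer(trajectory_frames),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# thin wrapper around the compiled engine; returns the full engine payload
run_engine <- function(state, affinities, config, mean_lifetime, loops_enabled,
                       n_mcs, snapshot_every = 0, rg_every = 0,
                       traj_every = 0, max_traj_frames = 0) {
  res <- cpp_run(state$positions, loops_i(state), loops_j(state),
                 loops_e(state), state$mcs_clock, as.integer(n_mcs),
                 as.integer(config$L),
                 as_affinities(affinities, state$N), mean_lifetime,
                 isTRUE(loops_enabled), as.integer(snapshot_every),
                 as.integer(rg_every), as.integer(traj_every),
                 as.integer(max_traj_frames))
  res$state <- new_polymer_state(res$positions,
                                 as.data.frame(res$loops), res$mcs_clock)
  res
}

#' Advance the chain by whole Monte-Carlo steps
#'
#' One Monte-Carlo step (MCS) is N trial moves, so each monomer is on
#' average translated once per MCS. After each accepted move a loop-formation
#' attempt is made for the moved monomer (when loops are enabled); expired
#' bonds are dissolved once per MCS, after the N trial moves, and the MCS
#' clock advances by one.
#'
#' @param state A `polymer_state`.
#' @param affinities Affinity profile or vector (recycled scalar allowed).
#' @param config A [lattice_config()].
#' @param mean_lifetime Mean Poisson bond lifetime (MCS).
#' @param loops_enabled Disable for a pure self-avoiding chain.
#' @param n_mcs Number of MCS to run.
#' @return The advanced `polymer_state`, with attributes `trials` and
#'   `accepts` counting elementary moves.
#' @export
run_mcs <- function(state, affinities, config = lattice_config(),
                    mean_lifetime = 8000, loops_enabled = TRUE, n_mcs = 1) {
  res <- run_engine(state, affinities, config, mean_lifetime, loops_enabled,
                    n_mcs)
  out <- res$state
  attr(out, "trials") <- res$trials
  attr(out, "accepts") <- res$accepts
  out
}

#' Two-phase equilibration
#'
#' Phase 1 runs `equilibration_mcs` MCS with loop formation rejected,
#' producing a random self-avoiding starting conformation; phase 2 runs the
#' same number of MCS with looping enabled so the loop population reaches its
#' stationary state before production sampling.
#'
#' @inheritParams run_mcs
#' @param equilibration_mcs MCS per phase.
#' @param rg_every Record the squared radius of gyration every this many MCS
#'   (0 = off); the recorded series of each phase is attached as attributes
#'   `rg_phase1` / `rg_phase2` for stationarity diagnostics
#'   ([stationarity_p_value()]).
#' @return The equilibrated `polymer_state`.
#' @export
equilibrate <- function(state, affinities, config = lattice_config(),
                        mean_lifetime = 8000, equilibration_mcs = 200000,
                        rg_every = 0) {
  p1 <- run_engine(state, affinities, config, mean_lifetime,
                   loops_enabled = FALSE, n_mcs = equilibration_mcs,
                   rg_every = rg_every)
  stopifnot(nrow(p1$state$loops) == 0)
  p2 <- run_engine(p1$state, affinities, config, mean_lifetime,
                   loops_enabled = TRUE, n_mcs = equilibration_mcs,
                   rg_every = rg_every)
  out <- p2$state
  if (rg_every > 0) {
    attr(out, "rg_phase1") <- data.frame(mcs = p1$rg_mcs, rg2 = p1$rg2)
    attr(out, "rg_phase2") <- data.frame(mcs = p2$rg_mcs, rg2 = p2$rg2)
  }
  out
}

#' Trend p-value of a time series (Mann-Kendall)
#'
#' Stationarity diagnostic for the tail of an equilibration run: the
#' two-sided p-value of Kendall's rank correlation between the series and
#' time. Small values indicate a residual monotone trend, i.e. incomplete
#' equilibration.
#'
#' @param series Numeric series (e.g. late-phase `Rg^2` values).
#' @return Two-sided p-value.
#' @export
stationarity_p_value <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 8) stop("series too short for a trend test")
  suppressWarnings(
    cor.test(seq_along(series), series, method = "kendall")$p.value)
}

#' Autocorrelation time by exponential fit
#'
#' Computes the normalised autocorrelation function of the series and fits
#' `C(t) = exp(-t / tau)` to its decay by least squares on the log scale
#' (through `C(0) = 1`). The fit window runs to the first lag at which the
#' autocorrelation drops below 0.1, with a minimum of `min_lags` lags;
#' non-positive autocorrelations inside the window are dropped from the fit.
#' For a genuinely exponential autocorrelation any window gives the same
#' `tau`; extending it to the 0.1 crossing makes the estimate track the
#' slowest relaxation mode when the decay is multi-exponential (as for the
#' squared radius of gyration of a looped chain), which is the mode that
#' governs the independence of production snapshots.
#'
#' @param series Numeric time series, much longer than the expected `tau`.
#' @param min_lags Minimum number of lags in the fit window.
#' @return Estimated autocorrelation time `tau` (in series time steps).
#' @export
autocorrelation_time <- function(series, min_lags = 5) {
  series <- as.numeric(series)
  series <- series[is.finite(series)]
  if (length(series) < 20) stop("series too short to estimate tau")
  if (sd(series) == 0) stop("constant series: autocorrelation undefined")
  n <- length(series)
  lag_max <- min(n - 1, max(100, floor(n / 4)))
  # FFT-based normalised autocorrelation (same biased-denominator estimator
  # as stats::acf, but O(n log n) on long pilot series)
  x <- series - mean(series)
  m <- stats::nextn(2 * n, 2)
  f <- stats::fft(c(x, rep(0, m - n)))
  raw <- Re(stats::fft(Conj(f) * f, inverse = TRUE))[seq_len(lag_max + 1)]
  ac <- (raw / raw[1])[-1]
  k <- which(ac < 0.1)[1]
  if (is.na(k)) k <- length(ac)
  k <- min(max(k, min_lags), length(ac))
  lags <- seq_len(k)
  keep <- ac[lags] > 0
  if (sum(keep) < 2) return(0.5)   # decorrelated within one step
  x <- lags[keep]
  y <- log(ac[x])
  slope <- sum(x * y) / sum(x * x)   # LS through log C(0) = 0
  if (slope >= 0) return(0.5)
  -1 / slope
}

#' Production sampling of decorrelated conformations
#'
#' Under the `"auto"` interval policy, a pilot segment records `Rg^2(t)`
#' every MCS, the autocorrelation time `tau` is estimated with
#' [autocorrelation_time()], and snapshots are then saved every
#' `ceiling(2 * tau)` MCS -- the spacing at which successive conformations
#' are treated as independent. A dense-interval trajectory stream can be
#' recorded in parallel for the MSMD observable.
#'
#' @inheritParams run_mcs
#' @param n_conformations Number of snapshots to generate.
#' @param interval `"auto"` or a fixed positive integer (MCS).
#' @param pilot_mcs Length of one pilot chunk for the `tau` estimate; chunks
#'   are appended until the pilot series spans at least `40 * tau`.
#' @param trajectory_every Dense-stream interval in MCS (0 = off).
#' @param trajectory_frames Cap on dense-stream frames.
#' @return List with `ensemble` (a `dl_ensemble`), `trajectory` (a
#'   `dl_trajectory` or `NULL`), `state`, `interval`, `tau`.
#' @export
run_production <- function(state, affinities, config = lattice_config(),
                           mean_lifetime = 8000, n_conformations = 1000,
                           interval = "auto", pilot_mcs = 4000,
                           trajectory_every = 0, trajectory_frames = 1000) {
  tau <- NA_real_
  if (identical(interval, "auto")) {
    # the tau estimate is only trustworthy when the pilot series is far
    # longer than tau itself (short-series acf estimates are biased low and
    # very noisy), so the pilot is extended until the series spans
    # >= 400 tau and two successive estimates agree within 30% (capped at
    # 60 pilot chunks)
    rg_series <- numeric(0)
    tau_prev <- Inf
    for (chunk in 1:60) {
      pilot <- run_engine(state, affinities, config, mean_lifetime,
                          loops_enabled = TRUE, n_mcs = pilot_mcs, rg_every = 1)
      state <- pilot$state
      rg_series <- c(rg_series, pilot$rg2)
      tau <- autocorrelation_time(rg_series)
      if (chunk >= 2 && length(rg_series) >= 400 * tau &&
          abs(tau - tau_prev) <= 0.3 * tau_prev) break
      tau_prev <- tau
    }
    interval <- max(1L, as.integer(ceiling(2 * tau)))
  } else {
    interval <- as.integer(interval)
    if (interval < 1) stop("interval must be >= 1 MCS")
  }
  total <- interval * n_conformations
  res <- run_engine(state, affinities, config, mean_lifetime,
                    loops_enabled = TRUE, n_mcs = total,
                    snapshot_every = interval,
                    traj_every = trajectory_every,
                    max_traj_frames = trajectory_frames)
  ens <- build_ensemble(res$snapshots, state$N, interval)
  traj <- NULL
  if (trajectory_every > 0 && length(res$trajectory) > 0) {
    traj <- build_trajectory(res$trajectory, res$trajectory_mcs,
                             trajectory_every)
  }
  list(ensemble = ens, trajectory = traj, state = res$state,
       interval = interval, tau = tau)
}

build_ensemble <- function(snapshots, N, interval = NA_integer_) {
  nc <- length(snapshots)
  if (nc == 0) stop("no snapshots recorded")
  pos <- array(0L, dim = c(N, 3, nc))
  mcs <- numeric(nc)
  loops <- vector("list", nc)
  for (k in seq_len(nc)) {
    pos[, , k] <- snapshots[[k]]$positions
    mcs[k] <- snapshots[[k]]$mcs
    loops[[k]] <- as.data.frame(snapshots[[k]]$loops)
  }
  if (is.unsorted(mcs, strictly = TRUE)) stop("snapshot stamps not increasing")
  structure(list(positions = pos, mcs = mcs, loops = loops, N = N,
                 n_conformations = nc, interval = interval),
            class = "dl_ensemble")
}

build_trajectory <- function(frames, mcs, every) {
  N <- nrow(frames[[1]])
  nt <- length(frames)
  pos <- array(0L, dim = c(N, 3, nt))
  for (k in seq_len(nt)) pos[, , k] <- frames[[k]]
  structure(list(positions = pos, mcs = as.numeric(mcs), every = every, N = N),
            class = "dl_trajectory")
}

#' Assemble an ensemble from coordinate matrices
#'
#' Builds a `dl_ensemble` from externally supplied conformations (e.g. for
#' re-analysing stored coordinates), so every observable can be applied to
#' them.
#'
#' @param conformations List of N x 3 coordinate matrices (equal N).
#' @param loops Optional list of bond data frames (columns `i`, `j`,
#'   `expiry`), one per conformation.
#' @param mcs Optional snapshot stamps (strictly increasing).
#' @return A `dl_ensemble`.
#' @export
as_dl_ensemble <- function(conformations, loops = NULL, mcs = NULL) {
  nc <- length(conformations)
  if (nc == 0) stop("no conformations supplied")
  if (is.null(mcs)) mcs <- seq_len(nc)
  no_loops <- data.frame(i = integer(0), j = integer(0), expiry = numeric(0))
  snaps <- lapply(seq_len(nc), function(k) {
    list(mcs = mcs[k], positions = as.matrix(conformations[[k]]),
         loops = if (is.null(loops)) no_loops else as.data.frame(loops[[k]]))
  })
  build_ensemble(snaps, nrow(snaps[[1]]$positions))
}

#' @export
print.dl_ensemble <- function(x, ...) {
  cat("conformation ensemble:", x$n_conformations, "snapshots of N =", x$N,
      "monomers, sampled every", x$interval, "MCS\n")
  invisible(x)
}

#' @export
print.dl_trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$positions)[3], "frames of N =", x$N,
      "monomers, every", x$every, "MCS\n")
  invisible(x)
}

#' End-to-end simulation of one chromosome
#'
#' Initialises a self-avoiding chain, equilibrates it in two phases (loops
#' rejected, then allowed) and generates a production ensemble of
#' decorrelated conformations. All randomness consumes the single RNG stream
#' seeded from `params$seed`, so `(seed, params)` determines the ensemble
#' exactly.
#'
#' @param affinities An [affinity_profile()] or affinity vector of length
#'   `params$N`.
#' @param params A [sim_params()].
#' @param verbose Emit progress messages.
#' @return As [run_production()], plus `params` and the equilibration
#'   `Rg^2` diagnostics.
#' @export
simulate_chromosome <- function(affinities, params, verbose = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  config <- lattice_config(params$L)
  aff <- as_affinities(affinities, params$N)
  state <- init_random_chain(params$N, config)
  if (verbose) message("equilibrating: 2 x ", params$equilibration_mcs, " MCS")
  state <- equilibrate(state, aff, config, params$mean_lifetime,
                       params$equilibration_mcs,
                       rg_every = max(1L, as.integer(params$equilibration_mcs / 200)))
  rg1 <- attr(state, "rg_phase1"); rg2 <- attr(state, "rg_phase2")
  if (verbose) message("production: ", params$n_conformations, " conformations")
  prod <- run_production(state, aff, config, params$mean_lifetime,
                         params$n_conformations, params$sample_interval,
                         params$pilot_mcs, params$trajectory_every,
                         params$trajectory_frames)
  if (verbose)
    message("sampled every ", prod$interval, " MCS (tau = ",
            format(prod$tau, digits = 3), "); ",
            nrow(prod$state$loops), " loops active at the end")
  prod$params <- params
  prod$rg_phase1 <- rg1
  prod$rg_phase2 <- rg2
  prod
}
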