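#' Parameters of the Metropolis Ising simulation
#'
#' Spins \eqn{s_i = \pm 1} live on the nodes of a unit-weight network (the
#' binary support `w > 0` of the adjacency); the energy counts each unordered
#' bond once, \eqn{E = -J \sum_{\{i,j\}} s_i s_j}. One sweep proposes `n`
#' single-spin flips, each accepted with probability
#' \eqn{\min(e^{-\Delta E / T}, 1)}.
#'
#' @param temperature temperature `T > 0`.
#' @param coupling ferromagnetic coupling `J` (default 1).
#' @param t_max total sweeps (default 5000).
#' @param t_init discarded initial sweeps (default 200).
#' @param p_minus_init probability that an initial spin is -1 (default 0.75).
#' @param sequential propose sites in index (raster) order within a sweep
#'   (default `TRUE`, the conventional reading of one sweep comprising one
#'   proposed flip of each node in turn; it also equilibrates biased initial
#'   conditions faster near criticality). `FALSE` proposes `n` uniformly
#'   random sites per sweep instead; both leave the stationary distribution
#'   unchanged.
#' @param seed integer seed.
#' @return object of class `ising_params`.
#' @export
ising_params <- function(temperature, coupling = 1, t_max = 5000L,
                         t_init = 200L, p_minus_init = 0.75,
                         sequential = TRUE, seed = 1L) {
  if (temperature <= 0) stop("temperature must be positive")
  if (t_init >= t_max) stop("t_init must be smaller than t_max")
  if (p_minus_init < 0 || p_minus_init > 1) stop("p_minus_init must be in [0, 1]")
  structure(list(temperature = temperature, coupling = coupling,
                 t_max = as.integer(t_max), t_init = as.integer(t_init),
                 p_minus_init = p_minus_init, sequential = sequential,
                 seed = as.integer(seed)),
            class = "ising_params")
}

#' Ising energy of a spin configuration
#'
#' \eqn{E = -J \sum_{\{i,j\}} a_{ij} s_i s_j} with each unordered bond of the
#' binary support counted once (the convention under which the square-lattice
#' critical temperature is \eqn{T_c = 2 / \ln(1 + \sqrt 2) \approx 2.27}).
#'
#' @param spins vector of -1/+1 spins.
#' @param net a `weighted_network`; its support pattern defines the bonds.
#' @param coupling coupling constant `J`.
#' @return scalar energy.
#' @examples
#' lat <- build_lattice(lattice_spec(2, 2))
#' ising_energy(rep(1L, 4), lat$network)  # 4 bonds -> -4
#' @export
ising_energy <- function(spins, net, coupling = 1) {
  stopifnot_network(net)
  if (length(spins) != net$n_nodes) stop("spins length must equal n_nodes")
  if (!all(spins %in% c(-1L, 1L))) stop("spins must be -1 or +1")
  a <- support_matrix(net)
  # quadratic form counts every ordered pair -> halve
  -coupling * as.numeric(spins %*% (a %*% spins)) / 2
}

#' Energy change of a single spin flip
#'
#' Computed locally as \eqn{\Delta E = 2 J s_i \sum_{j \sim i} s_j}; equals
#' the global energy difference `energy(after flip) - energy(before)`.
#'
#' @inheritParams ising_energy
#' @param site node index (1-based) of the proposed flip.
#' @return scalar energy change.
#' @export
delta_energy <- function(spins, site, net, coupling = 1) {
  stopifnot_network(net)
  if (site < 1L || site > net$n_nodes) stop("site out of range: ", site)
  a <- support_matrix(net)
  nb_sum <- as.numeric(a[site, , drop = FALSE] %*% spins)
  2 * coupling * spins[site] * nb_sum
}

#' One Metropolis sweep
#'
#' Proposes exactly `n` single-site flips (uniformly random sites with
#' replacement, or sequentially), each accepted with probability
#' \eqn{\min(e^{-\Delta E / T}, 1)}. Consumes R's RNG stream; seed at the R
#' level for reproducibility.
#'
#' @inheritParams ising_energy
#' @param params an `ising_params` (temperature, coupling, sequential flag).
#' @return updated spin vector.
#' @export
metropolis_sweep <- function(spins, net, params) {
  stopifnot_network(net)
  if (!inherits(params, "ising_params")) stop("expected ising_params")
  if (!all(spins %in% c(-1L, 1L))) stop("spins must be -1 or +1")
  adj <- csc_parts(support_matrix(net))
  cpp_metropolis_sweeps(as.integer(spins), adj$p, adj$i, 1L,
                        params$temperature, params$coupling, params$sequential)
}

#' Run the Ising model on a network
#'
#' Initial spins are -1 with probability `p_minus_init` (+1 otherwise); the
#' simulation runs `t_max` sweeps and discards the first `t_init`, returning
#' the n x (t_max - t_init) spin raster. Seeded and deterministic.
#'
#' @param net a `weighted_network` (bonds = binary support).
#' @param params an `ising_params`.
#' @return object of class `spin_raster`: list with `raster` (entries -1/+1)
#'   and `params`.
#' @export
run_ising <- function(net, params) {
  stopifnot_network(net)
  if (!inherits(params, "ising_params")) stop("expected ising_params")
  n <- net$n_nodes
  adj <- csc_parts(support_matrix(net))
  withr::with_seed(params$seed, {
    init <- ifelse(stats::runif(n) < params$p_minus_init, -1L, 1L)
    raster <- cpp_run_ising(adj$p, adj$i, n, params$temperature,
                            params$coupling, params$t_max, params$t_init,
                            init, params$sequential)
  })
  structure(list(raster = raster, params = params), class = "spin_raster")
}

#' @export
print.spin_raster <- function(x, ...) {
  cat("<spin_raster> ", nrow(x$raster), " sites x ", ncol(x$raster),
      " sweeps, T=", x$params$temperature, "\n", sep = "")
  invisible(x)
}

#' Temperature sweep of the Ising model
#'
#' One independent seeded run per temperature; assembles the same indicator
#' curves as [threshold_sweep()], with the total-activity series replaced by
#' the absolute magnetization \eqn{|\sum_i s_i(t)|} and clusters computed in
#' `"same_value"` mode (same-spin domains). Per-subsystem series are
#' computed when a parcellation is given.
#'
#' @param net a `weighted_network`.
#' @param temperatures ascending numeric grid (>= 2 values); the standard
#'   protocol uses 30 equally spaced values between 0.01 and 4.5.
#' @param params_base an `ising_params` acting as template and master seed.
#' @inheritParams threshold_sweep
#' @return a `sweep_result`.
#' @export
temperature_sweep <- function(net, temperatures, params_base, parc = NULL,
                              labels = NULL, keep_series = FALSE) {
  stopifnot_network(net)
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 2L) stop("need at least 2 temperature values")
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("temperatures must be strictly ascending")
  }
  if (!is.null(parc) && is.null(labels)) labels <- attr(parc, "levels")
  adj <- csc_parts(support_matrix(net))
  rows <- lapply(seq_along(temperatures), function(k) {
    p <- params_base
    p$temperature <- temperatures[k]
    p$seed <- derive_subseed(params_base$seed, k)
    sr <- run_ising(net, p)
    out <- summarize_run(sr$raster, adj, mode = 1L, net = net, parc = parc,
                         labels = labels, keep_series = keep_series)
    rm(sr)
    out
  })
  sweep_result(grid = temperatures, rows = rows, control = "temperature",
               params = params_base,
               seeds = vapply(seq_along(temperatures),
                              function(k) derive_subseed(params_base$seed, k),
                              integer(1)))
}

#' Standard temperature grid
#'
#' 30 equally spaced temperatures between 0.01 and 4.5, the protocol used for
#' the square-lattice simulations.
#' @param n_points number of grid points (default 30).
#' @param t_lo,t_hi grid limits.
#' @return numeric vector.
#' @export
default_temperature_grid <- function(n_points = 30L, t_lo = 0.01, t_hi = 4.5) {
  seq(t_lo, t_hi, length.out = n_points)
}
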