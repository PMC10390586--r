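#' Parameters of the excitable (Greenberg-Hastings) automaton
#'
#' The three-state automaton runs on a weighted network: each node is
#' inactive (I), active (A) or refractory (R). Per step, synchronously
#' against the start-of-step state: every active node becomes refractory;
#' every refractory node relaxes to inactive with probability `r2`; every
#' inactive node activates if the summed weight of its active in-neighbors
#' strictly exceeds the threshold \eqn{\mathcal{T}}, and otherwise
#' spontaneously with probability `r1`.
#'
#' @param threshold activation threshold \eqn{\mathcal{T} \ge 0}.
#' @param r1 spontaneous activation probability.
#' @param r2 refractory release probability.
#' @param t_max total number of steps (default 10000).
#' @param t_init discarded transient steps (default 200).
#' @param init_active_frac fraction of initially active nodes (default 0.01).
#' @param seed integer seed.
#' @return object of class `gh_params`.
#' @seealso [default_rates()] for the standard `r1`, `r2` choice.
#' @export
gh_params <- function(threshold, r1, r2, t_max = 10000L, t_init = 200L,
                      init_active_frac = 0.01, seed = 1L) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (r1 < 0 || r1 > 1 || r2 < 0 || r2 > 1) stop("r1, r2 must be in [0, 1]")
  if (t_init >= t_max) stop("t_init must be smaller than t_max")
  if (init_active_frac <= 0 || init_active_frac >= 1) {
    stop("init_active_frac must be in (0, 1)")
  }
  structure(list(threshold = threshold, r1 = r1, r2 = r2,
                 t_max = as.integer(t_max), t_init = as.integer(t_init),
                 init_active_frac = init_active_frac, seed = as.integer(seed)),
            class = "gh_params")
}

#' Default spontaneous-activation and refractory-release rates
#'
#' The standard parameterization ties both rates to the system size:
#' \eqn{r_1 = 2 / N} and \eqn{r_2 = r_1^{0.2}}. For the 998-node connectome
#' this gives \eqn{r_2 \approx 0.29}.
#'
#' @param n number of nodes (>= 1).
#' @return list with elements `r1` and `r2`.
#' @examples
#' default_rates(998)
#' @export
default_rates <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive count")
  r1 <- 2 / n
  if (r1 > 1) r1 <- 1
  list(r1 = r1, r2 = r1^0.2)
}

#' One synchronous automaton step (reference implementation)
#'
#' Pure-R single step used for inspection and as a cross-check of the
#' compiled simulation core. All three transitions are evaluated against the
#' start-of-step state; a node activated within the step does not count as an
#' active neighbor until the next step. The threshold test is strict
#' (`> threshold`). Consumes random numbers from R's RNG.
#'
#' @param state integer vector with entries 0 (I), 1 (A), 2 (R).
#' @param net a `weighted_network`.
#' @param params a `gh_params` (only `threshold`, `r1`, `r2` are used).
#' @return next state vector.
#' @export
gh_step <- function(state, net, params) {
  stopifnot_network(net)
  if (length(state) != net$n_nodes) stop("state length must equal n_nodes")
  if (!all(state %in% 0:2)) stop("states must be 0, 1 or 2")
  active <- as.numeric(state == 1L)
  input <- as.numeric(net$weights %*% active)  # sum_j active w_ij
  nxt <- integer(net$n_nodes)
  nxt[state == 1L] <- 2L
  ref <- which(state == 2L)
  nxt[ref] <- ifelse(stats::runif(length(ref)) < params$r2, 0L, 2L)
  inact <- which(state == 0L)
  fire <- input[inact] > params$threshold
  spont <- stats::runif(length(inact)) < params$r1
  nxt[inact] <- as.integer(fire | spont)
  nxt
}

#' Run the excitable automaton on a network
#'
#' Starts from a random state with `ceiling(init_active_frac * n)` active
#' nodes (chosen uniformly without replacement, rest inactive), runs `t_max`
#' synchronous steps, discards the first `t_init`, and returns the activity
#' raster with refractory conflated to 0 (entries 0/1). Fixed seed gives a
#' bit-identical raster.
#'
#' @param net a `weighted_network`.
#' @param params a `gh_params`.
#' @param keep_raw keep the raw three-state raster alongside the conflated
#'   one (entries 0/1/2)?
#' @return object of class `activity_raster`: list with `raster`
#'   (n x t_sim 0/1 matrix), optional `raw`, and the `params`.
#' @export
run_gh <- function(net, params, keep_raw = FALSE) {
  stopifnot_network(net)
  if (!inherits(params, "gh_params")) stop("expected gh_params")
  n <- net$n_nodes
  adj <- csc_parts(net$weights)
  withr::with_seed(params$seed, {
    n_active <- ceiling(params$init_active_frac * n)
    init <- sample.int(n, n_active) - 1L
    res <- cpp_run_gh(adj$p, adj$i, adj$x, n, params$threshold,
                      params$r1, params$r2, params$t_max, params$t_init,
                      init, keep_raw)
  })
  structure(list(raster = res$raster,
                 raw = if (keep_raw) res$raw else NULL,
                 params = params),
            class = "activity_raster")
}

#' @export
print.activity_raster <- function(x, ...) {
  cat("<activity_raster> ", nrow(x$raster), " nodes x ", ncol(x$raster),
      " steps, mean activity ", round(mean(colSums(x$raster)), 2), "\n", sep = "")
  invisible(x)
}

#' Deterministic sub-seed derivation
#'
#' Maps a master seed and an index to a reproducible sub-seed (affine map
#' modulo \eqn{2^{31} - 1}). Used for per-grid-point runs, lesion
#' realizations and replicate simulations, so that sweeps and ensembles are
#' reproducible and independent of execution order.
#'
#' @param seed integer master seed.
#' @param k non-negative index.
#' @return a positive integer seed below \eqn{2^{31}}.
#' @export
derive_subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647L) + 1L
}

#' Threshold sweep of the excitable automaton
#'
#' Runs one independent simulation per threshold value (each with a
#' deterministically derived sub-seed, so results do not depend on execution
#' order), and assembles the criticality indicator curves: time-averaged
#' \eqn{S_1}, \eqn{S_2}, mean and standard deviation of the total activity,
#' lag-1 autocorrelation of the activity, and the variance of \eqn{S_1(t)}.
#' If a parcellation and labels are supplied, per-subsystem cluster series
#' are computed as well.
#'
#' @param net a `weighted_network`.
#' @param thresholds ascending numeric grid with at least 2 values.
#' @param params_base a `gh_params`; its `threshold` is replaced by each grid
#'   value and its `seed` acts as the master seed.
#' @param parc optional `parcellation`.
#' @param labels module labels (subset of the parcellation's levels) for
#'   which subsystem series are computed; defaults to all levels when a
#'   parcellation is given.
#' @param keep_series keep per-step cluster series for every grid point
#'   (memory permitting)? Time averages are always kept.
#' @return a `sweep_result` (see [sweep_result()]).
#' @export
threshold_sweep <- function(net, thresholds, params_base, parc = NULL,
                            labels = NULL, keep_series = FALSE) {
  stopifnot_network(net)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 2L) stop("need at least 2 threshold values")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending")
  }
  if (!is.null(parc) && is.null(labels)) labels <- attr(parc, "levels")
  adj <- csc_parts(support_matrix(net))
  run_one <- function(k) {
    p <- params_base
    p$threshold <- thresholds[k]
    p$seed <- derive_subseed(params_base$seed, k)
    ar <- run_gh(net, p)
    summarize_run(ar$raster, adj, mode = 0L, net = net, parc = parc,
                  labels = labels, keep_series = keep_series)
  }
  rows <- lapply(seq_along(thresholds), run_one)
  sweep_result(grid = thresholds, rows = rows, control = "threshold",
               params = params_base,
               seeds = vapply(seq_along(thresholds),
                              function(k) derive_subseed(params_base$seed, k),
                              integer(1)))
}

# shared per-run summary for both dynamics; mode 0 = active_only, 1 = same_value
summarize_run <- function(raster, adj, mode, net, parc, labels, keep_series) {
  m <- cpp_two_largest_series(raster, adj$p, adj$i, mode, integer(0))
  series <- new_cluster_series(m[, 1L], m[, 2L], "whole")
  if (mode == 0L) {
    a_t <- colSums(raster)
  } else {
    a_t <- abs(colSums(raster))  # |magnetization| for spin rasters
  }
  st <- activity_stats(a_t)
  sub <- NULL
  if (!is.null(parc) && length(labels) > 0L) {
    sub <- lapply(labels, function(lb) {
      nodes <- parcellation_nodes(parc, lb) - 1L
      ms <- cpp_two_largest_series(raster, adj$p, adj$i, mode, nodes)
      new_cluster_series(ms[, 1L], ms[, 2L], lb)
    })
    names(sub) <- labels
  }
  list(
    S1 = mean(series$s1), S2 = mean(series$s2),
    mean_A = st[["mean"]], sd_A = st[["sd"]],
    rho1 = autocorr1(a_t), var_S1 = var_largest_cluster(series),
    sub_avg = if (!is.null(sub)) {
      lapply(sub, time_average)
    },
    series = if (keep_series) series,
    sub_series = if (keep_series) sub
  )
}
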