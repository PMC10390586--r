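#' Cluster sizes of a momentary network state
#'
#' A cluster is a maximal set of nodes sharing the same type of activity and
#' connected through the network's structural adjacency (the undirected
#' support `w_ij + w_ji > 0`; directed connectomes are symmetrized because
#' cluster membership is structural, not flow). Two modes are supported:
#' * `"active_only"` — clusters of nodes with state 1 (the excitable-dynamics
#'   convention: only active nodes form clusters);
#' * `"same_value"` — clusters of equal state values (the Ising convention:
#'   every site belongs to a same-spin domain).
#'
#' @param state integer vector of per-node states (0/1 for activity rasters,
#'   -1/+1 for spins).
#' @param net a `weighted_network`.
#' @param mode `"active_only"` or `"same_value"`.
#' @param nodes optional integer vector of (1-based) node indices restricting
#'   the computation to the induced subgraph.
#' @return integer vector of cluster sizes, sorted descending (possibly
#'   empty in `"active_only"` mode).
#' @examples
#' lat <- build_lattice(lattice_spec(2, 2))
#' find_clusters(c(1L, 1L, 0L, 1L), lat$network, mode = "active_only")
#' @export
find_clusters <- function(state, net, mode = c("active_only", "same_value"),
                          nodes = NULL) {
  stopifnot_network(net)
  mode <- match.arg(mode)
  if (length(state) != net$n_nodes) stop("state length must equal n_nodes")
  adj <- csc_parts(support_matrix(net))
  subset <- if (is.null(nodes)) integer(0) else as.integer(nodes) - 1L
  cpp_cluster_sizes(as.integer(state), adj$p, adj$i,
                    if (mode == "active_only") 0L else 1L, subset)
}

#' Largest and second-largest of a descending size list
#'
#' Convention for short lists: missing ranks count as 0, so a single-cluster
#' configuration has `s2 = 0` and an empty configuration `(0, 0)`.
#'
#' @param sizes integer vector of cluster sizes sorted descending.
#' @return named numeric vector `c(s1 = , s2 = )`.
#' @export
largest_two <- function(sizes) {
  c(s1 = if (length(sizes) >= 1L) sizes[[1L]] else 0,
    s2 = if (length(sizes) >= 2L) sizes[[2L]] else 0)
}

new_cluster_series <- function(s1, s2, scope) {
  structure(list(s1 = as.numeric(s1), s2 = as.numeric(s2), scope = scope),
            class = "cluster_series")
}

#' @export
print.cluster_series <- function(x, ...) {
  cat("<cluster_series> scope=", x$scope, ", t_sim=", length(x$s1),
      ", time-averaged S1=", round(mean(x$s1), 2),
      " S2=", round(mean(x$s2), 2), "\n", sep = "")
  invisible(x)
}

#' Per-time-step largest and second-largest cluster sizes
#'
#' Computes, for every column of an activity or spin raster, the sizes
#' \eqn{S_1(t)} and \eqn{S_2(t)} of the two largest clusters.
#'
#' @param raster n_nodes x t_sim integer matrix: a conflated activity raster
#'   (entries 0/1, use `mode = "active_only"`) or a spin raster (entries
#'   -1/+1, use `mode = "same_value"`).
#' @inheritParams find_clusters
#' @param scope label stored on the result (default `"whole"`).
#' @return a `cluster_series` with fields `s1`, `s2`, `scope`.
#' @export
cluster_series <- function(raster, net, mode = c("active_only", "same_value"),
                           nodes = NULL, scope = "whole") {
  stopifnot_network(net)
  mode <- match.arg(mode)
  if (nrow(raster) != net$n_nodes) stop("raster rows must equal n_nodes")
  adj <- csc_parts(support_matrix(net))
  subset <- if (is.null(nodes)) integer(0) else as.integer(nodes) - 1L
  m <- cpp_two_largest_series(raster, adj$p, adj$i,
                              if (mode == "active_only") 0L else 1L, subset)
  new_cluster_series(m[, 1L], m[, 2L], scope)
}

#' Cluster series restricted to one parcellation module
#'
#' Clusters are found on the subgraph induced by the nodes carrying `label`;
#' edges leaving the module are ignored. For a module with no external
#' connections this coincides with intersecting whole-system clusters with
#' the module.
#'
#' @inheritParams cluster_series
#' @param parc a `parcellation`.
#' @param label module label to restrict to.
#' @return a `cluster_series` with `scope = label`.
#' @export
subsystem_series <- function(raster, net, parc, label,
                             mode = c("active_only", "same_value")) {
  mode <- match.arg(mode)
  if (length(parc) != net$n_nodes) stop("parcellation length must equal n_nodes")
  nodes <- parcellation_nodes(parc, label)
  cluster_series(raster, net, mode = mode, nodes = nodes, scope = label)
}

#' Time-averaged largest cluster sizes
#'
#' \eqn{S_i = t_{sim}^{-1} \sum_t S_i(t)} for \eqn{i = 1, 2}.
#'
#' @param series a `cluster_series`.
#' @return named numeric vector `c(S1 = , S2 = )`.
#' @export
time_average <- function(series) {
  if (!inherits(series, "cluster_series")) stop("expected a cluster_series")
  if (length(series$s1) < 1L) stop("empty cluster series")
  c(S1 = mean(series$s1), S2 = mean(series$s2))
}

#' Whole-system cluster ranks predicted from two disconnected subsystems
#'
#' When the network is fully divided into subsystems A and B (no edges
#' across), every whole-system cluster lives inside one subsystem, so the
#' momentary whole-system sizes are order statistics of the subsystem sizes:
#' \deqn{S_1(t) = \max(S_1^A(t), S_1^B(t)),}
#' \deqn{S_2(t) = \mathrm{2nd\ largest\ of}\ \{S_1^A(t), S_2^A(t), S_1^B(t),
#' S_2^B(t)\}.}
#' The second rank is where subsystem clusters compete: near criticality
#' \eqn{S_2^A} and \eqn{S_1^B} can swap roles, which is the mechanism behind
#' the apparent loss of the \eqn{S_2} peak in divided systems.
#'
#' @param series_a,series_b `cluster_series` of the two subsystems, aligned
#'   in time.
#' @return a `cluster_series` with `scope = "predicted_whole"`.
#' @export
ordering_decomposition <- function(series_a, series_b) {
  if (!inherits(series_a, "cluster_series") ||
      !inherits(series_b, "cluster_series")) {
    stop("expected two cluster_series")
  }
  if (length(series_a$s1) != length(series_b$s1)) {
    stop("subsystem series are misaligned in time (",
         length(series_a$s1), " vs ", length(series_b$s1), " steps)")
  }
  four <- cbind(series_a$s1, series_a$s2, series_b$s1, series_b$s2)
  s1 <- pmax(series_a$s1, series_b$s1)
  s2 <- apply(four, 1L, function(v) sort(v, decreasing = TRUE)[2L])
  new_cluster_series(s1, s2, "predicted_whole")
}
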