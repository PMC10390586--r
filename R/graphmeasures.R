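#' Node strengths of a weighted directed graph
#'
#' In-strength \eqn{w^{in}_i = \sum_j w_{ij}}, out-strength
#' \eqn{w^{out}_i = \sum_j w_{ji}}, total strength
#' \eqn{2w = \sum_{ij} w_{ij}} and average in-strength.
#'
#' @param net a `weighted_network`.
#' @return list with `w_in`, `w_out`, `total` (= 2w), `mean_in`.
#' @export
strengths <- function(net) {
  stopifnot_network(net)
  w_in <- Matrix::rowSums(net$weights)
  w_out <- Matrix::colSums(net$weights)
  list(w_in = w_in, w_out = w_out, total = sum(w_in), mean_in = mean(w_in))
}

#' Conductance of a node subset
#'
#' \deqn{h_G(S, \bar S) = \frac{|\mathrm{cut}(S, \bar S)|}
#' {\min(\mathrm{vol}(S), \mathrm{vol}(\bar S))},}
#' with \eqn{|\mathrm{cut}|} the summed weight \eqn{w_{ij} + w_{ji}} over all
#' pairs \eqn{i \in S, j \in \bar S}, and \eqn{\mathrm{vol}(S)} the total
#' out-strength of `S`. Low conductance means the subset is poorly connected
#' to the rest of the graph; a fully disconnected subset has conductance 0.
#'
#' @param net a `weighted_network`.
#' @param node_set integer vector of node indices (1-based), a non-empty
#'   proper subset of the nodes.
#' @return scalar conductance.
#' @export
conductance <- function(net, node_set) {
  stopifnot_network(net)
  node_set <- unique(as.integer(node_set))
  n <- net$n_nodes
  if (length(node_set) == 0L || length(node_set) >= n) {
    stop("node_set must be a non-empty proper subset of the nodes")
  }
  if (any(node_set < 1L | node_set > n)) stop("node index out of range")
  in_s <- logical(n); in_s[node_set] <- TRUE
  w <- net$weights
  cut <- sum(w[in_s, !in_s]) + sum(w[!in_s, in_s])
  w_out <- Matrix::colSums(w)
  vols <- c(sum(w_out[in_s]), sum(w_out[!in_s]))
  if (min(vols) <= 0) {
    if (cut == 0) return(0)
    stop("zero volume on one side of the cut")
  }
  cut / min(vols)
}

partition_labels <- function(partition, n) {
  labels <- if (inherits(partition, "parcellation")) unclass(partition)
            else as.character(partition)
  if (length(labels) != n) stop("partition length must equal n_nodes")
  labels
}

#' Weighted (directed) modularity of a partition
#'
#' \deqn{Q = \frac{1}{2w} \sum_{i,j}\left(w_{ij} -
#' \frac{w^{out}_i w^{in}_j}{2w}\right)\delta_{c_i, c_j}.}
#' `q_max()` is the modularity of a perfectly mixed network with the same
#' strengths and partition,
#' \eqn{Q_{max} = 1 - (2w)^{-2}\sum_{i,j} w^{out}_i w^{in}_j \delta_{c_i,c_j}},
#' and `q_normalized()` is \eqn{Q / Q_{max}}, which equals 1 exactly when no
#' weight crosses module boundaries.
#'
#' @param net a `weighted_network` with positive total strength.
#' @param partition community labels, one per node (vector or
#'   `parcellation`).
#' @return scalar.
#' @export
modularity_q <- function(net, partition) {
  stopifnot_network(net)
  labels <- partition_labels(partition, net$n_nodes)
  s <- strengths(net)
  if (s$total <= 0) stop("modularity undefined: total strength is zero")
  two_w <- s$total
  q <- 0
  for (cc in unique(labels)) {
    idx <- labels == cc
    q <- q + sum(net$weights[idx, idx]) -
      sum(s$w_out[idx]) * sum(s$w_in[idx]) / two_w
  }
  q / two_w
}

#' @rdname modularity_q
#' @export
q_max <- function(net, partition) {
  stopifnot_network(net)
  labels <- partition_labels(partition, net$n_nodes)
  s <- strengths(net)
  if (s$total <= 0) stop("modularity undefined: total strength is zero")
  two_w <- s$total
  null_sum <- 0
  for (cc in unique(labels)) {
    idx <- labels == cc
    null_sum <- null_sum + sum(s$w_out[idx]) * sum(s$w_in[idx])
  }
  1 - null_sum / two_w^2
}

#' @rdname modularity_q
#' @export
q_normalized <- function(net, partition) {
  modularity_q(net, partition) / q_max(net, partition)
}

#' Community detection by modularity optimization (Louvain)
#'
#' Runs the Louvain heuristic (via igraph, on the symmetrized weighted
#' graph) with multiple seeded restarts and returns the partition with the
#' highest modularity as evaluated by this package's own [modularity_q()].
#' Louvain is order-dependent, hence the restarts; the returned partition's
#' Q is never below that of the all-in-one partition.
#'
#' @param net a `weighted_network`.
#' @param seed integer seed.
#' @param restarts number of restarts (default 10).
#' @param resolution Louvain resolution parameter (default 1).
#' @return character vector of community labels (one per node).
#' @export
louvain_partition <- function(net, seed = 1L, restarts = 10L, resolution = 1) {
  stopifnot_network(net)
  sym <- (net$weights + Matrix::t(net$weights)) / 2
  g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- NULL; best_q <- -Inf
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(g, resolution = resolution)
      memb <- as.character(igraph::membership(cl))
      q <- modularity_q(net, memb)
      if (q > best_q) { best_q <- q; best <- memb }
    }
  })
  best
}

#' Pearson correlation with test and Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return named list `rho`, `p`, `ci_low`, `ci_high` (95% CI).
#' @export
pearson_ci <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(rho = unname(ct$estimate), p = ct$p.value,
       ci_low = ct$conf.int[1L], ci_high = ct$conf.int[2L])
}
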