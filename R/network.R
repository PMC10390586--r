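#' Weighted network container
#'
#' A `weighted_network` holds the weighted adjacency of a (possibly directed)
#' graph. The convention throughout the package is that `weights[i, j]` is the
#' weight \eqn{w_{ij}} of the directed connection *from node j to node i*, so
#' that the in-strength of node i is the i-th row sum. Diagonal entries are
#' zero by convention and all weights are non-negative. Matrices are stored
#' sparse (`dgCMatrix`) so that lattices with tens of thousands of sites stay
#' cheap.
#'
#' @param weights square numeric matrix (dense or `Matrix` sparse) of
#'   non-negative weights with a zero diagonal.
#' @param directed logical; if `FALSE`, `weights` must be symmetric.
#' @param node_ids optional character vector of node labels; defaults to
#'   `"n1" ... "nN"`.
#' @return An object of class `weighted_network` with fields `n_nodes`,
#'   `weights`, `directed`, `node_ids`.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.5
#' net <- weighted_network(w, directed = FALSE)
#' net$n_nodes
#' @export
weighted_network <- function(weights, directed = FALSE, node_ids = NULL) {
  if (!inherits(weights, "Matrix")) {
    if (!is.matrix(weights)) stop("weights must be a matrix")
    weights <- Matrix::Matrix(weights, sparse = TRUE)
  }
  weights <- methods::as(methods::as(methods::as(weights, "dMatrix"),
                                     "generalMatrix"), "CsparseMatrix")
  if (nrow(weights) != ncol(weights)) {
    stop("weights must be a square matrix, got ", nrow(weights), "x", ncol(weights))
  }
  n <- nrow(weights)
  if (n < 1L) stop("network must have at least one node")
  if (any(weights@x < 0)) stop("all weights must be non-negative")
  if (any(Matrix::diag(weights) != 0)) {
    stop("diagonal entries must be zero (no self-loops)")
  }
  weights <- Matrix::drop0(weights)
  if (!directed && !Matrix::isSymmetric(weights, tol = 0)) {
    stop("undirected network requires a symmetric weight matrix")
  }
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  if (length(node_ids) != n) stop("node_ids length must equal n_nodes")
  structure(
    list(n_nodes = n, weights = weights, directed = directed,
         node_ids = as.character(node_ids)),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  nnz <- length(x$weights@x)
  cat("<weighted_network> ", x$n_nodes, " nodes, ",
      if (x$directed) nnz else nnz / 2L,
      if (x$directed) " directed edges" else " undirected edges", "\n", sep = "")
  invisible(x)
}

is_weighted_network <- function(x) inherits(x, "weighted_network")

stopifnot_network <- function(net) {
  if (!is_weighted_network(net)) stop("expected a weighted_network object")
  invisible(net)
}

#' Node parcellation into labeled modules
#'
#' Assigns every node of a network exactly one module label (for connectomes:
#' the resting-state network, RSN, the node belongs to). Used to define the
#' target of artificial lesions and the subsystems of divided lattices.
#'
#' @param labels vector of module labels, one per node (coerced to character).
#' @return Object of class `parcellation`: a character vector with the node
#'   labels, plus a `levels` attribute listing the distinct modules.
#' @export
parcellation <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("parcellation needs at least one node")
  if (anyNA(labels)) stop("parcellation labels must not be NA")
  structure(labels, levels = unique(labels), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation> ", length(x), " nodes, ",
      length(attr(x, "levels")), " modules: ",
      paste(utils::head(attr(x, "levels"), 8L), collapse = ", "), "\n", sep = "")
  invisible(x)
}

parcellation_nodes <- function(parc, label) {
  idx <- which(unclass(parc) == label)
  if (length(idx) == 0L) stop("unknown parcellation label: ", label)
  idx
}

#' Symmetric connectivity support of a network
#'
#' Cluster membership is structural, not flow: two nodes are adjacent if there
#' is weight in either direction. Returns the undirected binary support
#' pattern `w_ij + w_ji > 0` as a sparse 0/1 matrix.
#' @param net a `weighted_network`.
#' @return sparse symmetric `dgCMatrix` with unit entries.
#' @keywords internal
support_matrix <- function(net) {
  stopifnot_network(net)
  s <- net$weights + Matrix::t(net$weights)
  s@x[] <- 1
  Matrix::drop0(s)
}

# CSC pieces of a sparse matrix for the C++ kernels (0-based indices)
csc_parts <- function(m) {
  list(p = m@p, i = m@i, x = if (methods::.hasSlot(m, "x")) m@x else numeric(0))
}

#' Normalize each node's incoming weights to unit in-strength
#'
#' Homeostatic normalization: every incoming weight is divided by the node's
#' total in-strength, \eqn{\tilde w_{ij} = w_{ij} / w^{in}_i}, so each node
#' receives unit total excitatory input. Equalizing excitability this way
#' stabilizes the location of the critical threshold across connectomes. The
#' result is in general directed even for symmetric input.
#'
#' @param net a `weighted_network`; every node must have positive in-strength.
#' @return a `weighted_network` whose row sums are all exactly 1.
#' @export
normalize_in_strength <- function(net) {
  stopifnot_network(net)
  w_in <- Matrix::rowSums(net$weights)
  bad <- which(w_in <= 0)
  if (length(bad) > 0L) {
    stop("cannot normalize: zero in-strength at node(s) ",
         paste(net$node_ids[utils::head(bad, 5L)], collapse = ", "))
  }
  w <- Matrix::Diagonal(x = 1 / w_in) %*% net$weights
  w <- methods::as(methods::as(w, "generalMatrix"), "CsparseMatrix")
  directed <- !Matrix::isSymmetric(w, tol = 1e-14)
  weighted_network(w, directed = directed, node_ids = net$node_ids)
}
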