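#' Watts-Strogatz small-world network with exponential weights
#'
#' Builds a ring of `n` nodes each symmetrically connected to its `k/2`
#' nearest neighbors on either side, then rewires the far endpoint of every
#' ring edge independently with probability `pi` to a uniformly chosen node
#' (avoiding self-loops and duplicate edges), preserving the edge count
#' `n * k / 2` exactly. Edge weights are drawn i.i.d. from the exponential
#' density \eqn{p(w) = \lambda e^{-\lambda w}}, mimicking the weight
#' distribution of empirical connectomes. With total degree `k = 10` the
#' excitable dynamics on these networks show a continuous phase transition;
#' with `k = 2` they are non-critical (transient activity only).
#'
#' @param n number of nodes (>= 3).
#' @param k total degree of the initial ring; must be even and < n.
#' @param pi rewiring probability in \[0, 1\].
#' @param lam rate \eqn{\lambda} of the exponential weight distribution
#'   (default 12.5, the connectome-like value).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return an undirected `weighted_network` with exactly `n*k/2` edges.
#' @examples
#' net <- generate_ws_network(50, k = 4, pi = 0.3, seed = 1)
#' @export
generate_ws_network <- function(n, k, pi = 0.5, lam = 12.5, seed = 1L) {
  if (n < 3L) stop("n must be at least 3")
  if (k %% 2 != 0 || k >= n || k < 2) stop("k must be even, >= 2 and < n")
  if (pi < 0 || pi > 1) stop("pi must be in [0, 1]")
  if (lam <= 0) stop("lam must be positive")
  withr::with_seed(as.integer(seed), {
    half <- k / 2
    # ring edges as (a, b): b = a + d (mod n), d = 1..k/2
    a <- rep(seq_len(n), times = half)
    b <- ((a - 1L + rep(seq_len(half), each = n)) %% n) + 1L
    edge_key <- function(u, v) {
      lo <- pmin(u, v); hi <- pmax(u, v)
      (lo - 1) * n + (hi - 1)
    }
    existing <- new.env(hash = TRUE, size = n * k)
    for (key in edge_key(a, b)) assign(as.character(key), TRUE, envir = existing)
    rewire <- stats::runif(length(a)) < pi
    for (e in which(rewire)) {
      old_key <- edge_key(a[e], b[e])
      # draw until neither a self-loop nor an existing edge
      for (tries in seq_len(50L * n)) {
        cand <- sample.int(n, 1L)
        if (cand == a[e]) next
        key <- edge_key(a[e], cand)
        if (key == old_key) break  # rewired onto itself: keep edge
        if (!exists(as.character(key), envir = existing, inherits = FALSE)) {
          rm(list = as.character(old_key), envir = existing)
          assign(as.character(key), TRUE, envir = existing)
          b[e] <- cand
          break
        }
      }
    }
    w_vals <- stats::rexp(length(a), rate = lam)
    wmat <- Matrix::sparseMatrix(
      i = c(a, b), j = c(b, a), x = c(w_vals, w_vals), dims = c(n, n)
    )
    weighted_network(wmat, directed = FALSE)
  })
}

#' Synthetic modular connectome with RSN-like labels
#'
#' Generates a weighted stochastic-block network standing in for an empirical
#' human connectome: `length(module_sizes)` internally dense modules (the
#' resting-state networks) with sparser inter-module connectivity, and i.i.d.
#' exponential edge weights. The defaults emulate the healthy connectome used
#' throughout the package: 998 nodes, 8 labeled modules including a 119-node
#' "auditory" module, weight rate \eqn{\lambda = 12.5}, and mean within-module
#' degree 12 / cross-module degree 3 (overall mean degree about 15) —
#' calibrated so that the in-strength-normalized excitable dynamics on the
#' unmodified network reproduce the reference magnitudes of the healthy
#' system: largest active cluster around 0.17N at low threshold, an interior
#' second-largest-cluster peak of order 0.006N. Every module is
#' post-processed to be internally connected.
#'
#' @param n total number of nodes.
#' @param module_sizes integer vector summing to `n`.
#' @param module_labels labels for the modules (recycled names are not
#'   allowed); defaults to 8 RSN-like names when `length(module_sizes) == 8`,
#'   otherwise `"M1" ...`.
#' @param mean_degree_in expected within-module degree (must exceed
#'   `mean_degree_out`).
#' @param mean_degree_out expected cross-module degree (> 0).
#' @param lam exponential weight rate.
#' @param seed integer seed.
#' @return list with elements `network` (undirected `weighted_network`) and
#'   `parcellation`.
#' @export
generate_modular_connectome <- function(n = 998L,
                                        module_sizes = c(119L, 126L, 126L, 126L,
                                                         126L, 125L, 125L, 125L),
                                        module_labels = NULL,
                                        mean_degree_in = 12,
                                        mean_degree_out = 3,
                                        lam = 12.5,
                                        seed = 1L) {
  module_sizes <- as.integer(module_sizes)
  if (sum(module_sizes) != n) {
    stop("module_sizes must sum to n (", sum(module_sizes), " != ", n, ")")
  }
  if (any(module_sizes < 1L)) stop("module sizes must be positive")
  if (!(mean_degree_in > mean_degree_out && mean_degree_out > 0)) {
    stop("require mean_degree_in > mean_degree_out > 0")
  }
  m <- length(module_sizes)
  if (is.null(module_labels)) {
    module_labels <- if (m == 8L) {
      c("auditory", "visual", "somatomotor", "default_mode",
        "dorsal_attention", "ventral_attention", "frontoparietal",
        "cingulo_opercular")
    } else paste0("M", seq_len(m))
  }
  if (length(module_labels) != m || anyDuplicated(module_labels)) {
    stop("module_labels must be ", m, " distinct labels")
  }
  labels <- rep(module_labels, times = module_sizes)
  withr::with_seed(as.integer(seed), {
    block <- rep(seq_len(m), times = module_sizes)
    # within-module Bernoulli prob from expected degree; cross-module prob
    # relative to the number of outside nodes
    ii <- integer(0); jj <- integer(0)
    for (ma in seq_len(m)) {
      nodes_a <- which(block == ma)
      na <- length(nodes_a)
      if (na >= 2L) {
        p_in <- min(1, mean_degree_in / (na - 1))
        pairs <- utils::combn(nodes_a, 2L)
        keep <- stats::runif(ncol(pairs)) < p_in
        ii <- c(ii, pairs[1L, keep]); jj <- c(jj, pairs[2L, keep])
      }
      for (mb in seq_len(m)) {
        if (mb <= ma) next
        nodes_b <- which(block == mb)
        p_out <- min(1, mean_degree_out / (n - na))
        grid_n <- na * length(nodes_b)
        keep <- which(stats::runif(grid_n) < p_out)
        if (length(keep) > 0L) {
          ii <- c(ii, nodes_a[((keep - 1L) %% na) + 1L])
          jj <- c(jj, nodes_b[((keep - 1L) %/% na) + 1L])
        }
      }
    }
    # guarantee every module is internally connected: chain up components
    for (ma in seq_len(m)) {
      nodes_a <- which(block == ma)
      if (length(nodes_a) < 2L) next
      sub_sel <- ii %in% nodes_a & jj %in% nodes_a
      g <- igraph::graph_from_edgelist(
        cbind(match(ii[sub_sel], nodes_a), match(jj[sub_sel], nodes_a)),
        directed = FALSE
      )
      g <- igraph::add_vertices(g, max(0L, length(nodes_a) - igraph::vcount(g)))
      comp <- igraph::components(g)$membership
      if (max(comp) > 1L) {
        reps <- vapply(seq_len(max(comp)), function(cc) {
          sample(which(comp == cc), 1L)
        }, integer(1))
        ii <- c(ii, nodes_a[reps[-length(reps)]])
        jj <- c(jj, nodes_a[reps[-1L]])
      }
    }
    w_vals <- stats::rexp(length(ii), rate = lam)
    wmat <- Matrix::sparseMatrix(
      i = c(ii, jj), j = c(jj, ii), x = c(w_vals, w_vals), dims = c(n, n)
    )
    list(network = weighted_network(wmat, directed = FALSE),
         parcellation = parcellation(labels))
  })
}

#' Lattice geometry specification
#'
#' Describes a nonperiodic square lattice and an optional division into two
#' completely disconnected subsystems A and B: `"equal_halves"` cuts the
#' lattice into two `rows x cols/2` rectangles, `"central_patch"` disconnects
#' a centered `patch_side x patch_side` square (subsystem B) from its
#' complement (subsystem A).
#'
#' @param rows,cols lattice dimensions.
#' @param division one of `"none"`, `"equal_halves"`, `"central_patch"`.
#' @param patch_side side of the central patch (required for
#'   `"central_patch"`; must leave at least one boundary row/column, i.e.
#'   `patch_side <= min(rows, cols) - 2`).
#' @return object of class `lattice_spec`.
#' @export
lattice_spec <- function(rows, cols,
                         division = c("none", "equal_halves", "central_patch"),
                         patch_side = NULL) {
  division <- match.arg(division)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("rows and cols must be positive")
  if (division == "equal_halves" && cols %% 2L != 0L) {
    stop("equal_halves requires an even number of columns")
  }
  if (division == "central_patch") {
    if (is.null(patch_side)) stop("central_patch requires patch_side")
    patch_side <- as.integer(patch_side)
    if (patch_side < 1L || patch_side > min(rows, cols) - 2L) {
      stop("patch must be strictly interior: patch_side <= min(rows, cols) - 2")
    }
  }
  structure(list(rows = rows, cols = cols, division = division,
                 patch_side = patch_side),
            class = "lattice_spec")
}

#' Build a (possibly divided) square lattice network
#'
#' Constructs the 4-neighbor nonperiodic lattice with unit edge weights
#' described by a [lattice_spec()]. For divided lattices every bond crossing
#' the A/B border is removed, so the two subsystems are completely
#' disconnected, and the returned parcellation labels the nodes `"A"`/`"B"`
#' (undivided lattices get the single label `"A"`). Nodes are indexed
#' row-major: node `(r, c)` is `(r - 1) * cols + c`.
#'
#' @param spec a `lattice_spec`.
#' @return list with `network` and `parcellation`.
#' @examples
#' lat <- build_lattice(lattice_spec(10, 10, "equal_halves"))
#' table(lat$parcellation)
#' @export
build_lattice <- function(spec) {
  if (!inherits(spec, "lattice_spec")) stop("expected a lattice_spec")
  rows <- spec$rows; cols <- spec$cols
  n <- rows * cols
  idx <- function(r, c) (r - 1L) * cols + c
  # horizontal bonds (r, c)-(r, c+1) and vertical bonds (r, c)-(r+1, c)
  hr <- rep(seq_len(rows), each = cols - 1L)
  hc <- rep(seq_len(cols - 1L), times = rows)
  vr <- rep(seq_len(rows - 1L), each = cols)
  vc <- rep(seq_len(cols), times = rows - 1L)
  a <- c(idx(hr, hc), idx(vr, vc))
  b <- c(idx(hr, hc + 1L), idx(vr + 1L, vc))
  labels <- rep("A", n)
  if (spec$division == "equal_halves") {
    half <- cols %/% 2L
    in_b <- function(node) ((node - 1L) %% cols) + 1L > half
    labels[in_b(seq_len(n))] <- "B"
    keep <- in_b(a) == in_b(b)
    a <- a[keep]; b <- b[keep]
  } else if (spec$division == "central_patch") {
    s <- spec$patch_side
    r0 <- (rows - s) %/% 2L
    c0 <- (cols - s) %/% 2L
    in_b <- function(node) {
      r <- ((node - 1L) %/% cols) + 1L
      c <- ((node - 1L) %% cols) + 1L
      r > r0 & r <= r0 + s & c > c0 & c <= c0 + s
    }
    labels[in_b(seq_len(n))] <- "B"
    keep <- in_b(a) == in_b(b)
    a <- a[keep]; b <- b[keep]
  }
  wmat <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = 1, dims = c(n, n))
  list(network = weighted_network(wmat, directed = FALSE),
       parcellation = parcellation(labels))
}
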