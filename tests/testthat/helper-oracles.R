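# Brute-force oracles and small fixture builders used across the test files.
# All oracles deliberately avoid the package's compiled code paths.

# random symmetric weighted network on n nodes with edge probability p
random_test_network <- function(n, p = 0.4, seed = 1, directed = FALSE) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p) {
          w[i, j] <- stats::runif(1, 0.1, 2)
          w[j, i] <- if (directed) {
            if (stats::runif(1) < 0.5) stats::runif(1, 0.1, 2) else 0
          } else w[i, j]
        }
      }
    }
    weighted_network(w, directed = directed)
  })
}

# exhaustive BFS connected-component cluster sizes on the symmetric support
bf_cluster_sizes <- function(state, w, mode = "active_only", nodes = NULL) {
  n <- nrow(w)
  supp <- (w + t(w)) > 0
  if (is.null(nodes)) nodes <- seq_len(n)
  eligible <- if (mode == "active_only") {
    intersect(nodes, which(state == 1))
  } else nodes
  seen <- rep(FALSE, n)
  sizes <- integer(0)
  for (start in eligible) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- 0L
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- comp + 1L
      for (u in eligible) {
        if (!seen[u] && supp[v, u] &&
            (mode == "active_only" || state[u] == state[v])) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    sizes <- c(sizes, comp)
  }
  sort(sizes, decreasing = TRUE)
}

# conductance by explicit double loop over ordered pairs
bf_conductance <- function(w, node_set) {
  n <- nrow(w)
  in_s <- rep(FALSE, n); in_s[node_set] <- TRUE
  cut <- 0
  for (i in which(in_s)) for (j in which(!in_s)) cut <- cut + w[i, j] + w[j, i]
  w_out <- colSums(w)
  vol_s <- sum(w_out[in_s]); vol_c <- sum(w_out[!in_s])
  if (min(vol_s, vol_c) <= 0) return(if (cut == 0) 0 else NA_real_)
  cut / min(vol_s, vol_c)
}

# modularity by explicit double sum
bf_modularity <- function(w, labels) {
  n <- nrow(w)
  two_w <- sum(w)
  w_in <- rowSums(w); w_out <- colSums(w)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] == labels[j]) {
      q <- q + w[i, j] - w_out[i] * w_in[j] / two_w
    }
  }
  q / two_w
}

bf_q_max <- function(w, labels) {
  n <- nrow(w)
  two_w <- sum(w)
  w_in <- rowSums(w); w_out <- colSums(w)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] == labels[j]) s <- s + w_out[i] * w_in[j] / two_w
  }
  1 - s / two_w
}

# small modular connectome used by several slow-ish tests
small_test_connectome <- function(seed = 42) {
  generate_modular_connectome(
    n = 200L, module_sizes = c(30L, 60L, 55L, 55L),
    module_labels = c("auditory", "visual", "motor", "default"),
    mean_degree_in = 10, mean_degree_out = 2.5, seed = seed)
}
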