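test_that("find_clusters handles the canonical configurations", {
  lat <- build_lattice(lattice_spec(2, 2))
  # all active on a connected net -> one cluster of n
  expect_equal(find_clusters(rep(1L, 4), lat$network, "active_only"), 4L)
  # checkerboard spins on a 4-neighbor lattice -> four singletons
  expect_equal(find_clusters(c(1L, -1L, -1L, 1L), lat$network, "same_value"),
               rep(1L, 4))
  # no active nodes -> empty
  expect_length(find_clusters(rep(0L, 4), lat$network, "active_only"), 0)
})

test_that("cluster finder matches exhaustive component search", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      n <- sample(5:20, 1)
      net <- random_test_network(n, p = stats::runif(1, 0.1, 0.5), seed = rep)
      w <- as.matrix(net$weights)
      state_act <- sample(c(0L, 1L), n, replace = TRUE)
      expect_equal(
        find_clusters(state_act, net, "active_only"),
        bf_cluster_sizes(state_act, w, "active_only"),
        ignore_attr = TRUE)
      state_spin <- sample(c(-1L, 1L), n, replace = TRUE)
      expect_equal(
        find_clusters(state_spin, net, "same_value"),
        bf_cluster_sizes(state_spin, w, "same_value"),
        ignore_attr = TRUE)
      # induced subgraph
      nodes <- sort(sample(n, max(2, n %/% 2)))
      expect_equal(
        find_clusters(state_spin, net, "same_value", nodes = nodes),
        bf_cluster_sizes(state_spin, w, "same_value", nodes = nodes),
        ignore_attr = TRUE)
    }
  })
})

test_that("largest_two applies the short-list convention", {
  expect_equal(largest_two(c(7, 3, 3, 1)), c(s1 = 7, s2 = 3))
  expect_equal(largest_two(5), c(s1 = 5, s2 = 0))
  expect_equal(largest_two(integer(0)), c(s1 = 0, s2 = 0))
})

test_that("time_average reduces the per-step series", {
  cs <- criticonn:::new_cluster_series(c(2, 4), c(1, 1), "whole")
  expect_equal(time_average(cs), c(S1 = 3, S2 = 1))
  const <- criticonn:::new_cluster_series(rep(7, 10), rep(2, 10), "whole")
  expect_equal(time_average(const), c(S1 = 7, S2 = 2))
})

test_that("cluster series agrees with per-step recomputation", {
  net <- build_lattice(lattice_spec(6, 6))$network
  p <- gh_params(0.05, r1 = 0.05, r2 = 0.4, t_max = 80, t_init = 20, seed = 2)
  ar <- run_gh(net, p)
  cs <- cluster_series(ar$raster, net, mode = "active_only")
  for (t in c(1, 17, 60)) {
    sizes <- find_clusters(ar$raster[, t], net, "active_only")
    expect_equal(cs$s1[t], unname(largest_two(sizes)["s1"]))
    expect_equal(cs$s2[t], unname(largest_two(sizes)["s2"]))
  }
  expect_equal(unname(time_average(cs)["S1"]), mean(cs$s1))
})

test_that("subsystem series equals whole-system series for a full label", {
  net <- random_test_network(12, p = 0.4, seed = 8)
  parc <- parcellation(rep("all", 12))
  p <- gh_params(0.1, r1 = 0.1, r2 = 0.5, t_max = 60, t_init = 10, seed = 4)
  ar <- run_gh(net, p)
  whole <- cluster_series(ar$raster, net, "active_only")
  sub <- subsystem_series(ar$raster, net, parc, "all", "active_only")
  expect_equal(sub$s1, whole$s1)
  expect_equal(sub$s2, whole$s2)
  expect_error(subsystem_series(ar$raster, net, parc, "missing"), "unknown")
})

test_that("ordering decomposition selects the right ranks", {
  mk <- function(s1, s2, scope) criticonn:::new_cluster_series(s1, s2, scope)
  out <- ordering_decomposition(mk(10, 4, "A"), mk(6, 3, "B"))
  expect_equal(out$s1, 10)
  expect_equal(out$s2, 6)
  # competition won by the second cluster of A
  out <- ordering_decomposition(mk(10, 7, "A"), mk(6, 3, "B"))
  expect_equal(out$s2, 7)
  expect_error(
    ordering_decomposition(mk(c(1, 2), c(0, 0), "A"), mk(1, 0, "B")),
    "misaligned")
})

test_that("ordering identity is exact on a divided lattice (Ising)", {
  lat <- build_lattice(lattice_spec(12, 12, "central_patch", patch_side = 5))
  p <- ising_params(2.3, t_max = 150, t_init = 30, seed = 6)
  sr <- run_ising(lat$network, p)
  whole <- cluster_series(sr$raster, lat$network, "same_value")
  sa <- subsystem_series(sr$raster, lat$network, lat$parcellation, "A",
                         "same_value")
  sb <- subsystem_series(sr$raster, lat$network, lat$parcellation, "B",
                         "same_value")
  pred <- ordering_decomposition(sa, sb)
  expect_identical(whole$s1, pred$s1)
  expect_identical(whole$s2, pred$s2)
})

test_that("cluster sizes partition the eligible nodes", {
  net <- random_test_network(18, p = 0.3, seed = 12)
  withr::with_seed(5, {
    for (rep in 1:20) {
      spins <- sample(c(-1L, 1L), 18, replace = TRUE)
      expect_equal(sum(find_clusters(spins, net, "same_value")), 18)
      act <- sample(c(0L, 1L), 18, replace = TRUE)
      expect_equal(sum(find_clusters(act, net, "active_only")), sum(act))
    }
  })
})
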