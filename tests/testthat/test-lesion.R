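# 6-node toy: RSN {1,2,3} with internal edges and external edges to {4,5,6}
toy_lesion_net <- function() {
  w <- matrix(0, 6, 6)
  set_e <- function(i, j, v) { w[i, j] <<- v; w[j, i] <<- v }
  set_e(1, 2, 1); set_e(2, 3, 2); set_e(1, 3, 3)   # intra-RSN
  set_e(4, 5, 1); set_e(5, 6, 1)                   # outside
  set_e(1, 4, 5); set_e(2, 5, 6); set_e(3, 6, 7); set_e(3, 5, 8)  # cut
  weighted_network(w)
}
toy_parc <- parcellation(c("rsn", "rsn", "rsn", "rest", "rest", "rest"))

test_that("node-severity lesion removes exactly the selected external edges", {
  net <- toy_lesion_net()
  # severity 0 -> identity
  s0 <- lesion_spec("rsn", 0, "node_severity", seed = 1)
  expect_identical(as.matrix(apply_node_severity(net, toy_parc, s0)$weights),
                   as.matrix(net$weights))
  # severity 1 -> empty cut, conductance 0; intra weights untouched
  s1 <- lesion_spec("rsn", 1, "node_severity", seed = 1)
  cut1 <- apply_node_severity(net, toy_parc, s1)
  expect_equal(conductance(cut1, 1:3), 0)
  expect_equal(as.matrix(cut1$weights)[1:3, 1:3],
               as.matrix(net$weights)[1:3, 1:3])
  expect_equal(as.matrix(cut1$weights)[4:6, 4:6],
               as.matrix(net$weights)[4:6, 4:6])
  # severity 2/3 -> exactly the external edges of the 2 selected nodes gone
  s23 <- lesion_spec("rsn", 2 / 3, "node_severity", seed = 7)
  les <- apply_node_severity(net, toy_parc, s23)
  sel <- withr::with_seed(7L, (1:3)[sample.int(3, 2)])
  wl <- as.matrix(les$weights); w0 <- as.matrix(net$weights)
  expect_true(all(wl[sel, 4:6] == 0) && all(wl[4:6, sel] == 0))
  keep <- setdiff(1:3, sel)
  expect_equal(wl[keep, 4:6], w0[keep, 4:6])
  expect_equal(wl[1:3, 1:3], w0[1:3, 1:3])
  expect_error(apply_node_severity(net, toy_parc,
                                   lesion_spec("nope", 0.5, "node_severity")),
               "unknown")
})

test_that("edge-fraction lesion removes the right number of tract pairs", {
  net <- toy_lesion_net()  # 4 undirected cut edges
  s0 <- lesion_spec("rsn", 0, "edge_fraction", seed = 1)
  expect_identical(as.matrix(apply_edge_fraction(net, toy_parc, s0)$weights),
                   as.matrix(net$weights))
  half <- lesion_spec("rsn", 0.5, "edge_fraction", seed = 5)
  les <- apply_edge_fraction(net, toy_parc, half)
  w0 <- as.matrix(net$weights); wl <- as.matrix(les$weights)
  removed <- which(w0 > 0 & wl == 0, arr.ind = TRUE)
  # both directions of exactly 2 undirected edges
  expect_equal(nrow(removed), 4L)
  expect_true(all(xor(removed[, 1] <= 3, removed[, 2] <= 3)))
  # symmetry of removal
  expect_true(Matrix::isSymmetric(les$weights))
  # intra structure untouched
  expect_equal(wl[1:3, 1:3], w0[1:3, 1:3])
  full <- apply_edge_fraction(net, toy_parc,
                              lesion_spec("rsn", 1, "edge_fraction", seed = 2))
  expect_equal(conductance(full, 1:3), 0)
})

test_that("lesions preserve node count and matrix dimensions", {
  conn <- small_test_connectome(seed = 15)
  for (variant in c("node_severity", "edge_fraction")) {
    spec <- lesion_spec("auditory", 0.6, variant, seed = 3)
    les <- apply_lesion(conn$network, conn$parcellation, spec)
    expect_equal(les$n_nodes, conn$network$n_nodes)
    rsn <- which(unclass(conn$parcellation) == "auditory")
    expect_equal(as.matrix(les$weights)[rsn, rsn],
                 as.matrix(conn$network$weights)[rsn, rsn])
  }
})

test_that("lesion ensembles average downstream results reproducibly", {
  net <- toy_lesion_net()
  spec <- lesion_spec("rsn", 0.5, "node_severity", n_realizations = 8,
                      seed = 21)
  down <- function(lnet, seed) c(cond = conductance(lnet, 1:3))
  ens <- lesion_ensemble(net, toy_parc, spec, down)
  expect_length(ens$realizations, 8L)
  expect_equal(ens$mean[["cond"]],
               mean(vapply(ens$realizations, `[[`, numeric(1), "cond")))
  # reproducible
  ens2 <- lesion_ensemble(net, toy_parc, spec, down)
  expect_identical(ens$mean, ens2$mean)
  # single realization: mean equals the run
  one <- lesion_spec("rsn", 0.5, "node_severity", n_realizations = 1,
                     seed = 4)
  e1 <- lesion_ensemble(net, toy_parc, one, down)
  expect_equal(e1$mean, e1$realizations[[1]])
  # downstream failures carry the realization index
  expect_error(
    lesion_ensemble(net, toy_parc, one, function(lnet, seed) stop("boom")),
    "realization 1")
})

test_that("integrity measures respond monotonically to severity", {
  conn <- small_test_connectome(seed = 30)
  rsn <- which(unclass(conn$parcellation) == "auditory")
  sev_grid <- c(0, 0.5, 1)
  cond <- numeric(3); qn <- numeric(3)
  for (k in seq_along(sev_grid)) {
    spec <- lesion_spec("auditory", sev_grid[k], "node_severity",
                        n_realizations = 10, seed = 9)
    ens <- lesion_ensemble(conn$network, conn$parcellation, spec,
                           function(lnet, seed) {
                             c(h = conductance(lnet, rsn),
                               q = q_normalized(lnet, conn$parcellation))
                           })
    cond[k] <- ens$mean[["h"]]
    qn[k] <- ens$mean[["q"]]
  }
  expect_true(all(diff(cond) < 0))
  expect_equal(cond[3], 0)
  expect_true(all(diff(qn) > 0))
})
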