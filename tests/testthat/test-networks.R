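test_that("weighted_network validates its invariants", {
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  net <- weighted_network(w)
  expect_equal(net$n_nodes, 2L)
  expect_false(net$directed)
  expect_error(weighted_network(matrix(1:6, 2, 3)), "square")
  expect_error(weighted_network(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")
  expect_error(weighted_network(diag(2)), "diagonal")
  asym <- matrix(c(0, 2, 1, 0), 2, 2)
  expect_error(weighted_network(asym, directed = FALSE), "symmetric")
  expect_silent(weighted_network(asym, directed = TRUE))
})

test_that("WS generator: exact edge count, ring degrees, weight law", {
  # pi = 0: regular ring, every node degree k
  net0 <- generate_ws_network(10, k = 2, pi = 0, seed = 1)
  deg <- Matrix::colSums(net0$weights > 0)
  expect_equal(unname(deg), rep(2, 10))
  expect_equal(length(net0$weights@x) / 2, 10)

  # any pi: edge count exactly n*k/2, symmetric, connected weights >= 0
  for (seed in 1:3) {
    net <- generate_ws_network(200, k = 6, pi = 0.5, lam = 12.5, seed = seed)
    expect_equal(length(net$weights@x) / 2, 200 * 6 / 2)
    expect_true(Matrix::isSymmetric(net$weights))
  }

  # exponential weights: empirical mean close to 1/lambda
  big <- generate_ws_network(2000, k = 10, pi = 0.5, lam = 12.5, seed = 7)
  expect_equal(length(big$weights@x) / 2, 10000)
  m <- mean(big$weights@x)
  expect_lt(abs(m - 1 / 12.5), 4 * (1 / 12.5) / sqrt(10000))

  expect_error(generate_ws_network(10, k = 3), "even")
  expect_error(generate_ws_network(10, k = 10), "even|< n")
  expect_error(generate_ws_network(2, k = 2), "at least 3")
})

test_that("WS generator is deterministic given the seed", {
  a <- generate_ws_network(100, k = 4, pi = 0.3, seed = 5)
  b <- generate_ws_network(100, k = 4, pi = 0.3, seed = 5)
  expect_identical(as.matrix(a$weights), as.matrix(b$weights))
  c <- generate_ws_network(100, k = 4, pi = 0.3, seed = 6)
  expect_false(identical(as.matrix(a$weights), as.matrix(c$weights)))
})

test_that("modular connectome: sizes, labels, connectivity, determinism", {
  conn <- generate_modular_connectome(
    n = 60, module_sizes = c(25, 20, 15), mean_degree_in = 8,
    mean_degree_out = 2, seed = 3)
  expect_equal(length(conn$parcellation), 60)
  expect_equal(sum(conn$parcellation == "M1"), 25)
  expect_true(Matrix::isSymmetric(conn$network$weights))
  # every module internally connected
  for (lb in attr(conn$parcellation, "levels")) {
    nodes <- which(unclass(conn$parcellation) == lb)
    sizes <- find_clusters(rep(1L, 60), conn$network, mode = "active_only",
                           nodes = nodes)
    expect_equal(sizes[1], length(nodes))
  }
  again <- generate_modular_connectome(
    n = 60, module_sizes = c(25, 20, 15), mean_degree_in = 8,
    mean_degree_out = 2, seed = 3)
  expect_identical(as.matrix(conn$network$weights),
                   as.matrix(again$network$weights))

  expect_error(generate_modular_connectome(n = 50, module_sizes = c(30, 30)),
               "sum to n")
  expect_error(generate_modular_connectome(
    n = 40, module_sizes = c(20, 20), mean_degree_in = 2, mean_degree_out = 5),
    "mean_degree_in > mean_degree_out")
})

test_that("default connectome carries a 119-node auditory module", {
  conn <- generate_modular_connectome(seed = 1)
  expect_equal(conn$network$n_nodes, 998L)
  expect_equal(sum(conn$parcellation == "auditory"), 119)
  expect_equal(length(attr(conn$parcellation, "levels")), 8L)
})

test_that("in-strength normalization forces unit row sums", {
  net <- random_test_network(15, p = 0.5, seed = 2)
  norm <- normalize_in_strength(net)
  expect_lt(max(abs(Matrix::rowSums(norm$weights) - 1)), 1e-12)
  # sparsity pattern unchanged
  expect_equal(which(as.matrix(norm$weights) > 0),
               which(as.matrix(net$weights) > 0))
  # idempotence
  norm2 <- normalize_in_strength(norm)
  expect_equal(as.matrix(norm2$weights), as.matrix(norm$weights))
})

test_that("normalization of symmetric input is generally asymmetric", {
  # 3-node toy: weights 1 and 2 -> w~_12 != w~_21
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 2
  norm <- normalize_in_strength(weighted_network(w))
  expect_true(norm$directed)
  expect_equal(norm$weights[1, 2], 1)        # 1 / w_in_1 = 1/1
  expect_equal(norm$weights[2, 1], 1 / 3)    # 1 / w_in_2 = 1/3
  expect_equal(norm$weights[2, 3], 2 / 3)
  expect_equal(norm$weights[3, 2], 1)
})

test_that("normalization reports the offending node", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  expect_error(normalize_in_strength(weighted_network(w)), "n3")
})

test_that("lattice construction: bond counts and division sizes", {
  expect_equal(length(build_lattice(lattice_spec(2, 2))$network$weights@x) / 2,
               4)
  lat <- build_lattice(lattice_spec(100, 100))
  expect_equal(length(lat$network$weights@x) / 2, 19800)  # 2 * 100 * 99

  halves <- build_lattice(lattice_spec(100, 100, "equal_halves"))
  expect_equal(length(halves$network$weights@x) / 2, 19700)
  sizes <- find_clusters(rep(1L, 10000), halves$network, mode = "active_only")
  expect_equal(sizes, c(5000L, 5000L))
  expect_equal(unname(table(halves$parcellation)[c("A", "B")]),
               c(5000L, 5000L), ignore_attr = TRUE)

  patch <- build_lattice(lattice_spec(100, 100, "central_patch",
                                      patch_side = 50))
  sizes <- find_clusters(rep(1L, 10000), patch$network, mode = "active_only")
  expect_equal(sizes, c(7500L, 2500L))
  expect_equal(sum(patch$parcellation == "B"), 2500)

  expect_error(lattice_spec(10, 10, "central_patch", patch_side = 9),
               "interior")
  expect_error(lattice_spec(10, 10, "central_patch", patch_side = 10),
               "interior")
})

test_that("no bonds cross a lattice division", {
  for (div in c("equal_halves", "central_patch")) {
    lat <- build_lattice(lattice_spec(10, 10, div, patch_side = 4))
    labs <- unclass(lat$parcellation)
    s <- Matrix::summary(lat$network$weights)
    expect_true(all(labs[s$i] == labs[s$j]))
  }
})

test_that("network files round-trip in both formats", {
  net <- random_test_network(5, p = 0.6, seed = 9)
  for (fmt in c("matrix", "edgelist")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_network(net, path, format = fmt)
    back <- read_network(path, format = if (fmt == "matrix") "matrix"
                         else "edgelist")
    expect_equal(as.matrix(back$weights), as.matrix(net$weights))
  }
  # directed round trip via edge list
  dnet <- random_test_network(6, p = 0.5, seed = 4, directed = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(dnet, path, format = "edgelist")
  back <- read_network(path, format = "edgelist", directed = TRUE,
                       n_nodes = 6)
  expect_equal(as.matrix(back$weights), as.matrix(dnet$weights))
})

test_that("malformed network files are rejected with a line number", {
  p <- withr::local_tempfile()
  writeLines(c("0 1 2", "1 0 3"), p)                    # non-square
  expect_error(read_network(p, format = "matrix"), "non-square")
  writeLines(c("0 1", "-1 0"), p)                       # negative weight
  expect_error(read_network(p, format = "matrix"), "line 2.*negative")
  writeLines(c("1 1", "1 0"), p)                        # self-loop
  expect_error(read_network(p, format = "matrix"), "line 1.*self-loop")
  writeLines(c("source\ttarget\tweight", "0\t0\t0.5"), p)
  expect_error(read_network(p, format = "edgelist"), "line 2.*self-loop")
  writeLines(c("0\t1\t-0.5"), p)
  expect_error(read_network(p, format = "edgelist"), "negative")
})

test_that("parcellation files round-trip and validate", {
  parc <- parcellation(c("A", "A", "B", "C"))
  p <- withr::local_tempfile()
  write_parcellation(parc, p)
  back <- read_parcellation(p)
  expect_equal(unclass(back), unclass(parc), ignore_attr = TRUE)
  writeLines(c("0\tA", "0\tB"), p)
  expect_error(read_parcellation(p), "duplicate")
  writeLines(c("0\tA", "2\tB"), p)
  expect_error(read_parcellation(p), "missing")
})
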