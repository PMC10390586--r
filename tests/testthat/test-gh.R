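test_that("default rates follow the size rule", {
  r <- default_rates(998)
  expect_equal(r$r1, 2 / 998)
  expect_equal(round(r$r2, 2), 0.29)
  expect_equal(default_rates(2000)$r1, 0.001)
  r2 <- default_rates(2)
  expect_equal(r2$r1, 1)
  expect_equal(r2$r2, 1)
  expect_error(default_rates(0), "positive")
})

test_that("gh_params validates its fields", {
  expect_error(gh_params(-0.1, 0.1, 0.3), "non-negative")
  expect_error(gh_params(0.1, 1.5, 0.3), "r1, r2")
  expect_error(gh_params(0.1, 0.1, 0.3, t_max = 100, t_init = 100), "t_init")
  expect_error(gh_params(0.1, 0.1, 0.3, init_active_frac = 0), "init_active")
})

test_that("single step implements the three transitions", {
  # five-node hub: center 5 inactive, neighbors 1,3,4 active, 2 refractory
  w <- matrix(0, 5, 5)
  for (j in c(1, 2, 3, 4)) { w[5, j] <- 0.25; w[j, 5] <- 0.25 }
  net <- weighted_network(w, directed = FALSE)
  state <- c(1L, 2L, 1L, 1L, 0L)
  p <- gh_params(threshold = 0.7, r1 = 0, r2 = 1)
  nxt <- withr::with_seed(1, gh_step(state, net, p))
  # active sum 0.75 > 0.7 -> center activates; actives become refractory;
  # refractory releases (r2 = 1)
  expect_equal(nxt, c(2L, 0L, 2L, 2L, 1L))

  # strict inequality: input exactly at threshold does not activate
  p_eq <- gh_params(threshold = 0.75, r1 = 0, r2 = 1)
  nxt_eq <- withr::with_seed(1, gh_step(state, net, p_eq))
  expect_equal(nxt_eq[5], 0L)

  # absorbing quiescence at r1 = 0
  all_i <- rep(0L, 5)
  expect_equal(withr::with_seed(1, gh_step(all_i, net, p)), all_i)

  # all refractory with r2 = 1 -> all inactive
  all_r <- rep(2L, 5)
  expect_equal(withr::with_seed(1, gh_step(all_r, net, p)), rep(0L, 5))
})

test_that("run_gh respects the initial condition and conflation", {
  net <- random_test_network(50, p = 0.2, seed = 3)
  p <- gh_params(0.1, r1 = 0.02, r2 = 0.3, t_max = 120, t_init = 20, seed = 9)
  ar <- run_gh(net, p, keep_raw = TRUE)
  expect_equal(dim(ar$raster), c(50L, 100L))
  expect_true(all(ar$raster %in% c(0L, 1L)))
  expect_true(all(ar$raw %in% c(0L, 1L, 2L)))
  expect_equal(ar$raster, matrix(as.integer(ar$raw == 1L), 50, 100))
  # exactly ceiling(0.01 n) nodes initially active
  p1 <- gh_params(0, r1 = 0, r2 = 1, t_max = 2, t_init = 0, seed = 1,
                  init_active_frac = 0.01)
  ar1 <- run_gh(weighted_network(matrix(0, 324, 324)), p1, keep_raw = TRUE)
  # after one step all initially active are refractory
  expect_equal(sum(ar1$raw[, 1] == 2L), ceiling(0.01 * 324))
})

test_that("raster obeys conservation and the one-way cycle", {
  net <- random_test_network(30, p = 0.3, seed = 5)
  p <- gh_params(0.15, r1 = 0.05, r2 = 0.3, t_max = 150, t_init = 0, seed = 2)
  ar <- run_gh(net, p, keep_raw = TRUE)
  # every active node is refractory at the next step
  for (t in seq_len(ncol(ar$raw) - 1)) {
    act <- ar$raw[, t] == 1L
    expect_true(all(ar$raw[act, t + 1] == 2L))
  }
})

test_that("supercritical and subcritical limits behave as phases", {
  net <- random_test_network(40, p = 0.4, seed = 11)
  # threshold above max in-strength, no spontaneous activity -> silence
  tmax_in <- max(Matrix::rowSums(net$weights))
  p_sub <- gh_params(tmax_in * 1.01, r1 = 0, r2 = 0.3, t_max = 300,
                     t_init = 100, seed = 3)
  ar_sub <- run_gh(net, p_sub)
  expect_equal(sum(ar_sub$raster), 0)
  # threshold 0: any active neighbor fires its neighbors; activity spreads
  # from the seeds (waves can still die out in their refractory wake, so the
  # guarantee is on the full record, not the stationary state)
  p_sup <- gh_params(0, r1 = 0, r2 = 0.3, t_max = 300, t_init = 0, seed = 3,
                     init_active_frac = 0.1)
  ar_sup <- run_gh(net, p_sup)
  expect_gt(sum(ar_sup$raster), 0.1 * 40)
  # monotone activity: supercritical mean activity >= subcritical
  expect_gte(mean(colSums(ar_sup$raster)), mean(colSums(ar_sub$raster)))
})

test_that("runs are bit-identical under a fixed seed", {
  net <- random_test_network(25, p = 0.3, seed = 1)
  p <- gh_params(0.1, r1 = 0.05, r2 = 0.3, t_max = 80, t_init = 10, seed = 77)
  expect_identical(run_gh(net, p)$raster, run_gh(net, p)$raster)
})

test_that("threshold sweep assembles one row per grid value", {
  net <- random_test_network(30, p = 0.4, seed = 6)
  p <- gh_params(0.1, r1 = 0.05, r2 = 0.3, t_max = 60, t_init = 10, seed = 5)
  grid <- seq(0.02, 0.5, length.out = 6)
  sw <- threshold_sweep(net, grid, p)
  d <- as.data.frame(sw)
  expect_equal(nrow(d), 6L)
  expect_equal(d$threshold, grid)
  expect_true(all(d$S1 >= d$S2))
  expect_true(all(d$sd_A >= 0))
  # sub-seeds recorded and distinct
  expect_equal(length(unique(d$seed)), 6L)
  expect_error(threshold_sweep(net, 0.1, p), "at least 2")
  expect_error(threshold_sweep(net, c(0.2, 0.1), p), "ascending")
})
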