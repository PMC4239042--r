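test_that("the generator honours its planted-truth contract", {
  b <- generate_benchmark(n = 300, avg_degree = 10, n_modules = 6,
                          O_n = 40, O_m = 3, mu = 0.1, seed = 11)
  truth <- b$truth
  # exactly O_n nodes multi-clustered, each in exactly O_m modules
  expect_length(truth$multi, 40)
  expect_true(all(lengths(truth$membership[truth$multi]) == 3))
  expect_true(all(lengths(truth$membership[setdiff(names(truth$membership),
                                                   truth$multi)]) == 1))
  # realized mean degree within 15% of the target
  mean_deg <- 2 * nrow(b$network$edges) / length(b$network$nodes)
  expect_lt(abs(mean_deg - 10) / 10, 0.15)
  # realized mixing within 0.05 of mu
  expect_lt(abs(overmod:::realized_mixing(b$network, truth) - 0.1), 0.05)
  # determinism
  b2 <- generate_benchmark(n = 300, avg_degree = 10, n_modules = 6,
                           O_n = 40, O_m = 3, mu = 0.1, seed = 11)
  expect_identical(b$network$edges, b2$network$edges)
  expect_identical(b$truth$membership, b2$truth$membership)
})

test_that("mu = 0 with no overlap gives disconnected pure modules", {
  b <- generate_benchmark(n = 80, avg_degree = 6, n_modules = 4,
                          O_n = 0, O_m = 1, mu = 0, seed = 3)
  # every edge joins co-members, so the main component is one module
  expect_equal(overmod:::realized_mixing(b$network, b$truth), 0)
  mods <- unique(unlist(b$truth$membership))
  expect_length(mods, 1)
})

test_that("realized mixing increases with requested mu", {
  mus <- c(0.05, 0.1, 0.2, 0.3)
  realized <- vapply(mus, function(mu) {
    mean(vapply(1:3, function(s) {
      b <- generate_benchmark(n = 200, avg_degree = 10, n_modules = 5,
                              O_n = 20, O_m = 2, mu = mu, seed = 100 + s)
      overmod:::realized_mixing(b$network, b$truth)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(realized) > 0))
  expect_true(all(abs(realized - mus) < 0.05))
})

test_that("generator rejects infeasible parameters", {
  expect_error(generate_benchmark(n = 20, n_modules = 4, O_n = 5, O_m = 8,
                                  mu = 0.1, seed = 1))
  expect_error(generate_benchmark(n = 20, n_modules = 15, avg_degree = 10,
                                  O_n = 0, O_m = 1, mu = 0.1, seed = 1),
               "modules too small")
  expect_error(generate_benchmark(mu = 1, seed = 1))
  expect_error(generate_benchmark(mu = 0.1), "seed")
})

test_that("recovery_jaccard counts sets as stated", {
  b <- generate_benchmark(n = 100, avg_degree = 8, n_modules = 4,
                          O_n = 10, O_m = 2, mu = 0.1, seed = 9)
  expect_equal(recovery_jaccard(b$truth$multi, b$truth), 1)
  expect_equal(recovery_jaccard(character(0), b$truth), 0)
  extra <- setdiff(names(b$truth$membership), b$truth$multi)[1]
  pred <- c(b$truth$multi, extra)
  expect_equal(recovery_jaccard(pred, b$truth),
               length(b$truth$multi) / (length(b$truth$multi) + 1))
})

test_that("benchmark_suite reports per-cell means deterministically", {
  grid <- data.frame(mu = 0.1, n = 120, avg_degree = 8, n_modules = 4,
                     O_n = 15, O_m = 2)
  tab <- benchmark_suite(grid, replicates = 2, restarts = 5, seed = 13)
  expect_equal(nrow(tab), 1)
  expect_true(tab$mean_jaccard >= 0 && tab$mean_jaccard <= 1)
  expect_false(is.na(tab$sd_jaccard))
  expect_equal(tab$replicates, 2)
  tab2 <- benchmark_suite(grid, replicates = 2, restarts = 5, seed = 13)
  expect_identical(tab, tab2)
})
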