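test_that("qov matches hand evaluations on the two-triangle fixture", {
  tt <- two_triangle()
  hard_m <- as.list(setNames(as.integer(unclass(tt$hp)), names(tt$hp)))
  expect_equal(qov(tt$net, tt$roles, hard_m), 5 / 14, tolerance = 1e-12)
  expect_equal(qov(tt$net, tt$roles, hard_m),
               hard_modularity(tt$net, tt$hp), tolerance = 1e-12)

  both <- list(a = 1L, b = 1L, c = c(1L, 2L), d = 2L, e = 2L, f = 2L)
  expect_equal(qov(tt$net, tt$roles, both), 5 / 28 + 3 / 49, tolerance = 1e-12)

  # single-module assignment of a loop-free net scores 0
  one <- net_from_lines(c("a b", "b c"))
  hp1 <- new_hard_partition(setNames(rep(1L, 3), one$nodes))
  r1 <- classify_nodes(one, hp1)
  expect_equal(qov(one, r1, list(a = 1L, b = 1L, c = 1L)), 0, tolerance = 1e-15)
})

test_that("qov rejects infeasible assignments", {
  tt <- two_triangle()
  x <- overmod:::assignment_from_hard(tt$net, tt$roles$hard)
  x["c", ] <- FALSE
  expect_error(qov(tt$net, tt$roles, x), "zero module memberships")
  x2 <- overmod:::assignment_from_hard(tt$net, tt$roles$hard)
  x2["a", 2] <- TRUE # isolated node duplicated
  expect_error(qov(tt$net, tt$roles, x2), "isolated")
})

test_that("solve_exact finds the two-triangle optimum and honours its budget", {
  tt <- two_triangle()
  sp <- solve_exact(tt$net, tt$roles, tt$hp)
  expect_equal(sp$qov, 5 / 14, tolerance = 1e-12)
  expect_equal(sp$membership$c, 1L)
  expect_equal(sp$membership$d, 2L)
  expect_equal(unname(sp$roles[c("c", "d")]), c("intra", "intra"))
  expect_equal(unname(sp$roles[c("a", "b", "e", "f")]), rep("isolated", 4))

  # zero connectors: the hard partition comes straight back
  net <- net_from_lines(c("a b", "c d"))
  hp <- new_hard_partition(c(a = 1L, b = 1L, c = 2L, d = 2L))
  roles <- classify_nodes(net, hp)
  sp0 <- solve_exact(net, roles, hp)
  expect_equal(sp0$qov, hard_modularity(net, hp), tolerance = 1e-12)
  expect_true(all(lengths(sp0$membership) == 1))

  expect_error(solve_exact(tt$net, tt$roles, tt$hp, budget = 2),
               "solve_multistart")
})

test_that("solve_multistart is feasible, improving and deterministic", {
  tt <- two_triangle()
  sp <- solve_multistart(tt$net, tt$roles, tt$hp, restarts = 100, seed = 7)
  expect_equal(sp$qov, 5 / 14, tolerance = 1e-9)
  expect_identical(sp, solve_multistart(tt$net, tt$roles, tt$hp,
                                        restarts = 100, seed = 7))

  for (seed in c(2, 9, 31)) {
    inst <- rand_instance(seed, n = 12, p = 0.3)
    if (is.null(inst)) next
    sp <- solve_multistart(inst$net, inst$roles, inst$hp,
                           restarts = 10, seed = seed)
    q_hard <- hard_modularity(inst$net, inst$hp)
    expect_gte(sp$qov, q_hard - 1e-12)
    # reported objective is reproducible from the returned memberships
    expect_equal(qov(inst$net, inst$roles, sp$membership), sp$qov,
                 tolerance = 1e-12)
    # every connector keeps at least one membership, isolated keep exactly one
    expect_true(all(lengths(sp$membership) >= 1))
    iso <- names(which(!inst$roles$is_connector))
    expect_true(all(lengths(sp$membership[iso]) == 1))
    expect_true(all(vapply(iso, function(v)
      sp$membership[[v]] == inst$roles$hard[v], logical(1))))
  }
})

test_that("restart streams are stable when the restart count grows", {
  inst <- rand_instance(5, n = 12, p = 0.3)
  sp10 <- solve_multistart(inst$net, inst$roles, inst$hp, restarts = 10, seed = 3)
  sp25 <- solve_multistart(inst$net, inst$roles, inst$hp, restarts = 25, seed = 3)
  expect_identical(attr(sp10, "restart_qov"),
                   attr(sp25, "restart_qov")[1:10])
})

test_that("classify_connectors assigns roles from membership counts", {
  tt <- two_triangle()
  sp <- solve_exact(tt$net, tt$roles, tt$hp)
  sp$membership$c <- c(1L, 2L) # force a multi-membership
  sp <- classify_connectors(sp, tt$roles)
  expect_equal(unname(sp$roles["c"]), "inter")
  expect_equal(unname(sp$roles["d"]), "intra")
  counts <- attr(sp, "role_counts")
  expect_equal(unname(counts), c(4L, 1L, 1L),
               ignore_attr = TRUE)
})

test_that("strong inter-connector rules follow the stated selection logic", {
  mk_sp <- function(counts) {
    membership <- lapply(counts, function(k) seq_len(k))
    names(membership) <- sprintf("p%02d", seq_along(counts))
    roles <- ifelse(counts >= 2, "inter", "intra")
    names(roles) <- names(membership)
    overmod:::new_soft_partition(membership, NA_real_, roles)
  }
  # membership counts {3,3,2,1}: threshold 3 keeps two nodes
  expect_length(strong_interconnectors(mk_sp(c(3, 3, 2, 1)), "threshold:3"), 2)

  # counts {6,6,5 x 10, 4 ...}: top-ten range reaches down to 5, ties
  # included, so 12 nodes qualify
  counts <- c(6, 6, rep(5, 10), rep(4, 5), rep(3, 3), rep(2, 4))
  expect_length(strong_interconnectors(mk_sp(counts), "top10range"), 12)

  # no inter-connectors: empty set
  expect_length(strong_interconnectors(mk_sp(c(1, 1)), "threshold:3"), 0)

  # fewer than ten inter-connectors: fall back, flagged
  expect_warning(out <- strong_interconnectors(mk_sp(c(3, 2, 2)), "top10range"),
                 "fewer than 10")
  expect_length(out, 3)
  expect_true(isTRUE(attr(out, "fallback")))

  expect_error(strong_interconnectors(mk_sp(c(3, 2)), "nonsense"), "unknown")
})

test_that("each restart's climb improves on its own random initialisation", {
  for (seed in c(1, 8)) {
    inst <- rand_instance(seed, n = 12, p = 0.3)
    if (is.null(inst)) next
    restarts <- 5
    sp <- solve_multistart(inst$net, inst$roles, inst$hp,
                           restarts = restarts, seed = seed)
    trace <- attr(sp, "restart_qov")
    expect_equal(sp$qov, max(trace), tolerance = 1e-12)
    # reconstruct each restart's repaired initial assignment and check the
    # climb never ended below it
    roles <- inst$roles
    net <- inst$net
    x_hard <- overmod:::assignment_from_hard(net, roles$hard, roles$n_modules)
    pairs <- overmod:::candidate_pairs(net, roles)
    conn_idx <- sort(unique(pairs$node))
    for (r in seq_len(restarts)) {
      x0 <- x_hard
      overmod:::with_seed(overmod:::derive_seed(seed, r), {
        draw <- runif(length(pairs$node)) < 0.5
        x0[conn_idx, ] <- FALSE
        on <- which(draw)
        x0[cbind(pairs$node[on], pairs$mod[on])] <- TRUE
        zero <- conn_idx[rowSums(x0[conn_idx, , drop = FALSE]) == 0L]
        if (length(zero)) x0[cbind(zero, roles$hard[zero])] <- TRUE
      })
      expect_gte(trace[r], qov(net, roles, x0) - 1e-12)
    }
  }
})
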