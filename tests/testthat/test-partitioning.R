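test_that("classify_nodes applies the isolated/connector definitions", {
  tt <- two_triangle()
  r <- tt$roles
  expect_setequal(r$isolated_by_module[[1]], c("a", "b"))
  expect_setequal(r$isolated_by_module[[2]], c("e", "f"))
  expect_setequal(r$connectors_by_module[[1]], c("c", "d"))
  expect_setequal(r$connectors_by_module[[2]], c("c", "d"))
  expect_equal(r$candidates$c, c(1L, 2L))
  expect_equal(r$candidates$d, c(1L, 2L))

  # no edges between modules: everyone isolated
  net <- net_from_lines(c("a b", "c d"))
  hp <- new_hard_partition(c(a = 1L, b = 1L, c = 2L, d = 2L))
  r2 <- classify_nodes(net, hp)
  expect_equal(sum(r2$is_connector), 0)
  expect_length(r2$candidates, 0)

  # star centre in module 1, one leaf in module 2: both ends connectors
  star <- net_from_lines(c("hub l1", "hub l2", "hub l3"))
  hps <- new_hard_partition(c(hub = 1L, l1 = 1L, l2 = 1L, l3 = 2L))
  r3 <- classify_nodes(star, hps)
  expect_setequal(names(which(r3$is_connector)), c("hub", "l3"))
})

test_that("connector classification responds to inter-module edges", {
  for (seed in c(3, 11, 27)) {
    inst <- rand_instance(seed, n = 10, p = 0.35)
    if (is.null(inst)) next
    net <- inst$net
    hard <- unclass(inst$hp)[net$nodes]
    # dropping all inter-module edges makes every node isolated
    e <- net$edges
    intra <- e[hard[e$i] == hard[e$j], , drop = FALSE]
    lines <- paste(net$nodes[intra$i], net$nodes[intra$j])
    if (!nrow(intra)) next
    net2 <- net_from_lines(lines)
    hp2 <- new_hard_partition(hard[net2$nodes])
    expect_equal(sum(classify_nodes(net2, hp2)$is_connector), 0)
    # adding back one inter-module edge creates exactly its two endpoints
    inter <- e[hard[e$i] != hard[e$j], , drop = FALSE]
    add <- inter[1, ]
    keep <- union(net2$nodes, net$nodes[c(add$i, add$j)])
    net3 <- net_from_lines(c(lines, paste(net$nodes[add$i], net$nodes[add$j])))
    hp3 <- new_hard_partition(hard[net3$nodes])
    r3 <- classify_nodes(net3, hp3)
    expect_setequal(names(which(r3$is_connector)),
                    c(net$nodes[add$i], net$nodes[add$j]))
  }
})

test_that("hard modularity matches closed forms and the textbook oracle", {
  tt <- two_triangle()
  expect_equal(hard_modularity(tt$net, tt$hp), 5 / 14, tolerance = 1e-12)

  # whole network in one module: Q = 0
  one <- new_hard_partition(setNames(rep(1L, 6), tt$net$nodes))
  expect_equal(hard_modularity(tt$net, one), 0, tolerance = 1e-12)

  # singleton modules: Q = -sum (s_i/2L)^2
  singl <- new_hard_partition(setNames(seq_len(6), tt$net$nodes))
  expect_equal(hard_modularity(tt$net, singl),
               -sum((tt$net$strength / (2 * tt$net$L))^2), tolerance = 1e-12)

  # agreement with the independent double-sum formula on random graphs
  checked <- 0
  for (seed in 1:40) {
    inst <- rand_instance(seed, n = 11, p = 0.3)
    if (is.null(inst)) next
    expect_equal(hard_modularity(inst$net, inst$hp),
                 textbook_modularity(inst$net, inst$hp), tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("the greedy optimiser recovers planted cliques and is deterministic", {
  k5 <- character(0)
  for (i in 1:4) for (j in (i + 1):5) {
    k5 <- c(k5, paste0("a", i, " a", j), paste0("b", i, " b", j))
  }
  net <- net_from_lines(c(k5, "a1 b1"))
  hp <- greedy_hard_partition(net, seed = 1)
  groups <- split(names(hp), unclass(hp))
  expect_length(groups, 2)
  expect_true(all(startsWith(groups[[unclass(hp)[["a1"]]]], "a")))
  expect_true(all(startsWith(groups[[unclass(hp)[["b1"]]]], "b")))
  # no 2-module partition beats the planted one (exhaustive over splits)
  q_best <- hard_modularity(net, hp)
  nodes <- net$nodes
  for (code in 0:(2^10 - 1)) {
    asg <- as.integer(intToBits(code)[1:10]) + 1L
    if (length(unique(asg)) < 2) next
    q <- hard_modularity(net, new_hard_partition(setNames(asg, nodes)))
    expect_lte(q, q_best + 1e-12)
  }

  k4 <- net_from_lines(c("a b", "a c", "a d", "b c", "b d", "c d"))
  expect_equal(max(unclass(greedy_hard_partition(k4, seed = 5))), 1L)

  expect_identical(greedy_hard_partition(net, seed = 9),
                   greedy_hard_partition(net, seed = 9))
})

test_that("jaccard obeys its definition and properties", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard(character(0), character(0)), 1)
  set.seed(4)
  for (rep in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    j <- jaccard(a, b)
    expect_identical(j, jaccard(b, a))
    expect_gte(j, 0)
    expect_lte(j, 1)
    expect_identical(j == 1, setequal(a, b))
  }
})
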