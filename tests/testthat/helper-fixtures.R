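# Shared fixtures and independent oracles, all built in code.

# write an edge list to a temp file and parse it
net_from_lines <- function(lines, weighted = NA) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  writeLines(lines, f)
  read_edgelist(f, weighted = weighted)
}

# two triangles {a,b,c} and {d,e,f} bridged by the edge c-d
two_triangle <- function() {
  net <- net_from_lines(c("a b", "a c", "b c", "c d", "d e", "d f", "e f"))
  hp <- new_hard_partition(c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L, f = 2L))
  list(net = net, hp = hp, roles = classify_nodes(net, hp))
}

# independent textbook modularity oracle (loop-free graphs):
#   Q = (1 / 2L) * sum_ij [ a_ij - s_i s_j / 2L ] delta(c_i, c_j)
# evaluated over the full double sum with a_ij the symmetric adjacency.
textbook_modularity <- function(net, hp) {
  stopifnot(all(net$loops == 0))
  n <- length(net$nodes)
  A <- matrix(0, n, n)
  e <- net$edges
  A[cbind(e$i, e$j)] <- e$w
  A[cbind(e$j, e$i)] <- e$w
  s <- as.numeric(net$strength)
  cl <- unclass(hp)[net$nodes]
  twoL <- 2 * net$L
  delta <- outer(cl, cl, "==")
  sum((A - outer(s, s) / twoL) * delta) / twoL
}

# random connected loop-free instance: Erdos-Renyi main component plus a
# greedy hard partition; NULL if degenerate (single module)
rand_instance <- function(seed, n = 10, p = 0.35) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  sel <- runif(nrow(pairs)) < p
  if (sum(sel) < 2) return(NULL)
  lines <- paste0("v", sprintf("%02d", pairs[sel, 1]), " ",
                  "v", sprintf("%02d", pairs[sel, 2]))
  net <- main_component(net_from_lines(lines))
  if (length(net$nodes) < 4) return(NULL)
  hp <- greedy_hard_partition(net, seed = seed)
  if (max(unclass(hp)) < 2) return(NULL)
  list(net = net, hp = hp, roles = classify_nodes(net, hp))
}

# degrees of freedom of the conversion problem: number of flippable
# (connector, candidate-module) pairs
instance_dof <- function(roles) {
  sum(lengths(roles$candidates))
}

# collect random instances with bounded degrees of freedom
collect_instances <- function(n_wanted, max_dof = 12, seed_start = 1,
                              n = 10, p = 0.35) {
  out <- list()
  seed <- seed_start
  while (length(out) < n_wanted && seed < seed_start + 4000) {
    inst <- rand_instance(seed, n = n, p = p)
    if (!is.null(inst) &&
        length(inst$roles$candidates) >= 1 &&
        instance_dof(inst$roles) <= max_dof) {
      out[[length(out) + 1]] <- inst
    }
    seed <- seed + 1
  }
  out
}
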